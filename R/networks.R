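#' Construct an interactome
#'
#' An undirected gene interaction graph: no self-loops, no duplicate
#' unordered pairs. Edges carry a directness attribute (direct physical vs
#' indirect/literature relationship) and a supporting reference count; both
#' kinds count equally in all overlay computations.
#'
#' @param edges data.frame with columns \code{a}, \code{b} and optionally
#'   \code{directness} (\code{"direct"}/\code{"indirect"}) and \code{n_refs}.
#' @return object of class \code{"interactome"} with \code{edges} (unordered
#'   pairs, a < b) and \code{nodes}.
#' @export
interactome <- function(edges) {
  if (!all(c("a", "b") %in% names(edges))) stop_bt("edges need columns a and b")
  a <- normalize_genes(edges$a)
  b <- normalize_genes(edges$b)
  if (any(a == b)) stop_bt("self-loop(s) on: %s",
                           paste(unique(a[a == b]), collapse = ", "))
  lo <- pmin(a, b); hi <- pmax(a, b)
  e <- data.frame(a = lo, b = hi,
                  directness = if ("directness" %in% names(edges))
                    as.character(edges$directness) else "direct",
                  n_refs = if ("n_refs" %in% names(edges))
                    as.integer(edges$n_refs) else 1L,
                  stringsAsFactors = FALSE)
  bad <- !e$directness %in% c("direct", "indirect")
  if (any(bad)) stop_bt("directness must be 'direct' or 'indirect'")
  if (any(e$n_refs < 1)) stop_bt("every edge needs at least one reference")
  e <- e[!duplicated(paste(e$a, e$b)), , drop = FALSE]
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, nodes = sort(unique(c(e$a, e$b)))),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read an interactome edge list
#'
#' Three-column TSV (SIF-compatible): geneA, geneB, directness; an optional
#' fourth column gives the reference count.
#'
#' @param path TSV path (a header line \code{a<TAB>b...} is detected).
#' @return an [interactome()].
#' @export
read_interactome <- function(path) {
  if (!file.exists(path)) stop_bt("file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  # a literal lowercase "a<TAB>b" first row is a header (gene symbols are
  # normalized to uppercase on write, so data rows never collide)
  if (nrow(df) > 0 && identical(as.character(df[1, 1]), "a") &&
      identical(as.character(df[1, 2]), "b"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop_bt("interactome needs at least two columns")
  names(df)[1:2] <- c("a", "b")
  if (ncol(df) >= 3) names(df)[3] <- "directness"
  if (ncol(df) >= 4) names(df)[4] <- "n_refs"
  interactome(df)
}

#' Write an interactome edge list
#'
#' @param net an [interactome()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_interactome <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# named adjacency list
adjacency_list <- function(net) {
  adj <- split(c(net$edges$b, net$edges$a), c(net$edges$a, net$edges$b))
  lapply(adj, unique)
}

node_degree <- function(net, nodes = net$nodes) {
  tab <- table(c(net$edges$a, net$edges$b))
  d <- as.integer(tab[nodes])
  d[is.na(d)] <- 0L
  stats::setNames(d, nodes)
}

# integer adjacency list over net$nodes, neighbor lists sorted
int_adjacency <- function(net) {
  id <- stats::setNames(seq_along(net$nodes), net$nodes)
  a <- id[net$edges$a]; b <- id[net$edges$b]
  adj <- vector("list", length(net$nodes))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  lapply(adj, function(z) sort(unique(z)))
}

# connected component labels (integer) over an integer adjacency list
int_components <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nxt <- unlist(adj[frontier])
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- unique(nxt)
    }
  }
  comp
}

# exact best module on a small component: connected node set of size <=
# max_size maximizing (focus count, -size, lexicographic member string)
exact_module <- function(adj, nodes, comp_ids, focus_ids, max_size) {
  best <- NULL
  best_nf <- 0L
  best_size <- max_size + 1L
  best_key <- ""
  seen <- new.env(hash = TRUE, parent = emptyenv())
  consider <- function(set) {
    nf <- sum(set %in% focus_ids)
    if (nf == 0L) return()
    key <- paste(nodes[set], collapse = ",")
    if (nf > best_nf ||
        (nf == best_nf && (length(set) < best_size ||
                           (length(set) == best_size && key < best_key)))) {
      best <<- set; best_nf <<- nf
      best_size <<- length(set); best_key <<- key
    }
  }
  expand <- function(set) {
    key <- paste(set, collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    consider(set)
    if (length(set) >= max_size) return()
    nbrs <- setdiff(sort(unique(unlist(adj[set]))), set)
    nbrs <- nbrs[nbrs %in% comp_ids]
    for (v in nbrs) expand(sort(c(set, v)))
  }
  for (f in sort(focus_ids)) expand(f)
  best
}

# heuristic module on a large component: seed at the highest-degree
# unassigned focus gene, then repeatedly attach the nearest unassigned
# focus gene along a lexicographically deterministic shortest path
steiner_module <- function(adj, nodes, members, pool, max_size) {
  repeat {
    # BFS from the member set, deterministic parents
    n <- length(adj)
    dist <- rep(NA_integer_, n)
    parent <- integer(n)
    frontier <- sort(members)
    dist[frontier] <- 0L
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.na(dist[v])) {
            dist[v] <- dist[u] + 1L
            parent[v] <- u
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- sort(unique(nxt))
    }
    cand <- pool[!pool %in% members & !is.na(dist[pool])]
    cand <- cand[length(members) + dist[cand] <= max_size]
    if (length(cand) == 0) break
    o <- order(dist[cand], nodes[cand])
    tgt <- cand[o[1]]
    path <- tgt
    while (dist[path[1]] > 1L) path <- c(parent[path[1]], path)
    members <- sort(unique(c(members, path)))
    pool <- setdiff(pool, members)
  }
  members
}

#' Grow focus-gene interaction modules
#'
#' Deterministic emulation of knowledge-base focus-network construction
#' (the original algorithm is proprietary). Modules are extracted
#' best-first: at each step the candidate module maximizing the number of
#' recruited unassigned focus genes (ties: smaller module, then
#' lexicographic member order) is appended and its focus genes marked
#' assigned. Within a connected component of at most \code{exact_limit}
#' nodes the candidate is the exact optimum over all connected subgraphs of
#' size \code{max_size} or less; on larger components it is grown from the
#' highest-degree unassigned focus gene by repeatedly attaching the nearest
#' unassigned focus gene along a shortest path (non-focus connector genes
#' are admitted as path nodes). All tie-breaks are lexicographic, so the
#' result is a deterministic function of the inputs. Focus genes with no
#' interactome edge are reported in the \code{"unconnected"} attribute, not
#' assigned.
#'
#' @param focus a [gene_set()] or character vector of focus genes.
#' @param net an [interactome()].
#' @param max_size maximum module size (default 35).
#' @param max_modules maximum number of modules (default unlimited).
#' @param exact_limit component size up to which the exact bounded search is
#'   used (default 15).
#' @param source label stored on each module (\code{"all_genes"} or
#'   \code{"high_genes"}).
#' @return list of modules, each a list with \code{id}, \code{members},
#'   \code{focus_members}, \code{source}; attributes \code{"unconnected"}
#'   and \code{"unassigned"} report focus genes left out.
#' @export
build_focus_modules <- function(focus, net, max_size = 35,
                                max_modules = Inf, exact_limit = 15,
                                source = "all_genes") {
  all_focus <- as_members(focus)
  fg <- intersect(all_focus, net$nodes)
  deg <- node_degree(net)
  connected <- fg[deg[fg] > 0]
  if (length(connected) == 0)
    stop_bt("no focus gene has an interactome edge")
  adj <- int_adjacency(net)
  nodes <- net$nodes
  comp <- int_components(adj)
  unassigned <- sort(match(connected, nodes))
  modules <- list()
  while (length(unassigned) > 0 && length(modules) < max_modules) {
    comps <- unique(comp[unassigned])
    best <- NULL; best_nf <- -1L; best_size <- Inf; best_key <- ""
    for (cp in comps) {
      comp_ids <- which(comp == cp)
      pool <- intersect(unassigned, comp_ids)
      cand <- if (length(comp_ids) <= exact_limit) {
        exact_module(adj, nodes, comp_ids, pool, max_size)
      } else {
        seed <- pool[order(-deg[nodes[pool]], nodes[pool])][1]
        steiner_module(adj, nodes, seed, setdiff(pool, seed), max_size)
      }
      if (is.null(cand)) next
      nf <- sum(cand %in% unassigned)
      key <- paste(nodes[cand], collapse = ",")
      if (nf > best_nf ||
          (nf == best_nf && (length(cand) < best_size ||
                             (length(cand) == best_size && key < best_key)))) {
        best <- cand; best_nf <- nf
        best_size <- length(cand); best_key <- key
      }
    }
    if (is.null(best)) break
    members <- sort(nodes[best])
    modules[[length(modules) + 1]] <- list(
      id = sprintf("M%02d", length(modules) + 1),
      members = members,
      focus_members = intersect(members, all_focus),
      source = source)
    unassigned <- setdiff(unassigned, best)
  }
  attr(modules, "unconnected") <- sort(setdiff(all_focus, connected))
  attr(modules, "unassigned") <- sort(nodes[unassigned])
  modules
}

#' Count interactome edges between two modules
#'
#' Counts interactome interactions linking module A to module B. With the
#' default shared-member convention a gene present in both modules
#' contributes its edges to either side, but edges lying wholly inside the
#' intersection are not counted (avoiding double counting); with
#' \code{shared = "exclude"} only edges between exclusive members count.
#'
#' @param A,B modules (lists with \code{members}) or character vectors.
#' @param net an [interactome()].
#' @param shared \code{"count"} (default) or \code{"exclude"}.
#' @return integer edge count.
#' @export
inter_module_edges <- function(A, B, net, shared = c("count", "exclude")) {
  shared <- match.arg(shared)
  ma <- if (is.list(A)) A$members else A
  mb <- if (is.list(B)) B$members else B
  same_id <- is.list(A) && is.list(B) && !is.null(A$id) && identical(A$id, B$id)
  if (same_id || identical(A, B)) stop_bt("modules must differ")
  ea <- net$edges$a; eb <- net$edges$b
  if (shared == "count") {
    both <- intersect(ma, mb)
    cross <- ((ea %in% ma & eb %in% mb) | (ea %in% mb & eb %in% ma)) &
      !(ea %in% both & eb %in% both)
  } else {
    xa <- setdiff(ma, mb); xb <- setdiff(mb, ma)
    cross <- (ea %in% xa & eb %in% xb) | (ea %in% xb & eb %in% xa)
  }
  sum(cross)
}

#' Overlay modules into a meta-graph
#'
#' Nodes are gene modules; edge weights count interactome interactions
#' between module pairs. Orphaned modules (no interactions with any other
#' module) are excluded and listed.
#'
#' @param modules list of >= 2 modules from [build_focus_modules()] (or
#'   lists with \code{id} and \code{members}).
#' @param net an [interactome()].
#' @param shared shared-member convention, see [inter_module_edges()].
#' @return object of class \code{"meta_graph"}: \code{modules} (retained),
#'   \code{weights} (data.frame from, to, weight; weight > 0 only),
#'   \code{orphans} (excluded module ids).
#' @export
overlay_meta_graph <- function(modules, net, shared = c("count", "exclude")) {
  shared <- match.arg(shared)
  if (length(modules) < 2) stop_bt("need at least two modules to overlay")
  ids <- vapply(modules, function(m) m$id, "")
  if (anyDuplicated(ids)) stop_bt("module ids must be unique")
  pairs <- utils::combn(length(modules), 2)
  w <- apply(pairs, 2, function(ij)
    inter_module_edges(modules[[ij[1]]], modules[[ij[2]]], net, shared = shared))
  weights <- data.frame(from = ids[pairs[1, ]], to = ids[pairs[2, ]],
                        weight = as.integer(w), stringsAsFactors = FALSE)
  weights <- weights[weights$weight > 0, , drop = FALSE]
  strength <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(weights))) {
    strength[weights$from[i]] <- strength[weights$from[i]] + weights$weight[i]
    strength[weights$to[i]] <- strength[weights$to[i]] + weights$weight[i]
  }
  orphans <- ids[strength == 0]
  keep <- !ids %in% orphans
  rownames(weights) <- NULL
  structure(list(modules = modules[keep], weights = weights,
                 orphans = orphans),
            class = "meta_graph")
}

#' @export
print.meta_graph <- function(x, ...) {
  cat(sprintf("meta_graph: %d modules, %d weighted edges, %d orphan(s) excluded\n",
              length(x$modules), nrow(x$weights), length(x$orphans)))
  invisible(x)
}

#' Rank modules by meta-graph centrality
#'
#' Strength is the sum of incident inter-module interaction counts; ties
#' break by degree (number of partner modules), then module id.
#'
#' @param meta a [overlay_meta_graph()] result.
#' @param k number of top modules to return.
#' @return data.frame: module, strength, degree, in rank order.
#' @export
central_modules <- function(meta, k = length(meta$modules)) {
  if (k <= 0) stop_bt("k must be positive")
  ids <- vapply(meta$modules, function(m) m$id, "")
  if (length(ids) == 0) stop_bt("meta-graph has no modules")
  strength <- stats::setNames(numeric(length(ids)), ids)
  degree <- stats::setNames(integer(length(ids)), ids)
  for (i in seq_len(nrow(meta$weights))) {
    f <- meta$weights$from[i]; t <- meta$weights$to[i]
    strength[f] <- strength[f] + meta$weights$weight[i]
    strength[t] <- strength[t] + meta$weights$weight[i]
    degree[f] <- degree[f] + 1L
    degree[t] <- degree[t] + 1L
  }
  o <- order(-strength, -degree, ids)
  out <- data.frame(module = ids[o], strength = unname(strength[o]),
                    degree = unname(degree[o]), stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Rank hub genes within a module
#'
#' Genes ranked by degree within the module's induced interactome subgraph;
#' ties break lexicographically. Members absent from the interactome are
#' tolerated with a warning (degree 0).
#'
#' @param module a module (list with \code{members}) or character vector.
#' @param net an [interactome()].
#' @param k number of genes to return (default all members).
#' @return data.frame: gene, degree, in rank order.
#' @export
hub_genes <- function(module, net, k = NULL) {
  members <- if (is.list(module)) module$members else module
  if (length(members) == 0) stop_bt("empty module")
  missing <- setdiff(members, net$nodes)
  if (length(missing) > 0)
    warning(sprintf("module member(s) absent from interactome: %s",
                    paste(missing, collapse = ", ")))
  inmod <- net$edges$a %in% members & net$edges$b %in% members
  tab <- table(factor(c(net$edges$a[inmod], net$edges$b[inmod]),
                      levels = sort(members)))
  out <- data.frame(gene = names(tab), degree = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k %||% nrow(out))
}

#' Write a meta-graph edge list
#'
#' TSV edge list (from, to, weight) plus a node attribute block prefixed
#' with \code{#node}, GraphML-convertible.
#'
#' @param meta a [overlay_meta_graph()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_meta_graph <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta$modules)
    writeLines(sprintf("#node\t%s\tsize=%d\tfocus=%d\tsource=%s",
                       m$id, length(m$members), length(m$focus_members),
                       m$source %||% "na"), con)
  utils::write.table(meta$weights, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
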