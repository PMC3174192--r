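test_that("interactome construction validates and canonicalizes edges", {
  e <- data.frame(a = c("b", "a", "a"), b = c("a", "b", "c"))
  net <- interactome(e)  # unordered duplicates collapse
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$nodes, c("A", "B", "C"))
  expect_error(interactome(data.frame(a = "x", b = "x")), "self-loop")
  expect_error(interactome(data.frame(a = "x", b = "y", directness = "odd")),
               "directness")
  # TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(net, path)
  expect_equal(read_interactome(path)$edges, net$edges)
})

test_that("module construction recruits focus genes through connectors", {
  net <- interactome(data.frame(a = c("A", "X"), b = c("X", "B")))
  mods <- build_focus_modules(c("A", "B"), net)
  expect_length(mods, 1L)
  expect_equal(mods[[1]]$members, c("A", "B", "X"))
  expect_equal(mods[[1]]$focus_members, c("A", "B"))
  # focus genes in disconnected components yield separate modules
  net2 <- interactome(data.frame(a = c("A", "C"), b = c("B", "D")))
  mods2 <- build_focus_modules(c("A", "C"), net2)
  expect_length(mods2, 2L)
  # unconnected focus genes are reported, not assigned
  net3 <- interactome(data.frame(a = "A", b = "B"))
  mods3 <- build_focus_modules(c("A", "LONER"), net3)
  expect_equal(attr(mods3, "unconnected"), "LONER")
  expect_error(build_focus_modules("LONER", net3), "no focus gene")
})

test_that("module construction attains the exhaustive optimum on small graphs", {
  set.seed(77)
  n_run <- 0
  while (n_run < 80) {
    n <- sample(8:12, 1)
    net <- random_toy_net(n, sample(n:(2 * n), 1))
    if (is.null(net)) next
    focus <- sample(sprintf("N%02d", seq_len(n)), 3)
    if (!any(focus %in% net$nodes)) next
    n_run <- n_run + 1
    opt <- best_subgraph_oracle(net, focus, kmax = 5)
    mods <- build_focus_modules(focus, net, max_size = 5)
    nf <- vapply(mods, function(m) length(m$focus_members), 0L)
    expect_equal(max(nf), opt[1])
    expect_equal(min(vapply(mods, function(m) length(m$members), 0L)[nf == max(nf)]),
                 opt[2])
  }
})

test_that("inter-module counts follow the shared-member convention", {
  net <- interactome(data.frame(a = c("A", "B", "A"), b = c("C", "D", "D")))
  expect_equal(inter_module_edges(c("A", "B"), c("C", "D"), net), 3L)
  expect_equal(inter_module_edges(c("A", "B"), c("E", "F"), net), 0L)
  # symmetric
  expect_equal(inter_module_edges(c("C", "D"), c("A", "B"), net), 3L)
  # shared member contributes its cross edges, intersection-internal do not
  net2 <- interactome(data.frame(a = c("S", "S", "A"), b = c("A", "B", "T")))
  A <- c("A", "S"); B <- c("B", "S", "T")
  # edges: S-A (S in both, A in A only -> counts), S-B (counts), A-T (counts)
  expect_equal(inter_module_edges(A, B, net2), 3L)
  expect_equal(inter_module_edges(A, B, net2, shared = "exclude"), 1L)
})

test_that("inter-module counts equal the brute-force double loop", {
  set.seed(55)
  for (i in 1:150) {
    net <- random_toy_net(12, sample(8:24, 1))
    if (is.null(net)) next
    nodes <- net$nodes
    A <- sample(nodes, sample(2:5, 1))
    B <- sample(nodes, sample(2:5, 1))
    if (setequal(A, B)) next
    expect_equal(inter_module_edges(A, B, net),
                 cross_edges_oracle(A, B, net$edges))
  }
})

test_that("meta-graph overlay excludes orphans and keeps weights symmetric", {
  net <- interactome(data.frame(a = c("A", "C"), b = c("C", "B")))
  mods <- list(list(id = "M1", members = c("A")),
               list(id = "M2", members = c("B", "C")),
               list(id = "M3", members = c("Z")))
  meta <- overlay_meta_graph(mods, net)
  expect_equal(meta$orphans, "M3")
  expect_length(meta$modules, 2L)
  expect_equal(meta$weights$weight, 1L)
  expect_error(overlay_meta_graph(mods[1], net), "two modules")
  # relabeling/reordering invariance of the weight multiset
  meta2 <- overlay_meta_graph(mods[c(2, 1, 3)], net)
  expect_equal(sort(meta2$weights$weight), sort(meta$weights$weight))
  expect_equal(sort(meta2$orphans), sort(meta$orphans))
})

test_that("module centrality ranks by strength, degree, then id", {
  mk <- function(id) list(id = id, members = id)
  meta <- list(modules = lapply(c("HUB", "P1", "P2", "P3"), mk),
               weights = data.frame(from = "HUB", to = c("P1", "P2", "P3"),
                                    weight = c(2L, 2L, 2L)),
               orphans = character(0))
  class(meta) <- "meta_graph"
  r <- central_modules(meta, 2)
  expect_equal(r$module[1], "HUB")
  expect_equal(r$strength[1], 6)
  # equal strength, higher degree wins
  meta2 <- list(modules = lapply(c("A", "B", "C", "D"), mk),
                weights = data.frame(from = c("A", "B", "B", "C"),
                                     to = c("D", "C", "D", "D"),
                                     weight = c(4L, 2L, 2L, 1L)),
                orphans = character(0))
  class(meta2) <- "meta_graph"
  r2 <- central_modules(meta2, 4)
  # D leads on strength; A and B tie at strength 4, B has degree 2 -> B first
  expect_equal(r2$module, c("D", "B", "A", "C"))
  expect_error(central_modules(meta2, 0), "positive")
  # ranking equals a brute-force sort on the weight matrix
  ids <- vapply(meta2$modules, `[[`, "", "id")
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  for (i in seq_len(nrow(meta2$weights)))
    w[meta2$weights$from[i], meta2$weights$to[i]] <-
      w[meta2$weights$to[i], meta2$weights$from[i]] <- meta2$weights$weight[i]
  o <- order(-rowSums(w), -rowSums(w > 0), ids)
  expect_equal(r2$module, ids[o])
})

test_that("hub ranking uses within-module degree with lexicographic ties", {
  star <- interactome(data.frame(a = "HUB", b = sprintf("L%d", 1:5)))
  r <- hub_genes(c("HUB", sprintf("L%d", 1:5)), star)
  expect_equal(r$gene[1], "HUB")
  expect_equal(r$degree[1], 5L)
  # clique: all tie, identifier order
  cl <- t(combn(c("A", "B", "C"), 2))
  clique <- interactome(data.frame(a = cl[, 1], b = cl[, 2]))
  r2 <- hub_genes(c("A", "B", "C"), clique)
  expect_equal(r2$gene, c("A", "B", "C"))
  expect_warning(hub_genes(c("A", "GHOST"), clique), "GHOST")
  expect_error(hub_genes(character(0), clique), "empty")
})

test_that("degrees agree with igraph on a random graph", {
  skip_if_not_installed("igraph")
  set.seed(99)
  net <- random_toy_net(30, 60)
  g <- igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE)
  deg_ig <- igraph::degree(g)
  r <- hub_genes(net$nodes, net)
  expect_equal(r$degree, unname(deg_ig[r$gene]))
})
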