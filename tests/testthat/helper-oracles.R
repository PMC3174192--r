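# Small fixture builders and independent oracles used across the suite.

# atlas from a plain matrix
toy_atlas <- function(values, regions, ages, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  braintiers::expression_atlas(m, regions = regions, ages = ages)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# right-tail hypergeometric by direct combinatorial enumeration,
# independent of phyper: P(X >= a) for X ~ Hyper(N, K, n)
hyper_tail_oracle <- function(a, K, N, n) {
  ks <- a:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# hand-applied Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force inter-module interaction count: plain double loop over edges
cross_edges_oracle <- function(A, B, edges) {
  both <- intersect(A, B)
  n <- 0L
  for (i in seq_len(nrow(edges))) {
    u <- edges$a[i]; v <- edges$b[i]
    crosses <- (u %in% A && v %in% B) || (u %in% B && v %in% A)
    internal <- u %in% both && v %in% both
    if (crosses && !internal) n <- n + 1L
  }
  n
}

# exhaustive best connected subgraph of size <= kmax containing >= 1 focus
# gene, maximizing (focus count, then -size); returns c(n_focus, size)
best_subgraph_oracle <- function(net, focus, kmax = 5) {
  adj <- lapply(split(c(net$edges$b, net$edges$a),
                      c(net$edges$a, net$edges$b)), unique)
  best <- c(0L, kmax + 1L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  expand <- function(set) {
    key <- paste(sort(set), collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    nf <- sum(set %in% focus)
    if (nf > best[1] || (nf == best[1] && length(set) < best[2]))
      best <<- c(nf, length(set))
    if (length(set) == kmax) return()
    for (nb in setdiff(unique(unlist(adj[set])), set)) expand(c(set, nb))
  }
  for (n in names(adj)) expand(n)
  best
}

# random undirected toy graph as an interactome (uppercase node names)
random_toy_net <- function(n_nodes, n_draws) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  a <- sample(nodes, n_draws, replace = TRUE)
  b <- sample(nodes, n_draws, replace = TRUE)
  ok <- a != b
  if (!any(ok)) return(NULL)
  braintiers::interactome(data.frame(a = a[ok], b = b[ok]))
}
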