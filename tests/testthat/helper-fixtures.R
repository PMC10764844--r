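# Small deterministic fixture graphs used across the suite.

triangle_graph <- function() {
  graph_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
}

star_graph <- function(n_leaves = 3) {
  leaves <- paste0("l", seq_len(n_leaves))
  graph_from_edges(cbind("c", leaves))
}

cycle_graph <- function(n) {
  nodes <- as.character(seq_len(n))
  graph_from_edges(cbind(nodes, nodes[c(2:n, 1)]), nodes = nodes)
}

complete_graph <- function(n) {
  nodes <- as.character(seq_len(n))
  graph_from_edges(t(combn(nodes, 2)), nodes = nodes)
}

# chain of nt triangles sharing consecutive corner nodes: at patch scale
# k = 3 its patches are exactly the triangle and the 3-chain
triangle_chain_graph <- function(nt) {
  e <- NULL
  for (t in seq_len(nt)) {
    a <- 2 * t - 1; b <- 2 * t; c <- 2 * t + 1
    e <- rbind(e, c(a, b), c(b, c), c(a, c))
  }
  graph_from_edges(cbind(paste0("t", e[, 1]), paste0("t", e[, 2])))
}

# disjoint union of a long path and a triangle chain: exactly two distinct
# patch types at k = 3 (pure chain and triangle)
two_patch_type_graph <- function(n_path = 60, n_tri = 20) {
  tri <- triangle_chain_graph(n_tri)
  pe <- cbind(paste0("p", seq_len(n_path - 1)), paste0("p", seq_len(n_path - 1) + 1))
  te <- cbind(tri$nodes[tri$edges[, 1]], tri$nodes[tri$edges[, 2]])
  graph_from_edges(rbind(te, pe))
}

edge_set_keys_for_test <- function(g) {
  u <- g$nodes[g$edges[, 1]]; v <- g$nodes[g$edges[, 2]]
  paste(pmin(u, v), pmax(u, v))
}

# empirical frequency table of sampled paths against an enumeration oracle
path_key <- function(paths) apply(paths, 1, paste, collapse = "-")

expect_uniform_chisq <- function(observed_counts, n_categories, p_min = 0.01) {
  counts <- rep(0, n_categories)
  counts[seq_along(observed_counts)] <- observed_counts
  pval <- stats::chisq.test(counts, p = rep(1 / n_categories, n_categories))$p.value
  expect_gt(pval, p_min)
}
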