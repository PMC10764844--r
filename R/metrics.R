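## Accuracy and diagnostic metrics.

## Canonical unordered-pair keys ("u|v" with sorted labels) for edge sets
## given as a netdict_graph or a two-column matrix of labels.
edge_set_keys <- function(e) {
  if (inherits(e, "netdict_graph")) {
    u <- e$nodes[e$edges[, 1]]; v <- e$nodes[e$edges[, 2]]
  } else {
    if (is.data.frame(e)) e <- as.matrix(e)
    if (length(e) == 0) return(character(0))
    u <- as.character(e[, 1]); v <- as.character(e[, 2])
  }
  unique(paste(pmin(u, v), pmax(u, v), sep = "\r"))
}

#' Jaccard index of two edge sets
#'
#' Number of edges in the intersection divided by the number of edges in the
#' union; 1 when both sets are empty.
#'
#' @param e1,e2 Edge sets: \code{netdict_graph} objects or two-column
#'   matrices of node labels.
#' @return Value in [0, 1].
#' @export
jaccard_index <- function(e1, e2) {
  k1 <- edge_set_keys(e1); k2 <- edge_set_keys(e2)
  un <- length(union(k1, k2))
  if (un == 0) return(1)
  length(intersect(k1, k2)) / un
}

#' Rand index of two edge sets
#'
#' Fraction of unordered node pairs on which the two edge indicators agree.
#'
#' @param e1,e2 Edge sets as in \code{\link{jaccard_index}}.
#' @param nodes Node universe (character vector); defaults to the union of
#'   nodes when graphs are supplied.
#' @return Value in [0, 1].
#' @export
rand_index <- function(e1, e2, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- character(0)
    if (inherits(e1, "netdict_graph")) nodes <- union(nodes, e1$nodes)
    if (inherits(e2, "netdict_graph")) nodes <- union(nodes, e2$nodes)
    if (length(nodes) == 0) stop("`nodes` required when edge sets are bare matrices")
  }
  n <- length(nodes)
  total <- choose(n, 2)
  if (total == 0) return(1)
  k1 <- edge_set_keys(e1); k2 <- edge_set_keys(e2)
  # self-pairs are not part of the pair universe
  k1 <- k1[!self_key(k1)]; k2 <- k2[!self_key(k2)]
  disagree <- length(union(k1, k2)) - length(intersect(k1, k2))
  (total - disagree) / total
}

self_key <- function(keys) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  vapply(parts, function(p) p[1] == p[2], logical(1))
}

wgraph_key_weights <- function(w) {
  if (inherits(w, "netdict_graph")) w <- as_weighted(w)
  stopifnot(inherits(w, "netdict_wgraph"))
  u <- w$nodes[w$pairs[, 1]]; v <- w$nodes[w$pairs[, 2]]
  setNames(w$weight, paste(pmin(u, v), pmax(u, v), sep = "\r"))
}

#' Weighted Jaccard distance between two weighted graphs
#'
#' \deqn{1 - \sum_{pairs} \min(w_1, w_2) / \sum_{pairs} \max(w_1, w_2)}
#' over the union of weighted pairs (absent pairs have weight 0). On binary
#' weights this reduces exactly to 1 minus the Jaccard index of the edge
#' sets; two all-zero graphs have distance 0.
#'
#' @param w1,w2 \code{netdict_wgraph} (or binary \code{netdict_graph})
#'   objects; pairs are matched by node label.
#' @return Value in [0, 1].
#' @export
weighted_jaccard_distance <- function(w1, w2) {
  a <- wgraph_key_weights(w1)
  b <- wgraph_key_weights(w2)
  keys <- union(names(a), names(b))
  if (length(keys) == 0) return(0)
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  smax <- sum(pmax(av, bv))
  if (smax == 0) return(0)
  1 - sum(pmin(av, bv)) / smax
}

#' Mean local clustering coefficient
#'
#' Mean over all nodes of \eqn{2 T_v / (d_v (d_v - 1))}, where \eqn{T_v} is
#' the number of triangles through v and \eqn{d_v} its degree; nodes of
#' degree < 2 contribute 0 and self-edges are ignored.
#'
#' @param g A \code{netdict_graph}.
#' @return Value in [0, 1].
#' @export
mean_local_clustering <- function(g) {
  stopifnot(inherits(g, "netdict_graph"))
  n <- length(g$nodes)
  A <- graph_adjacency(g)
  diag(A) <- 0
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- setdiff(g$adj[[v]], v)
    d <- length(nb)
    if (d < 2) next
    tri <- sum(A[nb, nb]) / 2
    cc[v] <- 2 * tri / (d * (d - 1))
  }
  mean(cc)
}

#' Degree histogram
#'
#' Counts of nodes by degree; a self-edge adds 2 to its node's degree.
#'
#' @param g A \code{netdict_graph}.
#' @return Named integer vector mapping degree to node count.
#' @export
degree_histogram <- function(g) {
  stopifnot(inherits(g, "netdict_graph"))
  d <- graph_degrees(g)
  tab <- table(d)
  setNames(as.integer(tab), names(tab))
}

#' Accuracy report for a thresholded reconstruction
#'
#' Thresholds a weighted reconstruction at \code{theta} (strictly) and
#' compares its edge set with the original graph's.
#'
#' @param g Original \code{netdict_graph}.
#' @param rec \code{netdict_wgraph} reconstruction of \code{g}.
#' @param theta Edge threshold in [0, 1].
#' @return List with \code{jaccard_index}, \code{rand_index}, \code{theta}
#'   and the edge counts (original, reconstructed, intersection, union).
#' @export
reconstruction_accuracy <- function(g, rec, theta = 0.5) {
  gb <- threshold_graph(rec, theta)
  k1 <- edge_set_keys(g); k2 <- edge_set_keys(gb)
  list(jaccard_index = jaccard_index(g, gb),
       rand_index = rand_index(g, gb, nodes = union(g$nodes, gb$nodes)),
       theta = theta,
       n_edges_original = length(k1),
       n_edges_reconstructed = length(k2),
       n_intersection = length(intersect(k1, k2)),
       n_union = length(union(k1, k2)))
}
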