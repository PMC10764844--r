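#' Network reconstruction from a latent-motif dictionary
#'
#' Samples \code{n_paths} uniformly random k-paths of \code{g}, approximates
#' each induced patch by a nonnegative linear combination of the dictionary
#' motifs, and assigns every unordered node pair the mean of its
#' reconstructed entries over all (path, position) incidences. Reconstructed
#' patch entries are clipped to [0, 1] before averaging and diagonal
#' positions are ignored, so the result is a weighted graph with weights in
#' [0, 1]; pairs never covered by a sampled patch are absent (weight 0).
#'
#' With \code{mask_on_chain = TRUE} the on-chain dictionary entries are
#' zeroed, on-chain vector positions are excluded from the coding objective,
#' and reconstructed on-chain positions are discarded, so a pair is scored
#' only through its off-chain appearances.
#'
#' @param g A \code{netdict_graph}.
#' @param dict An \code{ndl} fit, or a bare k^2 x r dictionary matrix.
#' @param n_paths Number of k-paths to sample; default
#'   \code{ceiling(100 * n_edges(g) / (k - 1))} so each edge is covered about
#'   100 times on-chain in expectation.
#' @param lambda Nonnegative L1 penalty used in patch coding.
#' @param mask_on_chain Score pairs only through off-chain appearances.
#' @param seed Optional integer seed.
#' @param batch Paths processed per vectorized block (memory/speed knob).
#' @return A \code{netdict_wgraph} with per-pair mean weights and incidence
#'   counts, and attributes \code{k} and \code{n_paths}.
#' @examples
#' g <- er_graph(40, 0.2, seed = 2)
#' fit <- ndl(g, k = 3, r = 4, iterations = 8, minibatch = 100, seed = 2)
#' rec <- reconstruct(g, fit, n_paths = 2000, seed = 3)
#' acc <- reconstruction_accuracy(g, rec, theta = 0.5)
#' acc$jaccard_index
#' @export
reconstruct <- function(g, dict, n_paths = NULL, lambda = 0,
                        mask_on_chain = FALSE, seed = NULL, batch = 4000) {
  stopifnot(inherits(g, "netdict_graph"))
  W <- if (inherits(dict, "ndl")) dict$W else as.matrix(dict)
  k <- as.integer(round(sqrt(nrow(W))))
  if (k * k != nrow(W)) stop("dictionary rows are not a perfect square")
  if (k < 2) stop("dictionary scale k must be at least 2")
  if (all(W == 0)) stop("dictionary has no nonzero entries")
  if (is.null(n_paths)) n_paths <- ceiling(100 * nrow(g$edges) / (k - 1))
  if (n_paths < 1) stop("`n_paths` must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  if (mask_on_chain) W[on_chain_positions(k), ] <- 0
  code_rows <- setdiff(seq_len(k * k), diag_positions(k))
  if (mask_on_chain) code_rows <- setdiff(code_rows, on_chain_positions(k))

  # unordered patch positions (a, b), a < b, kept for accumulation
  ab <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  if (mask_on_chain) ab <- ab[ab[, 2] - ab[, 1] > 1, , drop = FALSE]
  pos_ab <- (ab[, 2] - 1) * k + ab[, 1]   # entry (a, b)
  pos_ba <- (ab[, 1] - 1) * k + ab[, 2]   # entry (b, a)

  wc <- walk_counts(g, k)
  A <- graph_adjacency(g)
  n <- length(g$nodes)
  keys_l <- list(); vals_l <- list(); cnts_l <- list()
  remaining <- n_paths
  bi <- 0
  while (remaining > 0) {
    b <- min(batch, remaining)
    remaining <- remaining - b
    bi <- bi + 1
    paths <- sample_k_paths(g, k, b, wc = wc)
    X <- patch_matrix(g, paths, A = A)
    H <- code_patches(X, W, lambda = lambda, rows = code_rows)
    Xhat <- pmin(W %*% H, 1)            # entries are >= 0 already
    u <- paths[, ab[, 1], drop = FALSE] # b x npairs node indices
    v <- paths[, ab[, 2], drop = FALSE]
    lo <- pmin(u, v); hi <- pmax(u, v)
    keys_l[[bi]] <- as.vector((lo - 1) * as.double(n) + hi)
    vals_l[[bi]] <- as.vector(t(Xhat[pos_ab, , drop = FALSE] +
                                  Xhat[pos_ba, , drop = FALSE]))
    cnts_l[[bi]] <- rep(2, length(keys_l[[bi]]))
  }
  keys <- unlist(keys_l, use.names = FALSE)
  sums <- rowsum(unlist(vals_l, use.names = FALSE), keys)
  cnts <- rowsum(unlist(cnts_l, use.names = FALSE), keys)
  ukey <- as.double(rownames(sums))
  hi <- as.integer((ukey - 1) %% n + 1)
  lo <- as.integer((ukey - hi) / n + 1)
  wt <- pmin(pmax(sums[, 1] / cnts[, 1], 0), 1)
  out <- new_netdict_wgraph(g$nodes, cbind(lo, hi), as.numeric(wt),
                            count = as.integer(cnts[, 1]))
  attr(out, "k") <- k
  attr(out, "n_paths") <- n_paths
  out
}

#' Monte-Carlo mean patch approximation error
#'
#' Estimates \eqn{E_x \|A_x - \hat A_{x;W}\|_1}, the expected entrywise L1
#' distance over uniformly random k-paths x between the induced patch and
#' its nonnegative linear approximation by the dictionary. Coding uses the
#' same conventions as \code{\link{reconstruct}} (diagonal positions are
#' not part of the least-squares objective), but the L1 norm is taken over
#' all k^2 entries of the raw, unclipped approximation \eqn{W h}: clipping
#' and diagonal skipping are averaging conventions of the reconstruction,
#' not part of the patch approximation error that bounds it.
#'
#' @param g A \code{netdict_graph}.
#' @param dict An \code{ndl} fit or a k^2 x r dictionary matrix.
#' @param n_samples Number of k-paths in the Monte-Carlo estimate.
#' @param lambda Nonnegative L1 penalty used in patch coding.
#' @param mask_on_chain Use the masked-dictionary coding of
#'   \code{\link{reconstruct}}.
#' @param seed Optional integer seed.
#' @return Numeric estimate with attribute \code{se} (standard error).
#' @export
mean_patch_l1_error <- function(g, dict, n_samples = 1000, lambda = 0,
                                mask_on_chain = FALSE, seed = NULL) {
  stopifnot(inherits(g, "netdict_graph"))
  W <- if (inherits(dict, "ndl")) dict$W else as.matrix(dict)
  k <- as.integer(round(sqrt(nrow(W))))
  if (k * k != nrow(W)) stop("dictionary rows are not a perfect square")
  if (!is.null(seed)) set.seed(seed)
  if (mask_on_chain) W[on_chain_positions(k), ] <- 0
  code_rows <- setdiff(seq_len(k * k), diag_positions(k))
  if (mask_on_chain) code_rows <- setdiff(code_rows, on_chain_positions(k))
  paths <- sample_k_paths(g, k, n_samples)
  X <- patch_matrix(g, paths)
  H <- code_patches(X, W, lambda = lambda, rows = code_rows)
  Xhat <- W %*% H
  per_patch <- colSums(abs(X - Xhat))
  est <- mean(per_patch)
  attr(est, "se") <- stats::sd(per_patch) / sqrt(n_samples)
  est
}

#' Coverage-weighted Jaccard distance of a reconstruction
#'
#' Weighted Jaccard distance between a graph and its weighted
#' reconstruction in which every node pair is weighted by its incidence
#' count in the sampled patches (the Monte-Carlo estimate of its coverage
#' probability under uniform k-path sampling):
#' \deqn{1 - \sum_e c_e \min(A_e, R_e) / \sum_e c_e \max(A_e, R_e).}
#' This is the distance controlled by the patch-error bound of
#' \code{\link{reconstruction_error_bound}}: pairs a k-path never covers carry no
#' weight, and on-chain coverage guarantees that at least a 2/k fraction of
#' the total coverage mass lies on true edges, which is what gives the
#' bound its 1/(2(k-1)) constant. The unweighted variant
#' (\code{\link{weighted_jaccard_distance}}) up-weights rarely covered
#' pairs and need not obey the bound.
#'
#' @param g The original \code{netdict_graph}.
#' @param rec A \code{netdict_wgraph} produced by \code{\link{reconstruct}}
#'   (its incidence counts are required).
#' @return Value in [0, 1].
#' @export
coverage_jaccard_distance <- function(g, rec) {
  stopifnot(inherits(rec, "netdict_wgraph"))
  if (is.null(rec$count)) stop("reconstruction lacks incidence counts")
  A <- as.numeric(has_edges(g, rec$pairs[, 1], rec$pairs[, 2]))
  den <- sum(rec$count * pmax(A, rec$weight))
  if (den == 0) return(0)
  1 - sum(rec$count * pmin(A, rec$weight)) / den
}

#' Reconstruction error bound from the patch approximation error
#'
#' The coverage-weighted Jaccard distance between a graph and its weighted
#' reconstruction is bounded by the mean patch L1 approximation error
#' divided by \eqn{2(k - 1)}. This returns the Monte-Carlo estimate of that
#' bound; set \code{check = TRUE} to also reconstruct the network and report
#' the achieved distance (\code{\link{coverage_jaccard_distance}})
#' alongside the bound.
#'
#' @param g A \code{netdict_graph}.
#' @param dict An \code{ndl} fit or a k^2 x r dictionary matrix.
#' @param n_samples Monte-Carlo sample size for the patch error.
#' @param lambda Nonnegative L1 coding penalty.
#' @param seed Optional integer seed.
#' @param check Also run reconstruction and report the achieved distance.
#' @param n_paths Paths used for the reconstruction when \code{check = TRUE}.
#' @return List with \code{bound}, \code{se} (Monte-Carlo standard error of
#'   the bound), \code{l1_error}, and when \code{check = TRUE} also
#'   \code{jaccard_distance} and \code{satisfied} (distance <= bound + 2 se).
#' @export
reconstruction_error_bound <- function(g, dict, n_samples = 1000, lambda = 0,
                           seed = NULL, check = FALSE, n_paths = NULL) {
  W <- if (inherits(dict, "ndl")) dict$W else as.matrix(dict)
  k <- as.integer(round(sqrt(nrow(W))))
  if (!is.null(seed)) set.seed(seed)
  l1 <- mean_patch_l1_error(g, W, n_samples = n_samples, lambda = lambda)
  out <- list(bound = as.numeric(l1) / (2 * (k - 1)),
              se = attr(l1, "se") / (2 * (k - 1)),
              l1_error = as.numeric(l1))
  if (check) {
    rec <- reconstruct(g, W, n_paths = n_paths, lambda = lambda)
    out$jaccard_distance <- coverage_jaccard_distance(g, rec)
    out$uniform_jaccard_distance <-
      weighted_jaccard_distance(as_weighted(g), rec)
    out$satisfied <- out$jaccard_distance <= out$bound + 2 * out$se
  }
  out
}
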