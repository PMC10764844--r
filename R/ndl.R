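#' Network dictionary learning
#'
#' Learns a dictionary of \code{r} latent motifs -- k-node weighted networks
#' with edge weights in [0, 1] -- that approximately span the mesoscale
#' patches of a network at scale \code{k}. At each of \code{iterations}
#' online steps a minibatch of \code{minibatch} uniformly random k-paths is
#' sampled, their induced k x k adjacency patches are column-wise vectorized
#' into a k^2 x N minibatch matrix, coded nonnegatively against the current
#' dictionary, and the dictionary is refit by block coordinate descent on
#' aggregate sufficient statistics weighted by the balanced 1/t schedule of
#' online matrix factorization.
#'
#' @param g A \code{netdict_graph} that admits at least one k-path.
#' @param k Patch scale (nodes per motif), k >= 2.
#' @param r Number of latent motifs.
#' @param iterations Number of online minibatch iterations T.
#' @param minibatch Number of k-paths per minibatch N.
#' @param lambda Nonnegative L1 penalty on patch codes (default 0).
#' @param seed Optional integer seed; with a fixed seed the fit is
#'   bitwise reproducible.
#' @param max_rejections Rejection cap forwarded to the k-path sampler.
#' @return An object of class \code{ndl} with components \code{W} (k^2 x r
#'   dictionary matrix, entries in [0, 1]), \code{k}, \code{r}, \code{P},
#'   \code{Q} (aggregate statistics), \code{iterations}, \code{minibatch},
#'   \code{lambda}, \code{seed}, \code{mean_residual} (mean per-patch L1
#'   coding residual over the final minibatch) and \code{call}.
#' @seealso \code{\link{reconstruct}}, \code{\link{remove_on_chain}},
#'   \code{\link{mean_patch_l1_error}}
#' @examples
#' g <- er_graph(60, 0.15, seed = 1)
#' fit <- ndl(g, k = 4, r = 4, iterations = 10, minibatch = 100, seed = 1)
#' fit
#' motifs(fit)[[1]]
#' @export
ndl <- function(g, k = 21, r = 25, iterations = 100, minibatch = 1000,
                lambda = 0, seed = NULL, max_rejections = 1e6) {
  stopifnot(inherits(g, "netdict_graph"))
  if (k < 2) stop("`k` must be at least 2")
  if (r < 1) stop("`r` must be at least 1")
  if (iterations < 1 || minibatch < 1)
    stop("`iterations` and `minibatch` must be positive")
  if (!is.null(seed)) set.seed(seed)
  wc <- walk_counts(g, k)
  if (wc$total <= 0) stop("graph admits no k-walk at k = ", k)
  A <- graph_adjacency(g)
  W <- matrix(runif(k * k * r), k * k, r)
  P <- matrix(0, r, r)
  Q <- matrix(0, k * k, r)
  mean_residual <- NA_real_
  for (t in seq_len(iterations)) {
    paths <- sample_k_paths(g, k, minibatch, max_rejections = max_rejections,
                            wc = wc)
    X <- patch_matrix(g, paths, A = A)
    H <- code_patches(X, W, lambda = lambda)
    P <- (1 - 1 / t) * P + (1 / t) * tcrossprod(H) / minibatch
    Q <- (1 - 1 / t) * Q + (1 / t) * (X %*% t(H)) / minibatch
    # a motif unused so far keeps its initialization; no per-iteration warning
    W <- suppressWarnings(update_dictionary(W, P, Q))
    if (t == iterations)
      mean_residual <- mean(colSums(abs(X - W %*% H)))
  }
  structure(list(W = W, k = k, r = r, P = P, Q = Q,
                 iterations = iterations, minibatch = minibatch,
                 lambda = lambda, seed = seed,
                 n_nodes = length(g$nodes), n_edges = nrow(g$edges),
                 mean_residual = mean_residual, call = match.call()),
            class = "ndl")
}

#' @method print ndl
#' @export
print.ndl <- function(x, ...) {
  cat("Network dictionary (ndl fit)\n")
  cat("  scale k =", x$k, ", motifs r =", x$r, "\n")
  cat("  learned over", x$iterations, "minibatches of", x$minibatch,
      "k-paths\n")
  if (is.finite(x$mean_residual))
    cat("  mean patch L1 coding residual (last minibatch):",
        signif(x$mean_residual, 4), "\n")
  invisible(x)
}

#' @method summary ndl
#' @export
summary.ndl <- function(object, ...) {
  mot <- motifs(object)
  oc <- on_chain_positions(object$k)
  dg <- diag_positions(object$k)
  off <- setdiff(seq_len(object$k^2), c(oc, dg))
  per_motif <- data.frame(
    motif = seq_len(object$r),
    on_chain_mean = vapply(seq_len(object$r),
                           function(j) mean(object$W[oc, j]), 0),
    off_chain_mean = vapply(seq_len(object$r),
                            function(j) mean(object$W[off, j]), 0),
    total_mass = colSums(object$W)
  )
  out <- list(k = object$k, r = object$r, per_motif = per_motif,
              mean_residual = object$mean_residual)
  class(out) <- "summary.ndl"
  out
}

#' @method print summary.ndl
#' @export
print.summary.ndl <- function(x, ...) {
  cat("Network dictionary: k =", x$k, ", r =", x$r, "\n")
  if (is.finite(x$mean_residual))
    cat("Mean patch L1 coding residual (last minibatch):",
        signif(x$mean_residual, 4), "\n")
  cat("Per-motif weight summary:\n")
  print(format(x$per_motif, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.ndl <- function(object, ...) object$W

#' Latent motifs of a fitted dictionary
#'
#' @param object An \code{ndl} fit.
#' @param symmetrize Average each motif with its transpose (display
#'   convention; learning itself does not enforce symmetry).
#' @return List of r k x k weighted adjacency matrices.
#' @export
motifs <- function(object, symmetrize = TRUE) {
  stopifnot(inherits(object, "ndl"))
  lapply(seq_len(object$r), function(j) {
    L <- devectorize_patch(object$W[, j])
    if (symmetrize) L <- (L + t(L)) / 2
    L
  })
}

#' @export
plot.ndl <- function(x, ncol = ceiling(sqrt(x$r)), ...) {
  mot <- motifs(x)
  nrow_ <- ceiling(x$r / ncol)
  op <- graphics::par(mfrow = c(nrow_, ncol), mar = c(0.5, 0.5, 1.2, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_len(x$r)) {
    L <- mot[[j]][, rev(seq_len(x$k))]
    graphics::image(L, zlim = c(0, 1), axes = FALSE,
                    col = grDevices::gray.colors(64, start = 1, end = 0),
                    main = paste0("L", j), cex.main = 0.8)
  }
  invisible(x)
}

#' Reconstruction from a fitted dictionary
#'
#' \code{predict} on an \code{ndl} fit runs network reconstruction
#' (\code{\link{reconstruct}}) of a graph with the learned motifs.
#'
#' @param object An \code{ndl} fit.
#' @param newdata A \code{netdict_graph} to reconstruct (it need not be the
#'   graph the dictionary was learned from).
#' @param type \code{"weights"} returns the weighted reconstruction;
#'   \code{"graph"} additionally thresholds it at \code{theta}.
#' @param theta Edge threshold used when \code{type = "graph"}.
#' @param ... Passed to \code{\link{reconstruct}} (e.g. \code{n_paths},
#'   \code{mask_on_chain}, \code{seed}).
#' @return A \code{netdict_wgraph} or \code{netdict_graph}.
#' @export
predict.ndl <- function(object, newdata, type = c("weights", "graph"),
                        theta = 0.5, ...) {
  type <- match.arg(type)
  w <- reconstruct(newdata, object, ...)
  if (type == "graph") threshold_graph(w, theta) else w
}

#' Remove on-chain entries from a dictionary
#'
#' Zeroes, in every motif, the entries at on-chain positions (i, i+1) and
#' (i+1, i). Reconstruction with such a masked dictionary scores node pairs
#' only through their off-chain appearances, so the trivially-present
#' on-chain entries of a patch cannot certify the very edges under
#' suspicion in denoising.
#'
#' @param object An \code{ndl} fit or a bare k^2 x r dictionary matrix.
#' @return Object of the same kind with on-chain entries set to 0.
#' @export
remove_on_chain <- function(object) {
  if (inherits(object, "ndl")) {
    object$W[on_chain_positions(object$k), ] <- 0
    return(object)
  }
  k <- as.integer(sqrt(nrow(object)))
  if (k * k != nrow(object)) stop("dictionary rows are not a perfect square")
  object[on_chain_positions(k), ] <- 0
  object
}

#' Connected components of a motif's off-chain graph
#'
#' Binarizes a motif at \code{edge_threshold}, discards on-chain and diagonal
#' entries, and returns the connected-component size distribution of the
#' remaining k-node graph. A descriptive diagnostic for hubs/communities
#' inside latent motifs.
#'
#' @param motif k x k weighted matrix (one element of \code{motifs()}).
#' @param edge_threshold Binarization threshold in [0, 1].
#' @return Integer vector of component sizes (decreasing).
#' @export
motif_communities <- function(motif, edge_threshold = 0.5) {
  if (edge_threshold < 0 || edge_threshold > 1)
    stop("`edge_threshold` must lie in [0, 1]")
  k <- nrow(motif)
  Bm <- (motif + t(motif)) / 2 >= edge_threshold
  diag(Bm) <- FALSE
  for (i in seq_len(k - 1)) {
    Bm[i, i + 1] <- FALSE
    Bm[i + 1, i] <- FALSE
  }
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (Bm[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[ri] <- rj
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  sort(as.integer(table(roots)), decreasing = TRUE)
}
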