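## Exact uniform sampling of k-walks and k-paths.
##
## The target distribution (uniform over all k-walks, hence uniform over
## k-paths after rejection of walks with repeated nodes) is realized by a
## sequential dynamic-programming scheme rather than an MCMC chain: with
## w_j(v) = number of j-step walk extensions starting at v, drawing
## x_1 with probability proportional to w_{k-1}(x_1) and then each successor
## x_{i+1} among the neighbours of x_i with probability proportional to
## w_{k-i-1}(x_{i+1}) gives every k-walk probability 1/total exactly.

#' Exact k-walk count table
#'
#' Computes, for every node v and every number of remaining steps j, the
#' number of j-step walk extensions \eqn{w_j(v)} starting at v, via the
#' recursion \eqn{w_0(v) = 1}, \eqn{w_j(v) = \sum_{u \sim v} w_{j-1}(u)}
#' (self-edges allow the step v to v). The total number of k-walks in the
#' graph is \eqn{\sum_v w_{k-1}(v)}.
#'
#' @param g A \code{netdict_graph}.
#' @param k Walk length in nodes, k >= 2.
#' @return List with \code{counts} (n x k matrix, column j holds
#'   \eqn{w_{j-1}}), \code{total} (number of k-walks) and \code{k}.
#' @export
walk_counts <- function(g, k) {
  stopifnot(inherits(g, "netdict_graph"))
  if (k < 2) stop("`k` must be at least 2")
  n <- length(g$nodes)
  A <- graph_adjacency(g)
  counts <- matrix(0, n, k)
  counts[, 1] <- 1
  for (j in seq_len(k - 1)) {
    counts[, j + 1] <- as.vector(A %*% counts[, j])
  }
  list(counts = counts, total = sum(counts[, k]), k = k)
}

#' Sample uniformly random k-walks
#'
#' Draws \code{n} independent k-walks, each exactly uniform over all k-walks
#' of the graph (sequential sampling from the walk-count table).
#'
#' @param g A \code{netdict_graph}.
#' @param k Walk length in nodes, k >= 2.
#' @param n Number of walks to draw.
#' @param wc Optional precomputed \code{walk_counts(g, k)}.
#' @return An n x k integer matrix of node indices, one walk per row.
#' @export
sample_k_walks <- function(g, k, n, wc = NULL) {
  if (is.null(wc)) wc <- walk_counts(g, k)
  if (wc$total <= 0) stop("graph admits no k-walk at k = ", k)
  nn <- length(g$nodes)
  walks <- matrix(0L, n, k)
  walks[, 1] <- sample.int(nn, n, replace = TRUE, prob = wc$counts[, k])
  for (step in seq_len(k - 1)) {
    wt <- wc$counts[, k - step]
    cur <- walks[, step]
    nxt <- integer(n)
    # walks currently at the same node share a successor distribution, so
    # group them and draw each group's successors in one call
    for (u in unique(cur)) {
      rows <- which(cur == u)
      nbrs <- g$adj[[u]]
      p <- wt[nbrs]
      if (length(nbrs) == 1L) {
        nxt[rows] <- nbrs
      } else {
        nxt[rows] <- nbrs[sample.int(length(nbrs), length(rows),
                                     replace = TRUE, prob = p)]
      }
    }
    walks[, step + 1] <- nxt
  }
  walks
}

#' Sample uniformly random k-paths
#'
#' Draws uniform k-walks and rejects those with repeated nodes, yielding
#' exact uniform samples over all k-paths of the graph.
#'
#' @param g A \code{netdict_graph}.
#' @param k Path length in nodes, k >= 2.
#' @param n Number of paths required.
#' @param max_rejections Abort if more than this many walks are rejected.
#' @param wc Optional precomputed \code{walk_counts(g, k)}.
#' @return An n x k integer matrix of node indices, one path per row, with
#'   attributes \code{rejections} (walks rejected) and \code{acceptance_rate}.
#' @export
sample_k_paths <- function(g, k, n, max_rejections = 1e6, wc = NULL) {
  if (is.null(wc)) wc <- walk_counts(g, k)
  if (wc$total <= 0) stop("graph admits no k-walk at k = ", k)
  out <- matrix(0L, n, k)
  got <- 0L
  rejected <- 0
  drawn <- 0
  batch <- max(n, 256L)
  while (got < n) {
    w <- sample_k_walks(g, k, batch, wc = wc)
    ok <- !apply_any_dup(w)
    rejected <- rejected + sum(!ok)
    drawn <- drawn + batch
    if (rejected > max_rejections)
      stop("rejection cap exceeded while sampling k-paths (acceptance rate ~ ",
           signif((drawn - rejected) / drawn, 3),
           "); consider a smaller k")
    w <- w[ok, , drop = FALSE]
    take <- min(nrow(w), n - got)
    if (take > 0) out[got + seq_len(take), ] <- w[seq_len(take), ]
    got <- got + take
    # adapt the batch to the observed acceptance rate
    acc <- max((drawn - rejected) / drawn, 1e-3)
    batch <- as.integer(min(max(ceiling((n - got) / acc * 1.2), 64), 1e5))
  }
  attr(out, "rejections") <- rejected
  attr(out, "acceptance_rate") <- (drawn - rejected) / drawn
  out
}

## Row-wise anyDuplicated for small k.
apply_any_dup <- function(m) {
  k <- ncol(m)
  dup <- logical(nrow(m))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      dup <- dup | (m[, i] == m[, j])
    }
  }
  dup
}

#' Enumerate all k-paths of a small graph
#'
#' Exhaustive depth-first enumeration of every ordered k-path, intended as a
#' test oracle for the samplers. Refuses to run when the number of paths
#' found exceeds \code{cap}.
#'
#' @param g A \code{netdict_graph}.
#' @param k Path length in nodes.
#' @param cap Maximum number of paths to enumerate before aborting.
#' @return Integer matrix with one path (node indices) per row.
#' @export
enumerate_k_paths <- function(g, k, cap = 1e5) {
  stopifnot(k >= 2)
  acc <- vector("list", 1024)
  cnt <- 0L
  extend <- function(prefix) {
    if (length(prefix) == k) {
      cnt <<- cnt + 1L
      if (cnt > cap) stop("path enumeration cap exceeded (> ", cap, " paths)")
      acc[[cnt]] <<- prefix
      return(invisible())
    }
    for (u in g$adj[[prefix[length(prefix)]]]) {
      if (!(u %in% prefix)) extend(c(prefix, u))
    }
  }
  for (v in seq_along(g$nodes)) extend(v)
  if (cnt == 0L) return(matrix(integer(0), 0, k))
  do.call(rbind, acc[seq_len(cnt)])
}

## Patch matrix for a batch of sampled paths: X is k^2 x B with column t the
## column-wise vectorization of the patch A_{x_t}.
patch_matrix <- function(g, paths, A = NULL) {
  if (is.null(A)) A <- graph_adjacency(g)
  k <- ncol(paths)
  B <- nrow(paths)
  p <- seq_len(k * k) - 1L
  icol <- (p %% k) + 1L   # row index of vector position p+1
  jcol <- (p %/% k) + 1L  # column index
  I <- paths[, icol, drop = FALSE]
  J <- paths[, jcol, drop = FALSE]
  vals <- A[cbind(as.vector(I), as.vector(J))]
  t(matrix(as.numeric(vals), B, k * k))
}
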