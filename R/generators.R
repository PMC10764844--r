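## Random-graph generators. All generators are seed-deterministic and label
## nodes "1".."n" in construction order. Bernoulli-pair models (ER, SBM) are
## drawn by sampling the binomial edge count and then a uniform subset of
## pairs, which is equal in law to independent pair flips.

## decode 1-based linear index over pairs (i < j), grouped by j
decode_pair_index <- function(idx) {
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  j <- ifelse((j - 1) * (j - 2) / 2 >= idx, j - 1, j)
  j <- ifelse(j * (j - 1) / 2 < idx, j + 1, j)
  i <- idx - (j - 1) * (j - 2) / 2
  cbind(i, j)
}

#' Erdos-Renyi random graph
#'
#' G(n, p): each unordered pair of distinct nodes is an edge independently
#' with probability p; no self-edges.
#'
#' @param n Number of nodes (>= 1).
#' @param p Edge probability in [0, 1].
#' @param seed Optional integer seed.
#' @return A \code{netdict_graph} with nodes "1".."n".
#' @export
er_graph <- function(n, p, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  npairs <- n * (n - 1) / 2
  m <- rbinom(1, npairs, p)
  nodes <- as.character(seq_len(n))
  if (m == 0) return(graph_from_edges(matrix(character(0), 0, 2), nodes = nodes))
  idx <- sample(npairs, m)
  ij <- decode_pair_index(idx)
  graph_from_edges(cbind(nodes[ij[, 1]], nodes[ij[, 2]]), nodes = nodes)
}

#' Watts-Strogatz random graph
#'
#' Starts from an n-node ring in which every node is adjacent to its k
#' nearest neighbours (nk/2 edges) and independently rewires each edge with
#' probability p: one of its two ends is detached (chosen with equal
#' probability) and reattached to a uniformly random node, redrawing on
#' self-loops and duplicate edges. The edge count nk/2 is conserved.
#'
#' @param n Number of nodes.
#' @param k Even ring degree, k < n.
#' @param p Rewiring probability in [0, 1].
#' @param seed Optional integer seed.
#' @return A \code{netdict_graph} with nodes "1".."n".
#' @export
ws_graph <- function(n, k, p, seed = NULL) {
  if (k %% 2 != 0) stop("`k` must be even")
  if (k >= n) stop("`k` must be smaller than `n`")
  if (k < 2) stop("`k` must be at least 2")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  i <- rep(seq_len(n), k / 2)
  off <- rep(seq_len(k / 2), each = n)
  j <- ((i + off - 1) %% n) + 1
  edges <- cbind(i, j)
  m <- nrow(edges)
  have <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  for (t in seq_len(m)) assign(ekey(edges[t, 1], edges[t, 2]), TRUE, envir = have)
  rewire <- which(runif(m) < p)
  for (t in rewire) {
    a <- edges[t, 1]; b <- edges[t, 2]
    keep <- if (runif(1) < 0.5) a else b
    repeat {
      newend <- sample.int(n, 1)
      if (newend != keep && !exists(ekey(keep, newend), envir = have,
                                    inherits = FALSE)) break
    }
    rm(list = ekey(a, b), envir = have)
    assign(ekey(keep, newend), TRUE, envir = have)
    edges[t, ] <- c(min(keep, newend), max(keep, newend))
  }
  nodes <- as.character(seq_len(n))
  graph_from_edges(cbind(nodes[edges[, 1]], nodes[edges[, 2]]), nodes = nodes)
}

#' Barabasi-Albert random graph
#'
#' Starts from n0 isolated nodes and adds nodes one at a time, each
#' attaching n0 new edges to distinct existing nodes with probability
#' proportional to their current degree (uniformly when all existing degrees
#' are 0, which happens only for the first arriving node). The final graph
#' has n nodes and n0 (n - n0) edges.
#'
#' @param n Final number of nodes.
#' @param n0 Seed size and edges per arriving node, 1 <= n0 < n.
#' @param seed Optional integer seed.
#' @return A \code{netdict_graph} with nodes "1".."n".
#' @export
ba_graph <- function(n, n0, seed = NULL) {
  if (n0 < 1 || n0 >= n) stop("need 1 <= n0 < n")
  if (!is.null(seed)) set.seed(seed)
  deg <- numeric(n)
  edges <- matrix(0L, (n - n0) * n0, 2)
  row <- 0L
  for (v in seq(n0 + 1, n)) {
    m <- v - 1
    w <- deg[seq_len(m)]
    targets <- if (sum(w) == 0) sample.int(m, n0)
               else sample.int(m, n0, prob = w)
    for (u in targets) {
      row <- row + 1L
      edges[row, ] <- c(u, v)
      deg[u] <- deg[u] + 1
    }
    deg[v] <- deg[v] + n0
  }
  nodes <- as.character(seq_len(n))
  graph_from_edges(cbind(nodes[edges[, 1]], nodes[edges[, 2]]), nodes = nodes)
}

#' Stochastic-block-model random graph
#'
#' Nodes are partitioned into communities of the given sizes; each unordered
#' pair of distinct nodes in communities i0 and j0 is an edge independently
#' with probability \code{B[i0, j0]}. With one community this specializes to
#' the Erdos-Renyi model.
#'
#' @param community_sizes Integer vector of community sizes.
#' @param B Symmetric block-probability matrix with entries in [0, 1].
#' @param seed Optional integer seed.
#' @return A \code{netdict_graph} with nodes "1".."n" and attribute
#'   \code{communities} (integer community label per node).
#' @export
sbm_graph <- function(community_sizes, B, seed = NULL) {
  B <- as.matrix(B)
  k0 <- length(community_sizes)
  if (nrow(B) != k0 || ncol(B) != k0) stop("`B` must be k0 x k0")
  if (!isSymmetric(unname(B))) stop("`B` must be symmetric")
  if (any(B < 0 | B > 1)) stop("entries of `B` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- sum(community_sizes)
  offs <- cumsum(c(0, community_sizes))
  el <- list(); li <- 0
  for (a in seq_len(k0)) {
    na <- community_sizes[a]
    # within-community pairs
    npairs <- na * (na - 1) / 2
    m <- rbinom(1, npairs, B[a, a])
    if (m > 0) {
      ij <- decode_pair_index(sample(npairs, m))
      li <- li + 1
      el[[li]] <- cbind(ij[, 1] + offs[a], ij[, 2] + offs[a])
    }
    for (b in seq_len(k0)[-seq_len(a)]) {
      nb <- community_sizes[b]
      m <- rbinom(1, na * nb, B[a, b])
      if (m > 0) {
        idx <- sample(na * nb, m)
        i <- ((idx - 1) %% na) + 1
        j <- ((idx - 1) %/% na) + 1
        li <- li + 1
        el[[li]] <- cbind(i + offs[a], j + offs[b])
      }
    }
  }
  nodes <- as.character(seq_len(n))
  em <- if (li > 0) do.call(rbind, el) else matrix(0L, 0, 2)
  g <- graph_from_edges(cbind(nodes[em[, 1]], nodes[em[, 2]]), nodes = nodes)
  attr(g, "communities") <- rep(seq_len(k0), community_sizes)
  g
}

#' Path graph on n nodes
#'
#' Convenience fixture: nodes "1".."n" with edges between consecutive nodes.
#'
#' @param n Number of nodes, n >= 2.
#' @param seed Unused; accepted for interface uniformity.
#' @return A \code{netdict_graph}.
#' @export
path_graph <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  nodes <- as.character(seq_len(n))
  graph_from_edges(cbind(nodes[seq_len(n - 1)], nodes[seq_len(n - 1) + 1]),
                   nodes = nodes)
}
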