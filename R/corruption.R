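## Edge corruption models with ground-truth labels for denoising benchmarks.
## A corruption record carries the observed (corrupted) graph, the true
## graph, and the added/removed edge sets.

new_corruption_record <- function(observed, truth, added, removed,
                                  noise_type, params) {
  structure(list(observed = observed, truth = truth,
                 added_edges = added, removed_edges = removed,
                 noise_type = noise_type, params = params),
            class = "corruption_record")
}

#' @method print corruption_record
#' @export
print.corruption_record <- function(x, ...) {
  cat("corruption_record [", x$noise_type, "]:",
      nrow(x$truth$edges), "true edges ->", nrow(x$observed$edges),
      "observed;", nrow(x$added_edges), "added,",
      nrow(x$removed_edges), "removed\n")
  invisible(x)
}

edge_label_matrix <- function(g, idx_matrix) {
  if (nrow(idx_matrix) == 0) return(matrix(character(0), 0, 2))
  cbind(g$nodes[idx_matrix[, 1]], g$nodes[idx_matrix[, 2]])
}

#' Uniform spanning tree by Wilson's algorithm
#'
#' Samples a spanning tree uniformly at random from all spanning trees of a
#' connected graph, via loop-erased random walks.
#'
#' @param g A connected \code{netdict_graph}.
#' @param seed Optional integer seed.
#' @return Integer matrix of tree edges (node indices), n - 1 rows.
#' @export
uniform_spanning_tree <- function(g, seed = NULL) {
  stopifnot(inherits(g, "netdict_graph"))
  if (!is_connected_graph(g)) stop("graph must be connected")
  if (!is.null(seed)) set.seed(seed)
  n <- length(g$nodes)
  nbrs <- lapply(seq_len(n), function(v) setdiff(g$adj[[v]], v))
  in_tree <- logical(n)
  nxt <- integer(n)
  root <- 1L
  in_tree[root] <- TRUE
  for (v in seq_len(n)) {
    u <- v
    while (!in_tree[u]) {       # random walk with successor overwriting
      nb <- nbrs[[u]]
      nxt[u] <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1)]
      u <- nxt[u]
    }
    u <- v
    while (!in_tree[u]) {       # retrace the loop-erased walk
      in_tree[u] <- TRUE
      u <- nxt[u]
    }
  }
  has <- which(in_tree & seq_len(n) != root)
  tree <- cbind(has, nxt[has])
  tree <- cbind(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
  storage.mode(tree) <- "integer"
  tree
}

#' Subtractive corruption preserving connectivity (-ER)
#'
#' Chooses a uniformly random spanning tree of the graph, lets E0 be the
#' edges outside the tree, and removes floor(|E0| / 2) of them uniformly at
#' random, so the observed graph is guaranteed to stay connected.
#'
#' @param g A connected \code{netdict_graph}.
#' @param seed Optional integer seed.
#' @return A \code{corruption_record} with empty \code{added_edges}.
#' @export
corrupt_subtract_er <- function(g, seed = NULL) {
  if (!is_connected_graph(g)) stop("graph must be connected")
  if (!is.null(seed)) set.seed(seed)
  tree <- uniform_spanning_tree(g)
  n <- length(g$nodes)
  tree_keys <- edge_keys(tree, n)
  all_keys <- edge_keys(g$edges, n)
  e0 <- which(!(all_keys %in% tree_keys))
  n_remove <- floor(length(e0) / 2)
  rem <- if (n_remove > 0) sort(sample(e0, n_remove)) else integer(0)
  keep <- setdiff(seq_len(nrow(g$edges)), rem)
  observed <- new_netdict_graph(g$nodes, g$edges[keep, , drop = FALSE])
  new_corruption_record(
    observed = observed, truth = g,
    added = matrix(character(0), 0, 2),
    removed = edge_label_matrix(g, g$edges[rem, , drop = FALSE]),
    noise_type = "-ER",
    params = list(n_removed = n_remove, n_e0 = length(e0)))
}

#' Additive Erdos-Renyi corruption (+ER)
#'
#' \code{variant = "uniform"}: adds exactly floor(|E| / 2) new edges chosen
#' uniformly among nonadjacent node pairs. \code{variant = "block"}: selects
#' \code{ceiling(q_nodes |V|)} nodes uniformly at random and adds each
#' currently-absent pair among them independently with probability
#' \code{q_p}.
#'
#' @param g A \code{netdict_graph}.
#' @param variant "uniform" or "block".
#' @param seed Optional integer seed.
#' @param q_nodes Fraction of nodes selected by the block variant.
#' @param q_p Within-block edge probability of the block variant.
#' @return A \code{corruption_record} with empty \code{removed_edges}.
#' @export
corrupt_add_er <- function(g, variant = c("uniform", "block"), seed = NULL,
                           q_nodes = 0.05, q_p = 0.3) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  n <- length(g$nodes)
  if (variant == "uniform") {
    m_add <- floor(nrow(g$edges) / 2)
    npairs <- n * (n - 1) / 2
    n_self <- sum(g$edges[, 1] == g$edges[, 2])
    if (npairs - (nrow(g$edges) - n_self) < m_add)
      stop("not enough nonadjacent pairs to add ", m_add, " edges")
    new_idx <- integer(0)
    while (length(new_idx) < m_add) {
      cand <- unique(sample(npairs, min(npairs, 2 * (m_add - length(new_idx)) + 16)))
      ij <- decode_pair_index(cand)
      ok <- !has_edges(g, ij[, 1], ij[, 2])
      new_idx <- unique(c(new_idx, cand[ok]))
    }
    new_idx <- new_idx[seq_len(m_add)]
    ij <- decode_pair_index(new_idx)
    added_idx <- cbind(ij[, 1], ij[, 2])
    params <- list(variant = variant, n_added = m_add)
  } else {
    nsel <- ceiling(q_nodes * n)
    sel <- sort(sample.int(n, nsel))
    if (nsel >= 2) {
      pr <- which(upper.tri(matrix(0, nsel, nsel)), arr.ind = TRUE)
      u <- sel[pr[, 1]]; v <- sel[pr[, 2]]
      absent <- !has_edges(g, u, v)
      flip <- runif(length(u)) < q_p
      keep <- absent & flip
      added_idx <- cbind(pmin(u, v), pmax(u, v))[keep, , drop = FALSE]
    } else {
      added_idx <- matrix(0L, 0, 2)
    }
    params <- list(variant = variant, q_nodes = q_nodes, q_p = q_p,
                   selected_nodes = g$nodes[sel])
  }
  observed <- new_netdict_graph(
    g$nodes, order_edge_matrix(rbind(g$edges, added_idx)))
  new_corruption_record(
    observed = observed, truth = g,
    added = edge_label_matrix(g, added_idx),
    removed = matrix(character(0), 0, 2),
    noise_type = if (variant == "uniform") "+ER-uniform" else "+ER-block",
    params = params)
}

order_edge_matrix <- function(em) {
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  em <- em[!duplicated(em), , drop = FALSE]
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  storage.mode(em) <- "integer"
  em
}

#' Additive Watts-Strogatz corruption (+WS)
#'
#' Chooses n0 nodes uniformly at random, generates a WS(n0, k, p) network on
#' them (ring order = random selection order), and adds its n0 k/2 edges to
#' the graph. Generated edges already present in \code{g} are logged in
#' \code{params$collisions} and excluded from the added (false-positive
#' label) set.
#'
#' @param g A \code{netdict_graph}.
#' @param n0 Number of corrupting nodes, n0 <= |V|.
#' @param k Even WS ring degree, k < n0.
#' @param p WS rewiring probability.
#' @param seed Optional integer seed.
#' @return A \code{corruption_record} with empty \code{removed_edges}.
#' @export
corrupt_add_ws <- function(g, n0, k, p, seed = NULL) {
  n <- length(g$nodes)
  if (n0 > n) stop("`n0` cannot exceed the number of nodes")
  if (!is.null(seed)) set.seed(seed)
  v0 <- sample.int(n, n0)          # selection order fixes the ring order
  h <- ws_graph(n0, k, p)
  he <- cbind(v0[h$edges[, 1]], v0[h$edges[, 2]])
  he <- order_edge_matrix(he)
  collide <- has_edges(g, he[, 1], he[, 2])
  added_idx <- he[!collide, , drop = FALSE]
  observed <- new_netdict_graph(
    g$nodes, order_edge_matrix(rbind(g$edges, added_idx)))
  new_corruption_record(
    observed = observed, truth = g,
    added = edge_label_matrix(g, added_idx),
    removed = matrix(character(0), 0, 2),
    noise_type = "+WS",
    params = list(n0 = n0, k = k, p = p,
                  n_generated = nrow(he),
                  collisions = edge_label_matrix(g, he[collide, , drop = FALSE]),
                  selected_nodes = g$nodes[v0]))
}

#' Serialize a corruption record to edge lists and a manifest
#'
#' Writes \code{observed.edgelist}, \code{added.edgelist},
#' \code{removed.edgelist} and \code{manifest.json} under \code{dir}.
#'
#' @param rec A \code{corruption_record}.
#' @param dir Output directory (created if needed).
#' @export
write_corruption_record <- function(rec, dir) {
  stopifnot(inherits(rec, "corruption_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edgelist(rec$observed, file.path(dir, "observed.edgelist"))
  writeLines(apply(rec$added_edges, 1, paste, collapse = " "),
             file.path(dir, "added.edgelist"))
  writeLines(apply(rec$removed_edges, 1, paste, collapse = " "),
             file.path(dir, "removed.edgelist"))
  manifest <- c(list(noise_type = rec$noise_type),
                rec$params[!vapply(rec$params, is.matrix, logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
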