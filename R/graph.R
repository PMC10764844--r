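#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail
NULL

## Internal representation of an undirected binary graph:
##   nodes: character vector of labels (order fixes the integer index),
##   edges: m x 2 integer matrix with edges[, 1] <= edges[, 2], unique rows,
##   adj:   list of sorted integer neighbour vectors (a self-edge puts a node
##          in its own neighbour list once).
## Objects are immutable; all derived structures are built at construction.

new_netdict_graph <- function(nodes, edges) {
  g <- structure(list(nodes = nodes, edges = edges, adj = NULL),
                 class = "netdict_graph")
  g$adj <- build_adj(length(nodes), edges)
  g
}

build_adj <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    self <- edges[, 1] == edges[, 2]
    i <- c(edges[!self, 1], edges[!self, 2], edges[self, 1])
    j <- c(edges[!self, 2], edges[!self, 1], edges[self, 2])
    adj <- unname(split(j, factor(i, levels = seq_len(n))))
    adj <- lapply(adj, sort)
  } else {
    adj <- rep(list(integer(0)), n)
  }
  adj
}

#' Construct a graph from an edge table
#'
#' Builds an undirected, unweighted graph (possibly with self-edges) from a
#' two-column table of node labels. Reversed duplicates and repeated rows are
#' collapsed to a single undirected edge.
#'
#' @param edges Two-column matrix or data frame of node labels (coerced to
#'   character), one edge per row. May have zero rows.
#' @param nodes Optional character vector of node labels; must contain every
#'   endpoint. Isolated nodes can only be introduced this way.
#' @return An object of class \code{netdict_graph}.
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) < 2) stop("`edges` must have at least two columns")
  u <- as.character(edges[, 1]); v <- as.character(edges[, 2])
  if (is.null(nodes)) {
    nodes <- sort(unique(c(u, v)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node labels")
    missing <- setdiff(unique(c(u, v)), nodes)
    if (length(missing) > 0)
      stop("edge endpoints not in node set: ", paste(head(missing, 5), collapse = ", "))
  }
  if (length(nodes) < 1) stop("a graph must have at least one node")
  ui <- match(u, nodes); vi <- match(v, nodes)
  lo <- pmin(ui, vi); hi <- pmax(ui, vi)
  em <- cbind(lo, hi)
  em <- em[!duplicated(em), , drop = FALSE]
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  storage.mode(em) <- "integer"
  dimnames(em) <- NULL
  new_netdict_graph(nodes, em)
}

#' Read a graph from a plain-text edge list
#'
#' Each non-comment line holds at least two whitespace-separated node labels;
#' extra columns (e.g. weights) are ignored, lines starting with \code{#} are
#' skipped, and reversed duplicate pairs are collapsed.
#'
#' @param path Path to the edge-list file.
#' @return A \code{netdict_graph}.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) < 2)
  if (length(bad) > 0)
    stop("malformed edge-list line ", idx[bad[1]], " in ", path)
  graph_from_edges(cbind(vapply(toks, `[`, "", 1), vapply(toks, `[`, "", 2)))
}

#' Write a graph as a plain-text edge list
#'
#' @param g A \code{netdict_graph}.
#' @param path Output file path.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "netdict_graph"))
  writeLines(paste(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]]), path)
  invisible(path)
}

#' @method print netdict_graph
#' @export
print.netdict_graph <- function(x, ...) {
  ns <- sum(x$edges[, 1] == x$edges[, 2])
  cat("netdict_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (ns > 0) paste0("(", ns, " self-edges)"), "\n")
  invisible(x)
}

#' Number of nodes / edges
#' @param g A \code{netdict_graph}.
#' @return Integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

## Sparse symmetric 0/1 adjacency (pattern) matrix; self-edges on the diagonal.
graph_adjacency <- function(g) {
  n <- length(g$nodes)
  e <- g$edges
  self <- e[, 1] == e[, 2]
  i <- c(e[, 1], e[!self, 2])
  j <- c(e[, 2], e[!self, 1])
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

## Node degrees (self-edge contributes 2), as used by degree-based statistics.
graph_degrees <- function(g) {
  n <- length(g$nodes)
  e <- g$edges
  d <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  d
}

## Fast membership test for unordered pairs given as integer indices.
edge_keys <- function(edges, n) (edges[, 1] - 1) * as.double(n) + edges[, 2]

has_edges <- function(g, u, v) {
  lo <- pmin(u, v); hi <- pmax(u, v)
  n <- length(g$nodes)
  keys <- (lo - 1) * as.double(n) + hi
  keys %in% edge_keys(g$edges, n)
}

is_connected_graph <- function(g) {
  n <- length(g$nodes)
  if (n == 1) return(TRUE)
  seen <- logical(n)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    nxt <- unique(unlist(g$adj[queue], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  all(seen)
}

#' Mesoscale patch induced by a k-path
#'
#' Returns the k x k binary adjacency matrix \eqn{A_x} of the subgraph induced
#' by the ordered node sequence \eqn{x = (x_1, \dots, x_k)}, i.e.
#' \eqn{A_x(i, j) = A(x_i, x_j)}. The sequence must be a path: the nodes are
#' distinct and consecutive nodes are adjacent, so the on-chain entries
#' \eqn{(i, i+1)} are always 1. Diagonal entries record self-edges.
#'
#' @param g A \code{netdict_graph}.
#' @param path Character vector of node labels or integer node indices.
#' @return A k x k symmetric 0/1 matrix.
#' @export
induced_patch <- function(g, path) {
  idx <- path_to_index(g, path)
  k <- length(idx)
  if (k < 2) stop("a path needs at least 2 nodes")
  if (anyDuplicated(idx)) stop("invalid path: repeated nodes")
  for (i in seq_len(k - 1)) {
    if (!(idx[i + 1] %in% g$adj[[idx[i]]]))
      stop("invalid path: nodes at positions ", i, " and ", i + 1,
           " are not adjacent")
  }
  ii <- rep(idx, times = k)
  jj <- rep(idx, each = k)
  matrix(as.numeric(has_edges(g, ii, jj)), k, k)
}

path_to_index <- function(g, path) {
  if (is.character(path) || is.factor(path)) {
    idx <- match(as.character(path), g$nodes)
    if (anyNA(idx)) stop("path contains unknown node labels")
  } else {
    idx <- as.integer(path)
    if (any(idx < 1 | idx > length(g$nodes))) stop("node index out of range")
  }
  idx
}

#' Column-wise vectorization of a square matrix
#'
#' Stacks the columns of a k x k matrix into a length-k^2 vector (the second
#' column underneath the first, and so on); \code{devectorize} is its inverse.
#'
#' @param m A square matrix.
#' @return Numeric vector of length \code{k^2}.
#' @export
vectorize_patch <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  as.vector(m)
}

#' @rdname vectorize_patch
#' @param v Numeric vector whose length is a perfect square.
#' @export
devectorize_patch <- function(v) {
  k <- sqrt(length(v))
  if (k != floor(k)) stop("vector length is not a perfect square")
  matrix(v, as.integer(k), as.integer(k))
}

## ---- weighted graphs ------------------------------------------------------

new_netdict_wgraph <- function(nodes, pairs, weight, count = NULL) {
  structure(list(nodes = nodes, pairs = pairs, weight = weight,
                 count = count),
            class = "netdict_wgraph")
}

#' Weighted graph from explicit pair weights
#'
#' @param nodes Character vector of node labels.
#' @param pairs Two-column matrix of node labels or integer indices.
#' @param weight Numeric weights in [0, 1], one per pair. Pairs absent from
#'   the table have weight 0.
#' @return An object of class \code{netdict_wgraph}.
#' @export
weighted_graph <- function(nodes, pairs, weight) {
  nodes <- as.character(nodes)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (length(weight) != nrow(pairs)) stop("one weight per pair required")
  if (any(weight < 0 | weight > 1)) stop("weights must lie in [0, 1]")
  if (is.character(pairs)) {
    ui <- match(pairs[, 1], nodes); vi <- match(pairs[, 2], nodes)
    if (anyNA(ui) || anyNA(vi)) stop("pair endpoints not in node set")
  } else {
    ui <- as.integer(pairs[, 1]); vi <- as.integer(pairs[, 2])
  }
  lo <- pmin(ui, vi); hi <- pmax(ui, vi)
  pm <- cbind(lo, hi)
  if (anyDuplicated(pm)) stop("duplicate pairs")
  storage.mode(pm) <- "integer"
  new_netdict_wgraph(nodes, pm, as.numeric(weight))
}

#' @method print netdict_wgraph
#' @export
print.netdict_wgraph <- function(x, ...) {
  cat("netdict_wgraph:", length(x$nodes), "nodes,", nrow(x$pairs),
      "weighted pairs; weight range [",
      if (nrow(x$pairs) > 0) round(min(x$weight), 4) else 0, ",",
      if (nrow(x$pairs) > 0) round(max(x$weight), 4) else 0, "]\n")
  invisible(x)
}

## View a binary graph as a weighted graph with unit weights.
as_weighted <- function(g) {
  stopifnot(inherits(g, "netdict_graph"))
  new_netdict_wgraph(g$nodes, g$edges, rep(1, nrow(g$edges)))
}

#' Threshold a weighted graph into a binary graph
#'
#' Keeps exactly the pairs whose weight is strictly larger than \code{theta}.
#'
#' @param w A \code{netdict_wgraph}.
#' @param theta Threshold in [0, 1].
#' @return A \code{netdict_graph} on the same node set.
#' @export
threshold_graph <- function(w, theta) {
  stopifnot(inherits(w, "netdict_wgraph"))
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1)
    stop("`theta` must be a single value in [0, 1]")
  keep <- w$weight > theta
  g <- new_netdict_graph(w$nodes, w$pairs[keep, , drop = FALSE])
  g
}

#' Write a weighted graph as "u v weight" lines
#'
#' Weights are printed with at least six significant digits.
#'
#' @param w A \code{netdict_wgraph}.
#' @param path Output file path.
#' @export
write_weighted_edgelist <- function(w, path) {
  stopifnot(inherits(w, "netdict_wgraph"))
  writeLines(paste(w$nodes[w$pairs[, 1]], w$nodes[w$pairs[, 2]],
                   sprintf("%.6g", w$weight)), path)
  invisible(path)
}

#' Degrees of freedom of a mesoscale patch
#'
#' Number of distinct off-diagonal, off-chain-unconstrained entries of a
#' k-node patch: \code{choose(k, 2) - (k - 1)} (all unordered pairs minus the
#' k - 1 on-chain pairs fixed to 1 by the path).
#'
#' @param k Patch size (number of nodes), k >= 2.
#' @return Integer.
#' @export
patch_dof <- function(k) {
  stopifnot(k >= 2)
  choose(k, 2) - (k - 1)
}

## Positions (column-major vector indices) of on-chain entries of a k x k patch.
on_chain_positions <- function(k) {
  i <- seq_len(k - 1)
  sort(c((i - 1) * k + i + 1,  # (i+1, i): column i, row i+1
         i * k + i))           # (i, i+1): column i+1, row i
}

diag_positions <- function(k) ((seq_len(k) - 1) * k) + seq_len(k)
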