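## Edge/nonedge classification from reconstruction weights, degree-biased
## negative sampling, classical link-prediction baselines, threshold
## selection, and ROC/AUC evaluation.

new_scored_pairs <- function(pairs, scores, labels, method) {
  structure(list(pairs = pairs, scores = as.numeric(scores),
                 labels = as.integer(labels), method = method),
            class = "scored_pairs")
}

#' @method print scored_pairs
#' @export
print.scored_pairs <- function(x, ...) {
  cat("scored_pairs [", x$method, "]:", nrow(x$pairs), "pairs,",
      sum(x$labels), "positive\n")
  invisible(x)
}

#' Candidate pairs and labels for a corruption record
#'
#' For additive noise the candidates are all edges of the observed graph,
#' labelled 1 when they are true edges of the uncorrupted graph. For
#' subtractive noise the candidates are the removed edges (label 1) plus an
#' equal number of never-existing nonedges (label 0) sampled without
#' replacement with probability proportional to the product of the two
#' endpoint degrees in the observed graph, which de-biases the evaluation
#' against degree-based scores.
#'
#' @param rec A \code{corruption_record}.
#' @param seed Optional integer seed (used by the subtractive sampler).
#' @return List with \code{pairs} (two-column label matrix) and
#'   \code{labels} (0/1 vector).
#' @export
candidate_sets <- function(rec, seed = NULL) {
  stopifnot(inherits(rec, "corruption_record"))
  if (!is.null(seed)) set.seed(seed)
  obs <- rec$observed
  if (nrow(rec$removed_edges) == 0) {
    # additive noise: classify the observed edges
    pairs <- edge_label_matrix(obs, obs$edges)
    truth_keys <- edge_set_keys(rec$truth)
    keys <- paste(pmin(pairs[, 1], pairs[, 2]),
                  pmax(pairs[, 1], pairs[, 2]), sep = "\r")
    labels <- as.integer(keys %in% truth_keys)
    return(list(pairs = pairs, labels = labels))
  }
  # subtractive noise: removed edges vs degree-product-biased nonedges
  n <- length(obs$nodes)
  m_pos <- nrow(rec$removed_edges)
  deg <- graph_degrees(obs)
  npairs <- n * (n - 1) / 2
  truth_keys_num <- edge_keys(rec$truth$edges, n)
  if (npairs <= 2e6) {
    ij <- decode_pair_index(seq_len(npairs))
    cand <- !(edge_keys(ij, n) %in% truth_keys_num)
    ij <- ij[cand, , drop = FALSE]
    w <- deg[ij[, 1]] * deg[ij[, 2]]
    if (sum(w > 0) < m_pos) stop("not enough nonedges with positive weight")
    pick <- sample(nrow(ij), m_pos, prob = w)
    neg <- ij[pick, , drop = FALSE]
  } else {
    # rejection sampling from the degree-product distribution
    neg_keys <- numeric(0)
    neg <- matrix(0L, 0, 2)
    while (nrow(neg) < m_pos) {
      u <- sample.int(n, 4 * m_pos, replace = TRUE, prob = deg)
      v <- sample.int(n, 4 * m_pos, replace = TRUE, prob = deg)
      ok <- u != v
      ij <- cbind(pmin(u[ok], v[ok]), pmax(u[ok], v[ok]))
      keys <- edge_keys(ij, n)
      keep <- !(keys %in% truth_keys_num) & !(keys %in% neg_keys) &
        !duplicated(keys)
      neg <- rbind(neg, ij[keep, , drop = FALSE])
      neg_keys <- c(neg_keys, keys[keep])
    }
    neg <- neg[seq_len(m_pos), , drop = FALSE]
  }
  pairs <- rbind(rec$removed_edges, edge_label_matrix(obs, neg))
  labels <- c(rep(1L, m_pos), rep(0L, m_pos))
  list(pairs = pairs, labels = labels)
}

#' Classical link-prediction baseline scores
#'
#' Scores node pairs from the observed graph alone. With neighbour sets
#' N(x): \code{jaccard} is |N(x) int N(y)| / |N(x) un N(y)|;
#' \code{pref_attach} is |N(x)| |N(y)|; \code{adamic_adar} is
#' sum over common neighbours z of 1 / ln |N(z)| (common neighbours of
#' degree 1 are skipped, as ln 1 = 0); \code{spectral} is the entry of the
#' rank-d truncated eigendecomposition of the adjacency matrix (a symmetric
#' adjacency spectral embedding inner product).
#'
#' @param g_obs A \code{netdict_graph} (the observed network; labels are
#'   never consulted).
#' @param pairs Two-column matrix of node labels.
#' @param method One of "jaccard", "pref_attach", "adamic_adar", "spectral".
#' @param labels Optional 0/1 ground truth stored alongside the scores.
#' @param d Embedding rank for the spectral method.
#' @return A \code{scored_pairs} object.
#' @export
baseline_scores <- function(g_obs, pairs, method = c("jaccard", "pref_attach",
                                                     "adamic_adar", "spectral"),
                            labels = NULL, d = 32) {
  method <- match.arg(method)
  stopifnot(inherits(g_obs, "netdict_graph"))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  u <- match(pairs[, 1], g_obs$nodes)
  v <- match(pairs[, 2], g_obs$nodes)
  if (anyNA(u) || anyNA(v)) stop("pair endpoints not in the observed graph")
  nbrs <- lapply(seq_along(g_obs$nodes), function(x) setdiff(g_obs$adj[[x]], x))
  degs <- lengths(nbrs)
  scores <- switch(method,
    jaccard = mapply(function(a, b) {
      un <- length(union(nbrs[[a]], nbrs[[b]]))
      if (un == 0) 0 else length(intersect(nbrs[[a]], nbrs[[b]])) / un
    }, u, v),
    pref_attach = degs[u] * degs[v],
    adamic_adar = mapply(function(a, b) {
      z <- intersect(nbrs[[a]], nbrs[[b]])
      z <- z[degs[z] > 1]
      if (length(z) == 0) 0 else sum(1 / log(degs[z]))
    }, u, v),
    spectral = {
      A <- as.matrix(graph_adjacency(g_obs))
      d <- min(d, nrow(A))
      ed <- eigen(A, symmetric = TRUE)
      ord <- order(abs(ed$values), decreasing = TRUE)[seq_len(d)]
      U <- ed$vectors[, ord, drop = FALSE]
      lam <- ed$values[ord]
      rowSums((U[u, , drop = FALSE] * rep(lam, each = length(u))) *
                U[v, , drop = FALSE])
    })
  if (is.null(labels)) labels <- rep(NA_integer_, nrow(pairs))
  new_scored_pairs(pairs, scores, labels, method)
}

#' NDR confidence scores for candidate pairs
#'
#' Learns nothing itself: takes a dictionary already fitted on the observed
#' graph, reconstructs the observed graph with it, and scores each candidate
#' pair by its reconstruction weight (0 when never covered). With the
#' default \code{mask_on_chain = TRUE} the masked dictionary is used, so an
#' observed edge cannot certify itself through the trivially-present
#' on-chain patch entries.
#'
#' @param rec A \code{corruption_record}.
#' @param fit An \code{ndl} fit learned from \code{rec$observed}.
#' @param pairs Two-column matrix of candidate node labels.
#' @param labels Optional 0/1 ground truth stored alongside the scores.
#' @param mask_on_chain Score pairs only through off-chain appearances.
#' @param ... Passed to \code{\link{reconstruct}} (e.g. \code{n_paths},
#'   \code{seed}).
#' @return A \code{scored_pairs} object.
#' @export
ndr_scores <- function(rec, fit, pairs, labels = NULL,
                       mask_on_chain = TRUE, ...) {
  stopifnot(inherits(rec, "corruption_record"))
  w <- reconstruct(rec$observed, fit, mask_on_chain = mask_on_chain, ...)
  kw <- wgraph_key_weights(w)
  keys <- paste(pmin(pairs[, 1], pairs[, 2]),
                pmax(pairs[, 1], pairs[, 2]), sep = "\r")
  scores <- ifelse(keys %in% names(kw), kw[keys], 0)
  if (is.null(labels)) labels <- rep(NA_integer_, nrow(pairs))
  new_scored_pairs(pairs, unname(scores), labels,
                   paste0("ndr", if (mask_on_chain) "-masked"))
}

#' Four-dictionary NDR scoring protocol
#'
#' Learns dictionaries with each \code{r} in \code{r_values} from the
#' observed graph and scores the candidates with both the full and the
#' on-chain-masked dictionary of each.
#'
#' @param rec A \code{corruption_record}.
#' @param pairs,labels Candidates as in \code{\link{ndr_scores}}.
#' @param k Patch scale.
#' @param r_values Numbers of motifs to learn (default c(2, 25)).
#' @param seed Optional integer seed.
#' @param ... Passed on to \code{\link{ndl}} and \code{\link{reconstruct}}
#'   via \code{ndr_scores}.
#' @return Named list of \code{scored_pairs}, one per (r, mask) cell.
#' @export
ndr_score_batch <- function(rec, pairs, labels = NULL, k = 21,
                            r_values = c(2, 25), seed = NULL, ...) {
  out <- list()
  for (r in r_values) {
    fit <- ndl(rec$observed, k = k, r = r, seed = seed, ...)
    for (mask in c(FALSE, TRUE)) {
      sp <- ndr_scores(rec, fit, pairs, labels = labels,
                       mask_on_chain = mask)
      nm <- paste0("r", r, if (mask) "_masked" else "_full")
      sp$method <- paste0("ndr_", nm)
      out[[nm]] <- sp
    }
  }
  out
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over all distinct scores and returns the ROC points
#' (false-positive rate, true-positive rate) together with the area under
#' the curve, computed as the tie-corrected Mann-Whitney statistic
#' P(score_pos > score_neg) + P(equal)/2.
#'
#' @param sp A \code{scored_pairs} object (or a list with \code{scores} and
#'   \code{labels}).
#' @return List with \code{curve} (data frame fpr/tpr/threshold) and
#'   \code{auc}.
#' @export
roc_auc <- function(sp) {
  scores <- sp$scores; labels <- sp$labels
  if (anyNA(labels)) stop("labels required for ROC analysis")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  rk <- rank(scores)                       # mid-ranks handle ties
  auc <- (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

#' Classification threshold from a training split
#'
#' Splits the scored pairs in half, picks the threshold maximizing training
#' accuracy (predict positive when score > theta), and reports held-out
#' accuracy, precision, recall and F-score (the harmonic mean of precision
#' and recall).
#'
#' @param sp A \code{scored_pairs} object.
#' @param train_fraction Fraction of pairs used to select the threshold.
#' @param seed Optional integer seed for the split.
#' @return List with \code{theta}, \code{train_accuracy}, \code{accuracy},
#'   \code{precision}, \code{recall} and \code{f_score} (held-out).
#' @export
select_threshold <- function(sp, train_fraction = 0.5, seed = NULL) {
  scores <- sp$scores; labels <- sp$labels
  if (anyNA(labels)) stop("labels required")
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  tr <- sample.int(n, floor(train_fraction * n))
  if (length(unique(labels[tr])) < 2 || length(unique(labels[-tr])) < 2)
    stop("degenerate split: both classes required in each half")
  s_tr <- scores[tr]; l_tr <- labels[tr]
  cuts <- sort(unique(s_tr))
  cand <- c(min(cuts) - 1, (head(cuts, -1) + tail(cuts, -1)) / 2, max(cuts))
  acc <- vapply(cand, function(th) mean((s_tr > th) == (l_tr == 1)), 0)
  theta <- cand[which.max(acc)]
  s_te <- scores[-tr]; l_te <- labels[-tr]
  pred <- as.integer(s_te > theta)
  tp <- sum(pred == 1 & l_te == 1); fp <- sum(pred == 1 & l_te == 0)
  fn <- sum(pred == 0 & l_te == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(theta = theta, train_accuracy = max(acc),
       accuracy = mean(pred == l_te),
       precision = precision, recall = recall, f_score = f)
}

#' Binary-classification summary at a fixed threshold
#'
#' @param sp A \code{scored_pairs} object.
#' @param theta Decision threshold (predict positive when score > theta).
#' @return List with accuracy, precision, recall and f_score.
#' @export
classification_metrics <- function(sp, theta) {
  pred <- as.integer(sp$scores > theta)
  l <- sp$labels
  tp <- sum(pred == 1 & l == 1); fp <- sum(pred == 1 & l == 0)
  fn <- sum(pred == 0 & l == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = mean(pred == l), precision = precision,
       recall = recall, f_score = f)
}
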