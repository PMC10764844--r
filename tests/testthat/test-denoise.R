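test_that("candidate sets follow the noise direction", {
  # additive: all observed edges, true edges labelled 1
  g <- er_graph(30, 0.15, seed = 61)
  rec <- corrupt_add_er(g, "uniform", seed = 62)
  cand <- candidate_sets(rec)
  expect_equal(nrow(cand$pairs), n_edges(rec$observed))
  expect_equal(sum(cand$labels), n_edges(g))
  expect_equal(sum(cand$labels == 0), nrow(rec$added_edges))

  # subtractive: removed edges plus an equal number of biased nonedges
  g2 <- er_graph(40, 0.25, seed = 63)
  rec2 <- corrupt_subtract_er(g2, seed = 64)
  cand2 <- candidate_sets(rec2, seed = 65)
  m <- nrow(rec2$removed_edges)
  expect_equal(nrow(cand2$pairs), 2 * m)
  expect_equal(sum(cand2$labels), m)
  # sampled negatives are true nonedges of the uncorrupted graph
  neg <- cand2$pairs[cand2$labels == 0, , drop = FALSE]
  truth_keys <- edge_set_keys_for_test(rec2$truth)
  expect_false(any(paste(pmin(neg[, 1], neg[, 2]),
                         pmax(neg[, 1], neg[, 2])) %in% truth_keys))
})

test_that("negative sampling is biased by the degree product", {
  # hub-and-spoke truth with one removable edge: nonedge sampling frequencies
  # must match the exact degree-product weights by enumeration
  g <- graph_from_edges(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3"),
                              c("c", "l4"), c("l1", "l2")))
  rec <- netdict:::new_corruption_record(
    observed = g, truth = g,
    added = matrix(character(0), 0, 2),
    removed = rbind(c("l1", "l2")),   # one positive -> one sampled negative
    noise_type = "-ER", params = list())
  # enumerate expected weights over nonedges of the truth
  deg <- stats::setNames(netdict:::graph_degrees(g), g$nodes)
  nonedges <- rbind(c("l1", "l3"), c("l1", "l4"), c("l2", "l3"),
                    c("l2", "l4"), c("l3", "l4"))
  w <- deg[nonedges[, 1]] * deg[nonedges[, 2]]
  pexp <- w / sum(w)
  draws <- vapply(1:3000, function(s) {
    cand <- candidate_sets(rec, seed = s)
    neg <- cand$pairs[cand$labels == 0, , drop = FALSE]
    paste(sort(neg[1, ]), collapse = "-")
  }, "")
  keys <- apply(nonedges, 1, function(p) paste(sort(p), collapse = "-"))
  emp <- as.numeric(table(factor(draws, levels = keys))) / 3000
  expect_lt(max(abs(emp - pexp)), 4 * sqrt(max(pexp * (1 - pexp)) / 3000) + 0.01)
  # center-incident nonedges are favoured over leaf-leaf ones
  expect_gt(emp[1], emp[5])
})

test_that("baseline scores match hand-computed star and clique values", {
  st <- star_graph(3)
  pairs <- rbind(c("l1", "l2"), c("c", "l1"))
  pa <- baseline_scores(st, pairs, "pref_attach")
  expect_equal(pa$scores, c(1, 3))
  jc <- baseline_scores(st, pairs, "jaccard")
  expect_equal(jc$scores[1], 1)        # N(l1) = N(l2) = {c}
  expect_equal(jc$scores[2], 0)        # N(c) and N(l1) are disjoint
  aa <- baseline_scores(st, pairs, "adamic_adar")
  expect_equal(aa$scores[1], 1 / log(3))
  expect_equal(aa$scores[2], 0)

  # K4: every nonadjacent-style pair has 2 common neighbours of degree 3
  k4 <- complete_graph(4)
  pr <- rbind(c("1", "2"))
  expect_equal(baseline_scores(k4, pr, "adamic_adar")$scores, 2 / log(3))
  expect_equal(baseline_scores(k4, pr, "pref_attach")$scores, 9)
  expect_equal(baseline_scores(k4, pr, "jaccard")$scores, 2 / 4)

  # a single degree-2 common neighbour contributes 1/ln 2
  gpath <- path_graph(3)
  expect_equal(baseline_scores(gpath, rbind(c("1", "3")), "adamic_adar")$scores,
               1 / log(2))
})

test_that("spectral baseline reproduces a rank-d adjacency approximation", {
  g <- er_graph(25, 0.3, seed = 66)
  pairs <- t(combn(g$nodes[1:6], 2))
  sp <- baseline_scores(g, pairs, "spectral", d = 25)
  # full-rank embedding reproduces adjacency entries exactly
  A <- as.matrix(netdict:::graph_adjacency(g))
  u <- match(pairs[, 1], g$nodes); v <- match(pairs[, 2], g$nodes)
  expect_equal(sp$scores, A[cbind(u, v)], tolerance = 1e-8)
})

test_that("ROC/AUC equals the tie-corrected rank statistic", {
  sp <- list(scores = c(0.9, 0.8, 0.1), labels = c(1L, 1L, 0L))
  expect_equal(roc_auc(sp)$auc, 1)
  sp2 <- list(scores = rep(0.4, 6), labels = c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(roc_auc(sp2)$auc, 0.5)
  sp3 <- list(scores = c(0.8, 0.2, 0.5), labels = c(1L, 1L, 0L))
  expect_equal(roc_auc(sp3)$auc, 0.5)
  expect_error(roc_auc(list(scores = 1:3, labels = c(1L, 1L, 1L))),
               "both classes")
  # curve endpoints and monotonicity
  set.seed(67)
  sp4 <- list(scores = runif(50), labels = rep(c(0L, 1L), 25))
  rc <- roc_auc(sp4)
  expect_equal(rc$curve$fpr[1], 0)
  expect_equal(rc$curve$tpr[nrow(rc$curve)], 1)
  expect_true(all(diff(rc$curve$fpr) >= 0))
  expect_true(all(diff(rc$curve$tpr) >= 0))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(90)
  scores <- c(runif(60), runif(40) + 0.3)
  labels <- rep(c(0L, 1L), c(60, 40))
  scores[1:10] <- scores[90:99]  # introduce ties across classes
  a1 <- roc_auc(list(scores = scores, labels = labels))$auc
  a2 <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                       direction = "<", quiet = TRUE)))
  expect_equal(a1, a2)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(68)
  scores <- rnorm(80)
  labels <- as.integer(runif(80) < plogis(scores))
  if (sum(labels) %in% c(0, 80)) labels[1:2] <- c(0L, 1L)
  a1 <- roc_auc(list(scores = scores, labels = labels))$auc
  a2 <- roc_auc(list(scores = exp(2 * scores) + 5, labels = labels))$auc
  expect_equal(a1, a2)
})

test_that("threshold selection reports held-out classification quality", {
  # perfectly separated scores classify the held-out half exactly
  sp <- list(scores = c(runif(40, 0.7, 1), runif(40, 0, 0.3)),
             labels = rep(c(1L, 0L), each = 40))
  out <- select_threshold(sp, seed = 69)
  expect_equal(out$accuracy, 1)
  expect_equal(out$f_score, 1)

  # scores independent of labels: held-out accuracy near chance
  set.seed(70)
  accs <- vapply(1:30, function(s) {
    spr <- list(scores = runif(200), labels = rep(c(0L, 1L), 100))
    select_threshold(spr, seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  # all-positive prediction at prevalence 1/2 has F-score 2/3
  spa <- list(scores = rep(c(0.6, 0.7), 50), labels = rep(c(0L, 1L), 50))
  cm <- classification_metrics(spa, theta = 0)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$recall, 1)
  expect_equal(cm$f_score, 2 / 3)
})

test_that("a k = 2 dictionary cannot discriminate additive noise", {
  g <- er_graph(40, 0.15, seed = 71)
  rec <- corrupt_add_er(g, "uniform", seed = 72)
  cand <- candidate_sets(rec)
  fit2 <- structure(list(W = chain_dictionary(2), k = 2, r = 1), class = "ndl")
  sp <- ndr_scores(rec, fit2, cand$pairs, labels = cand$labels,
                   mask_on_chain = FALSE, n_paths = 30000, seed = 73)
  expect_true(all(sp$scores == 1))
  expect_equal(roc_auc(sp)$auc, 0.5)
})

test_that("NDR separates structured truth from planted noise and beats PA", {
  B <- matrix(0.01, 3, 3); diag(B) <- 0.5
  g <- sbm_graph(c(60, 60, 60), B, seed = 74)
  rec <- corrupt_add_ws(g, n0 = 30, k = 8, p = 0.3, seed = 75)
  cand <- candidate_sets(rec)
  fit <- suppressWarnings(
    ndl(rec$observed, k = 6, r = 16, iterations = 15, minibatch = 250,
        seed = 76))
  sp <- ndr_scores(rec, fit, cand$pairs, labels = cand$labels,
                   n_paths = 6000, seed = 77)
  auc_ndr <- roc_auc(sp)$auc
  auc_pa <- roc_auc(baseline_scores(rec$observed, cand$pairs, "pref_attach",
                                    labels = cand$labels))$auc
  expect_gt(auc_ndr, 0.6)
  expect_gt(auc_ndr, auc_pa)
  # added-edge scores sit below true-edge scores on average
  expect_gt(mean(sp$scores[sp$labels == 1]), mean(sp$scores[sp$labels == 0]))
})

test_that("the four-dictionary batch returns one scored set per cell", {
  g <- er_graph(30, 0.2, seed = 78)
  rec <- corrupt_add_er(g, "uniform", seed = 79)
  cand <- candidate_sets(rec)
  out <- suppressWarnings(
    ndr_score_batch(rec, cand$pairs, labels = cand$labels, k = 3,
                    r_values = c(1, 2), seed = 80, iterations = 4,
                    minibatch = 80))
  expect_named(out, c("r1_full", "r1_masked", "r2_full", "r2_masked"))
  for (sp in out) expect_equal(nrow(sp$pairs), nrow(cand$pairs))
})
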