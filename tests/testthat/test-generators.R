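test_that("ER generator hits degenerate and binomial edge counts", {
  expect_equal(n_edges(er_graph(10, 0, seed = 1)), 0)
  expect_equal(n_edges(er_graph(10, 1, seed = 1)), choose(10, 2))
  g <- er_graph(5000, 0.01, seed = 2)
  mu <- choose(5000, 2) * 0.01
  sdv <- sqrt(choose(5000, 2) * 0.01 * 0.99)
  expect_lt(abs(n_edges(g) - mu), 4 * sdv)
  expect_error(er_graph(0, 0.5), "at least 1")
  expect_error(er_graph(10, 1.5), "\\[0, 1\\]")
})

test_that("WS generator conserves edges and degrees on the ring", {
  g0 <- ws_graph(40, 6, 0, seed = 3)
  expect_equal(n_edges(g0), 40 * 6 / 2)
  expect_true(all(netdict:::graph_degrees(g0) == 6))
  expect_equal(n_edges(ws_graph(100, 20, 0.3, seed = 4)), 1000)
  expect_equal(n_edges(ws_graph(50, 4, 1, seed = 5)), 100)
  expect_error(ws_graph(10, 3, 0.1), "even")
  expect_error(ws_graph(10, 10, 0.1), "smaller")
})

test_that("BA generator obeys the growth edge-count identity and is heavy-tailed", {
  g <- ba_graph(5, 1, seed = 6)
  expect_equal(n_edges(g), 4)               # a tree
  expect_equal(n_edges(ba_graph(500, 5, seed = 7)), 5 * 495)
  expect_equal(n_edges(ba_graph(200, 25, seed = 8)), 25 * 175)
  for (seed in 9:10) {
    gb <- ba_graph(2000, 5, seed = seed)
    d <- netdict:::graph_degrees(gb)
    expect_gt(max(d), 5 * mean(d))
    # ER of matching density has no such hub
    ge <- er_graph(2000, mean(d) / 1999, seed = seed)
    expect_lt(max(netdict:::graph_degrees(ge)), max(d))
  }
  expect_error(ba_graph(5, 5), "n0 < n")
})

test_that("SBM generator respects block probabilities", {
  expect_equal(n_edges(sbm_graph(c(10, 10), matrix(0, 2, 2), seed = 11)), 0)
  expect_error(sbm_graph(c(5, 5), matrix(c(0.1, 0.2, 0.3, 0.1), 2, 2)),
               "symmetric")
  # one community specializes exactly to ER (identical draw at equal seed)
  g_sbm <- sbm_graph(300, matrix(0.1), seed = 12)
  g_er <- er_graph(300, 0.1, seed = 12)
  expect_equal(g_sbm$edges, g_er$edges)
  # block structure: within-density above between-density
  B <- matrix(0.02, 2, 2); diag(B) <- 0.4
  g <- sbm_graph(c(50, 50), B, seed = 13)
  comm <- attr(g, "communities")
  within <- comm[g$edges[, 1]] == comm[g$edges[, 2]]
  expect_gt(sum(within), 5 * sum(!within))
})

test_that("uniform spanning trees are uniform on an enumerable fixture", {
  # 4-cycle plus chord 1-3: Kirchhoff oracle gives the tree count
  g <- graph_from_edges(rbind(c("1", "2"), c("2", "3"), c("3", "4"),
                              c("4", "1"), c("1", "3")))
  A <- as.matrix(netdict:::graph_adjacency(g))
  L <- diag(rowSums(A)) - A
  n_trees <- round(det(L[-1, -1]))
  expect_equal(n_trees, 8)
  set.seed(14)
  draws <- replicate(4e4, {
    t <- uniform_spanning_tree(g)
    paste(sort(paste(t[, 1], t[, 2])), collapse = "|")
  })
  tab <- table(draws)
  expect_equal(length(tab), n_trees)
  expect_uniform_chisq(as.numeric(tab), n_trees)
})

test_that("-ER corruption removes half the off-tree edges and stays connected", {
  # a tree has no removable edges
  tr <- path_graph(10)
  rec <- corrupt_subtract_er(tr, seed = 15)
  expect_equal(n_edges(rec$observed), n_edges(tr))
  expect_equal(nrow(rec$removed_edges), 0)

  # 4-cycle: |E0| = 1, floor(1/2) = 0 removals
  rec2 <- corrupt_subtract_er(cycle_graph(4), seed = 16)
  expect_equal(nrow(rec2$removed_edges), 0)

  # K5: 10 edges, tree 4, remove floor(6/2) = 3; always connected
  for (seed in 1:25) {
    rec3 <- corrupt_subtract_er(complete_graph(5), seed = seed)
    expect_equal(nrow(rec3$removed_edges), 3)
    expect_equal(n_edges(rec3$observed), 7)
    expect_true(netdict:::is_connected_graph(rec3$observed))
    expect_equal(nrow(rec3$added_edges), 0)
  }
  disc <- graph_from_edges(rbind(c("a", "b"), c("c", "d")))
  expect_error(corrupt_subtract_er(disc), "connected")
})

test_that("+ER corruption adds the prescribed number of new edges", {
  g <- er_graph(30, 0.1, seed = 17)  # some edges
  m <- n_edges(g)
  rec <- corrupt_add_er(g, "uniform", seed = 18)
  expect_equal(nrow(rec$added_edges), floor(m / 2))
  expect_equal(n_edges(rec$observed), m + floor(m / 2))
  # none of the added edges existed
  expect_false(any(edge_set_keys_for_test(rec$truth) %in%
                     paste(rec$added_edges[, 1], rec$added_edges[, 2])))
  expect_error(corrupt_add_er(complete_graph(5), "uniform"), "not enough")

  # block variant on an empty 100-node graph: mean added count ~ C(5,2) * 0.3
  empty <- graph_from_edges(matrix(character(0), 0, 2),
                            nodes = as.character(1:100))
  added <- vapply(1:200, function(s)
    nrow(corrupt_add_er(empty, "block", seed = s)$added_edges), 0)
  mu <- choose(5, 2) * 0.3
  se <- sqrt(choose(5, 2) * 0.3 * 0.7 / 200)
  expect_lt(abs(mean(added) - mu), 4 * se)
})

test_that("+WS corruption adds the WS edge set with exact counts", {
  empty <- graph_from_edges(matrix(character(0), 0, 2),
                            nodes = as.character(1:150))
  rec <- corrupt_add_ws(empty, n0 = 100, k = 20, p = 0.3, seed = 19)
  expect_equal(nrow(rec$added_edges), 1000)
  expect_equal(rec$params$n_generated, 1000)
  expect_equal(nrow(rec$removed_edges), 0)

  # p = 0 gives the exact ring lattice on the selected node ordering
  rec2 <- corrupt_add_ws(empty, n0 = 20, k = 4, p = 0, seed = 20)
  d <- netdict:::graph_degrees(rec2$observed)
  expect_equal(sort(unique(d)), c(0L, 4L))
  expect_equal(sum(d == 4), 20)
  expect_error(corrupt_add_ws(empty, n0 = 200, k = 4, p = 0.1), "exceed")
})

test_that("corruption records serialize to edge lists and a manifest", {
  g <- er_graph(20, 0.2, seed = 21)
  rec <- corrupt_add_er(g, "uniform", seed = 22)
  d <- withr::local_tempdir()
  write_corruption_record(rec, d)
  expect_true(file.exists(file.path(d, "observed.edgelist")))
  obs <- read_edgelist(file.path(d, "observed.edgelist"))
  expect_equal(n_edges(obs), n_edges(rec$observed))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$noise_type, "+ER-uniform")
})
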