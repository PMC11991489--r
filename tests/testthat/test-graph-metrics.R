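test_that("sparsity thresholding keeps the exact strongest-edge count", {
  set.seed(20)
  W <- matrix(runif(169), 13)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  A <- threshold_by_sparsity(W, 0.22)
  expect_equal(sum(A) / 2, 17)            # round(0.22 * 78)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # kept edges are the strongest ones
  kept_w <- W[upper.tri(W)][A[upper.tri(A)] == 1]
  drop_w <- W[upper.tri(W)][A[upper.tri(A)] == 0]
  expect_gte(min(kept_w), max(drop_w))
  # equal weights: the deterministic tie-break still hits the target count
  Wt <- matrix(0.5, 13, 13)
  diag(Wt) <- 1
  expect_equal(sum(threshold_by_sparsity(Wt, 0.25)) / 2, round(0.25 * 78))
  expect_identical(threshold_by_sparsity(Wt, 0.25),
                   threshold_by_sparsity(Wt, 0.25))
  A99 <- threshold_by_sparsity(W, 0.999)
  expect_equal(sum(A99) / 2, 78)          # effectively complete
  expect_error(threshold_by_sparsity(W, 0.001), "zero edges")
  expect_error(threshold_by_sparsity(W, 1.2), "sparsity")
})

test_that("metrics match closed forms on canonical graphs", {
  K13 <- matrix(1, 13, 13) - diag(13)
  expect_equal(clustering_coefficient(K13), 1)
  expect_equal(as.numeric(char_path_length(K13)), 1)
  expect_equal(global_efficiency(K13), 1)
  expect_equal(local_efficiency(K13), 1)
  star <- matrix(0, 7, 7)
  star[1, 2:7] <- star[2:7, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)
  expect_equal(local_efficiency(star), 0)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)
  empty <- matrix(0, 5, 5)
  expect_equal(global_efficiency(empty), 0)
  expect_error(char_path_length(empty), "no edges")
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(local_efficiency(K4), 1)
})

test_that("metrics equal exhaustive BFS brute force on random graphs", {
  set.seed(21)
  for (r in 1:15) {
    n <- sample(5:13, 1)
    A <- random_sym_adj(n, runif(1, 0.25, 0.7))
    if (sum(A) == 0) next
    expect_equal(clustering_coefficient(A), oracle_clustering(A))
    expect_equal(as.numeric(char_path_length(A)), oracle_path_length(A))
    expect_equal(global_efficiency(A), oracle_global_eff(A))
    expect_equal(local_efficiency(A), oracle_local_eff(A))
  }
  # and on a larger graph, as a cross-check of the BFS oracle itself
  A50 <- random_sym_adj(50, 0.1)
  expect_equal(as.numeric(char_path_length(A50)), oracle_path_length(A50))
  expect_equal(global_efficiency(A50), oracle_global_eff(A50))
})

test_that("adding edges never decreases global efficiency", {
  set.seed(22)
  A <- random_sym_adj(13, 0.2)
  e_prev <- global_efficiency(A)
  off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  for (k in sample(nrow(off), 10)) {
    A[off[k, 1], off[k, 2]] <- A[off[k, 2], off[k, 1]] <- 1
    e_now <- global_efficiency(A)
    expect_gte(e_now, e_prev - 1e-12)
    e_prev <- e_now
  }
})

test_that("degree-preserving nulls keep the degree sequence; K13 is rigid", {
  set.seed(23)
  g <- igraph::sample_smallworld(1, 30, 3, 0.1)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  # rewiring preserves degrees on every draw
  gr <- igraph::rewire(igraph::graph_from_adjacency_matrix(A, mode = "undirected"),
                       igraph::keeping_degseq(niter = 100 * sum(A) / 2))
  expect_equal(sort(igraph::degree(gr)), sort(rowSums(A)))
  null <- random_null(A, n_random = 30, seed = 1)
  expect_lt(null$C_random, clustering_coefficient(A))  # lattice-like input
  K13 <- matrix(1, 13, 13) - diag(13)
  m <- smallworld_metrics(K13, n_random = 5, seed = 2)
  expect_equal(m$sigma, 1)
  expect_error(random_null(matrix(0, 5, 5), 10), "edges")
})

test_that("metrics_over_sparsity produces every level plus a mean aggregate", {
  set.seed(24)
  W <- matrix(runif(169), 13)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  out <- metrics_over_sparsity(W, n_random = 10, seed = 3)
  expect_equal(nrow(out), 9)               # 8 levels + aggregate
  lv <- out[!is.na(out$sparsity), ]
  expect_equal(lv$sparsity, seq(0.22, 0.29, by = 0.01))
  expect_equal(lv$sigma, lv$gamma / lv$lambda)
  expect_true(all(lv$E_g >= 0 & lv$E_g <= 1))
  expect_true(all(lv$E_loc >= 0 & lv$E_loc <= 1))
  expect_true(all(diff(lv$E_g) >= -1e-12))  # monotone in sparsity
  agg <- out[is.na(out$sparsity), ]
  expect_equal(agg$E_g, mean(lv$E_g))
  # determinism under the same seed
  out2 <- metrics_over_sparsity(W, n_random = 10, seed = 3)
  expect_identical(out, out2)
})
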