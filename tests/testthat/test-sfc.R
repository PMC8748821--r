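path_graph <- function() {
  a <- matrix(0L, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  a
}

triangle_graph <- function() {
  a <- matrix(1L, 3, 3); diag(a) <- 0L; a
}

test_that("walk counts on the path graph match exhaustive enumeration", {
  wc <- sfc_walk_counts(path_graph(), seeds = 1, max_step = 3)
  expect_equal(unname(wc[1, ]), c(0, 1, 0))
  expect_equal(unname(wc[2, ]), c(1, 0, 1))
  expect_equal(unname(wc[3, ]), c(0, 2, 0))
})

test_that("walk counts on the triangle match exhaustive enumeration", {
  wc <- sfc_walk_counts(triangle_graph(), seeds = 1, max_step = 2)
  expect_equal(unname(wc[2, ]), c(2, 1, 1))
})

test_that("step one equals the sum of seed adjacency rows", {
  set.seed(31)
  a <- random_graph(9)
  seeds <- c(2, 5, 7)
  wc <- sfc_walk_counts(a, seeds, max_step = 1)
  expect_equal(unname(wc[1, ]), unname(colSums(a[seeds, ])))
})

test_that("matrix-power walk counts equal brute-force DFS enumeration", {
  set.seed(32)
  for (i in 1:25) {
    r <- sample(3:8, 1)
    a <- random_graph(r, density = runif(1, 0.2, 0.7))
    seeds <- sample(r, sample(1:min(3, r), 1))
    k <- sample(1:5, 1)
    expect_equal(unname(suppressWarnings(sfc_walk_counts(a, seeds, k))),
                 dfs_walk_counts(a, seeds, k))
  }
})

test_that("walk counts satisfy the recursion counts_{k+1} = counts_k %*% A", {
  set.seed(33)
  a <- random_graph(12)
  wc <- sfc_walk_counts(a, c(1, 4), max_step = 5)
  for (k in 1:4) {
    expect_equal(wc[k + 1, ], drop(wc[k, ] %*% a))
  }
})

test_that("walk counting validates its inputs", {
  a <- path_graph()
  expect_error(sfc_walk_counts(a, integer(0)), "empty")
  expect_error(sfc_walk_counts(a, 9), "1..R")
  bad <- a; bad[1, 1] <- 1L
  expect_error(sfc_walk_counts(bad, 1), "diagonal")
  iso <- matrix(0L, 3, 3); iso[2, 3] <- iso[3, 2] <- 1L
  expect_warning(sfc_walk_counts(iso, 1), "isolated")
})

test_that("z-normalization uses the population sd and flags constants", {
  z <- z_normalize_steps(matrix(c(0, 1, 2), 1, 3))
  expect_equal(unname(z[1, ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  zz <- z_normalize_steps(matrix(rpois(30, 5), 3, 10))
  expect_equal(rowMeans(zz), rep(0, 3), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(zz^2)), rep(1, 3), tolerance = 1e-12)
  const <- z_normalize_steps(matrix(4, 2, 5))
  expect_equal(attr(const, "degenerate_steps"), c(1L, 2L))
  expect_true(all(const == 0))
})

test_that("hub detection applies the mean-multiple rule", {
  expect_equal(detect_hubs(c(1, 1, 1, 1, 6), shift = "none"), 5L)
  expect_length(detect_hubs(rep(2, 8), shift = "none"), 0)
  d <- c(0, 1, 0, 2, 3)
  expect_equal(detect_hubs(d, multiplier = 0, shift = "none"),
               which(d > 0))
  # min-shift makes the rule meaningful on zero-mean z-degrees
  z <- c(-2, -1, 0, 1, 2)
  expect_equal(detect_hubs(z, shift = "min"),
               which(z - min(z) > 1.5 * mean(z - min(z))))
})

test_that("thresholding keeps the intended edge fraction", {
  set.seed(34)
  n <- 246
  fc <- matrix(0, n, n)
  fc[upper.tri(fc)] <- rnorm(n * (n - 1) / 2)
  fc <- fc + t(fc)
  g <- threshold_binarize(fc, 95)
  expected <- round(0.05 * n * (n - 1) / 2)
  expect_lte(abs(sum(g) / 2 - expected), 1)
  # single dominant edge survives a sufficiently strict threshold
  fc5 <- matrix(0.1, 5, 5); diag(fc5) <- 0
  fc5[1, 2] <- fc5[2, 1] <- 0.9
  g5 <- threshold_binarize(fc5, 95)
  expect_equal(sum(g5), 2)
  expect_equal(g5[1, 2], 1L)
  # percentile 0: complete graph minus diagonal
  g0 <- threshold_binarize(fc5, 0)
  expect_equal(sum(g0), 5 * 4)
  expect_error(threshold_binarize(matrix(1, 4, 4) - diag(4), 95), "equal")
})

test_that("signed ranking ignores strong negative edges, absolute keeps them", {
  fc <- matrix(0.1, 4, 4); diag(fc) <- 0
  fc[1, 2] <- fc[2, 1] <- -0.9
  fc[3, 4] <- fc[4, 3] <- 0.5
  g_signed <- threshold_binarize(fc, 80, edge_rank = "signed")
  g_abs <- threshold_binarize(fc, 80, edge_rank = "absolute")
  expect_equal(g_signed[1, 2], 0L)
  expect_equal(g_abs[1, 2], 1L)
})

test_that("cohort SFC is deterministic, prefix-stable, and permutation equivariant", {
  set.seed(35)
  ts <- matrix(rnorm(80 * 12), 80, 12)
  mats <- list(s1 = partial_correlation(ts), s2 = partial_correlation(ts))
  res <- run_sfc_cohort(mats, seeds = c(1, 2), percentile = 80)
  expect_equal(res$z_degrees[1, , ], res$z_degrees[2, , ])
  res6 <- run_sfc_cohort(mats, seeds = c(1, 2), percentile = 80,
                         max_step = 6)
  expect_equal(res6$raw_counts[, 1:5, ], res$raw_counts)
  # permuting region labels permutes walk counts identically
  a <- random_graph(10)
  perm <- sample(10)
  inv <- order(perm)
  wc <- sfc_walk_counts(a, c(1, 3), 4)
  wc_p <- sfc_walk_counts(a[perm, perm], inv[c(1, 3)], 4)
  expect_equal(unname(wc_p[, inv]), unname(wc))
})

test_that("per-subject failures are collected without aborting the cohort", {
  set.seed(36)
  good <- partial_correlation(matrix(rnorm(80 * 6), 80, 6))
  flat <- matrix(1, 6, 6); diag(flat) <- 0 # all-equal weights: undefined cutoff
  res <- suppressWarnings(run_sfc_cohort(list(ok = good, bad = flat),
                                         seeds = 1, percentile = 90))
  expect_equal(res$failures$subject_id, "bad")
  expect_false(anyNA(res$z_degrees["ok", , ]))
  expect_true(all(is.na(res$z_degrees["bad", , ])))
})
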