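test_that("BH adjustment reproduces hand-applied step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the reference step-up on random vectors and is monotone", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, stepup_bh(p), tolerance = 1e-12)
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

test_that("phenotype association matches a two-pass Pearson oracle", {
  set.seed(22)
  d <- matrix(rnorm(40 * 6), 40, 6)
  ph <- rnorm(40)
  em <- phenotype_association(d, ph)
  for (j in 1:6) {
    expect_equal(em$r[j], two_pass_pearson(d[, j], ph), tolerance = 1e-12)
    expect_equal(em$p[j], cor.test(d[, j], ph)$p.value, tolerance = 1e-10)
  }
  expect_true(all(em$q >= em$p))
})

test_that("a region equal to the phenotype is selected with r = 1", {
  set.seed(23)
  ph <- rnorm(30)
  d <- cbind(ph, matrix(rnorm(30 * 9), 30, 9))
  em <- phenotype_association(d, ph)
  expect_equal(em$r[1], 1)
  expect_equal(which.min(em$q), 1L)
  expect_true(1L %in% seed_regions(em))
})

test_that("constant degree columns are flagged, not propagated", {
  set.seed(24)
  d <- cbind(rep(2, 20), matrix(rnorm(20 * 3), 20, 3))
  em <- phenotype_association(d, rnorm(20))
  expect_equal(em$r[1], 0)
  expect_equal(em$p[1], 1)
  expect_true(em$degenerate[1])
  expect_false(em$selected[1])
  expect_error(phenotype_association(d, rep(1, 20)), "constant")
})

test_that("null degree matrices rarely yield any seed after FDR", {
  set.seed(25)
  hits <- vapply(1:100, function(i) {
    em <- phenotype_association(matrix(rnorm(50 * 100), 50, 100), rnorm(50))
    length(seed_regions(em))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("identity resampling gives perfect bootstrap stability", {
  set.seed(26)
  d <- matrix(rnorm(30 * 8), 30, 8)
  ph <- rnorm(30)
  bs <- bootstrap_stability(d, ph, n_boot = 5, frac = 1, replace = FALSE)
  expect_equal(bs$stability, rep(1, 5), tolerance = 1e-12)
})

test_that("bootstrap stability reflects planted signal strength", {
  set.seed(27)
  n <- 300
  ph <- rnorm(n)
  # strong planted map: half the regions correlate ~0.4 with the phenotype
  d <- cbind(sapply(1:10, \(.) 0.44 * ph + rnorm(n)),
             matrix(rnorm(n * 10), n, 10))
  strong <- bootstrap_stability(d, ph, n_boot = 100, rng_seed = 5)
  expect_gte(attr(strong, "mean"), 0.8)
  # without signal the only agreement comes from the ~63% subject overlap
  # of a with-replacement resample, so stability drops well below the
  # planted case but not to zero
  null <- bootstrap_stability(matrix(rnorm(n * 20), n, 20), ph,
                              n_boot = 100, rng_seed = 6)
  expect_lt(attr(null, "mean"), 0.75)
  expect_lt(attr(null, "mean"), attr(strong, "mean"))
})

test_that("network stratification equals a group-by average oracle", {
  p <- default_parcellation(28)
  v <- rnorm(28)
  strat <- stratify_by_network(v, p)
  oracle <- tapply(v, p$network, mean)
  expect_equal(strat$mean_value, as.numeric(oracle[strat$network]),
               tolerance = 1e-12)
  # constant vector: every network mean equals the constant
  expect_true(all(stratify_by_network(rep(3.5, 28), p)$mean_value == 3.5))
  # indicator contrast
  ind <- ifelse(p$network == "visual", 1, -1)
  s2 <- stratify_by_network(ind, p)
  expect_equal(s2$mean_value[s2$network == "visual"], 1)
  expect_true(all(s2$mean_value[s2$network != "visual"] == -1))
})

test_that("empty networks after restriction give NA, not zero", {
  p <- default_parcellation(28)
  visual_ids <- p$region_id[p$network == "visual"]
  s <- stratify_by_network(rnorm(28), p, regions = visual_ids)
  expect_true(is.na(s$mean_value[s$network == "somatomotor"]))
  expect_false(is.na(s$mean_value[s$network == "visual"]))
})
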