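test_that("BMI + WHR criteria reproduce the published group definitions", {
  ph <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    sex = c("female", "male", "female", "female"),
    bmi = c(22, 26, 24, 26),
    whr = c(0.80, 0.92, 0.95, 0.85)) # d: obese BMI but WHR at the cutoff
  g <- assign_groups(ph, "bmi_whr")
  expect_equal(as.character(g$group),
               c("healthy_weight", "overweight", "unassigned",
                 "unassigned"))
})

test_that("WHO risk bands use their own sex-specific cutoffs", {
  ph <- tibble::tibble(
    subject_id = as.character(1:5),
    sex = c("female", "female", "male", "male", "female"),
    bmi = rep(24, 5),
    whr = c(0.79, 0.87, 0.94, 1.01, 0.83))
  g <- assign_groups(ph, "who_whr")
  expect_equal(as.character(g$group),
               c("low_risk", "high_risk", "low_risk", "high_risk",
                 "unassigned"))
})

test_that("subjects with missing fields get error records, not groups", {
  ph <- tibble::tibble(subject_id = c("a", "b"), sex = c("female", "other"),
                       bmi = c(NA, 22), whr = c(0.8, 0.8))
  g <- assign_groups(ph)
  expect_true(all(is.na(g$group)))
  expect_true(all(!is.na(g$error)))
})

make_degrees <- function(n, steps = 2, r = 6, shift = 0, net_idx = NULL) {
  arr <- array(rnorm(n * steps * r), c(n, steps, r),
               dimnames = list(sprintf("s%03d", seq_len(n)),
                               paste0("step", seq_len(steps)), NULL))
  if (!is.null(net_idx)) arr[, , net_idx] <- arr[, , net_idx] + shift
  arr
}

fixed_assignment <- function(n, n_test) {
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = factor(rep(c("healthy_weight", "overweight"),
                       c(n - n_test, n_test)),
                   levels = c("healthy_weight", "overweight", "unassigned")),
    criteria = "bmi_whr")
}

test_that("group t-statistics match stats::t.test for both variants", {
  set.seed(41)
  n <- 40
  deg <- make_degrees(n)
  asg <- fixed_assignment(n, 15)
  for (variant in c("welch", "pooled")) {
    ct <- compare_groups(deg, asg, variant = variant)
    for (k in 1:2) {
      for (j in c(1, 4, 6)) {
        ref <- t.test(deg[26:40, k, j], deg[1:25, k, j],
                      var.equal = variant == "pooled")
        row <- ct$regional[ct$regional$step == k &
                             ct$regional$region_id == j, ]
        expect_equal(row$t, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(row$p, ref$p.value, tolerance = 1e-10)
        expect_equal(row$df, unname(ref$parameter), tolerance = 1e-8)
      }
    }
  }
})

test_that("swapping group labels flips every t sign exactly", {
  set.seed(42)
  n <- 30
  deg <- make_degrees(n)
  asg <- fixed_assignment(n, 12)
  swapped <- asg
  swapped$group <- factor(
    ifelse(asg$group == "overweight", "healthy_weight", "overweight"),
    levels = levels(asg$group))
  expect_equal(compare_groups(deg, asg)$regional$t,
               -compare_groups(deg, swapped)$regional$t)
})

test_that("tiny groups are rejected with the group sizes named", {
  deg <- make_degrees(10)
  expect_error(compare_groups(deg, fixed_assignment(10, 2)), "3")
})

test_that("network averaging equals an independent group-by oracle", {
  set.seed(43)
  p <- default_parcellation(28)
  deg <- make_degrees(5, steps = 3, r = 28)
  nd <- network_degree(deg, p)
  for (i in c(1, 5)) {
    for (k in 1:3) {
      oracle <- tapply(deg[i, k, ], p$network, mean)
      expect_equal(nd[i, k, ], oracle[dimnames(nd)[[3]]],
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # constant degrees: every network mean equals the constant
  cdeg <- array(2.5, c(4, 2, 28),
                dimnames = list(paste0("s", 1:4), NULL, NULL))
  expect_true(all(network_degree(cdeg, p) == 2.5))
  # single-region network passes its value through
  sizes <- c(visual = 26, thalamus = 1, caudate = 1)
  p2 <- parcellation_from_sizes(sizes)
  d2 <- make_degrees(3, steps = 1, r = 28)
  nd2 <- network_degree(d2, p2)
  thal_id <- p2$region_id[p2$network == "thalamus"]
  expect_equal(nd2[, 1, "thalamus"], d2[, 1, thal_id])
})

test_that("balanced bootstrap with the full reference group is degenerate", {
  set.seed(44)
  n <- 26
  deg <- make_degrees(n, r = 28)
  p <- default_parcellation(28)
  asg <- fixed_assignment(n, 10)
  bb <- balanced_bootstrap_compare(deg, asg, p, n_iter = 4,
                                   subsample_size = 16, rng_seed = 9)
  full <- compare_groups(deg, asg, p)
  for (it in 1:4) {
    expect_equal(bb$t[bb$iteration == it],
                 full$network$t, tolerance = 1e-12)
  }
})

test_that("balanced bootstrap recovers planted sign and is seed-reproducible", {
  set.seed(45)
  n <- 60
  p <- default_parcellation(28)
  net_idx <- which(p$network == "limbic")
  deg <- make_degrees(n, r = 28)
  deg[41:60, , net_idx] <- deg[41:60, , net_idx] + 1.2 # test group higher
  asg <- fixed_assignment(n, 20)
  bb <- balanced_bootstrap_compare(deg, asg, p, n_iter = 40,
                                   subsample_size = 20, rng_seed = 11)
  lim <- bb$t[bb$network == "limbic"]
  expect_gte(mean(lim > 0), 0.95)
  bb2 <- balanced_bootstrap_compare(deg, asg, p, n_iter = 40,
                                    subsample_size = 20, rng_seed = 11)
  expect_identical(bb$t, bb2$t)
  expect_error(balanced_bootstrap_compare(deg, asg, p, n_iter = 2,
                                          subsample_size = 41),
               "exceeds")
})
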