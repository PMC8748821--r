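test_that("identical config and seed reproduce the cohort exactly", {
  a <- simulate_cohort(quick_config(rng_seed = 7))
  b <- simulate_cohort(quick_config(rng_seed = 7))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$timeseries, b$timeseries)
  c <- simulate_cohort(quick_config(rng_seed = 8))
  expect_false(identical(a$timeseries[[1]], c$timeseries[[1]]))
})

test_that("phenotypes respect their physiological ranges", {
  co <- simulate_cohort(quick_config(n_subjects = 120, rng_seed = 2))
  ph <- co$phenotypes
  expect_true(all(ph$bmi > 0))
  expect_true(all(ph$whr > 0 & ph$whr < 2))
  expect_true(all(ph$age >= 18 & ph$age <= 85))
  expect_true(all(ph$sex %in% c("male", "female")))
  tf <- cbind(ph$tfeq_restraint, ph$tfeq_disinhibition, ph$tfeq_hunger)
  expect_true(all(tf >= 0))
  expect_true(all(tf == round(tf)))
  # sex-specific WHR: female distribution sits lower
  expect_lt(mean(ph$whr[ph$sex == "female"]),
            mean(ph$whr[ph$sex == "male"]))
})

test_that("group assignment counts match the configured fractions", {
  co <- simulate_cohort(sim_config(n_subjects = 300, n_regions = 28,
                                   n_timepoints = 30, n_true_seeds = 8,
                                   group_fraction = 0.25,
                                   healthy_fraction = 0.35, rng_seed = 3))
  g <- assign_groups(co$phenotypes)
  n_over <- sum(g$group == "overweight")
  n_healthy <- sum(g$group == "healthy_weight")
  # binomial-scale tolerance around the configured counts
  expect_lt(abs(n_over - 75), 3 * sqrt(300 * 0.25 * 0.75))
  expect_lt(abs(n_healthy - 105), 3 * sqrt(300 * 0.35 * 0.65))
})

test_that("ground truth marks exactly the planted regions", {
  co <- simulate_cohort(quick_config(rng_seed = 4))
  gt <- co$ground_truth
  expect_length(gt$seed_regions_true, 8)
  expect_true(all(gt$effect_sizes[gt$seed_regions_true] != 0))
  expect_true(all(gt$effect_sizes[-gt$seed_regions_true] == 0))
  # planted signs follow the community sign convention
  parc <- co$parcellation
  seeds_vis <- intersect(gt$seed_regions_true,
                         parc$region_id[parc$network == "visual"])
  if (length(seeds_vis)) {
    expect_true(all(gt$effect_sizes[seeds_vis] < 0))
  }
})

test_that("a null cohort yields no planted structure downstream", {
  co <- simulate_cohort(sim_config(n_subjects = 80, n_regions = 28,
                                   n_timepoints = 100, planted_effect_r = 0,
                                   group_effect_magnitude = 0,
                                   behavior_effect_r = 0, rng_seed = 5))
  d <- cohort_degrees(co)
  em <- phenotype_association(d, co$phenotypes$whr)
  expect_length(seed_regions(em), 0)
})

test_that("null-cohort phenotype p-values are uniform", {
  # one p-value per replicate cohort at a fixed region; KS against U(0,1)
  ps <- vapply(1:500, function(i) {
    co <- simulate_cohort(sim_config(
      n_subjects = 25, n_regions = 20, n_timepoints = 40,
      planted_effect_r = 0, n_true_seeds = 4, group_effect_magnitude = 0,
      behavior_effect_r = 0, rng_seed = 10000 + i))
    d <- cohort_degrees(co)
    phenotype_association(d, co$phenotypes$whr)$p[1]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_regions = 10), "20")
  expect_error(sim_config(planted_effect_r = 1), "\\[0, 1\\)")
  expect_error(sim_config(group_fraction = 0.7, healthy_fraction = 0.5),
               "<= 1")
  expect_error(sim_config(behavior_effects = tibble::tibble(
    network = "visual", score = "total", r = 0.2)), "subscale")
  expect_error(
    simulate_cohort(sim_config(n_subjects = 5, n_regions = 20,
                               n_timepoints = 10, n_true_seeds = 6,
                               behavior_effect_r = -0.9)),
    "attainable")
})

test_that("BMI and WHR effect maps align more strongly as coupling grows", {
  maps <- lapply(c(0.15, 0.9), function(cpl) {
    r_vals <- lapply(1:4, function(i) {
      co <- simulate_cohort(sim_config(
        n_subjects = 150, n_regions = 28, n_timepoints = 100,
        n_true_seeds = 10, group_effect_magnitude = 0,
        behavior_effect_r = 0, bmi_whr_coupling = cpl,
        rng_seed = 600 + i))
      d <- cohort_degrees(co)
      cor(phenotype_association(d, co$phenotypes$whr)$r,
          phenotype_association(d, co$phenotypes$bmi)$r)
    })
    mean(unlist(r_vals))
  })
  expect_gt(maps[[2]], 0)
  expect_gt(maps[[2]], maps[[1]])
})
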