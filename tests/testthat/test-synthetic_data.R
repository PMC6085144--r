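test_that("config constructors validate", {
  expect_error(cohort_sim_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_sim_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_sim_config(time_grid = c(0, 0, 6)), "strictly increasing")
  expect_error(cohort_sim_config(noise_sd_by_mark = c(1, 2)), "align")
  expect_error(ensemble_sim_config(rate_shape = 0), "positive")
})

test_that("generate_cohort is exact at zero noise and seed-reproducible", {
  cfg <- cohort_sim_config(n_subjects = 20, noise_sd = 0, seed = 6)
  g <- generate_cohort(cfg)
  # every record lies on its truth curve (up to the [0, 10] clamp)
  for (i in seq_len(20)) {
    tr <- g$truth[i, ]
    mu <- pmin(pmax(tr$prefactor * (1 + GRID)^(-tr$exponent), 0), 10)
    expect_equal(g$cohort$records[[i]]$values, mu, tolerance = 1e-12)
  }
  # bit-reproducibility under the seed
  g2 <- generate_cohort(cfg)
  expect_identical(cohort_matrix(g$cohort), cohort_matrix(g2$cohort))
  expect_identical(g$truth, g2$truth)
  # different seed differs
  g3 <- generate_cohort(cohort_sim_config(n_subjects = 20, noise_sd = 0, seed = 7))
  expect_false(identical(g$truth, g3$truth))
})

test_that("generated values respect bounds, worseners and missingness", {
  g <- generate_cohort(cohort_sim_config(seed = 2, worsener_frac = 0.2))
  m <- cohort_matrix(g$cohort)
  expect_true(all(m >= 0 & m <= 10))
  expect_gt(sum(g$truth$exponent < 0), 0)
  expect_true(all(g$truth$exponent[g$truth$worsener] < 0))
  expect_true(all(g$truth$exponent[!g$truth$worsener] >= 0))
  gm <- generate_cohort(cohort_sim_config(seed = 2, missing_frac = 0.25))
  expect_gt(sum(is.na(cohort_matrix(gm$cohort))), 0)
  # baseline mark never deleted
  expect_false(anyNA(cohort_matrix(gm$cohort)[, 1]))
})

test_that("per-mark scatter: noise recovery and approximate constancy", {
  # heterogeneity off: sample SDs recover the injected noise SD
  gn <- generate_cohort(cohort_sim_config(seed = 1, prefactor_sd = 1e-9,
                                          exponent_sd = 1e-9, worsener_frac = 0,
                                          value_bounds = c(-100, 100)))
  sds <- apply(cohort_matrix(gn$cohort), 2, sd)
  expect_lt(max(abs(sds - 1.9)), 0.25)
  # full defaults (unclamped): scatter approximately constant across marks
  gw <- generate_cohort(cohort_sim_config(seed = 1, value_bounds = c(-100, 100)))
  sdw <- apply(cohort_matrix(gw$cohort), 2, sd)
  expect_lt(max(sdw) / min(sdw), 1.25)
})

test_that("aggregate_exponentials converges to the closed form", {
  grid <- c(0, 1, 6, 12)
  # t = 0 is exactly 1 regardless of config
  agg <- aggregate_exponentials(ensemble_sim_config(1000, 2, 0.5, grid, seed = 1))
  expect_identical(unname(agg[1]), 1)
  # Monte Carlo within 3/sqrt(n) of (1 + bt)^(-a) at every grid point
  n <- 100000
  agg2 <- aggregate_exponentials(ensemble_sim_config(n, 0.5, 2, grid, seed = 1))
  expect_lt(max(abs(agg2 - closed_form_aggregate(0.5, 2, grid))), 3 / sqrt(n))
  # O(1/sqrt(n)) convergence: error shrinks with n (paired seeds, two sizes)
  err_at <- function(n) {
    e <- vapply(1:20, function(s) {
      a <- aggregate_exponentials(ensemble_sim_config(n, 1, 1, grid, seed = s))
      max(abs(a - closed_form_aggregate(1, 1, grid)))
    }, numeric(1))
    mean(e)
  }
  expect_lt(err_at(40000), err_at(400) / 5)
})

test_that("closed_form_aggregate has asymptotic log-log slope -a", {
  expect_equal(closed_form_aggregate(0.7, 2, 0), 1)
  expect_equal(closed_form_aggregate(1, 1, 1), 0.5)
  slope <- (log(closed_form_aggregate(0.3, 1, 1000)) -
            log(closed_form_aggregate(0.3, 1, 100))) / (log(1000) - log(100))
  expect_lt(abs(slope - (-0.3)) / 0.3, 0.01)
  expect_error(closed_form_aggregate(-1, 1, 0), "> 0")
  expect_error(closed_form_aggregate(1, 1, -2), ">= 0")
})

test_that("full-pipeline exponent recovery from the generator", {
  g <- generate_cohort(cohort_sim_config(noise_sd = 0.2, worsener_frac = 0, seed = 1))
  expect_lt(abs(exponent_distribution(g$cohort)$mean - 0.3), 0.03)
  g2 <- generate_cohort(cohort_sim_config(noise_sd = 1.9, worsener_frac = 0, seed = 1))
  expect_lt(abs(exponent_distribution(g2$cohort)$mean - 0.3), 0.1)
})

test_that("generate_crps_case round-trips its truth", {
  cs <- generate_crps_case(true_P = 1.7, seed = 1)  # zero noise: exact
  fit <- fit_two_param(dose_to_pain_proxy(cs$doses))
  expect_rel_equal(fit$exponent, 1.7, tol = 1e-6)
  # the oxycodone anchor: 70 mg/day at month 2
  expect_equal(cs$doses$daily_dose_mg[cs$doses$time_months == 2], 70)
  expect_error(generate_crps_case(true_P = -1), "> 0")
  expect_error(generate_crps_case(months = 6), "span")
})
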