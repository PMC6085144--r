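test_that("projection schemes are wired as labelled", {
  expect_equal(projection_scheme("I")$fit_marks, c(0, 6))
  expect_equal(projection_scheme("II")$fit_marks, c(0, 1, 6))
  expect_equal(projection_scheme("III")$fit_marks, c(0, 1))
  expect_equal(projection_scheme("IV")$exponent_mode, "fitted")
  expect_equal(projection_scheme("I")$exponent_mode, "fixed")
  expect_equal(projection_scheme("II")$fixed_P, 0.3)
  expect_error(custom_scheme(0, "fitted"), "not enough")
})

test_that("all schemes are exact on noise-free matching power laws", {
  r <- pl_record("s", 5, 0.3)
  truth <- pl_evaluate(powerlaw_params(5, 0.3, 1), 12)
  for (lb in c("I", "II", "III", "IV")) {
    pred <- project_record(r, projection_scheme(lb), T = 12)
    expect_rel_equal(as.numeric(pred), truth)
  }
  # flat record under scheme III: prefactor-averaging rule by hand
  flat <- ts_record("f", GRID, rep(2, 4))
  pred <- project_record(flat, projection_scheme("III"), T = 12)
  expect_equal(as.numeric(pred), mean(c(2 * 1^0.3, 2 * 2^0.3)) * 13^(-0.3))
  expect_error(project_record(r, projection_scheme("I"), T = 3), "precedes")
  expect_error(project_record(ts_record("m", c(1, 6, 12), c(4, 3, 2)),
                              projection_scheme("I")), "lacks mark")
})

test_that("cohort_deviations computes band accuracies inclusively", {
  # construct a cohort whose deviations at T = 12 are exactly (-0.5, 0.9, 2, -3)
  devs <- c(-0.5, 0.9, 2, -3)
  base <- pl_evaluate(powerlaw_params(8, 0.3, 1), GRID)
  recs <- lapply(seq_along(devs), function(i) {
    v <- base; v[4] <- v[4] + devs[i]
    ts_record(paste0("s", i), GRID, v)
  })
  d <- cohort_deviations(pain_cohort(recs), projection_scheme("II"), T = 12)
  expect_equal(unname(d$deviations), devs, tolerance = 1e-9)
  expect_equal(unname(d$accuracies), c(50, 50, 75))  # band 2 counts |d| = 2
  expect_equal(d$mean_bias, mean(devs), tolerance = 1e-9)
  # all-zero deviations: 100% everywhere
  d0 <- cohort_deviations(pain_cohort(lapply(1:3, function(i)
    pl_record(paste0("z", i), 4 + i, 0.3))), projection_scheme("I"), T = 12)
  expect_equal(unname(d0$accuracies), c(100, 100, 100))
  expect_equal(d0$mean_bias, 0, tolerance = 1e-9)
  expect_error(cohort_deviations(pain_cohort(recs), projection_scheme("I"), T = 5),
               "not on the cohort grid")
})

test_that("accuracy is monotone in the band and sign-symmetric", {
  set.seed(3)
  devs <- rnorm(60, 0.3, 1.5)
  for (sgn in c(1, -1)) {
    s <- painlaw:::deviation_summary(sgn * devs, bands = c(0.5, 1, 1.5, 2, 3))
    expect_true(all(diff(s$accuracies) >= 0))
    expect_true(all(s$accuracies >= 0 & s$accuracies <= 100))
  }
  a1 <- painlaw:::deviation_summary(devs, c(1, 2))$accuracies
  a2 <- painlaw:::deviation_summary(-devs, c(1, 2))$accuracies
  expect_equal(a1, a2)
})

test_that("exponent_distribution recovers per-record and cohort truth", {
  # identical exact records
  ch <- pl_cohort(rep(5, 4), rep(0.3, 4))
  ed <- exponent_distribution(ch)
  expect_equal(ed$mean, 0.3, tolerance = 1e-9)
  expect_equal(ed$sd, 0, tolerance = 1e-9)
  # two-record mean
  ed2 <- exponent_distribution(pl_cohort(c(5, 5), c(0.2, 0.4)))
  expect_equal(ed2$mean, 0.3, tolerance = 1e-9)
  # simulated recovery at low noise: mean within 0.03 of 0.3
  g <- generate_cohort(cohort_sim_config(noise_sd = 0.2, worsener_frac = 0, seed = 1))
  ed3 <- exponent_distribution(g$cohort)
  expect_equal(ed3$n, 243)
  expect_lt(abs(ed3$mean - 0.3), 0.03)
})

test_that("transition slope scatter flags the noisy first transition", {
  # exact common-P cohort: every slope -P, zero spread
  ch <- pl_cohort(2:6, rep(0.4, 5))
  ts <- transition_slope_scatter(ch)
  for (s in ts$slopes) expect_equal(unname(s), rep(-0.4, 5), tolerance = 1e-9)
  expect_lt(max(ts$spreads), 1e-12)  # zero up to float rounding
  # single record: degenerate zero spreads
  ts1 <- transition_slope_scatter(pain_cohort(list(pl_record())))
  expect_true(all(ts1$spreads == 0))
  # inflated noise at t = 0 makes the 0->1 transition disproportionately broad
  g <- generate_cohort(cohort_sim_config(
    seed = 1, worsener_frac = 0, noise_sd_by_mark = c(1.9 * 6, 1.9, 1.9, 1.9)))
  ts6 <- transition_slope_scatter(g$cohort)
  expect_gt(ts6$spread_ratios[["0->1"]], 3)
})

test_that("noise at t = 0 only penalizes schemes that use t = 0", {
  g <- generate_cohort(cohort_sim_config(
    seed = 1, worsener_frac = 0, noise_sd_by_mark = c(1.9 * 6, 1.9, 1.9, 1.9)))
  dI <- cohort_deviations(g$cohort, projection_scheme("I"))
  d16 <- cohort_deviations(g$cohort, custom_scheme(c(1, 6), "fixed"))
  expect_gt(dI$spread, d16$spread)
})
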