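test_that("mean_trajectory computes per-mark means and SDs on both scales", {
  ch <- pain_cohort(list(ts_record("a", c(0, 12), c(4, 2)),
                         ts_record("b", c(0, 12), c(6, 4))))
  tr <- mean_trajectory(ch)
  expect_equal(unname(tr$means), c(5, 3))
  expect_equal(unname(tr$sds), c(sqrt(2), sqrt(2)))
  expect_equal(tr$n, c(2, 2))
  # geometric scale transforms record-wise before averaging
  trg <- mean_trajectory(ch, "geometric")
  expect_equal(unname(trg$means), c(mean(c(16, 64)), mean(c(4, 16))))
  expect_error(mean_trajectory(pain_cohort(list(ts_record("a", c(0, 12), c(4, 2))))),
               ">= 2 subjects")
  # injected noise SD is recovered when heterogeneity is off (unclamped)
  g <- generate_cohort(cohort_sim_config(seed = 1, prefactor_sd = 1e-9,
                                         exponent_sd = 1e-9, worsener_frac = 0,
                                         value_bounds = c(-100, 100)))
  sds <- mean_trajectory(g$cohort)$sds
  expect_lt(max(abs(sds - 1.9)), 0.25)
})

test_that("fit_exponential inverts exponential decay on noise-free means", {
  ch <- pain_cohort(lapply(1:3, function(i) {
    ts_record(paste0("s", i), GRID, (5 + 0.1 * i) * exp(-GRID / 8),
              scale = "dose_proxy")
  }))
  fit <- fit_exponential(mean_trajectory(ch))
  expect_rel_equal(fit$amplitude, mean(5 + 0.1 * (1:3)))
  expect_rel_equal(fit$tau, 8)
  # flat means: infinite time constant sentinel
  flat <- pain_cohort(list(ts_record("a", GRID, rep(3, 4)),
                           ts_record("b", GRID, rep(5, 4))))
  expect_equal(fit_exponential(mean_trajectory(flat))$tau, Inf)
})

test_that("chi_square follows its definition and scaling law", {
  ch <- pain_cohort(list(ts_record("a", c(0, 12), c(4, 2)),
                         ts_record("b", c(0, 12), c(6, 4))))
  tr <- mean_trajectory(ch)
  expect_equal(chi_square(tr, tr$means), 0)
  # one mark off by exactly one standard error
  se <- tr$sds / sqrt(tr$n)
  expect_equal(chi_square(tr, tr$means + c(se[1], 0)), 1)
  expect_error(chi_square(tr, c(1, 2, 3)), "align")
  # duplication of every record: with the sample-SD convention (n-1
  # denominator, matching the hand-arithmetic SDs above) the chi-square of
  # a fixed misfit scales by exactly (2n-1)/(n-1), i.e. 3 at n = 2,
  # approaching the idealized factor 2 as n grows
  dup <- function(ch) pain_cohort(c(ch$records,
    lapply(ch$records, function(r)
      ts_record(paste0(r$subject_id, "_dup"), r$times, r$values, r$scale))))
  tr2 <- mean_trajectory(dup(ch))
  model <- tr$means + 0.5
  expect_rel_equal(chi_square(tr2, model), 3 * chi_square(tr, model))
  g <- generate_cohort(cohort_sim_config(n_subjects = 60, seed = 4))
  trg <- mean_trajectory(g$cohort)
  trg2 <- mean_trajectory(dup(g$cohort))
  mg <- trg$means + 0.5
  expect_rel_equal(chi_square(trg2, mg),
                   chi_square(trg, mg) * (2 * 60 - 1) / (60 - 1))
  flat <- pain_cohort(list(ts_record("a", c(0, 12), c(3, 3)),
                           ts_record("b", c(0, 12), c(3, 3))))
  expect_error(chi_square(mean_trajectory(flat), c(3, 3)), "zero SD")
})

test_that("the generating family wins the chi-square comparison", {
  # power-law cohort: power-law chi-square ~0, exponential penalized
  g <- generate_cohort(cohort_sim_config(seed = 1, worsener_frac = 0))
  mc <- compare_models(g$cohort)
  expect_gt(mc$nrs$ratio, 5)
  expect_gt(mc$geometric$ratio, 5)
  # symmetric sanity check: exponential-generated cohort favors exponential
  set.seed(2)
  recs <- lapply(1:60, function(i) {
    y <- pmin(pmax(6 * exp(-GRID / 5) + rnorm(4, 0, 0.8), 0), 10)
    ts_record(paste0("e", i), GRID, y)
  })
  che <- pain_cohort(recs)
  tre <- mean_trajectory(che)
  c_ex <- chi_square(tre, pl_evaluate(fit_exponential(tre), GRID))
  c_pl <- chi_square(tre, pl_evaluate(fit_powerlaw_mean(tre), GRID))
  expect_lt(c_ex, c_pl)
})

test_that("the generating family wins in most replicates at reduced n", {
  # 100 replicate cohorts at n = 60: power-law truth beats exponential >= 95%
  wins <- vapply(1:100, function(s) {
    g <- generate_cohort(cohort_sim_config(n_subjects = 60, seed = 1000 + s,
                                           worsener_frac = 0))
    tr <- mean_trajectory(g$cohort)
    c_pl <- chi_square(tr, pl_evaluate(fit_powerlaw_mean(tr), GRID))
    c_ex <- chi_square(tr, pl_evaluate(fit_exponential(tr), GRID))
    c_pl < c_ex
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
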