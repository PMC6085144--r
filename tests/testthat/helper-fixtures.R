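# Fixtures are built in code: exact power-law records and small cohorts.

GRID <- c(0, 1, 6, 12)

# record lying exactly on F(t) = prefactor * (1 + t/t0)^(-P)
pl_record <- function(id = "s1", prefactor = 5, exponent = 0.4, t0 = 1,
                      marks = GRID, scale = "nrs") {
  ts_record(id, marks,
            pl_evaluate(powerlaw_params(prefactor, exponent, t0), marks),
            scale = scale)
}

# cohort of exact power-law records with per-subject parameters
pl_cohort <- function(prefactors, exponents, t0 = 1, marks = GRID) {
  stopifnot(length(prefactors) == length(exponents))
  pain_cohort(lapply(seq_along(prefactors), function(i) {
    pl_record(sprintf("s%02d", i), prefactors[i], exponents[i], t0, marks)
  }), marks)
}

expect_rel_equal <- function(object, expected, tol = 1e-9) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
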