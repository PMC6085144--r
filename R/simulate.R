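#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a musculoskeletal physical-therapy
#' cohort: 243 complete records on the 0/1/6/12-month grid, per-subject
#' power-law mean trajectories with exponents centered on 0.3, and
#' approximately constant cross-sectional SD of 1.9 NRS units at each mark.
#' A small fraction of subjects (default 5%) are "worseners" with a
#' negative exponent (pain increasing over time).
#'
#' @param n_subjects Number of subjects (default 243).
#' @param time_grid Time marks in months (default 0, 1, 6, 12).
#' @param prefactor_mean,prefactor_sd Baseline pain distribution in NRS
#'   units (defaults 5.5, 1.5), truncated below at 0.5.
#' @param exponent_mean,exponent_sd Exponent distribution (defaults 0.3,
#'   0.1), truncated below at `exponent_floor` for non-worseners.
#' @param exponent_floor Lower truncation for recovery exponents (default 0).
#' @param worsener_frac Fraction of subjects drawn with a negative exponent
#'   (default 0.05); worsener exponents are -|N(0.1, 0.05)|.
#' @param noise_sd Additive Gaussian noise SD in NRS units at every mark
#'   (default 1.9).
#' @param noise_sd_by_mark Optional per-mark noise SD vector overriding
#'   `noise_sd` (e.g. to inflate scatter at t = 0 only).
#' @param t0 Time offset of the generating power law (default 1 month).
#' @param value_bounds Clamp interval for generated values (default 0-10).
#' @param missing_frac Fraction of non-baseline marks deleted completely at
#'   random (default 0), for imputation testing.
#' @param seed Integer seed; every draw is reproducible under it.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 243, time_grid = c(0, 1, 6, 12),
                              prefactor_mean = 5.5, prefactor_sd = 1.5,
                              exponent_mean = 0.3, exponent_sd = 0.1,
                              exponent_floor = 0, worsener_frac = 0.05,
                              noise_sd = 1.9, noise_sd_by_mark = NULL,
                              t0 = 1, value_bounds = c(0, 10),
                              missing_frac = 0, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  if (!is.null(noise_sd_by_mark) && length(noise_sd_by_mark) != length(time_grid))
    stop("noise_sd_by_mark must align with time_grid")
  if (worsener_frac < 0 || worsener_frac > 1) stop("worsener_frac in [0, 1]")
  if (missing_frac < 0 || missing_frac >= 1) stop("missing_frac in [0, 1)")
  structure(as.list(environment()), class = "cohort_sim_config")
}

# Truncated-normal draw by rejection; fine for mild truncation.
rtruncnorm_low <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate a synthetic cohort with known truth
#'
#' Per subject: draw a prefactor and exponent, form the mean trajectory
#' `prefactor * (1 + t/t0)^(-P)` on the grid, add independent Gaussian noise
#' and clamp to the value bounds. Optionally deletes non-baseline marks
#' completely at random. Bit-reproducible under the config seed.
#'
#' @param config A [cohort_sim_config()].
#' @return List with `cohort` (a [pain_cohort()]) and `truth` (data.frame of
#'   per-subject prefactor and exponent).
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  grid <- config$time_grid
  prefactor <- rtruncnorm_low(n, config$prefactor_mean, config$prefactor_sd, 0.5)
  worsener <- stats::runif(n) < config$worsener_frac
  exponent <- rtruncnorm_low(n, config$exponent_mean, config$exponent_sd,
                             config$exponent_floor)
  exponent[worsener] <- -abs(stats::rnorm(sum(worsener), 0.1, 0.05))
  sd_k <- if (is.null(config$noise_sd_by_mark))
    rep(config$noise_sd, length(grid)) else config$noise_sd_by_mark
  # widened bounds (diagnostic, unclamped runs) leave the NRS range
  rec_scale <- if (config$value_bounds[1] >= 0 && config$value_bounds[2] <= 10)
    "nrs" else "dose_proxy"
  records <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- prefactor[i] * (1 + grid / config$t0)^(-exponent[i])
    y <- mu + stats::rnorm(length(grid), 0, sd_k)
    y <- pmin(pmax(y, config$value_bounds[1]), config$value_bounds[2])
    if (config$missing_frac > 0 && length(grid) > 1L) {
      drop <- which(stats::runif(length(grid) - 1L) < config$missing_frac) + 1L
      y[drop] <- NA_real_
    }
    records[[i]] <- ts_record(sprintf("s%03d", i), grid, y, scale = rec_scale)
  }
  list(cohort = pain_cohort(records, grid),
       truth = data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                          prefactor = prefactor, exponent = exponent,
                          worsener = worsener, stringsAsFactors = FALSE))
}

#' Configuration for an exponential-decay ensemble
#'
#' Many elements decaying exponentially with rates drawn from a gamma
#' distribution; their aggregate follows a power law whose exponent equals
#' the gamma shape (see [closed_form_aggregate()]).
#'
#' @param n_elements Number of ensemble elements.
#' @param rate_shape Gamma shape a (> 0, dimensionless).
#' @param rate_scale Gamma scale b (> 0, per month).
#' @param time_grid Evaluation times (months).
#' @param seed Integer seed.
#' @return List of class `ensemble_sim_config`.
#' @export
ensemble_sim_config <- function(n_elements = 10000, rate_shape = 0.3,
                                rate_scale = 1, time_grid = c(0, 1, 6, 12),
                                seed = 1L) {
  if (n_elements < 1 || rate_shape <= 0 || rate_scale <= 0)
    stop("n_elements, rate_shape, rate_scale must be positive")
  structure(as.list(environment()), class = "ensemble_sim_config")
}

#' Monte-Carlo aggregate of exponential decays
#'
#' Draws `n_elements` rates lambda ~ Gamma(shape a, scale b) and returns the
#' ensemble mean of exp(-lambda t) at each grid time. As n grows this
#' converges at rate O(1/sqrt(n)) to the gamma-mixture closed form
#' `(1 + b t)^(-a)`.
#'
#' @param config An [ensemble_sim_config()].
#' @return Numeric vector of trajectory values, named by the grid times.
#' @export
aggregate_exponentials <- function(config = ensemble_sim_config()) {
  stopifnot(inherits(config, "ensemble_sim_config"))
  set.seed(config$seed)
  lambda <- stats::rgamma(config$n_elements, shape = config$rate_shape,
                          scale = config$rate_scale)
  stats::setNames(
    vapply(config$time_grid, function(t) mean(exp(-lambda * t)), numeric(1)),
    paste0("t", config$time_grid))
}

#' Closed-form gamma-mixture of exponential decays
#'
#' The expectation of exp(-lambda t) over lambda ~ Gamma(shape a, scale b)
#' is exactly \deqn{(1 + b t)^{-a},} a shifted power law whose asymptotic
#' log-log slope is -a: aggregating heterogeneous exponential decays
#' produces a power law, with the exponent set by the shape of the rate
#' distribution.
#'
#' @param a Gamma shape (> 0).
#' @param b Gamma scale (> 0, per month).
#' @param t Times (>= 0, vectorized).
#' @return Aggregate trajectory values.
#' @export
closed_form_aggregate <- function(a, b, t) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (!is.finite(b) || b <= 0) stop("b must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  (1 + b * t)^(-a)
}

#' Generate a synthetic single-subject case study
#'
#' Emulates the structure of the CRPS case: an oxycodone phase, a gabapentin
#' phase, and a no-medication tail whose residual NRS ratings come from the
#' geometric pain map, all consistent with one underlying power-law pain
#' trajectory; plus an independent strength-gap series following its own
#' power law. Truth parameters are returned for recovery tests.
#'
#' @param true_P Pain-trajectory exponent (> 0; case-study value 1.7).
#' @param months Total span in months (default 24).
#' @param pain_at_2m Proxy anchoring: oxycodone-equivalent dose at month 2
#'   (default 70 mg/day, i.e. prefactor chosen so F(2) = 70).
#' @param strength_q Strength-gap exponent (default 1.0).
#' @param noise_sd Multiplicative log-normal noise sigma on doses and gaps
#'   (default 0, exact trajectories).
#' @param t0 Time offset (default 1).
#' @param step_ratio Geometric map ratio for residual ratings (default 2).
#' @param equivalence Medication equivalence map as in
#'   [dose_to_pain_proxy()].
#' @param seed Integer seed.
#' @return List with `doses` ([dose_history()]), `strength_time`,
#'   `strength_ratio`, and `truth` (P, prefactor, q, q_prefactor, kappa).
#' @export
generate_crps_case <- function(true_P = 1.7, months = 24, pain_at_2m = 70,
                               strength_q = 1.0, noise_sd = 0, t0 = 1,
                               step_ratio = 2,
                               equivalence = c(oxycodone = 1, gabapentin = 300),
                               seed = 1L) {
  if (true_P <= 0) stop("true_P must be > 0")
  if (months <= 9) stop("span must exceed the 9-month medicated period")
  set.seed(seed)
  F0 <- pain_at_2m * (1 + 2 / t0)^true_P
  truth_curve <- function(t) F0 * (1 + t / t0)^(-true_P)
  times <- sort(unique(c(0:9, seq(10, months, by = 2), months)))
  med <- ifelse(times <= 3, "oxycodone", ifelse(times <= 9, "gabapentin", "none"))
  pain <- truth_curve(times) * exp(stats::rnorm(length(times), 0, noise_sd))
  medicated <- med != "none"
  equiv <- rep(1, length(times))
  equiv[medicated] <- unlist(equivalence[med[medicated]])
  dose <- ifelse(medicated, pain * equiv, 0)
  # residual ratings: geometric map of the proxy with kappa = 1, so the
  # splice in dose_to_pain_proxy() is exact; rated at the last medicated
  # mark too, which anchors the calibration.
  residual <- rep(NA_real_, length(times))
  anchor <- med == "none" | times == max(times[med != "none"])
  residual[anchor] <- log(pain[anchor]) / log(step_ratio)
  doses <- dose_history(times, med, dose, residual)
  s_pref <- 0.9  # strength gap at t = 0 (90% deficit)
  s_times <- seq(1, months, by = 2)
  gap <- s_pref * (1 + s_times / t0)^(-strength_q) *
    exp(stats::rnorm(length(s_times), 0, noise_sd))
  list(doses = doses,
       strength_time = s_times,
       strength_ratio = 1 - pmin(gap, 1),
       truth = list(P = true_P, prefactor = F0, q = strength_q,
                    q_prefactor = s_pref, kappa = 1))
}
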