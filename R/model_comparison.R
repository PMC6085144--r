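#' Mean trajectory of a cohort
#'
#' Per-mark mean, SD and count of the complete records, on the raw NRS scale
#' or after mapping each value through the geometric pain scale
#' ([geometric_from_nrs()], applied record-wise before averaging).
#'
#' @param cohort A [pain_cohort()].
#' @param scale `"nrs"` or `"geometric"`.
#' @param step_ratio Per-step ratio for the geometric mapping (default 2).
#' @return Object of class `mean_trajectory`: `time_grid`, `means`, `sds`,
#'   `n` (per mark), `scale`.
#' @export
mean_trajectory <- function(cohort, scale = c("nrs", "geometric"), step_ratio = 2) {
  scale <- match.arg(scale)
  stopifnot(inherits(cohort, "pain_cohort"))
  cohort <- complete_records(cohort)
  m <- cohort_matrix(cohort)
  if (scale == "geometric") m <- geometric_from_nrs(m, step_ratio)
  if (nrow(m) < 2L) stop("mean trajectory needs >= 2 subjects per mark")
  structure(list(time_grid = cohort$time_grid,
                 means = colMeans(m),
                 sds = apply(m, 2, stats::sd),
                 n = rep(nrow(m), ncol(m)),
                 scale = scale),
            class = "mean_trajectory")
}

#' @export
print.mean_trajectory <- function(x, ...) {
  cat(sprintf("<mean_trajectory> scale %s, n = %d\n", x$scale, x$n[1]))
  print(data.frame(t = x$time_grid, mean = x$means, sd = x$sds, row.names = NULL))
  invisible(x)
}

#' Fit a power law to a mean trajectory
#'
#' The same log-space regression as the per-record fits, applied to the
#' per-mark means.
#'
#' @param traj A [mean_trajectory()].
#' @param t0 Time offset (default 1).
#' @param floor Value floor (default 0.1).
#' @return [powerlaw_params()].
#' @export
fit_powerlaw_mean <- function(traj, t0 = 1, floor = 0.1) {
  stopifnot(inherits(traj, "mean_trajectory"))
  r <- ts_record("mean", traj$time_grid, traj$means, scale = "dose_proxy")
  fit_two_param(r, t0 = t0, floor = floor)
}

#' Fit an exponential decay to a mean trajectory
#'
#' Least squares of log(mean) on t: amplitude = exp(intercept),
#' tau = -1/slope. A non-decaying fit (slope >= 0) reports `tau = Inf`.
#'
#' @inheritParams fit_powerlaw_mean
#' @return [expdecay_params()].
#' @export
fit_exponential <- function(traj, floor = 0.1) {
  stopifnot(inherits(traj, "mean_trajectory"))
  if (length(traj$time_grid) < 2L) stop("need >= 2 marks")
  ly <- log(floor_values(traj$means, floor))
  fit <- stats::lm.fit(cbind(1, traj$time_grid), ly)
  slope <- fit$coefficients[[2L]]
  expdecay_params(exp(fit$coefficients[[1L]]),
                  if (slope >= 0) Inf else -1 / slope)
}

#' Chi-square goodness of fit to a mean trajectory
#'
#' \deqn{\chi^2 = \sum_k \left(\frac{\bar Y_k - m_k}{s_k/\sqrt{n_k}}\right)^2}
#' with per-mark standard errors as weights (the fit target is the mean, so
#' its sampling error is SD/sqrt(n)). Zero at a perfect fit; one per mark
#' that misses by exactly one standard error.
#'
#' @param traj A [mean_trajectory()].
#' @param model_values Model predictions aligned with `traj$time_grid`.
#' @return Chi-square statistic (dimensionless).
#' @export
chi_square <- function(traj, model_values) {
  stopifnot(inherits(traj, "mean_trajectory"))
  if (length(model_values) != length(traj$time_grid))
    stop("model_values must align with the time grid")
  if (any(traj$sds == 0)) stop("zero SD at a mark: chi-square weight undefined")
  se <- traj$sds / sqrt(traj$n)
  sum(((traj$means - model_values) / se)^2)
}

#' Compare power-law and exponential fits on both pain scales
#'
#' Fits both models to the cohort mean trajectory on the NRS scale and on
#' the geometric scale (values transformed record-wise before averaging;
#' each scale is fitted independently), and reports chi-square per model per
#' scale plus the exponential/power-law ratio.
#'
#' @param cohort A [pain_cohort()].
#' @param t0,floor Fitting controls.
#' @param step_ratio Geometric-scale step ratio (default 2).
#' @return List keyed by scale; each entry holds `powerlaw` and
#'   `exponential` (params + chisq) and `ratio` = chisq(exp)/chisq(power).
#' @export
compare_models <- function(cohort, t0 = 1, floor = 0.1, step_ratio = 2) {
  out <- lapply(c(nrs = "nrs", geometric = "geometric"), function(sc) {
    traj <- mean_trajectory(cohort, scale = sc, step_ratio = step_ratio)
    pl <- fit_powerlaw_mean(traj, t0 = t0, floor = floor)
    ex <- fit_exponential(traj, floor = floor)
    c_pl <- chi_square(traj, pl_evaluate(pl, traj$time_grid))
    c_ex <- chi_square(traj, pl_evaluate(ex, traj$time_grid))
    list(powerlaw = list(params = pl, chisq = c_pl),
         exponential = list(params = ex, chisq = c_ex),
         ratio = if (c_pl == 0) Inf else c_ex / c_pl)
  })
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  for (sc in names(x)) {
    cat(sprintf("%-9s chisq: power law %.3g, exponential %.3g (ratio %.3g)\n",
                sc, x[[sc]]$powerlaw$chisq, x[[sc]]$exponential$chisq, x[[sc]]$ratio))
  }
  invisible(x)
}
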