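#' Power-law decay parameters
#'
#' The decay model used throughout is the shifted power law
#' \deqn{F(t) = F_0 (1 + t/t_0)^{-P}}
#' with prefactor \eqn{F_0 > 0} (the value at t = 0), dimensionless exponent
#' P (positive for recovery, negative for worsening pain), and time offset
#' \eqn{t_0 > 0} months. The offset regularizes t = 0, where a bare
#' \eqn{t^{-P}} diverges, while the curve is asymptotically log-log linear
#' with slope -P for \eqn{t \gg t_0}.
#'
#' @param prefactor Value at t = 0, pain units, > 0.
#' @param exponent Decay exponent P (any sign).
#' @param offset Time offset t0 in months, > 0 (default 1).
#' @return Object of class `powerlaw_params`.
#' @export
powerlaw_params <- function(prefactor, exponent, offset = 1) {
  if (!is.finite(prefactor) || prefactor <= 0) stop("prefactor must be > 0")
  if (!is.finite(exponent)) stop("exponent must be finite")
  if (!is.finite(offset) || offset <= 0) stop("offset must be > 0")
  structure(list(prefactor = prefactor, exponent = exponent, offset = offset),
            class = "powerlaw_params")
}

#' @export
print.powerlaw_params <- function(x, ...) {
  cat(sprintf("<powerlaw> F(t) = %.4g * (1 + t/%.3g)^(-%.4g)\n",
              x$prefactor, x$offset, x$exponent))
  invisible(x)
}

#' Exponential decay parameters
#'
#' The alternative model \eqn{F(t) = A e^{-t/\tau}} used for goodness-of-fit
#' comparison. `tau = Inf` encodes a flat (non-decaying) fit.
#'
#' @param amplitude Value at t = 0, > 0.
#' @param tau Time constant in months, > 0 (may be `Inf`).
#' @return Object of class `expdecay_params`.
#' @export
expdecay_params <- function(amplitude, tau) {
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  if (is.na(tau) || tau <= 0) stop("tau must be > 0")
  structure(list(amplitude = amplitude, tau = tau), class = "expdecay_params")
}

#' Evaluate a decay model at times t
#'
#' @param params [powerlaw_params()] or [expdecay_params()].
#' @param t Times in months, >= 0 (vectorized).
#' @return Model values at `t`.
#' @examples
#' pl_evaluate(powerlaw_params(6, 0.3, 1), 0)   # 6
#' pl_evaluate(powerlaw_params(1, 1, 1), 1)     # 0.5
#' @export
pl_evaluate <- function(params, t) {
  if (anyNA(t) || any(t < 0)) stop("t must be non-negative")
  if (inherits(params, "expdecay_params"))
    return(params$amplitude * exp(-t / params$tau))
  stopifnot(inherits(params, "powerlaw_params"))
  params$prefactor * (1 + t / params$offset)^(-params$exponent)
}

# Floor values before a log transform: zeros are legal on the 0-10 rating
# scale but have no logarithm.
floor_values <- function(values, floor = 0.1) pmax(values, floor)

#' Fit a two-parameter power law to one record
#'
#' Ordinary least squares of log(value) on log(1 + t/t0) over the chosen
#' marks, with the offset t0 held fixed: the slope estimates -P and the
#' intercept log(prefactor). Recovery is exact (to rounding) when the data
#' lie on a shifted power law with the same t0.
#'
#' @param record A [ts_record()].
#' @param marks Time marks to fit (default: all marks of the record). Must
#'   be a subset of `record$times` with observed values.
#' @param t0 Fixed time offset in months (default 1).
#' @param floor Value floor applied before the log transform (default 0.1).
#' @return [powerlaw_params()] with attribute `marks_used`.
#' @export
fit_two_param <- function(record, marks = record$times, t0 = 1, floor = 0.1) {
  stopifnot(inherits(record, "ts_record"))
  y <- record_values_at(record, marks)
  if (length(marks) < 2L) stop("need >= 2 marks to fit two parameters")
  ly <- log(floor_values(y, floor))
  lx <- log(1 + marks / t0)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  p <- powerlaw_params(exp(fit$coefficients[[1L]]), -fit$coefficients[[2L]], t0)
  attr(p, "marks_used") <- marks
  p
}

record_values_at <- function(record, marks) {
  idx <- match(marks, record$times)
  if (anyNA(idx))
    stop("record ", record$subject_id, " lacks mark(s): ",
         paste(marks[is.na(idx)], collapse = ", "))
  y <- record$values[idx]
  if (anyNA(y))
    stop("record ", record$subject_id, " missing value at mark(s): ",
         paste(marks[is.na(y)], collapse = ", "))
  y
}

#' Fit the prefactor with the exponent held fixed
#'
#' For each mark k the implied prefactor is
#' \eqn{A_k = Y_k (1 + t_k/t_0)^{P}}; the estimate is the arithmetic mean of
#' the \eqn{A_k} over the chosen marks. On an exact power law with exponent
#' P every \eqn{A_k} is identical.
#'
#' @inheritParams fit_two_param
#' @param exponent The fixed exponent P.
#' @return [powerlaw_params()] with the given exponent and fitted prefactor.
#' @export
fit_prefactor_fixed_exponent <- function(record, exponent, marks = record$times,
                                         t0 = 1, floor = 0.1) {
  stopifnot(inherits(record, "ts_record"))
  if (length(marks) < 1L) stop("need >= 1 mark")
  y <- floor_values(record_values_at(record, marks), floor)
  a <- y * (1 + marks / t0)^exponent
  p <- powerlaw_params(mean(a), exponent, t0)
  attr(p, "marks_used") <- marks
  p
}

#' Half-reduction time ratio M
#'
#' Under a pure power law \eqn{u^{-P}} in shifted time \eqn{u = t_0 + t},
#' pain halves when elapsed time grows by the factor
#' \deqn{M = 2^{1/P}.}
#' Small exponents give large M: slow, chronic-looking recovery.
#'
#' @param exponent P > 0.
#' @return M = 2^(1/P).
#' @examples
#' halving_ratio(1)    # 2
#' signif(halving_ratio(1.7), 2)  # 1.5
#' @export
halving_ratio <- function(exponent) {
  if (!is.finite(exponent) || exponent <= 0)
    stop("halving requires exponent > 0 (non-decreasing trajectories never halve)")
  2^(1 / exponent)
}

#' Projected time at which pain is half its current level
#'
#' Pure power-law convention: the half-reduction time is `t_now * M` in the
#' same unit as `t_now`. For the shifted model this is exact in shifted time
#' u = t0 + t and a close approximation in t once t >> t0.
#'
#' @param t_now Current time (> 0), any single time unit.
#' @param exponent P > 0.
#' @return Projected half-reduction time, full precision (rounding is left
#'   to presentation).
#' @examples
#' half_reduction_time(30, 1.7)  # ~45 (days)
#' half_reduction_time(24, 1.7)  # ~36 (months)
#' @export
half_reduction_time <- function(t_now, exponent) {
  if (any(!is.finite(t_now)) || any(t_now <= 0)) stop("t_now must be > 0")
  t_now * halving_ratio(exponent)
}

#' Map an NRS level to the geometric pain scale
#'
#' Treats equal rating steps as equal pain ratios: level N maps to
#' `step_ratio^N` (default ratio 2, so NRS 8 maps to 256).
#'
#' @param nrs NRS level(s).
#' @param step_ratio Ratio per rating step, > 0 (default 2).
#' @return Geometric pain value(s).
#' @export
geometric_from_nrs <- function(nrs, step_ratio = 2) {
  if (!is.finite(step_ratio) || step_ratio <= 0) stop("step_ratio must be > 0")
  step_ratio^nrs
}

#' Inverse of [geometric_from_nrs()]
#' @param value Geometric pain value(s), > 0.
#' @param step_ratio Ratio per rating step, > 0 (default 2).
#' @return NRS level(s).
#' @export
nrs_from_geometric <- function(value, step_ratio = 2) {
  if (!is.finite(step_ratio) || step_ratio <= 0 || step_ratio == 1)
    stop("step_ratio must be > 0 and != 1")
  if (any(value <= 0)) stop("geometric pain values must be > 0")
  log(value) / log(step_ratio)
}

#' Estimate the per-step ratio of the geometric scale from two endpoints
#'
#' Given the ratio of pain magnitudes at two widely separated points and the
#' number of rating steps between them, the per-step ratio is the n-th root
#' of the magnitude ratio (e.g. a 64-fold pain ratio across 6 steps gives a
#' step ratio of 2).
#'
#' @param pain_ratio Ratio of the two pain magnitudes, > 0.
#' @param n_steps Number of rating steps between the endpoints, >= 1.
#' @return Estimated step ratio.
#' @export
step_ratio_from_endpoints <- function(pain_ratio, n_steps) {
  if (!is.finite(pain_ratio) || pain_ratio <= 0) stop("pain_ratio must be > 0")
  if (!is.finite(n_steps) || n_steps < 1 || n_steps != round(n_steps))
    stop("n_steps must be a positive integer")
  pain_ratio^(1 / n_steps)
}
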