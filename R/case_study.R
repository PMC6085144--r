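#' Dose-history table for a single-subject case study
#'
#' @param time_months Months since injury (non-negative, strictly increasing).
#' @param medication Character vector: `"oxycodone"`, `"gabapentin"` or
#'   `"none"` (any medication named in the equivalence map is accepted).
#' @param daily_dose_mg Daily dose in mg/day; must be 0 where medication is
#'   `"none"`.
#' @param residual_nrs Optional NRS pain under (or after) medication; `NA`
#'   where not recorded. Required at no-medication marks.
#' @return data.frame of class `dose_history`.
#' @export
dose_history <- function(time_months, medication, daily_dose_mg,
                         residual_nrs = NA_real_) {
  df <- data.frame(time_months = as.numeric(time_months),
                   medication = as.character(medication),
                   daily_dose_mg = as.numeric(daily_dose_mg),
                   residual_nrs = as.numeric(residual_nrs),
                   stringsAsFactors = FALSE)
  if (any(df$daily_dose_mg < 0)) stop("daily_dose_mg must be >= 0")
  if (any(df$medication == "none" & df$daily_dose_mg != 0))
    stop("medication 'none' implies daily_dose_mg 0")
  if (any(diff(df$time_months) <= 0)) stop("time_months must be strictly increasing")
  class(df) <- c("dose_history", "data.frame")
  df
}

#' Convert a medication-dose history to a no-medication-pain proxy series
#'
#' Under dose titration, the dose needed to keep residual pain tolerable is
#' approximately proportional to the underlying no-medication pain, so the
#' dose itself serves as a pain proxy. Doses are expressed in
#' oxycodone-mg-equivalents through the equivalence map (default: 1 mg
#' oxycodone is equivalent to 300 mg gabapentin). After medication stops,
#' the residual NRS rating is mapped onto the same proxy axis through the
#' geometric pain scale `kappa * step_ratio^N`, with the calibration
#' constant `kappa` chosen for continuity at the medication-stop boundary:
#' if the last medicated record carries a `residual_nrs`, kappa equates its
#' dose-derived proxy with `step_ratio^N` at that same time; otherwise the
#' first no-medication record's rating is used (documented approximation).
#'
#' @param doses A [dose_history()].
#' @param equivalence Named vector, mg of each medication per
#'   oxycodone-mg-equivalent; must contain every medication present and map
#'   oxycodone to 1. Default `c(oxycodone = 1, gabapentin = 300)`.
#' @param step_ratio Geometric-scale step ratio (default 2).
#' @return A [ts_record()] on scale `"dose_proxy"` (attribute `kappa` holds
#'   the calibration constant, `NA` if no no-medication marks).
#' @export
dose_to_pain_proxy <- function(doses,
                               equivalence = c(oxycodone = 1, gabapentin = 300),
                               step_ratio = 2) {
  stopifnot(inherits(doses, "dose_history"))
  if (!"oxycodone" %in% names(equivalence) || equivalence[["oxycodone"]] != 1)
    stop("equivalence must map oxycodone to 1")
  meds <- setdiff(unique(doses$medication), "none")
  unknown <- setdiff(meds, names(equivalence))
  if (length(unknown))
    stop("unknown medication(s): ", paste(unknown, collapse = ", "))
  medicated <- doses$medication != "none"
  proxy <- rep(NA_real_, nrow(doses))
  proxy[medicated] <- doses$daily_dose_mg[medicated] /
    unlist(equivalence[doses$medication[medicated]])
  kappa <- NA_real_
  if (any(!medicated)) {
    if (!any(medicated))
      stop("dose history has no medicated records to calibrate against")
    i_last <- max(which(medicated))
    anchor <- if (!is.na(doses$residual_nrs[i_last])) i_last else {
      i_first_none <- min(which(!medicated))
      if (is.na(doses$residual_nrs[i_first_none]))
        stop("no residual_nrs available to calibrate the no-medication period")
      i_first_none
    }
    kappa <- proxy[i_last] / step_ratio^doses$residual_nrs[anchor]
    idx <- which(!medicated)
    if (anyNA(doses$residual_nrs[idx]))
      stop("residual_nrs required at every no-medication mark")
    proxy[idx] <- kappa * step_ratio^doses$residual_nrs[idx]
  }
  rec <- ts_record("case", doses$time_months, proxy, scale = "dose_proxy")
  attr(rec, "kappa") <- kappa
  rec
}

#' Strength-gap series from limb strength ratios
#'
#' The strength gap is Q(t) = 1 - S(t), where S(t) is the affected/unaffected
#' limb strength ratio (mean over the strength tests performed). A fully
#' recovered limb has Q = 0; the gap itself decays over recovery and is
#' fit-ready for [fit_two_param()].
#'
#' @param time_months Months since injury, strictly increasing.
#' @param strength_ratio S(t) values (typically in \[0, 1\], slight
#'   overshoot above 1 tolerated and clamped to gap 0).
#' @param subject_id Identifier (default "case").
#' @return A [ts_record()] on scale `"strength_gap"`.
#' @export
strength_gap_series <- function(time_months, strength_ratio, subject_id = "case") {
  if (any(!is.finite(strength_ratio))) stop("strength_ratio must be finite")
  gap <- pmax(1 - strength_ratio, 0)
  ts_record(subject_id, time_months, gap, scale = "strength_gap")
}

#' Single-subject case report: fits and half-reduction forecasts
#'
#' Fits the shifted power law to the pain-proxy and strength-gap series,
#' computes the half-reduction ratio M = 2^(1/P) for each, and projects the
#' half-reduction time from each requested "now" time.
#'
#' @param pain_proxy A [ts_record()] (scale `dose_proxy`), e.g. from
#'   [dose_to_pain_proxy()].
#' @param strength Optional [ts_record()] on scale `strength_gap`.
#' @param now Times (months) from which to project half reduction.
#' @param t0,floor Fitting controls for the pain-proxy series.
#' @param strength_floor Value floor for the strength-gap series (default
#'   0.01, i.e. a 1% gap: the gap lives on a 0-1 ratio scale, so the NRS
#'   floor of 0.1 units would be far too coarse).
#' @return List of class `case_report`: per-series fit, M, and a table of
#'   half-reduction times.
#' @export
case_report <- function(pain_proxy, strength = NULL, now = c(24),
                        t0 = 1, floor = 0.1, strength_floor = 0.01) {
  series <- list(pain = pain_proxy)
  if (!is.null(strength)) series$strength <- strength
  out <- lapply(series, function(rec) {
    fl <- if (rec$scale == "strength_gap") strength_floor else floor
    fit <- fit_two_param(rec, t0 = t0, floor = fl)
    P <- fit$exponent
    M <- if (P > 0) halving_ratio(P) else NA_real_
    data_half <- if (P > 0) half_reduction_time(now, P) else rep(NA_real_, length(now))
    list(fit = fit, M = M,
         forecast = data.frame(now = now, half_reduction_at = data_half))
  })
  structure(out, class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  for (nm in names(x)) {
    f <- x[[nm]]
    cat(sprintf("%s: P = %.3g, prefactor = %.3g, M = %.3g\n",
                nm, f$fit$exponent, f$fit$prefactor, f$M))
    for (i in seq_len(nrow(f$forecast)))
      cat(sprintf("  half reduction from t = %g: %.1f months\n",
                  f$forecast$now[i], f$forecast$half_reduction_at[i]))
  }
  invisible(x)
}
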