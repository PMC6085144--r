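#' Projection schemes I-IV
#'
#' A projection scheme names which early time marks feed the fit and whether
#' the exponent is fixed or fitted per record:
#' \describe{
#'   \item{I}{marks 0 and 6 months, fixed exponent}
#'   \item{II}{marks 0, 1 and 6 months, fixed exponent}
#'   \item{III}{marks 0 and 1 month, fixed exponent}
#'   \item{IV}{marks 0, 1 and 6 months, exponent fitted per record}
#' }
#' The fixed exponent defaults to P = 0.3, the cohort-typical value obtained
#' by per-record fitting (scheme IV).
#'
#' @param label One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param fixed_P Exponent used when the mode is fixed (default 0.3).
#' @return Object of class `projection_scheme` with fields `label`,
#'   `fit_marks`, `exponent_mode` and `fixed_P`.
#' @export
projection_scheme <- function(label = c("I", "II", "III", "IV"), fixed_P = 0.3) {
  label <- match.arg(label)
  spec <- switch(label,
    I   = list(fit_marks = c(0, 6),    exponent_mode = "fixed"),
    II  = list(fit_marks = c(0, 1, 6), exponent_mode = "fixed"),
    III = list(fit_marks = c(0, 1),    exponent_mode = "fixed"),
    IV  = list(fit_marks = c(0, 1, 6), exponent_mode = "fitted")
  )
  structure(c(list(label = label), spec, list(fixed_P = fixed_P)),
            class = "projection_scheme")
}

#' Custom projection scheme
#'
#' Build a non-standard scheme, e.g. a fixed-exponent fit on marks {1, 6}
#' to probe the effect of excluding the t = 0 mark.
#'
#' @param fit_marks Time marks feeding the fit.
#' @param exponent_mode `"fixed"` or `"fitted"`.
#' @param fixed_P Exponent when fixed.
#' @param label Free-text label.
#' @return A `projection_scheme`.
#' @export
custom_scheme <- function(fit_marks, exponent_mode = c("fixed", "fitted"),
                          fixed_P = 0.3, label = "custom") {
  exponent_mode <- match.arg(exponent_mode)
  if (length(fit_marks) < 1L || (exponent_mode == "fitted" && length(fit_marks) < 2L))
    stop("not enough fit marks for the requested mode")
  structure(list(label = label, fit_marks = sort(fit_marks),
                 exponent_mode = exponent_mode, fixed_P = fixed_P),
            class = "projection_scheme")
}

#' @export
print.projection_scheme <- function(x, ...) {
  cat(sprintf("<scheme %s> marks {%s}, exponent %s%s\n", x$label,
              paste(x$fit_marks, collapse = ","), x$exponent_mode,
              if (x$exponent_mode == "fixed") sprintf(" (P = %g)", x$fixed_P) else ""))
  invisible(x)
}

#' Project a record's pain at a future time
#'
#' Fixed-exponent schemes estimate the prefactor by per-mark averaging
#' ([fit_prefactor_fixed_exponent()]); scheme IV fits both parameters by
#' log-log regression ([fit_two_param()]). The fitted curve is then
#' evaluated at the target time `T`.
#'
#' @param record A [ts_record()] containing all of the scheme's fit marks.
#' @param scheme A [projection_scheme()].
#' @param T Target time in months, >= max(fit marks).
#' @param t0 Time offset (default 1 month).
#' @param floor Value floor before log transforms (default 0.1).
#' @return Predicted pain at `T` (attribute `params` holds the fit).
#' @export
project_record <- function(record, scheme, T = 12, t0 = 1, floor = 0.1) {
  stopifnot(inherits(scheme, "projection_scheme"))
  if (T < max(scheme$fit_marks)) stop("target time precedes the fitted marks")
  params <- if (scheme$exponent_mode == "fixed") {
    fit_prefactor_fixed_exponent(record, scheme$fixed_P,
                                 marks = scheme$fit_marks, t0 = t0, floor = floor)
  } else {
    fit_two_param(record, marks = scheme$fit_marks, t0 = t0, floor = floor)
  }
  pred <- pl_evaluate(params, T)
  attr(pred, "params") <- params
  pred
}

#' Deviation summary of cohort projections
#'
#' Projects every complete record to time `T` under a scheme and summarizes
#' observed - predicted deviations: per-subject deviations, mean bias,
#' spread (SD) and tolerance-band accuracies (percent of subjects whose
#' absolute deviation is <= each band, inclusive).
#'
#' @param cohort A [pain_cohort()]; incomplete records are dropped with a
#'   count kept in the result.
#' @param scheme A [projection_scheme()].
#' @param T Target time in months (default 12).
#' @param bands Tolerance bands in pain units (default 1, 1.5, 2).
#' @inheritParams project_record
#' @return Object of class `deviation_summary` with fields `deviations`
#'   (named by subject), `mean_bias`, `spread`, `accuracies` (percent, named
#'   by band), `n`, `n_excluded`, `scheme_label`, `T`.
#' @export
cohort_deviations <- function(cohort, scheme, T = 12, bands = c(1, 1.5, 2),
                              t0 = 1, floor = 0.1) {
  stopifnot(inherits(cohort, "pain_cohort"))
  if (!T %in% cohort$time_grid) stop("target time ", T, " is not on the cohort grid")
  n_all <- length(cohort$records)
  cohort <- complete_records(cohort)
  dev <- vapply(cohort$records, function(r) {
    obs <- r$values[match(T, r$times)]
    obs - as.numeric(project_record(r, scheme, T = T, t0 = t0, floor = floor))
  }, numeric(1))
  names(dev) <- vapply(cohort$records, `[[`, character(1), "subject_id")
  deviation_summary(dev, bands, scheme_label = scheme$label, T = T,
                    n_excluded = n_all - length(dev))
}

deviation_summary <- function(deviations, bands = c(1, 1.5, 2),
                              scheme_label = NA_character_, T = NA_real_,
                              n_excluded = 0L) {
  acc <- vapply(bands, function(b) 100 * mean(abs(deviations) <= b), numeric(1))
  structure(list(
    deviations = deviations,
    mean_bias = mean(deviations),
    spread = stats::sd(deviations),
    accuracies = stats::setNames(acc, format(bands)),
    n = length(deviations), n_excluded = n_excluded,
    scheme_label = scheme_label, T = T
  ), class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("<deviations> scheme %s at T = %g months, n = %d\n",
              x$scheme_label, x$T, x$n))
  cat(sprintf("  mean bias %.3f, spread (SD) %.3f\n", x$mean_bias, x$spread))
  cat("  accuracy within +/-", paste(sprintf("%s: %.1f%%", names(x$accuracies),
                                             x$accuracies), collapse = ", "), "\n")
  invisible(x)
}

#' Distribution of per-record fitted exponents
#'
#' Fits a two-parameter power law to every complete record over the given
#' marks and summarizes the exponents. Records whose fit fails are excluded
#' from the summary and counted.
#'
#' @param cohort A [pain_cohort()].
#' @param fit_marks Marks used for the per-record fit (default the full grid).
#' @inheritParams project_record
#' @return List with `exponents` (named), `mean`, `sd`, `n`, `n_failed`.
#' @export
exponent_distribution <- function(cohort, fit_marks = cohort$time_grid,
                                  t0 = 1, floor = 0.1) {
  stopifnot(inherits(cohort, "pain_cohort"))
  cohort <- complete_records(cohort)
  fits <- lapply(cohort$records, function(r) {
    tryCatch(fit_two_param(r, marks = fit_marks, t0 = t0, floor = floor)$exponent,
             error = function(e) NA_real_)
  })
  p <- stats::setNames(unlist(fits),
                       vapply(cohort$records, `[[`, character(1), "subject_id"))
  ok <- !is.na(p)
  list(exponents = p[ok], mean = mean(p[ok]), sd = stats::sd(p[ok]),
       n = sum(ok), n_failed = sum(!ok))
}

#' Scatter of log-log slopes per time transition
#'
#' For each consecutive pair of grid marks, the per-subject slope is
#' \eqn{\Delta \log(value) / \Delta \log(1 + t/t_0)} (so a pure power law
#' yields -P at every transition). The spread per transition is the
#' interquartile range by default (SD optional), and each transition's
#' spread is reported as a ratio to the median spread of the others --
#' a diagnostic for disproportionate scatter in the earliest transition.
#'
#' @param cohort A [pain_cohort()].
#' @param t0 Time offset (default 1).
#' @param floor Value floor (default 0.1).
#' @param spread `"iqr"` (default) or `"sd"`.
#' @return List with `transitions` (labels), `slopes` (list of per-subject
#'   slope vectors), `spreads`, `spread_ratios`, `n_floored` per transition.
#' @export
transition_slope_scatter <- function(cohort, t0 = 1, floor = 0.1,
                                     spread = c("iqr", "sd")) {
  spread <- match.arg(spread)
  stopifnot(inherits(cohort, "pain_cohort"))
  cohort <- complete_records(cohort)
  grid <- cohort$time_grid
  if (length(grid) < 2L) stop("need >= 2 grid marks")
  m <- cohort_matrix(cohort)
  n_floored <- integer(length(grid) - 1L)
  slopes <- vector("list", length(grid) - 1L)
  labels <- character(length(grid) - 1L)
  for (k in seq_len(length(grid) - 1L)) {
    y1 <- m[, k]; y2 <- m[, k + 1L]
    n_floored[k] <- sum(y1 < floor | y2 < floor)
    dly <- log(floor_values(y2, floor)) - log(floor_values(y1, floor))
    dlx <- log(1 + grid[k + 1L] / t0) - log(1 + grid[k] / t0)
    slopes[[k]] <- dly / dlx
    labels[k] <- sprintf("%g->%g", grid[k], grid[k + 1L])
  }
  sp <- vapply(slopes, function(s) {
    if (length(s) < 2L) return(0)
    if (spread == "iqr") stats::IQR(s) else stats::sd(s)
  }, numeric(1))
  ratios <- vapply(seq_along(sp), function(k) {
    others <- sp[-k]
    med <- stats::median(others)
    if (med == 0) if (sp[k] == 0) 1 else Inf else sp[k] / med
  }, numeric(1))
  list(transitions = labels,
       slopes = stats::setNames(slopes, labels),
       spreads = stats::setNames(sp, labels),
       spread_ratios = stats::setNames(ratios, labels),
       n_floored = stats::setNames(n_floored, labels),
       spread_measure = spread)
}
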