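#' Longitudinal pain time-series record
#'
#' A single subject's pain (or pain-proxy) values at an ordered set of time
#' marks. Values may contain `NA` for missing marks; such records are kept
#' but flagged incomplete, so that imputation workflows can use them.
#'
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param times Numeric vector of time marks in months, strictly increasing,
#'   non-negative, length >= 2.
#' @param values Numeric vector of pain intensities aligned with `times`.
#'   `NA` marks a missing observation; non-missing values must be finite.
#' @param scale One of `"nrs"`, `"geometric"`, `"dose_proxy"`,
#'   `"strength_gap"`. On the `"nrs"` scale every non-missing value must lie
#'   in \[0, 10\].
#' @return An object of class `ts_record`.
#' @examples
#' ts_record("s1", c(0, 1, 6, 12), c(6, 5, 3.5, 3))
#' @export
ts_record <- function(subject_id, times, values, scale = "nrs") {
  scale <- match.arg(scale, c("nrs", "geometric", "dose_proxy", "strength_gap"))
  subject_id <- as.character(subject_id)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(subject_id) != 1L || is.na(subject_id))
    stop("subject_id must be a single non-missing string")
  if (length(times) < 2L || length(times) != length(values))
    stop("times and values must be aligned vectors of length >= 2")
  if (anyNA(times) || any(times < 0))
    stop("times must be non-negative and non-missing")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs)))
    stop("non-missing values must be finite")
  if (scale == "nrs" && any(obs < 0 | obs > 10))
    stop("nrs values must lie in [0, 10]")
  structure(
    list(subject_id = subject_id, times = times, values = values, scale = scale),
    class = "ts_record"
  )
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("<ts_record> subject %s, scale %s%s\n", x$subject_id, x$scale,
              if (is_complete(x)) "" else " (incomplete)"))
  print(stats::setNames(x$values, paste0("t", x$times)))
  invisible(x)
}

#' Is a record complete (no missing marks)?
#' @param record A [ts_record()].
#' @return Logical scalar.
#' @export
is_complete <- function(record) {
  stopifnot(inherits(record, "ts_record"))
  !anyNA(record$values)
}

#' Cohort of records on a shared time grid
#'
#' @param records List of [ts_record()] objects whose `times` all equal
#'   `time_grid`.
#' @param time_grid Numeric vector of shared time marks (months); defaults to
#'   the first record's times.
#' @return An object of class `pain_cohort`.
#' @export
pain_cohort <- function(records, time_grid = NULL) {
  if (length(records) == 0L) stop("cohort must contain at least one record")
  if (!all(vapply(records, inherits, logical(1), "ts_record")))
    stop("records must all be ts_record objects")
  if (is.null(time_grid)) time_grid <- records[[1L]]$times
  ok <- vapply(records, function(r) {
    length(r$times) == length(time_grid) && all(r$times == time_grid)
  }, logical(1))
  if (!all(ok)) {
    bad <- vapply(records[!ok], `[[`, character(1), "subject_id")
    stop("records not on the shared time grid: ", paste(bad, collapse = ", "))
  }
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records, time_grid = time_grid), class = "pain_cohort")
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat(sprintf("<pain_cohort> %d records on grid {%s} months; %d complete\n",
              length(x$records), paste(x$time_grid, collapse = ", "),
              sum(vapply(x$records, is_complete, logical(1)))))
  invisible(x)
}

#' @export
length.pain_cohort <- function(x) length(x$records)

#' Keep only complete records
#' @param cohort A [pain_cohort()].
#' @return A `pain_cohort` of the complete records (error if none remain).
#' @export
complete_records <- function(cohort) {
  stopifnot(inherits(cohort, "pain_cohort"))
  keep <- vapply(cohort$records, is_complete, logical(1))
  if (!any(keep)) stop("no complete records in cohort")
  pain_cohort(cohort$records[keep], cohort$time_grid)
}

#' Matrix of cohort values (subjects x time marks)
#' @param cohort A [pain_cohort()].
#' @return Numeric matrix, rownames = subject ids, colnames = `t<mark>`.
#' @export
cohort_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "pain_cohort"))
  m <- t(vapply(cohort$records, `[[`, numeric(length(cohort$time_grid)), "values"))
  rownames(m) <- vapply(cohort$records, `[[`, character(1), "subject_id")
  colnames(m) <- paste0("t", cohort$time_grid)
  m
}

#' Read a cohort from CSV
#'
#' Two layouts are supported. `wide`: one row per subject, columns
#' `subject_id, t0, t1, t6, t12, ...` (one `t<mark>` column per time mark).
#' `long`: columns `subject_id, time_months, value` and optionally `scale`.
#' Empty cells become `NA` (missing mark); rows that cannot be parsed raise
#' an error naming the offending row.
#'
#' @param path Path to a comma-delimited UTF-8 CSV file with a header.
#' @param format `"wide"` or `"long"`.
#' @param scale Scale tag applied to records lacking one (default `"nrs"`).
#' @return A [pain_cohort()].
#' @export
read_cohort <- function(path, format = c("wide", "long"), scale = "nrs") {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (format == "wide") {
    if (!"subject_id" %in% names(df))
      stop("wide cohort CSV must have a 'subject_id' column")
    tcols <- grep("^t[0-9.]+$", names(df), value = TRUE)
    if (length(tcols) < 2L)
      stop("wide cohort CSV needs >= 2 time-mark columns named 't<mark>'")
    marks <- as.numeric(sub("^t", "", tcols))
    tcols <- tcols[order(marks)]
    marks <- sort(marks)
    records <- lapply(seq_len(nrow(df)), function(i) {
      vals <- vapply(tcols, function(cn) parse_value(df[[cn]][i], i, cn), numeric(1))
      ts_record(df$subject_id[i], marks, vals, scale)
    })
    return(pain_cohort(records, marks))
  }
  need <- c("subject_id", "time_months", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  df$time_months <- vapply(seq_len(nrow(df)),
                           function(i) parse_value(df$time_months[i], i, "time_months"),
                           numeric(1))
  df$.value <- vapply(seq_len(nrow(df)),
                      function(i) parse_value(df$value[i], i, "value"),
                      numeric(1))
  grid <- sort(unique(df$time_months))
  by_subj <- split(df, factor(df$subject_id, levels = unique(df$subject_id)))
  records <- lapply(by_subj, function(d) {
    if (length(unique(d$time_months)) != nrow(d))
      stop("duplicate time marks for subject ", d$subject_id[1])
    vals <- d$.value[match(grid, d$time_months)]  # NA where the mark is absent
    sc <- if ("scale" %in% names(d) && nzchar(d$scale[1])) d$scale[1] else scale
    ts_record(d$subject_id[1], grid, vals, sc)
  })
  pain_cohort(unname(records), grid)
}

parse_value <- function(x, row, col) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop(sprintf("row %d, column '%s': cannot parse '%s' as a number", row, col, x))
  v
}

#' Write a cohort to CSV
#'
#' Values are serialized with 6 decimals so that write/read round trips are
#' stable at that precision. Missing marks are written as empty cells.
#'
#' @param cohort A [pain_cohort()].
#' @param path Output file path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "pain_cohort"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  if (format == "wide") {
    m <- cohort_matrix(cohort)
    df <- data.frame(subject_id = rownames(m), apply(m, 2, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(cohort$records, function(r) {
      data.frame(subject_id = r$subject_id, time_months = r$times,
                 value = fmt(r$values), scale = r$scale,
                 stringsAsFactors = FALSE)
    }))
    df <- df[!(df$value == ""), , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Average the current/best/worst NRS ratings
#'
#' The composite pain score is the equal-weight arithmetic mean of the three
#' ratings taken at one session.
#'
#' @param current,best,worst NRS values in \[0, 10\] (vectorized).
#' @return Mean rating, same length as the inputs.
#' @examples
#' average_nrs(4, 2, 6)  # 4
#' @export
average_nrs <- function(current, best, worst) {
  vals <- cbind(current, best, worst)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 10))
    stop("all ratings must be finite NRS values in [0, 10]")
  rowMeans(vals)
}

#' Empirical cumulative frequency distribution
#'
#' Returns the step function of cumulative fractions at the sorted unique
#' sample values; ties collapse onto one step and the final fraction is
#' exactly 1.
#'
#' @param samples Non-empty numeric vector, no `NA`.
#' @return List with components `values` (sorted unique) and `fractions`
#'   (cumulative, in (0, 1\]), class `cumdist`.
#' @export
cumulative_distribution <- function(samples) {
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (anyNA(samples) || any(!is.finite(samples))) stop("samples must be finite")
  v <- sort(unique(samples))
  counts <- vapply(v, function(x) sum(samples == x), numeric(1))
  f <- cumsum(counts) / length(samples)
  f[length(f)] <- 1  # guard against rounding drift
  structure(list(values = v, fractions = f), class = "cumdist")
}

#' @export
print.cumdist <- function(x, ...) {
  cat(sprintf("<cumdist> %d steps on [%g, %g]\n", length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
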