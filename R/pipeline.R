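#' Pipeline run configuration
#'
#' @param input Path to a cohort CSV (wide or long; auto-detected by
#'   header), or `NULL` to simulate a cohort from `sim`.
#' @param sim A [cohort_sim_config()] used when `input` is `NULL`.
#' @param analyses Subset of `"projections"`, `"imputation"`,
#'   `"model_comparison"`, `"exponents"`, `"slopes"`, `"case_study"`.
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed governing every stochastic stage.
#' @param scale `"nrs"` or `"geometric"` for scale-sensitive stages.
#' @param t0 Time offset in months (default 1).
#' @param fixed_exponent Fixed P for schemes I-III (default 0.3).
#' @param bands Tolerance bands (default 1, 1.5, 2).
#' @param target_time Projection target in months (default 12).
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL,
                       analyses = c("projections", "imputation",
                                    "model_comparison", "exponents", "slopes"),
                       outdir = tempfile("painlaw_run_"), seed = 1L,
                       scale = c("nrs", "geometric"), t0 = 1,
                       fixed_exponent = 0.3, bands = c(1, 1.5, 2),
                       target_time = 12) {
  scale <- match.arg(scale)
  known <- c("projections", "imputation", "model_comparison", "exponents",
             "slopes", "case_study")
  analyses <- unique(analyses)
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (length(analyses) == 0L) stop("at least one analysis must be selected")
  if (is.null(input) && is.null(sim)) sim <- cohort_sim_config(seed = seed)
  structure(list(input = input, sim = sim, analyses = analyses,
                 outdir = outdir, seed = as.integer(seed), scale = scale,
                 t0 = t0, fixed_exponent = fixed_exponent, bands = bands,
                 target_time = target_time),
            class = "run_config")
}

config_digest <- function(config) {
  list(input = if (is.null(config$input)) NA else config$input,
       simulated = is.null(config$input),
       analyses = config$analyses, seed = config$seed, scale = config$scale,
       t0 = config$t0, fixed_exponent = config$fixed_exponent,
       bands = config$bands, target_time = config$target_time,
       package_version = as.character(utils::packageVersion("painlaw")))
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Loads (or simulates) a cohort, runs the selected analyses, and writes one
#' JSON report per analysis plus a combined `summary.json` under the output
#' directory. Every report embeds the config and seed; a rerun with
#' identical inputs reproduces byte-identical files. A failing stage is
#' recorded with its error message and the remaining stages still run.
#'
#' @param config A [run_config()].
#' @return The report bundle (named list), invisibly; element `ok` is `TRUE`
#'   only if every requested stage succeeded.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- config_digest(config)
  if (is.null(config$input)) {
    sim <- config$sim
    gen <- generate_cohort(sim)
    cohort <- gen$cohort
  } else {
    hdr <- names(utils::read.csv(config$input, nrows = 1, check.names = FALSE))
    fmt <- if ("time_months" %in% hdr) "long" else "wide"
    cohort <- read_cohort(config$input, format = fmt)
  }
  n_all <- length(cohort$records)
  cohort_c <- complete_records(cohort)
  n_excluded <- n_all - length(cohort_c$records)
  if (n_excluded > 0)
    message(sprintf("[painlaw] %d incomplete record(s) excluded from ", n_excluded),
            "cohort-level analyses")

  reports <- list()
  ok <- TRUE
  for (an in config$analyses) {
    res <- tryCatch(
      run_stage(an, cohort_c, config, n_excluded),
      error = function(e) {
        ok <<- FALSE
        message(sprintf("[painlaw] stage '%s' failed: %s", an, conditionMessage(e)))
        list(error = conditionMessage(e))
      })
    report <- list(analysis = an, config = meta, result = res)
    write_report(report, file.path(config$outdir, paste0(an, ".json")))
    reports[[an]] <- report
  }
  summary <- list(config = meta, n_records = n_all, n_excluded = n_excluded,
                  stages = names(reports), ok = ok)
  write_report(summary, file.path(config$outdir, "summary.json"))
  invisible(c(reports, list(summary = summary, ok = ok)))
}

run_stage <- function(analysis, cohort, config, n_excluded) {
  t0 <- config$t0
  switch(analysis,
    projections = {
      lapply(stats::setNames(nm = c("I", "II", "III", "IV")), function(lb) {
        sc <- projection_scheme(lb, fixed_P = config$fixed_exponent)
        d <- cohort_deviations(cohort, sc, T = config$target_time,
                               bands = config$bands, t0 = t0)
        list(label = lb, fit_marks = sc$fit_marks,
             exponent_mode = sc$exponent_mode, fixed_P = sc$fixed_P,
             n = d$n, mean_bias = d$mean_bias, spread = d$spread,
             accuracies = as.list(d$accuracies))
      })
    },
    imputation = {
      st <- imputation_study(cohort, missing_mark = 6, flanking = c(1, 12), t0 = t0)
      lapply(st$summary, function(s)
        list(mean_bias = s$mean_bias, spread = s$spread,
             sign_test_p = s$sign_test_p))
    },
    model_comparison = {
      mc <- compare_models(cohort, t0 = t0)
      lapply(mc, function(m) list(
        powerlaw = list(prefactor = m$powerlaw$params$prefactor,
                        exponent = m$powerlaw$params$exponent,
                        chisq = m$powerlaw$chisq),
        exponential = list(amplitude = m$exponential$params$amplitude,
                           tau = m$exponential$params$tau,
                           chisq = m$exponential$chisq),
        ratio = m$ratio))
    },
    exponents = {
      ed <- exponent_distribution(cohort, t0 = t0)
      list(mean = ed$mean, sd = ed$sd, n = ed$n, n_failed = ed$n_failed)
    },
    slopes = {
      ts <- transition_slope_scatter(cohort, t0 = t0)
      list(transitions = ts$transitions, spreads = as.list(ts$spreads),
           spread_ratios = as.list(ts$spread_ratios),
           spread_measure = ts$spread_measure)
    },
    case_study = {
      cs <- generate_crps_case(seed = config$seed)
      proxy <- dose_to_pain_proxy(cs$doses)
      strength <- strength_gap_series(cs$strength_time, cs$strength_ratio)
      cr <- case_report(proxy, strength, now = c(24), t0 = t0)
      lapply(unclass(cr), function(f) list(
        exponent = f$fit$exponent, prefactor = f$fit$prefactor, M = f$M,
        forecast = f$forecast))
    },
    stop("unknown analysis: ", analysis)
  )
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a cohort CSV plus its truth table),
#' `project`, `impute`, `compare-models`, `exponents`, `slopes`, `case`, and
#' `report-all` (every analysis). Flags: `--input`, `--n`, `--seed`,
#' `--outdir`, `--scale`, `--t0`, `--fixed-exponent`, `--tolerance-bands`,
#' `--noise-sd`. Logging goes to stderr; machine output to files.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly (0 on success); the installed
#'   `cli/painlaw.R` script forwards it to `quit()`.
#' @export
painlaw_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: painlaw <simulate|project|impute|compare-models|",
            "exponents|slopes|case|report-all> [options]")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opts <- optparse::parse_args(cli_parser(), args = args[-1L])
  an <- switch(cmd,
    simulate = NULL,
    project = "projections", impute = "imputation",
    `compare-models` = "model_comparison", exponents = "exponents",
    slopes = "slopes", case = "case_study",
    `report-all` = c("projections", "imputation", "model_comparison",
                     "exponents", "slopes", "case_study"),
    { message("unknown subcommand: ", cmd); return(invisible(1L)) })
  sim <- cohort_sim_config(n_subjects = opts$n, seed = opts$seed,
                           noise_sd = opts$`noise-sd`, t0 = opts$t0)
  if (cmd == "simulate") {
    dir.create(opts$outdir, showWarnings = FALSE, recursive = TRUE)
    gen <- generate_cohort(sim)
    write_cohort(gen$cohort, file.path(opts$outdir, "cohort.csv"), "wide")
    utils::write.csv(gen$truth, file.path(opts$outdir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    message(sprintf("[painlaw] simulated %d subjects (seed %d) -> %s",
                    opts$n, opts$seed, opts$outdir))
    return(invisible(0L))
  }
  bands <- as.numeric(strsplit(opts$`tolerance-bands`, ",")[[1L]])
  cfg <- run_config(input = opts$input, sim = sim, analyses = an,
                    outdir = opts$outdir, seed = opts$seed,
                    scale = opts$scale, t0 = opts$t0,
                    fixed_exponent = opts$`fixed-exponent`, bands = bands)
  out <- run_pipeline(cfg)
  invisible(if (isTRUE(out$ok)) 0L else 1L)
}

cli_parser <- function() {
  optparse::OptionParser(option_list = list(
    optparse::make_option("--input", type = "character", default = NULL,
                          help = "cohort CSV (omit to simulate)"),
    optparse::make_option("--n", type = "integer", default = 243L,
                          help = "simulated cohort size [default %default]"),
    optparse::make_option("--seed", type = "integer", default = 1L,
                          help = "random seed [default %default]"),
    optparse::make_option("--outdir", type = "character", default = "painlaw_out",
                          help = "output directory [default %default]"),
    optparse::make_option("--scale", type = "character", default = "nrs",
                          help = "nrs or geometric [default %default]"),
    optparse::make_option("--t0", type = "double", default = 1,
                          help = "power-law time offset, months [default %default]"),
    optparse::make_option("--fixed-exponent", type = "double", default = 0.3,
                          help = "fixed P for schemes I-III [default %default]"),
    optparse::make_option("--tolerance-bands", type = "character",
                          default = "1,1.5,2",
                          help = "comma-separated bands [default %default]"),
    optparse::make_option("--noise-sd", type = "double", default = 1.9,
                          help = "simulated per-mark noise SD [default %default]")
  ))
}
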