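#' Configuration for the end-to-end threshold analysis
#'
#' Bundles every tunable of the pipeline: where the cohort comes from
#' (a data frame, a CSV path, or a [cohort_spec()] to simulate), which
#' biomarkers are analysed against year-1 25(OH)D, the MARS and
#' grid-search settings, and the survival horizon.
#'
#' @param cohort Optional cohort data frame (takes precedence).
#' @param input Optional cohort CSV path.
#' @param spec Optional [cohort_spec()] used when neither `cohort` nor
#'   `input` is given.
#' @param biomarkers Named character vector mapping display names to
#'   year-1 biomarker columns.
#' @param x25ohd Predictor column (year-1 25(OH)D).
#' @param baseline Baseline 25(OH)D column used for survival
#'   stratification.
#' @param k_folds,repetitions,max_terms,penalty_per_knot MARS settings
#'   (see [fit_mars()]).
#' @param lo,hi,step Grid-search window (see [grid_search_cut()]).
#' @param bootstrap_reps Intersection-ordinate bootstrap resamples.
#' @param horizon RFS horizon (years).
#' @param lowess_bandwidth LOWESS bandwidth.
#' @param seed Master seed.
#' @param output_dir Optional directory for CSV/text reports.
#' @param verbose Emit progress messages to standard error.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cohort = NULL, input = NULL, spec = NULL,
                            biomarkers = c(calcium = "calcium_y1",
                                           pth = "pth_y1"),
                            x25ohd = "x25ohd_y1",
                            baseline = "x25ohd_baseline",
                            k_folds = 10, repetitions = 100, max_terms = 6,
                            penalty_per_knot = 2,
                            lo = 15, hi = 40, step = 1,
                            bootstrap_reps = 1000,
                            horizon = 5, lowess_bandwidth = 0.8,
                            seed = 1, output_dir = NULL, verbose = TRUE) {
  if (is.null(cohort) && is.null(input) && is.null(spec)) {
    spec <- cohort_spec()
  }
  structure(as.list(environment()), class = "analysis_config")
}

log_stage <- function(config, ...) {
  if (isTRUE(config$verbose)) inform(paste0("[hingefit] ", sprintf(...)))
}

#' Run the full threshold-estimation pipeline
#'
#' Executes, in order: cohort load-or-simulate, LOWESS screening, MARS
#' threshold estimation, piecewise linear regression with intersection
#' points, threshold-stratified survival analysis (strata from the first
#' calcium hinge and the PTH hinge when both are available), and the
#' baseline comparison table.  Patients missing a stage's inputs are
#' excluded from that stage only, and exclusion counts are logged.
#'
#' @param config An [analysis_config()].
#' @return A `report_bundle`: `cohort`, per-biomarker `lowess`, `mars`,
#'   `piecewise` results, `thresholds`, `survival`, `baseline_table`, and
#'   a `provenance` block (seed, settings, package version).
#' @examples
#' cfg <- analysis_config(spec = cohort_spec(), repetitions = 3,
#'                        bootstrap_reps = 0, verbose = FALSE)
#' bundle <- run_full_analysis(cfg)
#' bundle$thresholds
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- if (!is.null(config$cohort)) {
    tibble::as_tibble(config$cohort)
  } else if (!is.null(config$input)) {
    log_stage(config, "reading cohort from %s", config$input)
    read_cohort(config$input)
  } else {
    log_stage(config, "simulating cohort (seed %d)", config$seed)
    simulate_cohort(config$spec, seed = config$seed)
  }

  results <- list()
  thresholds <- list()
  for (nm in names(config$biomarkers)) {
    ycol <- config$biomarkers[[nm]]
    usable <- sum(complete.cases(cohort[, c(config$x25ohd, ycol)]))
    excluded <- nrow(cohort) - usable
    log_stage(config, "%s: %d usable patients (%d excluded for missing values)",
              nm, usable, excluded)
    if (usable < max(10, 2 * config$k_folds)) {
      log_stage(config, "%s: threshold stages skipped (too few complete cases)", nm)
      results[[nm]] <- list(skipped = TRUE,
                            reason = "insufficient complete cases")
      next
    }
    sc <- lowess_fit(cohort, config$x25ohd, ycol,
                     bandwidth = config$lowess_bandwidth)
    mm <- fit_mars(cohort, config$x25ohd, ycol,
                   k_folds = config$k_folds,
                   repetitions = config$repetitions,
                   max_terms = config$max_terms,
                   penalty_per_knot = config$penalty_per_knot,
                   seed = config$seed)
    pw <- piecewise_analysis(cohort, config$x25ohd, ycol,
                             lo = config$lo, hi = config$hi,
                             step = config$step,
                             bootstrap_reps = config$bootstrap_reps,
                             seed = config$seed)
    results[[nm]] <- list(skipped = FALSE, lowess = sc, mars = mm,
                          piecewise = pw,
                          thresholds = extract_thresholds(mm))
    if (length(mm$hinges) > 0) thresholds[[nm]] <- mm$hinges
    log_stage(config, "%s: MARS hinges [%s], piecewise intersection %.3g",
              nm, paste(round(mm$hinges, 1), collapse = ", "),
              pw$intersection_x)
  }

  # survival stratification: first calcium hinge + PTH hinge, when present
  strat_thresholds <- numeric(0)
  if (!is.null(thresholds$calcium)) {
    strat_thresholds <- round(thresholds$calcium[1])
  }
  if (!is.null(thresholds$pth)) {
    strat_thresholds <- sort(unique(c(strat_thresholds,
                                      round(thresholds$pth[1]))))
  }
  log_stage(config, "survival stratification thresholds: %s",
            if (length(strat_thresholds)) paste(strat_thresholds, collapse = ", ")
            else "(none; unstratified)")
  surv <- stratified_comparison(cohort, strat_thresholds,
                                baseline = config$baseline,
                                horizon = config$horizon)

  baseline_table <- compare_baseline(
    cohort,
    paired_pairs = list(calcium_change = c("calcium_baseline", "calcium_y1"),
                        pth_change = c("pth_baseline", "pth_y1")))

  bundle <- structure(
    list(cohort = cohort, biomarkers = results,
         thresholds = strat_thresholds, survival = surv,
         baseline_table = baseline_table,
         provenance = list(
           seed = config$seed,
           settings = config[c("k_folds", "repetitions", "max_terms",
                               "penalty_per_knot", "lo", "hi", "step",
                               "bootstrap_reps", "horizon",
                               "lowess_bandwidth")],
           package_version = as.character(utils::packageVersion("hingefit")))),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", nrow(x$cohort), "patients\n")
  for (nm in names(x$biomarkers)) {
    b <- x$biomarkers[[nm]]
    if (isTRUE(b$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", nm, b$reason))
    } else {
      cat(sprintf("  %s: MARS hinges [%s], R^2 %.3f; piecewise cut %.4g, intersection %.4g\n",
                  nm, paste(round(b$mars$hinges, 1), collapse = ", "),
                  b$mars$r_squared, b$piecewise$cut,
                  b$piecewise$intersection_x))
    }
  }
  cat("  survival thresholds:",
      if (length(x$thresholds)) paste(x$thresholds, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits per-biomarker MARS/piecewise summaries, the stratified survival
#' table, the baseline comparison table and a provenance echo as CSV and
#' plain text under `dir`.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory, created if needed.
#' @return `bundle`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$biomarkers)) {
    b <- bundle$biomarkers[[nm]]
    if (isTRUE(b$skipped)) next
    readr::write_csv(tidy(b$mars), file.path(dir, paste0("mars_", nm, ".csv")))
    readr::write_csv(b$piecewise$r2_profile,
                     file.path(dir, paste0("r2_profile_", nm, ".csv")))
  }
  readr::write_csv(tidy(bundle$survival), file.path(dir, "survival_strata.csv"))
  readr::write_csv(bundle$baseline_table, file.path(dir, "baseline_table.csv"))
  txt <- c(utils::capture.output(print(bundle)),
           "", "provenance:",
           utils::capture.output(utils::str(bundle$provenance)))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(bundle)
}
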