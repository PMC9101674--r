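#' Nelson-Aalen cumulative hazard estimate
#'
#' Cumulative hazard `H(t) = sum_{t_i <= t} d_i / n_i` over the distinct
#' event times, with `d_i` events among `n_i` at risk.
#'
#' @param data Data frame with time and event columns.
#' @param time,event Column names (strings); `event` is 0/1.
#' @return A `hazard_curve`: tibble columns `time`, `n_risk`, `n_event`,
#'   `cumulative_hazard` (event times only).
#' @examples
#' d <- tibble::tibble(time_years = c(1, 2, 3), event = c(1, 1, 1))
#' tidy(nelson_aalen(d))
#' @export
nelson_aalen <- function(data, time = "time_years", event = "event") {
  check_xy_columns(data, time, event)
  tv <- data[[time]]
  ev <- data[[event]]
  keep <- is.finite(tv) & !is.na(ev)
  tv <- tv[keep]; ev <- ev[keep]
  if (any(tv <= 0)) {
    abort("Survival times must be positive.", class = "hingefit_invalid_parameter")
  }
  if (sum(ev) == 0) {
    warn("No events observed; cumulative hazard is identically zero.")
    out <- tibble::tibble(time = numeric(), n_risk = integer(),
                          n_event = integer(), cumulative_hazard = numeric())
    return(structure(list(curve = out, n = length(tv), n_events = 0L),
                     class = "hazard_curve"))
  }
  sf <- survival::survfit(survival::Surv(tv, ev) ~ 1)
  at_event <- sf$n.event > 0
  out <- tibble::tibble(
    time = sf$time[at_event],
    n_risk = sf$n.risk[at_event],
    n_event = sf$n.event[at_event],
    cumulative_hazard = cumsum(sf$n.event[at_event] / sf$n.risk[at_event]))
  structure(list(curve = out, n = length(tv), n_events = sum(ev)),
            class = "hazard_curve")
}

#' @export
tidy.hazard_curve <- function(x, ...) x$curve

#' @export
print.hazard_curve <- function(x, ...) {
  cat("<hazard_curve>", x$n_events, "events among", x$n, "subjects\n")
  if (nrow(x$curve) > 0) {
    cat(sprintf("  H(max t) = %.4f at t = %.3g\n",
                max(x$curve$cumulative_hazard), max(x$curve$time)))
  }
  invisible(x)
}

#' Kaplan-Meier survival probability at a horizon
#'
#' Product-limit estimate evaluated at `horizon` years; if the horizon
#' exceeds the last observed time the last estimate is carried forward
#' with a warning.
#'
#' @inheritParams nelson_aalen
#' @param horizon Evaluation time (years), default 5.
#' @return A single survival probability.
#' @export
rfs_at <- function(data, horizon = 5, time = "time_years", event = "event") {
  check_xy_columns(data, time, event)
  tv <- data[[time]]
  ev <- data[[event]]
  keep <- is.finite(tv) & !is.na(ev)
  tv <- tv[keep]; ev <- ev[keep]
  if (length(tv) == 0) abort("No usable observations.",
                             class = "hingefit_degenerate_input")
  if (horizon > max(tv)) {
    warn(sprintf(
      "Horizon %.3g beyond last observed time %.3g; carrying last estimate.",
      horizon, max(tv)))
  }
  if (sum(ev) == 0) return(1)
  sf <- survival::survfit(survival::Surv(tv, ev) ~ 1)
  s <- summary(sf, times = min(horizon, max(tv)), extend = TRUE)
  unname(s$surv)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood via [survival::coxph()] (Efron tie
#' handling by default) and reports hazard ratios with Wald 95%
#' confidence intervals on the log scale.  Monotone-likelihood fits
#' (complete separation of events) are flagged, not raised.
#'
#' @inheritParams nelson_aalen
#' @param covariates Character vector of covariate column names; the first
#'   is conventionally the treatment indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit` object; `tidy()` gives one row per covariate.
#' @examples
#' strat <- simulate_survival(rep(2L, 200), rep(c("placebo", "vitamin_d"), 100),
#'                            survival_params())
#' strat$arm_treated <- rep(c(0, 1), 100)
#' fit <- cox_fit(strat, covariates = "arm_treated", time = "time")
#' tidy(fit)
#' @export
cox_fit <- function(data, covariates, time = "time_years", event = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_xy_columns(data, time, event)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("Missing covariate columns: ",
                 paste(missing_cov, collapse = ", ")),
          class = "hingefit_schema_error")
  }
  df <- data[complete.cases(data[, c(time, event, covariates)]), ]
  if (sum(df[[event]]) < 1) {
    abort("Cox model needs at least one event.",
          class = "hingefit_degenerate_input")
  }
  fml <- as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- all(is.finite(beta)) && all(abs(beta) < 15)
  structure(
    list(coefficients = beta, se = se, hr = exp(beta),
         ci95 = cbind(lower = exp(beta - qnorm(0.975) * se),
                      upper = exp(beta + qnorm(0.975) * se)),
         p = 2 * stats::pnorm(-abs(beta / se)),
         n = fit$n, n_events = fit$nevent,
         ties = ties, converged = converged, coxph = fit),
    class = "cox_fit")
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 hr = unname(x$hr),
                 conf.low = unname(x$ci95[, "lower"]),
                 conf.high = unname(x$ci95[, "upper"]),
                 p.value = unname(x$p))
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, ties = x$ties,
                 converged = x$converged)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", x$n_events, "events /", x$n, "subjects, ties =", x$ties, "\n")
  print(tidy(x))
  if (!x$converged) cat("  WARNING: monotone likelihood / non-convergence flagged\n")
  invisible(x)
}

#' Treatment-by-stratum interaction model
#'
#' Three-covariate Cox model: treatment arm, high-25(OH)D group, and
#' their product as the interaction covariate; the interaction p-value is
#' the Wald p of the product term.
#'
#' @inheritParams nelson_aalen
#' @param arm Column name of the treatment indicator (0/1 or
#'   placebo/vitamin_d labels).
#' @param high_group Column name of the above-threshold indicator (0/1).
#' @return A `cox_fit` with an extra `interaction_p` element.
#' @export
interaction_model <- function(data, arm = "arm", high_group = "high_group",
                              time = "time_years", event = "event") {
  check_xy_columns(data, arm, high_group)
  df <- data[complete.cases(data[, c(time, event, arm, high_group)]), ]
  treated <- as.numeric(df[[arm]] %in% c(1, "1", "vitamin_d", "treatment", TRUE))
  high <- as.numeric(df[[high_group]])
  cells <- table(treated, high, df[[event]])
  for (tr in 0:1) for (hg in 0:1) {
    has_events <- sum(df[[event]][treated == tr & high == hg]) > 0
    if (sum(treated == tr & high == hg) == 0 || !has_events) {
      abort(sprintf(
        "Stratum-arm cell (arm=%d, high=%d) has no subjects with events.",
        tr, hg), class = "hingefit_degenerate_input")
    }
  }
  df$.arm_treated <- treated
  df$.high <- high
  df$.interaction <- treated * high
  fit <- cox_fit(df, covariates = c(".arm_treated", ".high", ".interaction"),
                 time = time, event = event)
  fit$interaction_p <- unname(fit$p[".interaction"])
  fit
}

#' Threshold-stratified survival comparison
#'
#' Assigns baseline strata from the estimated 25(OH)D thresholds (see
#' [assign_stratum()] for the boundary convention), then per stratum fits
#' the treatment-vs-placebo Cox model and evaluates the Kaplan-Meier RFS
#' for each arm at the horizon.  With a single threshold the two-stratum
#' interaction model is also fitted, and per-stratum hazard ratios are
#' reported both from the stratum-restricted fit and from the interaction
#' model's linear combination.
#'
#' @param cohort Cohort tibble (the [simulate_cohort()] schema).
#' @param thresholds Sorted 25(OH)D thresholds (ng/mL).
#' @param baseline Column used for stratification.
#' @param horizon RFS evaluation time (years).
#' @inheritParams nelson_aalen
#' @return A `stratified_survival` object with a per-stratum results
#'   tibble (`tidy()`).
#' @export
stratified_comparison <- function(cohort, thresholds,
                                  baseline = "x25ohd_baseline",
                                  horizon = 5,
                                  time = "time_years", event = "event") {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing.",
          class = "hingefit_invalid_parameter")
  }
  check_xy_columns(cohort, baseline, time)
  df <- cohort[complete.cases(cohort[, c(baseline, time, event)]), ]
  df$.stratum <- assign_stratum(df[[baseline]], thresholds)
  df$.arm_treated <- as.numeric(df$arm %in% c(1, "1", "vitamin_d", "treatment"))
  k <- length(thresholds) + 1L
  labels <- stratum_labels(thresholds)

  rows <- purrr::map_dfr(seq_len(k), function(s) {
    sub <- df[df$.stratum == s, ]
    base <- tibble::tibble(
      stratum = s, label = labels[s], n = nrow(sub),
      n_events = sum(sub[[event]]),
      rfs_placebo = NA_real_, rfs_treatment = NA_real_,
      hr = NA_real_, hr_low = NA_real_, hr_high = NA_real_,
      hr_p = NA_real_)
    if (nrow(sub) == 0) return(base)
    for (arm_val in c(0, 1)) {
      asub <- sub[sub$.arm_treated == arm_val, ]
      if (nrow(asub) > 0) {
        val <- suppressWarnings(rfs_at(asub, horizon, time, event))
        if (arm_val == 0) base$rfs_placebo <- val else base$rfs_treatment <- val
      }
    }
    fit <- tryCatch(
      cox_fit(sub, covariates = ".arm_treated", time = time, event = event),
      error = function(e) NULL)
    if (!is.null(fit)) {
      base$hr <- unname(fit$hr[1])
      base$hr_low <- fit$ci95[1, "lower"]
      base$hr_high <- fit$ci95[1, "upper"]
      base$hr_p <- unname(fit$p[1])
    }
    base
  })

  interaction <- NULL
  if (k == 2L) {
    df$.high <- as.numeric(df$.stratum == 2L)
    interaction <- tryCatch(
      interaction_model(df, arm = ".arm_treated", high_group = ".high",
                        time = time, event = event),
      error = function(e) NULL)
    if (!is.null(interaction)) {
      # HR in the high stratum implied by the interaction model
      b <- interaction$coefficients
      rows$hr_interaction_model <- c(
        exp(unname(b[".arm_treated"])),
        exp(unname(b[".arm_treated"] + b[".interaction"])))
    }
  }

  structure(list(table = rows, thresholds = thresholds, horizon = horizon,
                 interaction = interaction, data = df),
            class = "stratified_survival")
}

stratum_labels <- function(thresholds) {
  k <- length(thresholds) + 1L
  if (k == 1L) return("all")
  labs <- character(k)
  labs[1] <- sprintf("<=%.4g", thresholds[1])
  if (k > 2L) {
    for (s in 2:(k - 1L)) {
      labs[s] <- sprintf("(%.4g, %.4g)", thresholds[s - 1L], thresholds[s])
    }
  }
  labs[k] <- if (k > 2L) sprintf(">=%.4g", thresholds[k - 1L])
             else sprintf(">%.4g", thresholds[1])
  labs
}

#' @export
tidy.stratified_survival <- function(x, ...) x$table

#' @export
print.stratified_survival <- function(x, ...) {
  cat("<stratified_survival> thresholds at",
      paste(x$thresholds, collapse = ", "), "ng/mL; RFS at",
      x$horizon, "years\n")
  print(x$table)
  if (!is.null(x$interaction)) {
    cat(sprintf("  treatment x high-group interaction p = %.3g\n",
                x$interaction$interaction_p))
  }
  invisible(x)
}

#' Write the per-stratum survival table as CSV
#'
#' @param x A `stratified_survival`.
#' @param path File path.
#' @return `x`, invisibly.
#' @export
write_stratified_table <- function(x, path) {
  readr::write_csv(tidy(x), path)
  invisible(x)
}
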