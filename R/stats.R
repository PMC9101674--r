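#' Baseline and change comparisons between trial arms
#'
#' Per-variable tests following the trial's conventions: Fisher's exact
#' test on the arm-by-level contingency table for categorical variables,
#' the two-sample Student's t-test between arms for continuous variables,
#' and the paired t-test for within-arm year-1 minus baseline changes.
#' All p-values are two-sided; no multiplicity correction is applied.
#'
#' @param data Cohort data frame containing `group` plus the requested
#'   variables.
#' @param group Column defining the two arms.
#' @param continuous Character vector of continuous column names compared
#'   between arms.
#' @param categorical Character vector of categorical column names tested
#'   by Fisher's exact test.
#' @param paired_pairs Named list of `c(baseline_col, followup_col)`
#'   pairs; the paired t-test of followup minus baseline is run within
#'   each arm.
#' @return A tibble with columns `variable`, `test`, `arm`, `estimate`,
#'   `statistic`, `p_value`, `note`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 1)
#' compare_baseline(cohort,
#'   continuous = c("x25ohd_y1", "calcium_y1"),
#'   paired_pairs = list(calcium = c("calcium_baseline", "calcium_y1")))
#' @export
compare_baseline <- function(data, group = "arm",
                             continuous = c("x25ohd_baseline", "x25ohd_y1",
                                            "calcium_y1", "pth_y1"),
                             categorical = character(),
                             paired_pairs = list()) {
  check_xy_columns(data, group, group)
  arms <- sort(unique(data[[group]]))
  if (length(arms) != 2) {
    abort("`compare_baseline` needs exactly two arms.",
          class = "hingefit_invalid_parameter")
  }
  rows <- list()

  for (v in continuous) {
    check_xy_columns(data, v, v)
    a <- data[[v]][data[[group]] == arms[1]]
    b <- data[[v]][data[[group]] == arms[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(unique(c(a, b))) < 2 || sd(c(a, b)) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, test = "two-sample t", arm = "both",
        estimate = NA_real_, statistic = NA_real_, p_value = NA_real_,
        note = "incomparable: zero variance")
      next
    }
    tt <- t.test(a, b)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "two-sample t", arm = "both",
      estimate = unname(diff(rev(tt$estimate))),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      note = sprintf("%s minus %s", arms[1], arms[2]))
  }

  for (v in categorical) {
    check_xy_columns(data, v, v)
    tab <- table(data[[group]], data[[v]])
    ft <- fisher.test(tab)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "Fisher exact", arm = "both",
      estimate = if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_,
      statistic = NA_real_, p_value = ft$p.value, note = "")
  }

  for (nm in names(paired_pairs)) {
    pair <- paired_pairs[[nm]]
    check_xy_columns(data, pair[1], pair[2])
    for (arm_val in arms) {
      sub <- data[data[[group]] == arm_val, ]
      delta <- sub[[pair[2]]] - sub[[pair[1]]]
      delta <- delta[!is.na(delta)]
      if (length(delta) < 2 || sd(delta) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = nm, test = "paired t", arm = as.character(arm_val),
          estimate = mean(delta), statistic = NA_real_, p_value = NA_real_,
          note = "incomparable: too few pairs or zero variance")
        next
      }
      tt <- t.test(delta)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = nm, test = "paired t", arm = as.character(arm_val),
        estimate = unname(tt$estimate), statistic = unname(tt$statistic),
        p_value = tt$p.value,
        note = sprintf("%s minus %s", pair[2], pair[1]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Bootstrap normality diagnostic for the t statistic
#'
#' Resamples `values` with replacement, computes the studentized
#' statistic `(mean* - mean) / (sd* / sqrt(n))` per resample, and returns
#' the quantile-quantile comparison against the standard normal together
#' with a Shapiro-Wilk p-value on the bootstrap replicates.  A p-value
#' above 0.05 and a QQ line near the identity support using t-based
#' inference on these data.
#'
#' @param values Numeric vector, at least 8 non-missing observations.
#' @param reps Number of bootstrap resamples (>= 8; default 1000).
#' @param seed RNG seed.
#' @return A `bootstrap_t_diag`: `qq` tibble (`theoretical`, `sample`),
#'   `shapiro_p`, `qq_slope`, `qq_intercept`.
#' @export
bootstrap_t_normality <- function(values, reps = 1000, seed = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) abort("Need at least 8 observations.",
                   class = "hingefit_degenerate_input")
  if (sd(values) == 0) abort("Constant input: t statistic undefined.",
                             class = "hingefit_degenerate_input")
  if (reps < 8) abort("`reps` must be at least 8 for a usable diagnostic.",
                      class = "hingefit_invalid_parameter")
  set_master_seed(seed)
  m0 <- mean(values)
  tstats <- vapply(seq_len(reps), function(b) {
    s <- sample(values, n, replace = TRUE)
    sdv <- sd(s)
    if (sdv == 0) return(NA_real_)
    (mean(s) - m0) / (sdv / sqrt(n))
  }, numeric(1))
  tstats <- tstats[is.finite(tstats)]
  qq <- tibble::tibble(
    theoretical = qnorm(ppoints(length(tstats))),
    sample = sort(tstats))
  qfit <- ols_line(qq$theoretical, qq$sample)
  sw <- shapiro.test(if (length(tstats) > 5000) sample(tstats, 5000) else tstats)
  structure(list(qq = qq, shapiro_p = sw$p.value,
                 qq_slope = qfit$slope, qq_intercept = qfit$intercept,
                 reps = length(tstats), n = n),
            class = "bootstrap_t_diag")
}

#' @export
print.bootstrap_t_diag <- function(x, ...) {
  cat("<bootstrap_t_diag>", x$reps, "bootstrap t statistics from n =", x$n, "\n")
  cat(sprintf("  Shapiro-Wilk p = %.3g; QQ slope %.3f, intercept %.3f\n",
              x$shapiro_p, x$qq_slope, x$qq_intercept))
  invisible(x)
}

#' Levene's test for homogeneity of variance
#'
#' Levene statistic on absolute deviations from the group means
#' (center = mean, the trial's convention), via [car::leveneTest()].
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`; at least two
#'   groups with two observations each.
#' @return A tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    abort("Need at least two groups.", class = "hingefit_invalid_parameter")
  }
  if (any(table(groups) < 2)) {
    abort("Every group needs at least 2 observations.",
          class = "hingefit_invalid_parameter")
  }
  lt <- car::leveneTest(values, groups, center = mean)
  tibble::tibble(statistic = lt[1, "F value"],
                 df1 = lt[1, "Df"], df2 = lt[2, "Df"],
                 p_value = lt[1, "Pr(>F)"])
}
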