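#' Simulate a synthetic trial cohort
#'
#' Draws one patient-level cohort from a [cohort_spec()]: arm-specific
#' truncated-normal 25(OH)D at baseline and year 1, calcium and PTH lying on
#' the configured hinge curves plus Gaussian residual noise, and
#' stratum-by-arm exponential relapse-free survival with administrative
#' censoring.  Supplemented patients whose baseline 25(OH)D is at or below
#' the first calcium hinge receive the configured mean year-1 calcium
#' increase (`treatment_calcium_shift`) on top of their baseline curve
#' level, so the expected paired change in that subgroup equals the shift.
#'
#' Generation is vectorized in a fixed column order under a single seed, so
#' the same `spec` and `seed` always reproduce the identical table.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed; defaults to `spec$seed`.
#' @return A tibble with one row per patient and columns `patient_id`,
#'   `arm`, `x25ohd_baseline`, `x25ohd_y1`, `calcium_baseline`,
#'   `calcium_y1`, `pth_baseline`, `pth_y1`, `time_years`, `event`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 42)
#' mean(cohort$x25ohd_y1)
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(vapply(spec$arms, function(a) a$n, integer(1)))
  if (n_total == 0L) return(empty_cohort())

  set_master_seed(seed)
  pieces <- lapply(names(spec$arms), function(arm_name) {
    a <- spec$arms[[arm_name]]
    if (a$n == 0L) return(NULL)
    xb <- rnorm_trunc(a$n, a$mean_baseline, a$sd_baseline, a$floor, a$cap)
    xy <- rnorm_trunc(a$n, a$mean_y1, a$sd_y1, a$floor, a$cap)

    ca_b <- predict(spec$calcium_curve, xb) + rnorm(a$n, 0, spec$calcium_noise_sd)
    ca_y <- predict(spec$calcium_curve, xy) + rnorm(a$n, 0, spec$calcium_noise_sd)
    # treated patients starting at or below the first calcium hinge: year-1
    # calcium is baseline curve level + configured mean increase; a zero
    # shift disables this and leaves year-1 calcium on the response curve
    if (arm_name == "vitamin_d" && spec$treatment_calcium_shift != 0 &&
        length(spec$calcium_curve$hinges) > 0) {
      low <- xb <= spec$calcium_curve$hinges[1]
      if (any(low)) {
        ca_y[low] <- predict(spec$calcium_curve, xb[low]) +
          spec$treatment_calcium_shift +
          rnorm(sum(low), 0, spec$calcium_noise_sd)
      }
    }
    pth_b <- predict(spec$pth_curve, xb) + rnorm(a$n, 0, spec$pth_noise_sd)
    pth_y <- predict(spec$pth_curve, xy) + rnorm(a$n, 0, spec$pth_noise_sd)

    stratum <- assign_stratum(xb, spec$survival$strata_bounds)
    surv <- simulate_survival(stratum, rep(arm_name, a$n), spec$survival)

    tibble::tibble(
      arm = arm_name,
      x25ohd_baseline = xb, x25ohd_y1 = xy,
      calcium_baseline = ca_b, calcium_y1 = ca_y,
      pth_baseline = pmax(pth_b, 0.5), pth_y1 = pmax(pth_y, 0.5),
      time_years = surv$time, event = surv$event
    )
  })
  cohort <- dplyr::bind_rows(pieces)
  cohort <- dplyr::mutate(cohort, patient_id = dplyr::row_number(),
                          .before = 1)
  if (spec$missing_y1_fraction > 0) {
    knockout <- runif(nrow(cohort)) < spec$missing_y1_fraction
    cohort$x25ohd_y1[knockout] <- NA_real_
    cohort$calcium_y1[knockout] <- NA_real_
    cohort$pth_y1[knockout] <- NA_real_
  }
  cohort
}

empty_cohort <- function() {
  tibble::tibble(patient_id = integer(), arm = character(),
                 x25ohd_baseline = numeric(), x25ohd_y1 = numeric(),
                 calcium_baseline = numeric(), calcium_y1 = numeric(),
                 pth_baseline = numeric(), pth_y1 = numeric(),
                 time_years = numeric(), event = integer())
}

#' Assign baseline 25(OH)D strata
#'
#' Boundary convention for integer-reported bounds `c(t1, t2)`: low is
#' `x <= t1`, intermediate is `t1 < x < t2`, high is `x >= t2`.
#'
#' @param x Baseline 25(OH)D values (ng/mL).
#' @param bounds Strictly increasing cut points.
#' @return Integer stratum index, 1 = lowest.
#' @export
assign_stratum <- function(x, bounds) {
  if (length(bounds) == 0) return(rep(1L, length(x)))
  k <- length(bounds)
  idx <- rep(1L, length(x))
  for (j in seq_len(k - 1L)) idx <- idx + (x > bounds[j])
  # the top stratum is closed on the left ("x >= 29") when there are two or
  # more bounds; a single threshold splits as low <= t < high
  top <- if (k >= 2L) x >= bounds[k] else x > bounds[k]
  as.integer(idx + top)
}

#' Simulate stratum-by-arm relapse-free survival
#'
#' Exponential relapse times with placebo hazard
#' `-log(rfs5_placebo) / 5` per stratum, multiplied by the stratum hazard
#' ratio in the treatment arm; administrative censoring at
#' `censor_horizon` minus a uniform accrual offset.
#'
#' @param stratum Integer stratum indices (1-based).
#' @param arm Character vector, `"placebo"` or `"vitamin_d"` (any non-placebo
#'   label is treated as the treatment arm).
#' @param params A [survival_params()].
#' @return A tibble with columns `time` (years, > 0) and `event` (0/1).
#' @export
simulate_survival <- function(stratum, arm, params) {
  stopifnot(inherits(params, "survival_params"))
  n <- length(stratum)
  k <- length(params$rfs5_placebo)
  if (length(arm) == 1L) arm <- rep(arm, n)
  if (any(stratum < 1L | stratum > k | stratum != floor(stratum))) {
    abort(sprintf("Unknown stratum; expected integers in 1..%d.", k),
          class = "hingefit_invalid_parameter")
  }
  lambda0 <- -log(params$rfs5_placebo) / 5
  rate <- lambda0[stratum] * ifelse(arm == "placebo", 1, params$hr_treatment[stratum])
  relapse <- ifelse(rate > 0, stats::rexp(n) / pmax(rate, .Machine$double.xmin), Inf)
  censor <- params$censor_horizon -
    (if (params$accrual_window > 0) runif(n, 0, params$accrual_window) else 0)
  tibble::tibble(time = pmax(pmin(relapse, censor), 1e-6),
                 event = as.integer(relapse <= censor))
}

# truncated normal by redraw (not clamping), preserving the density shape
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- out < lo | out > hi
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  abort("Truncation bounds capture too little probability mass.",
        class = "hingefit_invalid_parameter")
}

# set the RNG seed locally without clobbering the caller's stream
set_master_seed <- function(seed) {
  seed <- as.integer(seed)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Read / write a cohort CSV
#'
#' The on-disk schema has one row per patient with columns `patient_id`,
#' `arm`, `x25ohd_baseline`, `x25ohd_y1`, `calcium_baseline`, `calcium_y1`,
#' `pth_baseline`, `pth_y1`, `time_years`, `event`; missing values are
#' empty fields.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns a tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cols <- readr::cols(
    patient_id = readr::col_integer(),
    arm = readr::col_character(),
    x25ohd_baseline = readr::col_double(),
    x25ohd_y1 = readr::col_double(),
    calcium_baseline = readr::col_double(),
    calcium_y1 = readr::col_double(),
    pth_baseline = readr::col_double(),
    pth_y1 = readr::col_double(),
    time_years = readr::col_double(),
    event = readr::col_integer()
  )
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(names(cols$cols), header)
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hingefit_schema_error")
  }
  readr::read_csv(path, col_types = cols, na = "")
}
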