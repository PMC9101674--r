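#' Locally weighted scatterplot smoothing (LOWESS)
#'
#' Visual threshold-screening stage: at each evaluation point a tricube
#' weighted local linear regression is fit on the nearest
#' `bandwidth * n` observations (Cleveland's LOWESS, via [stats::lowess()]);
#' optional bisquare robustifying iterations downweight large residuals.
#' The default bandwidth of 0.8 uses 80% of the data for each local fit.
#' The smooth is intended for qualitative inspection — judging whether the
#' scatter can be approximated by straight-line segments — not for
#' inference; no confidence bands are produced.
#'
#' @param data Data frame with the predictor and response columns.
#' @param x,y Column names (strings) of the 25(OH)D predictor and the
#'   biomarker response.
#' @param bandwidth Fraction of the data entering each local fit, in (0, 1].
#' @param robust_iterations Number of bisquare robustifying iterations
#'   (0 = plain weighted least squares).
#' @param grid Either `"data"` (evaluate at the sorted, deduplicated
#'   observed x values, the default) or an integer: evaluate on that many
#'   uniformly spaced points across the observed range (for plotting) by
#'   linear interpolation of the fit at the data points.
#' @return A `smooth_curve` object; `tidy()` returns a tibble with
#'   `grid_x` and `fitted_y`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 1)
#' sc <- lowess_fit(cohort, "x25ohd_y1", "calcium_y1")
#' head(tidy(sc))
#' @export
lowess_fit <- function(data, x = "x25ohd_y1", y = "calcium_y1",
                       bandwidth = 0.8, robust_iterations = 0,
                       grid = "data") {
  check_xy_columns(data, x, y)
  keep <- complete.cases(data[, c(x, y)])
  xv <- data[[x]][keep]
  yv <- data[[y]][keep]
  if (length(xv) < 3) {
    abort("LOWESS needs at least 3 complete observations.",
          class = "hingefit_degenerate_input")
  }
  if (diff(range(xv)) == 0) {
    abort("All x values identical; nothing to smooth.",
          class = "hingefit_degenerate_input")
  }
  if (bandwidth <= 0 || bandwidth > 1) {
    abort("`bandwidth` must lie in (0, 1].", class = "hingefit_invalid_parameter")
  }
  fit <- stats::lowess(xv, yv, f = bandwidth, iter = robust_iterations,
                       delta = 0)
  # deduplicate tied x (lowess returns one fitted value per observation)
  dedup <- !duplicated(fit$x)
  grid_x <- fit$x[dedup]
  fitted_y <- fit$y[dedup]
  if (is.numeric(grid)) {
    gx <- seq(min(xv), max(xv), length.out = as.integer(grid))
    fitted_y <- stats::approx(grid_x, fitted_y, xout = gx)$y
    grid_x <- gx
  }
  extrapolated <- fitted_y < min(yv) - diff(range(yv)) |
    fitted_y > max(yv) + diff(range(yv))
  structure(
    list(grid_x = grid_x, fitted_y = fitted_y, bandwidth = bandwidth,
         robust_iterations = robust_iterations,
         extrapolation_flag = any(extrapolated),
         data = tibble::tibble(x = xv, y = yv),
         x_label = x, y_label = y),
    class = "smooth_curve"
  )
}

check_xy_columns <- function(data, x, y) {
  missing_cols <- setdiff(c(x, y), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "hingefit_schema_error")
  }
  invisible(TRUE)
}

#' @export
tidy.smooth_curve <- function(x, ...) {
  tibble::tibble(grid_x = x$grid_x, fitted_y = x$fitted_y)
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat("<smooth_curve> LOWESS, bandwidth", x$bandwidth, "\n")
  cat("  ", length(x$grid_x), "evaluation points over [",
      round(min(x$grid_x), 2), ",", round(max(x$grid_x), 2), "]\n")
  if (x$extrapolation_flag) cat("  note: fitted values stray beyond the data range\n")
  invisible(x)
}

#' Write the smoothed curve as a two-column CSV
#'
#' @param curve A `smooth_curve`.
#' @param path File path.
#' @return `curve`, invisibly.
#' @export
write_smooth_curve <- function(curve, path) {
  readr::write_csv(tidy(curve), path)
  invisible(curve)
}
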