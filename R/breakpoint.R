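#' R-squared grid search for the piecewise segment limit
#'
#' For each candidate cut `c` in `seq(lo, hi, step)` (ng/mL), fits an
#' ordinary least-squares line on the observations with `x <= c` and
#' records its R-squared.  The selected cut maximizes R-squared; exact
#' ties are broken toward the largest tied cut (maximizing lower-segment
#' data use).  Candidate cuts capturing fewer than 3 points are skipped
#' with a warning.
#'
#' @param data Data frame.
#' @param x,y Column names (strings).
#' @param lo,hi,step Candidate cut window (ng/mL) and spacing.
#' @return A list with `r2_profile` (tibble `cut`, `r_squared`, `n_points`)
#'   and `cut` (the selected limit).
#' @export
grid_search_cut <- function(data, x = "x25ohd_y1", y = "calcium_y1",
                            lo = 15, hi = 40, step = 1) {
  check_xy_columns(data, x, y)
  keep <- complete.cases(data[, c(x, y)])
  xv <- data[[x]][keep]
  yv <- data[[y]][keep]
  if (sum(xv <= lo) < 3) {
    abort("Fewer than 3 points at or below the lowest candidate cut.",
          class = "hingefit_degenerate_input")
  }
  cand <- seq(lo, hi, by = step)
  prof <- purrr::map_dfr(cand, function(cut) {
    inside <- xv <= cut
    if (sum(inside) < 3) {
      warn(sprintf("Candidate cut %.4g captures fewer than 3 points; skipped.", cut))
      return(tibble::tibble(cut = cut, r_squared = NA_real_,
                            n_points = sum(inside)))
    }
    f <- ols_line(xv[inside], yv[inside])
    tibble::tibble(cut = cut, r_squared = f$r_squared, n_points = f$n)
  })
  ok <- which(!is.na(prof$r_squared))
  best <- max(prof$r_squared[ok])
  tied <- ok[prof$r_squared[ok] >= best - 1e-12]
  selected <- max(prof$cut[tied])
  list(r2_profile = prof, cut = selected)
}

# closed-form simple OLS with t-based slope inference; verified against lm
# in the test suite
ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    return(list(slope = NA_real_, intercept = mean(y), r_squared = NA_real_,
                slope_se = NA_real_, slope_ci95 = c(NA_real_, NA_real_),
                slope_p = NA_real_, n = n))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  df <- n - 2
  se <- if (df > 0) sqrt(rss / df / sxx) else NA_real_
  tcrit <- if (df > 0) qt(0.975, df) else NA_real_
  p <- if (df > 0 && se > 0) 2 * pt(-abs(slope / se), df) else NA_real_
  list(slope = slope, intercept = intercept, r_squared = r2,
       slope_se = se, slope_ci95 = c(slope - tcrit * se, slope + tcrit * se),
       slope_p = p, n = n)
}

new_segment_fit <- function(fit, x_range) {
  structure(list(x_range = x_range, slope = fit$slope,
                 intercept = fit$intercept, slope_ci95 = fit$slope_ci95,
                 slope_p = fit$slope_p, r_squared = fit$r_squared,
                 n_points = fit$n),
            class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> x in [%.3g, %.3g], n=%d\n",
              x$x_range[1], x$x_range[2], x$n_points))
  cat(sprintf("  slope %.4g (95%% CI %.4g to %.4g, p=%.3g), R^2 %.3f\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2], x$slope_p,
              x$r_squared))
  invisible(x)
}

#' @export
tidy.segment_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 conf.low = x$slope_ci95[1], conf.high = x$slope_ci95[2],
                 p.value = x$slope_p, r.squared = x$r_squared,
                 n = x$n_points)
}

#' Fit the upper (near-plateau) regression segment
#'
#' Ordinary least squares on the observations strictly above the cut,
#' with a t-distribution confidence interval on the slope.
#'
#' @inheritParams grid_search_cut
#' @param cut Segment limit (ng/mL); points with `x > cut` are used.
#' @return A `segment_fit`.
#' @export
fit_upper_segment <- function(data, x = "x25ohd_y1", y = "calcium_y1", cut) {
  check_xy_columns(data, x, y)
  keep <- complete.cases(data[, c(x, y)]) & data[[x]] > cut
  if (sum(keep) < 3) {
    abort("Fewer than 3 points above the cut.",
          class = "hingefit_degenerate_input")
  }
  xv <- data[[x]][keep]
  yv <- data[[y]][keep]
  new_segment_fit(ols_line(xv, yv), range(xv))
}

fit_lower_segment <- function(data, x, y, cut) {
  keep <- complete.cases(data[, c(x, y)]) & data[[x]] <= cut
  if (sum(keep) < 3) {
    abort("Fewer than 3 points at or below the cut.",
          class = "hingefit_degenerate_input")
  }
  xv <- data[[x]][keep]
  yv <- data[[y]][keep]
  new_segment_fit(ols_line(xv, yv), range(xv))
}

#' Intersection point of two fitted line segments
#'
#' Solves `a1 + b1 x = a2 + b2 x`.  Near-parallel lines (slope difference
#' below `parallel_tol`) do not crash: the result carries
#' `reliable = FALSE` and the slope difference, since a diverging
#' intersection abscissa is a real failure mode of this construction.
#'
#' @param lower,upper `segment_fit` objects.
#' @param parallel_tol Minimum slope difference treated as non-parallel.
#' @return A list with `x`, `y`, `reliable`, `slope_difference`.
#' @export
intersect_lines <- function(lower, upper, parallel_tol = 1e-8) {
  b_diff <- lower$slope - upper$slope
  if (!is.finite(b_diff) || abs(b_diff) <= parallel_tol) {
    return(list(x = NA_real_, y = NA_real_, reliable = FALSE,
                slope_difference = b_diff))
  }
  x_star <- (upper$intercept - lower$intercept) / b_diff
  y_star <- lower$intercept + lower$slope * x_star
  list(x = x_star, y = y_star, reliable = TRUE, slope_difference = b_diff)
}

#' Full piecewise linear threshold analysis
#'
#' Composes the grid search for the segment limit, the independent lower
#' and upper OLS fits, their intersection point, a percentile-bootstrap
#' interval for the intersection ordinate (resampling patients and
#' repeating the whole procedure), and an optional search for a second
#' (upper-range) threshold which always carries a reliability flag —
#' near-parallel segments or an intersection outside the observed range
#' are flagged rather than trusted.
#'
#' @inheritParams grid_search_cut
#' @param bootstrap_reps Number of patient resamples for the intersection
#'   ordinate interval (default 1000; 0 disables).
#' @param second_window `c(lo, hi)` candidate window for the upper-range
#'   second threshold search (default `c(40, 70)`); `NULL` disables.
#' @param seed RNG seed for the bootstrap.
#' @return A `piecewise_result`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 1)
#' pw <- piecewise_analysis(cohort, "x25ohd_y1", "pth_y1",
#'                          bootstrap_reps = 50)
#' pw$intersection
#' @export
piecewise_analysis <- function(data, x = "x25ohd_y1", y = "calcium_y1",
                               lo = 15, hi = 40, step = 1,
                               bootstrap_reps = 1000,
                               second_window = c(40, 70), seed = 1) {
  check_xy_columns(data, x, y)
  keep <- complete.cases(data[, c(x, y)])
  df <- data[keep, c(x, y)]
  xv <- df[[x]]
  yv <- df[[y]]

  gs <- grid_search_cut(df, x, y, lo = lo, hi = hi, step = step)
  lower <- fit_lower_segment(df, x, y, gs$cut)
  upper <- fit_upper_segment(df, x, y, cut = gs$cut)
  inter <- intersect_lines(lower, upper)
  if (isTRUE(inter$reliable) &&
      (inter$x < min(xv) || inter$x > max(xv))) {
    inter$reliable <- FALSE
  }

  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0 && isTRUE(inter$reliable)) {
    set_master_seed(seed)
    ys <- rep(NA_real_, bootstrap_reps)
    n <- length(xv)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      ys[b] <- tryCatch({
        bdf <- tibble::as_tibble(setNames(list(xv[idx], yv[idx]), c(x, y)))
        bgs <- suppressWarnings(grid_search_cut(bdf, x, y, lo, hi, step))
        bl <- fit_lower_segment(bdf, x, y, bgs$cut)
        bu <- fit_upper_segment(bdf, x, y, cut = bgs$cut)
        bi <- intersect_lines(bl, bu)
        if (isTRUE(bi$reliable)) bi$y else NA_real_
      }, error = function(e) NA_real_)
    }
    ys <- ys[is.finite(ys)]
    if (length(ys) >= 20) ci <- unname(quantile(ys, c(0.025, 0.975)))
  }

  second <- NULL
  if (!is.null(second_window)) {
    second <- tryCatch(
      second_threshold_search(xv, yv, gs$cut, second_window, step),
      error = function(e) list(available = FALSE, reason = conditionMessage(e)))
  }

  structure(
    list(cut = gs$cut, r2_profile = gs$r2_profile,
         lower_fit = lower, upper_fit = upper,
         intersection_x = inter$x, intersection_y = inter$y,
         intersection_reliable = inter$reliable,
         slope_difference = inter$slope_difference,
         intersection_y_ci95 = ci,
         second_threshold = second,
         data = tibble::tibble(x = xv, y = yv),
         x_label = x, y_label = y),
    class = "piecewise_result")
}

# upper-range second threshold: grid search over cuts in the window, lower
# segment = (first cut, c], upper segment = x > c
second_threshold_search <- function(xv, yv, first_cut, window, step) {
  cand <- seq(window[1], window[2], by = step)
  mid <- xv > first_cut
  best <- NULL
  prof <- purrr::map_dfr(cand, function(cut) {
    inside <- mid & xv <= cut
    above <- xv > cut
    if (sum(inside) < 3 || sum(above) < 3) {
      return(tibble::tibble(cut = cut, r_squared = NA_real_))
    }
    f <- ols_line(xv[above], yv[above])
    tibble::tibble(cut = cut, r_squared = f$r_squared)
  })
  ok <- which(!is.na(prof$r_squared))
  if (length(ok) == 0) return(list(available = FALSE, reason = "window empty"))
  top <- max(prof$r_squared[ok])
  cut2 <- max(prof$cut[ok[prof$r_squared[ok] >= top - 1e-12]])
  mid_fit <- new_segment_fit(ols_line(xv[mid & xv <= cut2], yv[mid & xv <= cut2]),
                             range(xv[mid & xv <= cut2]))
  up_fit <- new_segment_fit(ols_line(xv[xv > cut2], yv[xv > cut2]),
                            range(xv[xv > cut2]))
  inter <- intersect_lines(mid_fit, up_fit)
  reliable <- isTRUE(inter$reliable) &&
    !is.na(up_fit$slope_p) && up_fit$slope_p < 0.05 &&
    inter$x >= min(xv) && inter$x <= max(xv)
  list(available = TRUE, cut = cut2, r2_profile = prof,
       mid_fit = mid_fit, upper_fit = up_fit,
       intersection_x = inter$x, intersection_y = inter$y,
       reliable = reliable)
}

#' @export
print.piecewise_result <- function(x, ...) {
  cat("<piecewise_result> ", x$y_label, " ~ ", x$x_label, "\n", sep = "")
  cat(sprintf("  segment limit (max R^2): %.4g; lower R^2 %.3f, upper R^2 %.3f\n",
              x$cut, x$lower_fit$r_squared, x$upper_fit$r_squared))
  cat(sprintf("  lower slope %.4g (p=%.3g), upper slope %.4g (p=%.3g)\n",
              x$lower_fit$slope, x$lower_fit$slope_p,
              x$upper_fit$slope, x$upper_fit$slope_p))
  if (isTRUE(x$intersection_reliable)) {
    cat(sprintf("  intersection at %.4g ng/mL, %.4g (95%% CI %.4g-%.4g)\n",
                x$intersection_x, x$intersection_y,
                x$intersection_y_ci95[1], x$intersection_y_ci95[2]))
  } else {
    cat(sprintf("  intersection unreliable (slope difference %.3g)\n",
                x$slope_difference))
  }
  if (!is.null(x$second_threshold) && isTRUE(x$second_threshold$available)) {
    st <- x$second_threshold
    cat(sprintf("  second threshold attempt: cut %.4g, intersection %.4g, %s\n",
                st$cut, st$intersection_x,
                if (isTRUE(st$reliable)) "reliable" else "flagged unreliable"))
  }
  invisible(x)
}

#' @export
tidy.piecewise_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$lower_fit), segment = "lower", .before = 1),
    dplyr::mutate(tidy(x$upper_fit), segment = "upper", .before = 1))
}

#' @export
glance.piecewise_result <- function(x, ...) {
  tibble::tibble(cut = x$cut,
                 intersection_x = x$intersection_x,
                 intersection_y = x$intersection_y,
                 intersection_reliable = x$intersection_reliable,
                 ci_low = x$intersection_y_ci95[1],
                 ci_high = x$intersection_y_ci95[2],
                 n = nrow(x$data))
}

#' Export the R-squared profile as CSV
#'
#' @param result A `piecewise_result`.
#' @param path File path.
#' @return `result`, invisibly.
#' @export
write_r2_profile <- function(result, path) {
  readr::write_csv(result$r2_profile, path)
  invisible(result)
}
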