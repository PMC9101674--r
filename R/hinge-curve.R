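#' Continuous piecewise-linear biomarker response curve
#'
#' A hinge curve describes how a serum biomarker (calcium in mg/dL, intact
#' PTH in pg/mL) responds to 25-hydroxyvitamin D, as a continuous
#' piecewise-linear function: `length(hinges) + 1` segments whose slopes
#' change at the hinge (knot) locations, anchored so that the curve passes
#' exactly through `(anchor_x, anchor_y)`.
#'
#' The package ships two calibrated defaults, [calcium_curve()] and
#' [pth_curve()], used by the synthetic cohort generator.
#'
#' @param hinges Numeric vector of knot locations (ng/mL), strictly
#'   increasing. May be empty (a single straight line).
#' @param slopes Numeric vector of per-segment slopes (biomarker units per
#'   ng/mL); must have `length(hinges) + 1` elements, ordered left to right.
#' @param anchor_x,anchor_y Point the curve passes through exactly;
#'   `anchor_x` in ng/mL, `anchor_y` in biomarker units.
#'
#' @return An object of class `hinge_curve`.
#' @examples
#' cc <- calcium_curve()
#' predict(cc, c(7, 17, 30))
#' @export
hinge_curve <- function(hinges, slopes, anchor_x, anchor_y) {
  hinges <- as.numeric(hinges)
  slopes <- as.numeric(slopes)
  if (length(hinges) > 0 && any(diff(hinges) <= 0)) {
    abort("`hinges` must be strictly increasing.", class = "hingefit_invalid_parameter")
  }
  if (length(slopes) != length(hinges) + 1L) {
    abort("`slopes` must have length(hinges) + 1 elements.",
          class = "hingefit_invalid_parameter")
  }
  if (!is.finite(anchor_x) || !is.finite(anchor_y)) {
    abort("Anchor coordinates must be finite.", class = "hingefit_invalid_parameter")
  }
  structure(
    list(hinges = hinges, slopes = slopes,
         anchor_x = anchor_x, anchor_y = anchor_y),
    class = "hinge_curve"
  )
}

#' Default calcium and PTH response curves
#'
#' Calibrated piecewise-linear responses of serum calcium and intact PTH to
#' 25(OH)D: calcium rises by 0.04 mg/dL per ng/mL up to a hinge at 17 ng/mL,
#' plateaus at 9.3 mg/dL between 17 and 47 ng/mL, then rises again at
#' 0.006 mg/dL per ng/mL; PTH falls by 0.96 pg/mL per ng/mL up to a hinge at
#' 29 ng/mL and plateaus at 20.1 pg/mL above it.
#'
#' @return A [hinge_curve()].
#' @export
calcium_curve <- function() {
  hinge_curve(hinges = c(17, 47), slopes = c(0.04, 0, 0.006),
              anchor_x = 17, anchor_y = 9.3)
}

#' @rdname calcium_curve
#' @export
pth_curve <- function() {
  hinge_curve(hinges = 29, slopes = c(-0.96, 0), anchor_x = 29, anchor_y = 20.1)
}

#' Evaluate a hinge curve
#'
#' @param object A [hinge_curve()].
#' @param x Numeric vector of 25(OH)D values (ng/mL).
#' @param ... Unused.
#' @return Numeric vector of biomarker values, same length as `x`.
#' @export
predict.hinge_curve <- function(object, x, ...) {
  evaluate_hinge_curve(object, x)
}

#' @rdname predict.hinge_curve
#' @param params A [hinge_curve()].
#' @export
evaluate_hinge_curve <- function(params, x) {
  if (!inherits(params, "hinge_curve")) {
    params <- do.call(hinge_curve, params)
  }
  x <- as.numeric(x)
  if (any(!is.finite(x))) {
    abort("`x` must be finite.", class = "hingefit_invalid_parameter")
  }
  # integrate the slope function from anchor_x to x; knots partition the line
  knots <- params$hinges
  slopes <- params$slopes
  value_at <- function(xi) {
    # signed sum of slope * overlap of [anchor_x, xi] with each segment
    lo <- min(params$anchor_x, xi)
    hi <- max(params$anchor_x, xi)
    bounds <- c(-Inf, knots, Inf)
    total <- 0
    for (s in seq_along(slopes)) {
      seg_lo <- max(lo, bounds[s])
      seg_hi <- min(hi, bounds[s + 1L])
      if (seg_hi > seg_lo) total <- total + slopes[s] * (seg_hi - seg_lo)
    }
    params$anchor_y + sign(xi - params$anchor_x) * total
  }
  vapply(x, value_at, numeric(1))
}

#' @export
print.hinge_curve <- function(x, ...) {
  cat("<hinge_curve>\n")
  if (length(x$hinges) == 0) {
    cat("  single segment, slope", x$slopes, "\n")
  } else {
    cat("  hinges (ng/mL):", paste(x$hinges, collapse = ", "), "\n")
    cat("  segment slopes:", paste(signif(x$slopes, 4), collapse = ", "), "\n")
  }
  cat("  anchor: (", x$anchor_x, ", ", x$anchor_y, ")\n", sep = "")
  invisible(x)
}
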