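#' Plot methods
#'
#' Each result type has an `autoplot()` method returning a ggplot:
#' scatter plus smooth for LOWESS, scatter plus fitted hinge line with
#' dashed hinge markers for MARS, the two regression segments with their
#' intersection for the piecewise result, and step curves for the
#' survival objects.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hingefit-autoplot
NULL

#' @rdname hingefit-autoplot
#' @export
autoplot.smooth_curve <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = tidy(object),
                       ggplot2::aes(x = .data$grid_x, y = .data$fitted_y),
                       linewidth = 1, colour = "#2166ac") +
    ggplot2::labs(x = paste0(object$x_label, " (ng/mL)"), y = object$y_label,
                  title = sprintf("LOWESS, bandwidth %.2f", object$bandwidth)) +
    ggplot2::theme_minimal()
}

#' @rdname hingefit-autoplot
#' @export
autoplot.mars_model <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = 400))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = grid, linewidth = 1, colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$hinges, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = paste0(object$x_label, " (ng/mL)"), y = object$y_label,
                  title = sprintf("MARS fit: hinges at %s, R^2 = %.2f",
                                  paste(round(object$hinges, 1),
                                        collapse = ", "),
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname hingefit-autoplot
#' @export
autoplot.piecewise_result <- function(object, ...) {
  seg <- function(fit) {
    tibble::tibble(x = fit$x_range,
                   y = fit$intercept + fit$slope * fit$x_range)
  }
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = seg(object$lower_fit),
                       colour = "#1b7837", linewidth = 1) +
    ggplot2::geom_line(data = seg(object$upper_fit),
                       colour = "#762a83", linewidth = 1) +
    ggplot2::labs(x = paste0(object$x_label, " (ng/mL)"), y = object$y_label,
                  title = sprintf("Piecewise regression, cut %.4g", object$cut)) +
    ggplot2::theme_minimal()
  if (isTRUE(object$intersection_reliable)) {
    p <- p + ggplot2::annotate("point", x = object$intersection_x,
                               y = object$intersection_y, size = 3,
                               shape = 21, fill = "orange")
  }
  p
}

#' @rdname hingefit-autoplot
#' @export
autoplot.hazard_curve <- function(object, ...) {
  curve <- dplyr::bind_rows(
    tibble::tibble(time = 0, cumulative_hazard = 0),
    object$curve[, c("time", "cumulative_hazard")])
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time,
                                      y = .data$cumulative_hazard)) +
    ggplot2::geom_step(linewidth = 1) +
    ggplot2::labs(x = "years", y = "cumulative hazard",
                  title = "Nelson-Aalen cumulative hazard") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves by arm within each stratum
#'
#' @param x A `stratified_survival`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_stratified_rfs <- function(x, ...) {
  stopifnot(inherits(x, "stratified_survival"))
  df <- x$data
  pieces <- purrr::map_dfr(sort(unique(df$.stratum)), function(s) {
    sub <- df[df$.stratum == s, ]
    purrr::map_dfr(c(0, 1), function(a) {
      asub <- sub[sub$.arm_treated == a, ]
      if (nrow(asub) == 0 || sum(asub$event) == 0) return(NULL)
      sf <- survival::survfit(survival::Surv(asub$time_years, asub$event) ~ 1)
      tibble::tibble(stratum = stratum_labels(x$thresholds)[s],
                     arm = if (a == 1) "vitamin D" else "placebo",
                     time = c(0, sf$time), surv = c(1, sf$surv))
    })
  })
  ggplot2::ggplot(pieces, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$arm)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "relapse-free survival") +
    ggplot2::theme_minimal()
}
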