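#' @title Univariate MARS engine
#' @description Internal helpers shared by [forward_pass()],
#'   [backward_prune()] and [fit_mars()].
#' @name mars-engine
#' @keywords internal
NULL

# design matrix for a set of signed hinge terms; terms is a data frame with
# columns `direction` ("+"/"-") and `knot`
hinge_basis_matrix <- function(x, terms) {
  if (is.null(terms) || nrow(terms) == 0) {
    return(matrix(numeric(0), nrow = length(x), ncol = 0))
  }
  cols <- lapply(seq_len(nrow(terms)), function(j) {
    if (terms$direction[j] == "+") pmax(x - terms$knot[j], 0)
    else pmax(terms$knot[j] - x, 0)
  })
  do.call(cbind, cols)
}

# least-squares refit of intercept + hinge terms; aliased columns (the pair
# basis is rank-deficient beyond one knot) are dropped, yielding the
# canonical full-rank representation
refit_terms <- function(x, y, terms) {
  X <- cbind(`(Intercept)` = 1, hinge_basis_matrix(x, terms))
  fit <- stats::lm.fit(X, y)
  keep <- !is.na(fit$coefficients)
  retained <- terms[keep[-1], , drop = FALSE]
  coefs <- fit$coefficients[keep]
  rss <- sum(fit$residuals^2)
  list(terms = retained, intercept = unname(coefs[1]),
       coefficients = unname(coefs[-1]), rss = rss)
}

predict_terms <- function(x, model) {
  B <- hinge_basis_matrix(x, model$terms)
  coefs <- model$coefficients %||% model$terms$coefficient
  drop(model$intercept + if (ncol(B) > 0) B %*% coefs else 0)
}

#' MARS forward pass: greedy hinge-pair selection
#'
#' Starting from an intercept-only model, greedily adds mirrored hinge
#' pairs `max(0, x - t)`, `max(0, t - x)` at the candidate knot giving the
#' largest drop in residual sum of squares, refitting all coefficients by
#' least squares at each step.  Candidate knots are all distinct observed
#' x values (optionally thinned to quantiles for large inputs).  Because
#' `max(0, t - x) = max(0, x - t) - x + t`, the pair basis is
#' rank-deficient once more than one knot is present; aliased columns are
#' dropped at refit, so each step after the first effectively adds one
#' degree of freedom.  The scan exploits this: after the first pair the
#' model space is `span{1, x, max(0, x - t_j)}` and each candidate is
#' scored by projecting its upward hinge column onto the orthogonal
#' complement of the current fit.
#'
#' Ties in residual sum of squares are broken toward the smallest knot;
#' the pass stops at `max_terms` retained terms or when the best relative
#' improvement falls below `tol`.
#'
#' @param x,y Numeric vectors (same length, >= 10 points).
#' @param max_terms Maximum number of retained hinge terms (>= 2).
#' @param tol Relative RSS-improvement stopping tolerance (fraction of the
#'   total sum of squares).
#' @param minspan Minimum number of observations between candidate knots;
#'   `NULL` (default) uses Friedman's formula
#'   `-log2(-log(1 - alpha) / n) / 2.5` with `alpha = 0.05`, guarding the
#'   forward pass against runs of correlated noise; 0 admits every
#'   distinct observed x value.
#' @param endspan Number of observations excluded at each end of the
#'   ordered sample before knots are admitted; `NULL` (default) uses
#'   Friedman's `3 - log2(alpha)` with `alpha = 0.05`; 0 disables.
#' @param thin_to If not `NULL`, additionally thin candidate knots to this
#'   many quantiles of x.
#' @return A `mars_forward` object: the accepted mirrored pairs in order
#'   (`$pairs`), the retained canonical terms (`$terms`), the fitted
#'   coefficients, and the RSS trace (`$rss_trace`, element 1 =
#'   intercept-only).
#' @export
forward_pass <- function(x, y, max_terms = 6, tol = 1e-8, minspan = NULL,
                         endspan = NULL, thin_to = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10) {
    abort("forward_pass needs at least 10 observations.",
          class = "hingefit_degenerate_input")
  }
  if (max_terms < 2) {
    abort("`max_terms` must be at least 2 (one mirrored pair).",
          class = "hingefit_invalid_parameter")
  }
  if (diff(range(x)) == 0) {
    abort("Constant x: singular design.", class = "hingefit_degenerate_input")
  }

  if (is.null(minspan)) {
    minspan <- max(1L, floor(-log2(-log(1 - 0.05) / n) / 2.5))
  }
  if (is.null(endspan)) endspan <- max(0L, floor(3 - log2(0.05)))
  xs <- sort(x)
  if (endspan > 0 && n > 2 * endspan + 2) {
    xs <- xs[(endspan + 1L):(n - endspan)]
  }
  if (minspan > 1 && length(xs) > minspan) {
    xs <- xs[seq(1L, length(xs), by = minspan)]
  }
  cand <- sort(unique(xs))
  if (!is.null(thin_to) && length(cand) > thin_to) {
    cand <- unique(quantile(cand, probs = ppoints(thin_to), type = 1))
  }
  cand <- cand[cand < max(x)]   # a hinge at max(x) has an all-zero column
  if (length(cand) == 0) cand <- sort(unique(x))[1]
  A <- outer(x, cand, function(xx, t) pmax(xx - t, 0))

  ybar <- mean(y)
  tss <- sum((y - ybar)^2)
  rss_trace <- tss
  if (tss <= 0) {  # constant response: no term can improve
    return(new_mars_forward(pairs = empty_terms(), x = x, y = y,
                            rss_trace = rss_trace))
  }

  # orthonormal basis of the model space; starts at {1, x} because the
  # first pair brings the linear term in with it
  q1 <- rep(1 / sqrt(n), n)
  xc <- x - mean(x)
  q2 <- xc / sqrt(sum(xc^2))
  Q <- cbind(q1, q2)
  r <- y - ybar
  r <- r - q2 * sum(q2 * r)
  rss_linear <- sum(r^2)   # RSS of {1, x}; only reached once a pair is in

  pairs <- empty_terms()
  used <- logical(length(cand))
  n_retained <- 0L

  while (n_retained < max_terms) {
    W <- A - Q %*% crossprod(Q, A)
    den <- colSums(W^2)
    num <- drop(crossprod(W, r))^2
    valid <- !used & den > 1e-9 * max(den, .Machine$double.eps)
    if (!any(valid)) break
    gain <- ifelse(valid, num / den, -Inf)
    # improvement over the *current model* RSS; the first pair also banks
    # the linear component
    step_gain <- gain + if (n_retained == 0L) tail(rss_trace, 1) - rss_linear else 0
    best <- max(step_gain)
    if (best < tol * tss) break
    tie <- which(step_gain >= best - 1e-9 * tss & valid)
    j <- tie[which.min(cand[tie])]

    new_rss <- tail(rss_trace, 1) - step_gain[j]
    pairs <- rbind(pairs,
                   data.frame(direction = c("+", "-"), knot = cand[j]))
    used[j] <- TRUE
    w <- W[, j] / sqrt(den[j])
    Q <- cbind(Q, w)
    r <- r - w * sum(w * r)
    rss_trace <- c(rss_trace, max(sum(r^2), 0))
    n_retained <- n_retained + if (n_retained == 0L) 2L else 1L
  }

  new_mars_forward(pairs = pairs, x = x, y = y, rss_trace = rss_trace)
}

empty_terms <- function() data.frame(direction = character(), knot = numeric())

new_mars_forward <- function(pairs, x, y, rss_trace) {
  fit <- refit_terms(x, y, pairs)
  structure(list(pairs = pairs, terms = fit$terms,
                 intercept = fit$intercept, coefficients = fit$coefficients,
                 rss = fit$rss, rss_trace = rss_trace),
            class = "mars_forward")
}

#' @export
print.mars_forward <- function(x, ...) {
  cat("<mars_forward>", nrow(x$terms), "retained hinge terms at knots",
      paste(sort(unique(x$terms$knot)), collapse = ", "), "\n")
  invisible(x)
}

#' Generalized cross-validation score
#'
#' `rss / (n * (1 - C/n)^2)` with effective parameter count
#' `C = n_terms + 1 + penalty_per_knot * n_knots` (the `+ 1` is the
#' intercept).  Inadmissible models (`C >= n`) score `+Inf` rather than
#' raising an error.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param n_terms Number of hinge terms (excluding the intercept).
#' @param penalty_per_knot Smoothing penalty per distinct knot; default 2,
#'   the additive-model convention.
#' @param n_knots Number of distinct knots; defaults to `n_terms`.
#' @return Numeric score (possibly `Inf`).
#' @export
gcv_score <- function(rss, n, n_terms, penalty_per_knot = 2,
                      n_knots = n_terms) {
  C <- n_terms + 1 + penalty_per_knot * n_knots
  if (C >= n) return(Inf)
  rss / (n * (1 - C / n)^2)
}

#' MARS backward pass: term-by-term pruning
#'
#' From the forward-pass model, repeatedly deletes the hinge term whose
#' removal least increases the residual sum of squares, producing one
#' candidate model per size from the full model down to intercept-only,
#' each scored by [gcv_score()].
#'
#' @param terms A `mars_forward` object or a data frame of hinge terms
#'   (`direction`, `knot`).
#' @param x,y The training data.
#' @param penalty_per_knot Passed to [gcv_score()].
#' @return A list of model entries (size descending to 0), each with
#'   `terms`, `intercept`, `coefficients`, `rss`, `size`, `gcv`.
#' @export
backward_prune <- function(terms, x, y, penalty_per_knot = 2) {
  if (inherits(terms, "mars_forward")) terms <- terms$terms
  n <- length(x)
  current <- refit_terms(x, y, terms)
  entry <- function(fit) {
    size <- nrow(fit$terms)
    list(terms = fit$terms, intercept = fit$intercept,
         coefficients = fit$coefficients, rss = fit$rss, size = size,
         gcv = gcv_score(fit$rss, n, size, penalty_per_knot,
                         n_knots = length(unique(fit$terms$knot))))
  }
  sequence <- list(entry(current))
  while (nrow(current$terms) > 0) {
    m <- nrow(current$terms)
    fits <- lapply(seq_len(m), function(j) {
      refit_terms(x, y, current$terms[-j, , drop = FALSE])
    })
    rss <- vapply(fits, `[[`, numeric(1), "rss")
    current <- fits[[which.min(rss)]]
    sequence <- c(sequence, list(entry(current)))
  }
  sequence
}

#' Fit a univariate MARS model with repeated k-fold model-size selection
#'
#' Runs the forward and backward passes on each of `k_folds` training
#' splits, `repetitions` times, recording the held-out residual sum of
#' squares of every model size in the pruned sequence; averages the
#' validation RSS per size across all folds and repetitions; selects the
#' size with the smallest mean validation RSS (ties broken toward the
#' smaller model); and refits that size on the full data.
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of predictor and response.
#' @param k_folds Number of cross-validation folds (default 10).
#' @param repetitions Number of times the fold assignment is redrawn
#'   (default 100).
#' @param max_terms Forward-pass term budget.
#' @param penalty_per_knot GCV penalty used inside pruning.
#' @param seed RNG seed governing the fold assignments.
#' @param tol Forward-pass stopping tolerance.
#' @param minspan,endspan Candidate-knot spacing controls, see
#'   [forward_pass()].
#' @return A `mars_model` with the fitted terms, training R-squared,
#'   hinge locations, per-segment slopes, and the cross-validation table
#'   (`$cv`: `candidate_sizes`, `mean_cv_rss`, `selected_size`).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 3)
#' m <- fit_mars(cohort, "x25ohd_y1", "pth_y1", repetitions = 5, seed = 1)
#' m$hinges
#' @export
fit_mars <- function(data, x = "x25ohd_y1", y = "calcium_y1",
                     k_folds = 10, repetitions = 100, max_terms = 6,
                     penalty_per_knot = 2, seed = 1, tol = 1e-8,
                     minspan = NULL, endspan = NULL) {
  check_xy_columns(data, x, y)
  keep <- complete.cases(data[, c(x, y)])
  xv <- data[[x]][keep]
  yv <- data[[y]][keep]
  n <- length(xv)
  if (n < 2 * k_folds) {
    abort(sprintf(
      "Only %d complete observations for %d-fold validation; lower `k_folds`.",
      n, k_folds), class = "hingefit_invalid_parameter")
  }
  set_master_seed(seed)

  n_sizes <- max_terms + 1L   # sizes 0 .. max_terms
  cv_sum <- numeric(n_sizes)
  cv_count <- 0L
  for (rep_i in seq_len(repetitions)) {
    fold_id <- sample(rep(seq_len(k_folds), length.out = n))
    for (fold in seq_len(k_folds)) {
      tr <- fold_id != fold
      fwd <- forward_pass(xv[tr], yv[tr], max_terms = max_terms, tol = tol,
                          minspan = minspan, endspan = endspan)
      seqs <- backward_prune(fwd, xv[tr], yv[tr], penalty_per_knot)
      val_rss <- rep(NA_real_, n_sizes)
      for (entry in seqs) {
        pred <- predict_terms(xv[!tr], entry)
        val_rss[entry$size + 1L] <- sum((yv[!tr] - pred)^2)
      }
      # sizes above the attained maximum saturate at the largest model
      attained <- which(!is.na(val_rss))
      val_rss[seq_len(n_sizes) > max(attained)] <- val_rss[max(attained)]
      # sizes skipped inside the sequence (first pair adds two terms):
      # carry the nearest smaller model
      for (s in seq_len(n_sizes)) {
        if (is.na(val_rss[s])) val_rss[s] <- val_rss[s - 1L]
      }
      cv_sum <- cv_sum + val_rss
      cv_count <- cv_count + 1L
    }
  }
  mean_cv <- cv_sum / cv_count
  best <- min(mean_cv)
  selected_size <- which(mean_cv <= best * (1 + 1e-10))[1] - 1L

  fwd <- forward_pass(xv, yv, max_terms = max_terms, tol = tol,
                      minspan = minspan, endspan = endspan)
  seqs <- backward_prune(fwd, xv, yv, penalty_per_knot)
  sizes <- vapply(seqs, `[[`, integer(1), "size")
  pick <- if (any(sizes == selected_size)) {
    which(sizes == selected_size)[1]
  } else {
    # selected size not attained on the full data (or skipped): nearest
    # smaller attained size
    which(sizes == max(sizes[sizes <= selected_size]))[1]
  }
  final <- seqs[[pick]]
  tss <- sum((yv - mean(yv))^2)
  r2 <- if (tss > 0) 1 - final$rss / tss else 0

  model <- structure(
    list(intercept = final$intercept,
         terms = tibble::tibble(direction = final$terms$direction,
                                knot = final$terms$knot,
                                coefficient = final$coefficients),
         r_squared = r2,
         cv = list(candidate_sizes = 0:max_terms, mean_cv_rss = mean_cv,
                   selected_size = selected_size,
                   k_folds = k_folds, repetitions = repetitions),
         data = tibble::tibble(x = xv, y = yv),
         x_label = x, y_label = y, seed = seed),
    class = "mars_model")
  model$hinges <- sort(unique(model$terms$knot))
  model$segment_slopes <- segment_slopes(model)
  model
}

# derivative of the fitted piecewise-linear function on each segment
segment_slopes <- function(model) {
  hinges <- sort(unique(model$terms$knot))
  if (length(hinges) == 0) return(0)
  mids <- midpoints_of_segments(hinges, range(model$data$x))
  vapply(mids, function(m) {
    up <- model$terms$direction == "+" & model$terms$knot < m
    dn <- model$terms$direction == "-" & model$terms$knot > m
    sum(model$terms$coefficient[up]) - sum(model$terms$coefficient[dn])
  }, numeric(1))
}

midpoints_of_segments <- function(hinges, xr) {
  bounds <- c(min(xr[1], hinges[1] - 1), hinges, max(xr[2], tail(hinges, 1) + 1))
  (head(bounds, -1) + tail(bounds, -1)) / 2
}

#' @export
predict.mars_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    xv <- object$data$x
  } else if (is.numeric(newdata)) {
    xv <- newdata
  } else {
    xv <- newdata[[object$x_label]]
  }
  predict_terms(xv, object)
}

#' @export
print.mars_model <- function(x, ...) {
  cat("<mars_model> ", x$y_label, " ~ hinges(", x$x_label, ")\n", sep = "")
  if (nrow(x$terms) == 0) {
    cat("  intercept-only model:", signif(x$intercept, 4), "\n")
  } else {
    cat("  hinges (ng/mL):", paste(round(x$hinges, 1), collapse = ", "), "\n")
    cat("  segment slopes:", paste(signif(x$segment_slopes, 3), collapse = ", "), "\n")
  }
  cat(sprintf("  R-squared %.3f | CV-selected size %d (k=%d folds x %d reps)\n",
              x$r_squared, x$cv$selected_size, x$cv$k_folds, x$cv$repetitions))
  invisible(x)
}

#' @export
tidy.mars_model <- function(x, ...) {
  if (nrow(x$terms) == 0) {
    return(tibble::tibble(term = "(Intercept)", direction = NA_character_,
                          knot = NA_real_, estimate = x$intercept))
  }
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", direction = NA_character_,
                   knot = NA_real_, estimate = x$intercept),
    tibble::tibble(
      term = sprintf("h(%s%s%.6g)",
                     ifelse(x$terms$direction == "+", "x-", ""),
                     ifelse(x$terms$direction == "+", "", "-x+"),
                     x$terms$knot),
      direction = x$terms$direction, knot = x$terms$knot,
      estimate = x$terms$coefficient))
}

#' @export
glance.mars_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 n = nrow(x$data),
                 n_terms = nrow(x$terms),
                 n_hinges = length(x$hinges),
                 selected_size = x$cv$selected_size,
                 k_folds = x$cv$k_folds,
                 repetitions = x$cv$repetitions)
}

#' Extract threshold summary from a fitted MARS model
#'
#' Reports the sorted hinge locations and, per segment, the slope, the
#' fitted level (mean of the model predictions over the observed x values
#' inside the segment, exact for a flat segment), and whether the segment
#' qualifies as a plateau (`abs(slope) < slope_epsilon`).
#'
#' @param model A `mars_model`.
#' @param slope_epsilon Plateau classification threshold in biomarker
#'   units per ng/mL; default `0.01 * y-range / x-range` of the training
#'   data.
#' @return A tibble with one row per segment (`x_lo`, `x_hi`, `slope`,
#'   `level`, `is_plateau`); the hinge vector is in `attr(, "hinges")`.
#' @export
extract_thresholds <- function(model, slope_epsilon = NULL) {
  stopifnot(inherits(model, "mars_model"))
  xr <- range(model$data$x)
  if (is.null(slope_epsilon)) {
    yr <- diff(range(model$data$y))
    slope_epsilon <- if (diff(xr) > 0 && yr > 0) 0.01 * yr / diff(xr) else 0.01
  }
  hinges <- model$hinges
  bounds <- c(xr[1], hinges, xr[2])
  if (length(hinges) == 0) {
    out <- tibble::tibble(x_lo = xr[1], x_hi = xr[2], slope = 0,
                          level = model$intercept, prop_data = 1,
                          is_plateau = TRUE)
    attr(out, "hinges") <- numeric(0)
    return(out)
  }
  slopes <- model$segment_slopes
  level <- vapply(seq_along(slopes), function(s) {
    inside <- model$data$x >= bounds[s] & model$data$x <= bounds[s + 1L]
    if (any(inside)) mean(predict_terms(model$data$x[inside], model))
    else predict_terms(mean(bounds[s:(s + 1L)]), model)
  }, numeric(1))
  prop <- vapply(seq_along(slopes), function(s) {
    mean(model$data$x >= bounds[s] & model$data$x <= bounds[s + 1L])
  }, numeric(1))
  out <- tibble::tibble(
    x_lo = head(bounds, -1), x_hi = tail(bounds, -1),
    slope = slopes, level = level, prop_data = prop,
    is_plateau = abs(slopes) < slope_epsilon)
  attr(out, "hinges") <- hinges
  attr(out, "slope_epsilon") <- slope_epsilon
  out
}

#' Locate the plateau segment and the primary threshold
#'
#' The plateau is the flattest fitted segment (smallest absolute slope)
#' among segments holding at least `min_prop` of the observations —
#' sparse edge segments cannot masquerade as the plateau.  The primary
#' hinge is the plateau's left boundary: the 25(OH)D level above which
#' the biomarker stays (near) constant.  For the calcium response this is
#' the first hinge; for PTH it is the single hinge.
#'
#' @param model A `mars_model`.
#' @param min_prop Minimum fraction of observations a segment needs to be
#'   eligible as the plateau (default 0.1).
#' @return `plateau_segment()`: the one-row segment tibble;
#'   `primary_hinge()`: the hinge location (ng/mL), or `NA` if the model
#'   has no hinge or the plateau is the leftmost segment.
#' @export
plateau_segment <- function(model, min_prop = 0.1) {
  seg <- extract_thresholds(model)
  eligible <- seg$prop_data >= min_prop
  if (!any(eligible)) eligible <- rep(TRUE, nrow(seg))
  seg[eligible, ][which.min(abs(seg$slope[eligible])), ]
}

#' @rdname plateau_segment
#' @export
primary_hinge <- function(model, min_prop = 0.1) {
  if (length(model$hinges) == 0) return(NA_real_)
  plat <- plateau_segment(model, min_prop)
  if (plat$x_lo %in% model$hinges) plat$x_lo else NA_real_
}

#' @rdname plateau_segment
#' @details `pre_hinge_slope()` summarizes how fast the biomarker changes
#'   below the primary hinge as the mean model derivative over the
#'   observed x values below it.  For a model with a single segment below
#'   the hinge this equals that segment's slope; with additional
#'   sub-hinge structure it is the observation-weighted average rate, the
#'   natural single-number analogue of a one-hinge fit's slope.
#' @export
pre_hinge_slope <- function(model, min_prop = 0.1) {
  h <- primary_hinge(model, min_prop)
  if (is.na(h)) return(NA_real_)
  seg <- extract_thresholds(model)
  xs <- model$data$x[model$data$x < h]
  if (length(xs) == 0) return(NA_real_)
  j <- pmax(findInterval(xs, seg$x_lo), 1L)
  mean(seg$slope[j])
}

#' Serialize a MARS model to a human-readable JSON-like list
#'
#' @param model A `mars_model`.
#' @return A plain list (suitable for `jsonlite::toJSON` or YAML).
#' @export
mars_model_summary <- function(model) {
  list(intercept = model$intercept,
       terms = lapply(seq_len(nrow(model$terms)), function(j) {
         list(direction = model$terms$direction[j],
              knot = model$terms$knot[j],
              coefficient = model$terms$coefficient[j])
       }),
       r_squared = model$r_squared,
       hinges = model$hinges,
       segment_slopes = model$segment_slopes,
       cv = model$cv)
}
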