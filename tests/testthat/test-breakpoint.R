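test_that("grid search finds the break in noiseless two-segment data", {
  set.seed(1)
  x <- sort(runif(300, 4, 60))
  y <- make_piecewise_xy(x, knots = 20, slopes = c(0.5, 0), y0 = 2)
  d <- tibble::tibble(x = x, y = y)
  gs <- grid_search_cut(d, "x", "y", lo = 15, hi = 40, step = 1)
  prof <- gs$r2_profile
  expect_equal(nrow(prof), 26)          # 15..40 in steps of 1
  # every cut at or below the break sees a single straight line
  expect_true(all(prof$r_squared[prof$cut <= 20] > 1 - 1e-12))
  expect_true(all(prof$r_squared[prof$cut >= 22] < 1 - 1e-9))
  # tie rule: largest tied cut
  expect_equal(gs$cut, 20)
})

test_that("reported R-squared matches the direct 1 - RSS/TSS formula", {
  set.seed(5)
  x <- runif(200, 4, 60)
  y <- 8 + 0.05 * pmin(x, 23) + rnorm(200, 0, 0.4)
  d <- tibble::tibble(x = x, y = y)
  gs <- grid_search_cut(d, "x", "y")
  for (i in seq(1, 26, by = 5)) {
    cut <- gs$r2_profile$cut[i]
    sub <- d[d$x <= cut, ]
    fit <- lm(y ~ x, data = sub)
    r2 <- 1 - sum(resid(fit)^2) / sum((sub$y - mean(sub$y))^2)
    expect_equal(gs$r2_profile$r_squared[i], r2, tolerance = 1e-10)
  }
})

test_that("upper-segment inference is exact on lines and calibrated on noise", {
  x <- seq(1, 50, by = 0.5)
  d <- tibble::tibble(x = x, y = 4 + 0.25 * x)
  sf <- fit_upper_segment(d, "x", "y", cut = 20)
  expect_equal(sf$slope, 0.25, tolerance = 1e-12)
  expect_equal(sf$r_squared, 1, tolerance = 1e-12)
  expect_equal(sf$n_points, sum(x > 20))

  # 95% slope CI covers the true zero slope in at least 90% of replicates
  covered <- 0
  for (s in 1:60) {
    set.seed(100 + s)
    dd <- tibble::tibble(x = runif(80, 20, 60), y = 9.3 + rnorm(80, 0, 0.4))
    ci <- fit_upper_segment(dd, "x", "y", cut = 20)$slope_ci95
    covered <- covered + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(covered / 60, 0.9)

  expect_error(fit_upper_segment(d, "x", "y", cut = 49.9),
               class = "hingefit_degenerate_input")
})

test_that("line intersection solves the system and flags parallel limits", {
  l1 <- hingefit:::new_segment_fit(list(slope = 1, intercept = 0,
                                        r_squared = 1, slope_se = 0,
                                        slope_ci95 = c(1, 1), slope_p = 0,
                                        n = 10), c(0, 2))
  l2 <- hingefit:::new_segment_fit(list(slope = -1, intercept = 2,
                                        r_squared = 1, slope_se = 0,
                                        slope_ci95 = c(-1, -1), slope_p = 0,
                                        n = 10), c(0, 2))
  res <- intersect_lines(l1, l2)
  expect_equal(c(res$x, res$y), c(1, 1))
  expect_true(res$reliable)

  l3 <- l1; l3$slope <- 1 + 1e-12
  res2 <- intersect_lines(l1, l3)
  expect_false(res2$reliable)
  expect_true(is.na(res2$x))
})

test_that("piecewise analysis recovers a noiseless hinge exactly", {
  spec <- cohort_spec(calcium_noise_sd = 0, pth_noise_sd = 0,
                      treatment_calcium_shift = 0)
  ch <- simulate_cohort(spec, seed = 41)
  pw <- piecewise_analysis(ch, "x25ohd_y1", "pth_y1", bootstrap_reps = 0)
  # exact geometry: lower line has the pre-hinge slope, upper line is the
  # plateau, so they cross exactly at the generating hinge
  expect_equal(pw$intersection_x, 29, tolerance = 1e-6)
  expect_equal(pw$intersection_y, 20.1, tolerance = 1e-6)
  expect_true(pw$intersection_reliable)

  # the intersection lies on both fitted lines
  on_lower <- pw$lower_fit$intercept + pw$lower_fit$slope * pw$intersection_x
  on_upper <- pw$upper_fit$intercept + pw$upper_fit$slope * pw$intersection_x
  expect_equal(pw$intersection_y, on_lower, tolerance = 1e-9)
  expect_equal(pw$intersection_y, on_upper, tolerance = 1e-9)
})

test_that("intersections always lie on both segments, noisy or not", {
  for (s in 1:5) {
    ch <- simulate_cohort(cohort_spec(), seed = 50 + s)
    pw <- piecewise_analysis(ch, "x25ohd_y1", "calcium_y1", bootstrap_reps = 0)
    if (isTRUE(pw$intersection_reliable)) {
      expect_equal(pw$intersection_y,
                   pw$lower_fit$intercept + pw$lower_fit$slope * pw$intersection_x,
                   tolerance = 1e-9)
      expect_equal(pw$intersection_y,
                   pw$upper_fit$intercept + pw$upper_fit$slope * pw$intersection_x,
                   tolerance = 1e-9)
    }
  }
})

test_that("a single straight line is flagged: no interior threshold", {
  set.seed(9)
  x <- runif(300, 4, 60)
  d <- tibble::tibble(x = x, y = 1 + 0.5 * x + rnorm(300, 0, 0.01))
  pw <- piecewise_analysis(d, "x", "y", bootstrap_reps = 0,
                           second_window = NULL)
  # near-identical slopes push the intersection outside the data or to
  # a parallel flag; either way it must not be reported as reliable
  expect_false(isTRUE(pw$intersection_reliable) &&
                 pw$intersection_x >= min(x) && pw$intersection_x <= max(x) &&
                 abs(pw$lower_fit$slope - pw$upper_fit$slope) > 0.05)
})

test_that("slope p-values hold their nominal level at a fixed cut", {
  rejections <- 0
  n_sims <- 200
  for (s in seq_len(n_sims)) {
    set.seed(1000 + s)
    x <- runif(120, 4, 60)
    y <- rnorm(120)
    d <- tibble::tibble(x = x, y = y)
    sf <- hingefit:::fit_lower_segment(d, "x", "y", cut = 25)
    rejections <- rejections + (sf$slope_p < 0.05)
  }
  expect_lt(abs(rejections / n_sims - 0.05), 0.045)
})

test_that("bootstrap interval brackets the intersection ordinate", {
  ch <- simulate_cohort(cohort_spec(), seed = 61)
  pw <- piecewise_analysis(ch, "x25ohd_y1", "pth_y1", bootstrap_reps = 200,
                           seed = 3)
  expect_true(all(is.finite(pw$intersection_y_ci95)))
  expect_lt(pw$intersection_y_ci95[1], pw$intersection_y_ci95[2])
  expect_gt(pw$intersection_y, pw$intersection_y_ci95[1] - 5)
  expect_lt(pw$intersection_y, pw$intersection_y_ci95[2] + 5)

  # determinism of the seeded bootstrap
  pw2 <- piecewise_analysis(ch, "x25ohd_y1", "pth_y1", bootstrap_reps = 200,
                            seed = 3)
  expect_identical(pw$intersection_y_ci95, pw2$intersection_y_ci95)
})
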