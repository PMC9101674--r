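test_that("forward pass recovers realizable hinge functions exactly", {
  x <- c(0:20, 10.5, 3.3)          # knot 10 among the observations
  y <- 2 * pmax(x - 10, 0) + 1
  fwd <- forward_pass(x, y, max_terms = 4, minspan = 0, endspan = 0)
  expect_equal(fwd$pairs$knot[1], 10)
  expect_lt(fwd$rss, 1e-12)

  # pure line: the first pair (any knot) already fits perfectly
  y2 <- 3 * x
  fwd2 <- forward_pass(x, y2, max_terms = 4, minspan = 0, endspan = 0)
  expect_lt(fwd2$rss, 1e-12)
  expect_equal(unname(hingefit:::predict_terms(x, fwd2)), y2, tolerance = 1e-9)

  # constant response: nothing to add
  fwd3 <- forward_pass(x, rep(5, length(x)), max_terms = 4)
  expect_equal(nrow(fwd3$pairs), 0)

  expect_error(forward_pass(rep(1, 20), rnorm(20)),
               class = "hingefit_degenerate_input")
  expect_error(forward_pass(1:20, rnorm(20), max_terms = 1),
               class = "hingefit_invalid_parameter")
})

test_that("greedy knot scan matches the exhaustive least-squares oracle", {
  for (s in 1:3) {
    set.seed(s)
    x <- round(sort(runif(30, 0, 40)), 1)
    y <- make_piecewise_xy(x, knots = c(12, 25), slopes = c(0.5, -0.3, 0.1)) +
      rnorm(30, 0, 0.3)
    fwd <- forward_pass(x, y, max_terms = 5, minspan = 0, endspan = 0)
    # replay the greedy path: at each step the achieved RSS must equal the
    # brute-force minimum over every candidate knot added to the previous model
    prev <- hingefit:::empty_terms()
    cand <- sort(unique(x)); cand <- cand[cand < max(x)]
    for (step in seq_len(nrow(fwd$pairs) / 2)) {
      oracle <- brute_best_pair_rss(x, y, prev, cand)
      expect_equal(fwd$rss_trace[step + 1], oracle, tolerance = 1e-8)
      prev <- rbind(prev, fwd$pairs[(2 * step - 1):(2 * step), ])
    }
  }
})

test_that("gcv score follows its closed form and admissibility rules", {
  expect_equal(gcv_score(0, 100, 3), 0)
  expect_equal(gcv_score(50, 10, 5, penalty_per_knot = 2, n_knots = 2), Inf)
  scores <- sapply(1:6, function(m) gcv_score(50, 100, m))
  expect_true(all(diff(scores) > 0))
  # closed form at one point: rss / (n (1 - C/n)^2), C = 3 + 1 + 2*2 = 8
  expect_equal(gcv_score(12, 50, 3, 2, 2), 12 / (50 * (1 - 8 / 50)^2))
})

test_that("backward pruning yields a nested sequence with optimal deletions", {
  x <- c(0:25, 7.3, 18.6, 11.1, 2.2)
  y <- make_piecewise_xy(x, knots = c(8, 16), slopes = c(1, -0.5, 0.2))
  fwd <- forward_pass(x, y, max_terms = 5, minspan = 0, endspan = 0)
  seqs <- backward_prune(fwd, x, y)
  sizes <- vapply(seqs, `[[`, integer(1), "size")
  expect_equal(sizes, seq(max(sizes), 0))
  # noiseless realizable data: the true-size model in the sequence is exact
  expect_lt(min(vapply(seqs, `[[`, numeric(1), "rss")[sizes >= 3]), 1e-16)

  # each deletion is the best single deletion from its parent (oracle check)
  for (k in seq_len(length(seqs) - 1)) {
    parent <- seqs[[k]]
    m <- nrow(parent$terms)
    child_rss <- vapply(seq_len(m), function(j) {
      tt <- parent$terms[-j, , drop = FALSE]
      B <- cbind(1, hingefit:::hinge_basis_matrix(x, tt))
      sum(stats::lm.fit(B, y)$residuals^2)
    }, numeric(1))
    expect_equal(seqs[[k + 1]]$rss, min(child_rss), tolerance = 1e-9)
  }

  # single-term model prunes to (term, intercept-only)
  one <- data.frame(direction = "+", knot = 8)
  expect_length(backward_prune(one, x, y), 2)
})

test_that("fitted MARS models are continuous piecewise-linear functions", {
  ch <- simulate_cohort(cohort_spec(), seed = 31)
  m <- fit_mars(ch, "x25ohd_y1", "pth_y1", repetitions = 3, seed = 4)
  grid <- seq(min(ch$x25ohd_y1), max(ch$x25ohd_y1), length.out = 2000)
  fy <- predict(m, grid)
  d1 <- diff(fy) / diff(grid)
  # slope changes only near hinges
  changes <- which(abs(diff(d1)) > 1e-8)
  change_x <- grid[changes + 1]
  for (cx in change_x) expect_true(min(abs(cx - m$hinges)) < diff(grid[1:2]) * 2)
  # continuity: no jumps anywhere
  expect_lt(max(abs(diff(fy))), max(abs(d1)) * diff(grid[1:2]) * 1.5 + 1e-9)
  # training R^2 consistent with residuals
  expect_equal(m$r_squared,
               1 - sum((ch$pth_y1 - predict(m))^2) /
                 sum((ch$pth_y1 - mean(ch$pth_y1))^2),
               tolerance = 1e-10)
})

test_that("model-size selection recovers noiseless hinge data exactly", {
  set.seed(12)
  x <- sort(c(seq(2, 50, length.out = 58), 20))   # knot 20 observed
  y <- make_piecewise_xy(x, knots = 20, slopes = c(-0.8, 0), y0 = 40)
  d <- tibble::tibble(x = x, y = y)
  m <- fit_mars(d, "x", "y", k_folds = 5, repetitions = 3, seed = 2,
                minspan = 0, endspan = 0)
  expect_equal(m$hinges, 20)
  expect_equal(m$segment_slopes, c(-0.8, 0), tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(primary_hinge(m), 20)

  # determinism under a fixed seed
  m2 <- fit_mars(d, "x", "y", k_folds = 5, repetitions = 3, seed = 2,
                 minspan = 0, endspan = 0)
  expect_equal(m$terms, m2$terms)
  expect_equal(m$cv$mean_cv_rss, m2$cv$mean_cv_rss)

  expect_error(fit_mars(d[1:15, ], "x", "y", k_folds = 10),
               regexp = "k_folds")
})

test_that("threshold extraction reports hinges, slopes and plateaus", {
  # hand-built model: 9.3 plateau between 17 and 47, rise 0.04 below, 0.006 above
  ch <- simulate_cohort(cohort_spec(), seed = 33)
  m <- fit_mars(ch, "x25ohd_y1", "calcium_y1", repetitions = 2, seed = 1)
  # slope below 17 is +0.04, so the downward hinge max(0, 17 - x) carries
  # coefficient -0.04 (its derivative is -coef below the knot)
  m$terms <- tibble::tibble(direction = c("-", "+", "+"),
                            knot = c(17, 17, 47),
                            coefficient = c(-0.04, 0, 0.006))
  m$intercept <- 9.3
  m$hinges <- c(17, 47)
  m$segment_slopes <- hingefit:::segment_slopes(m)
  expect_equal(m$segment_slopes, c(0.04, 0, 0.006))

  seg <- extract_thresholds(m)
  expect_equal(attr(seg, "hinges"), c(17, 47))
  expect_equal(nrow(seg), 3)
  expect_true(seg$is_plateau[2])
  expect_false(seg$is_plateau[1])
  expect_equal(seg$level[2], 9.3, tolerance = 1e-9)
  expect_equal(plateau_segment(m)$x_lo, 17)
  expect_equal(primary_hinge(m), 17)

  # intercept-only model has no hinges
  m$terms <- m$terms[0, ]
  m$hinges <- numeric(0)
  seg0 <- extract_thresholds(m)
  expect_length(attr(seg0, "hinges"), 0)
  expect_true(is.na(primary_hinge(m)))
})

test_that("tidy, glance and serialization expose the fitted structure", {
  ch <- simulate_cohort(cohort_spec(), seed = 35)
  m <- fit_mars(ch, "x25ohd_y1", "pth_y1", repetitions = 2, seed = 6)
  td <- tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), nrow(m$terms) + 1)
  gl <- glance(m)
  expect_equal(gl$n, 357)
  expect_equal(gl$selected_size, m$cv$selected_size)
  js <- mars_model_summary(m)
  expect_equal(js$intercept, m$intercept)
  expect_length(js$terms, nrow(m$terms))
})
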