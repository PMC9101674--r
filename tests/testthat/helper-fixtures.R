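# shared fixture builders; everything is generated in code

# noiseless continuous piecewise-linear data built directly from segment
# arithmetic (independent of hinge_curve, so it can serve as its oracle);
# integrates the slope function from the anchor (x0, y0) in either direction
make_piecewise_xy <- function(x, knots, slopes, y0 = 0, x0 = min(x)) {
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- min(x0, x[i]); hi <- max(x0, x[i])
    grid <- sort(unique(c(lo, knots[knots > lo & knots < hi], hi)))
    acc <- 0
    if (hi > lo) {
      for (j in seq_len(length(grid) - 1)) {
        seg <- sum(knots < (grid[j] + grid[j + 1]) / 2) + 1
        acc <- acc + slopes[seg] * (grid[j + 1] - grid[j])
      }
    }
    y[i] <- y0 + sign(x[i] - x0) * acc
  }
  y
}

# brute-force single-step knot scan: minimum RSS over all candidate knots
# when one mirrored pair is added to an existing term set
brute_best_pair_rss <- function(x, y, terms, cand) {
  rss <- vapply(cand, function(t) {
    extra <- data.frame(direction = c("+", "-"), knot = t)
    all_terms <- rbind(terms, extra)
    B <- cbind(1, sapply(seq_len(nrow(all_terms)), function(j) {
      if (all_terms$direction[j] == "+") pmax(x - all_terms$knot[j], 0)
      else pmax(all_terms$knot[j] - x, 0)
    }))
    sum(stats::lm.fit(B, y)$residuals^2)
  }, numeric(1))
  min(rss)
}

# exponential two-arm survival fixture
make_exp_arms <- function(n_per_arm, lambda0, hr, horizon = Inf) {
  t0 <- rexp(n_per_arm, lambda0)
  t1 <- rexp(n_per_arm, lambda0 * hr)
  tibble::tibble(
    time_years = pmax(pmin(c(t0, t1), horizon), 1e-9),
    event = as.integer(c(t0, t1) <= horizon),
    arm_treated = rep(c(0, 1), each = n_per_arm))
}

# independent Cox partial log-likelihood (no ties) for the grid oracle
partial_loglik <- function(beta, time, event, z) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
    }
  }
  ll
}
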