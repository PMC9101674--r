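test_that("Nelson-Aalen estimate matches hand computation", {
  d <- tibble::tibble(time_years = c(1, 2, 3), event = c(1L, 1L, 1L))
  na <- nelson_aalen(d)
  expect_equal(tidy(na)$cumulative_hazard,
               c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1))
  expect_equal(tidy(na)$n_risk, c(3, 2, 1))

  censored <- tibble::tibble(time_years = 1:4, event = rep(0L, 4))
  expect_warning(na0 <- nelson_aalen(censored), "No events")
  expect_equal(nrow(tidy(na0)), 0)

  # large exponential sample: H(t) ~ lambda * t
  set.seed(2)
  lam <- 0.3
  big <- tibble::tibble(time_years = rexp(20000, lam), event = 1L)
  curve <- tidy(nelson_aalen(big))
  at2 <- max(curve$cumulative_hazard[curve$time <= 2])
  expect_equal(at2, lam * 2, tolerance = 0.05)
})

test_that("Kaplan-Meier RFS matches closed forms and edge cases", {
  none <- tibble::tibble(time_years = runif(10, 6, 8), event = rep(0L, 10))
  expect_equal(rfs_at(none, 5), 1)

  single <- tibble::tibble(time_years = 2, event = 1L)
  expect_warning(s <- rfs_at(single, 5), "beyond last observed")
  expect_equal(s, 0)

  set.seed(3)
  lam <- -log(0.71) / 5
  d <- tibble::tibble(time_years = rexp(10000, lam), event = 1L)
  expect_equal(rfs_at(d, 5), 0.71, tolerance = 0.02 / 0.71)

  # agreement with exp(-H) under light censoring
  set.seed(4)
  t_raw <- rexp(5000, lam)
  d2 <- tibble::tibble(time_years = pmin(t_raw, 5.5),
                       event = as.integer(t_raw <= 5.5))
  H <- tidy(nelson_aalen(d2))
  H5 <- max(H$cumulative_hazard[H$time <= 5])
  expect_equal(rfs_at(d2, 5), exp(-H5), tolerance = 0.02)
})

test_that("Cox fits match the exhaustive partial-likelihood oracle", {
  # tiny no-ties dataset: grid search over the coefficient
  set.seed(7)
  d <- tibble::tibble(time_years = c(1.1, 1.9, 2.3, 3.2, 4.1, 4.9, 5.6, 6.4),
                      event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L),
                      z = c(1, 0, 1, 0, 1, 0, 0, 1))
  fit <- cox_fit(d, covariates = "z")
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, partial_loglik, numeric(1),
               time = d$time_years, event = d$event, z = d$z)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)], tolerance = 5e-3)

  # two groups with identical event patterns: HR exactly 1
  base <- tibble::tibble(time_years = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 1L))
  dd <- dplyr::bind_rows(dplyr::mutate(base, g = 0), dplyr::mutate(base, g = 1))
  expect_equal(unname(cox_fit(dd, "g")$hr), 1, tolerance = 1e-8)

  # consistency: true HR 0.5 at n = 4000
  set.seed(8)
  big <- make_exp_arms(2000, lambda0 = 0.2, hr = 0.5, horizon = 8)
  bigfit <- cox_fit(big, "arm_treated")
  expect_equal(unname(bigfit$hr), 0.5, tolerance = 0.05 / 0.5)
  # exp/log consistency and CI symmetry on the log scale
  expect_equal(log(unname(bigfit$ci95[, "upper"] / bigfit$hr)),
               log(unname(bigfit$hr / bigfit$ci95[, "lower"])),
               tolerance = 1e-9)

  expect_error(cox_fit(none <- tibble::tibble(time_years = 1:5,
                                              event = rep(0L, 5),
                                              g = c(0, 1, 0, 1, 0)), "g"),
               class = "hingefit_degenerate_input")
})

test_that("Wald test is calibrated near its nominal level under the null", {
  n_sims <- 500
  rejections <- 0
  for (s in seq_len(n_sims)) {
    set.seed(2000 + s)
    d <- make_exp_arms(40, lambda0 = 0.25, hr = 1, horizon = 6)
    f <- cox_fit(d, "arm_treated")
    rejections <- rejections + (f$p[1] < 0.05)
  }
  expect_lt(abs(rejections / n_sims - 0.05), 0.02)
})

test_that("interaction model tests effect modification across strata", {
  set.seed(11)
  # protective effect only in the 'low' stratum
  low <- make_exp_arms(400, lambda0 = 0.2, hr = 0.45, horizon = 6)
  high <- make_exp_arms(400, lambda0 = 0.2, hr = 1, horizon = 6)
  d <- dplyr::bind_rows(dplyr::mutate(low, high_group = 0),
                        dplyr::mutate(high, high_group = 1))
  fit <- interaction_model(d, arm = "arm_treated")
  expect_length(fit$coefficients, 3)
  expect_lt(fit$interaction_p, 0.05)
  # interaction covariate is the elementwise product by construction
  mm <- fit$coxph
  X <- stats::model.matrix(mm)
  expect_equal(unname(X[, 3]), unname(X[, 1] * X[, 2]))

  empty_cell <- d[!(d$arm_treated == 1 & d$high_group == 1), ]
  expect_error(interaction_model(empty_cell, arm = "arm_treated"),
               regexp = "cell")
})

test_that("threshold stratification partitions the cohort and reports HRs", {
  ch <- simulate_cohort(cohort_spec(), seed = 71)
  sc <- stratified_comparison(ch, c(17, 29))
  tab <- tidy(sc)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$n), nrow(ch))
  expect_equal(tab$label, c("<=17", "(17, 29)", ">=29"))
  expect_true(all(tab$rfs_placebo >= 0 & tab$rfs_placebo <= 1, na.rm = TRUE))

  # single threshold: two strata plus the interaction fit
  sc2 <- stratified_comparison(ch, 17)
  expect_equal(nrow(tidy(sc2)), 2)
  expect_false(is.null(sc2$interaction))
  expect_true("hr_interaction_model" %in% names(tidy(sc2)))

  expect_error(stratified_comparison(ch, c(29, 17)),
               class = "hingefit_invalid_parameter")
})

test_that("stratified fits recover the generator's treatment effect", {
  # intermediate stratum only, large n: HR near 0.49 and treatment RFS ~ 84%
  set.seed(13)
  p <- survival_params()
  d <- simulate_survival(rep(2L, 6000), rep(c("placebo", "vitamin_d"),
                                            each = 3000), p)
  d$arm <- rep(c("placebo", "vitamin_d"), each = 3000)
  d$x25ohd_baseline <- 22
  d$time_years <- d$time
  fit <- cox_fit(dplyr::mutate(d, arm_treated =
                                 as.numeric(arm == "vitamin_d")),
                 "arm_treated")
  expect_equal(unname(fit$hr), 0.49, tolerance = 0.12 / 0.49)
  trt <- d[d$arm == "vitamin_d", ]
  expect_equal(rfs_at(trt, 5), 0.71^0.49, tolerance = 0.03)
})
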