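test_that("theta matches direct evaluation of the logistic formula", {
  # independent evaluation of the published equation
  eta <- 3.96e-2 * 80 * 2.0 - 7.09e-2 * 80 - 7.09e-2
  expect_equal(eta, 0.5931, tolerance = 1e-12)
  expect_equal(theta(80, 2.0), exp(eta) / (1 + exp(eta)), tolerance = 1e-12)
  expect_equal(theta(80, 2.0), 0.6441, tolerance = 1e-4)

  # viability 0 collapses both viability terms
  eta0 <- -7.09e-2
  for (fdf in c(0.5, 2, 50)) {
    expect_equal(theta(0, fdf), exp(eta0) / (1 + exp(eta0)), tolerance = 1e-12)
  }
  expect_equal(theta(0, 1), 0.4823, tolerance = 1e-4)

  expect_equal(theta(50, 3, model_coefficients(0, 0, 0)), 0.5)

  # numerically stable at extreme linear predictors
  big <- model_coefficients(0, 0, 10)
  expect_equal(theta(100, 8, big), 1, tolerance = 1e-12)
  expect_gt(theta(100, 8, big), 0)

  expect_error(theta(-5, 2), "viability")
  expect_error(theta(50, 0), "fdf")
  expect_error(theta(NA_real_, 2), "finite")
})

test_that("the three-way rule maps theta to labels with abstaining boundaries", {
  expect_equal(classify_theta(0.6441), "engrafter")
  expect_equal(classify_theta(0.30), "nonengrafter")
  expect_equal(classify_theta(0.6363636), "no_prediction")
  expect_equal(classify_theta(0.3535354), "no_prediction")
  expect_equal(classify_theta(0.50), "no_prediction")
  expect_error(classify_theta(1.2), "in \\(0, 1\\)")
})

test_that("classification over a dense (viability, fdf) grid equals direct threshold comparison", {
  grid <- tidyr::expand_grid(
    viability = seq(1, 100, length.out = 200),
    fdf = seq(1, 8, length.out = 200)
  )
  scored <- predict_engraftment(grid)
  thr <- default_thresholds()
  direct <- ifelse(scored$theta > thr$t_high, "engrafter",
                   ifelse(scored$theta < thr$t_low, "nonengrafter",
                          "no_prediction"))
  expect_identical(scored$label, direct)
})

test_that("theta increases with fdf at positive viability when the interaction is positive", {
  fdf <- seq(1, 10, by = 0.25)
  for (v in c(10, 50, 100)) {
    th <- theta(rep(v, length(fdf)), fdf)
    expect_true(all(diff(th) > 0))
  }
})

test_that("refitting recovers generating coefficients and matches glm", {
  cohort <- simulate_cohort(2000, seed = 17)
  fit <- fit_engraftment_model(cohort)
  expect_true(fit$converged)
  truth <- default_coefficients()
  expect_lt(abs(fit$estimates[["viability:fdf"]] - truth$interaction),
            2 * fit$std_errors[["viability:fdf"]])
  expect_lt(abs(fit$estimates[["viability"]] - truth$viability),
            2 * fit$std_errors[["viability"]])

  # independent cross-check: stats::glm on the same design
  ref <- stats::glm(status ~ viability + I(viability * fdf),
                    family = stats::binomial(), data = cohort)
  expect_equal(unname(fit$estimates), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$std_errors),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
})

test_that("a status independent of the covariates yields null coefficients", {
  cohort <- simulate_cohort(2000, coefficients = model_coefficients(0, 0, 0),
                            seed = 23)
  fit <- fit_engraftment_model(cohort)
  for (term in names(fit$estimates)) {
    expect_lt(abs(fit$estimates[[term]]), 2 * fit$std_errors[[term]] + 1e-9)
  }
})

test_that("degenerate cohorts are rejected with explicit errors", {
  cohort <- simulate_cohort(200, seed = 5)
  sep <- dplyr::mutate(cohort, status = as.integer(viability > 50))
  expect_error(fit_engraftment_model(sep), "separation")

  one_class <- dplyr::mutate(cohort, status = 1L)
  expect_error(fit_engraftment_model(one_class), "single")

  expect_error(fit_engraftment_model(cohort[1:2, ]), "at least 3")
})

test_that("the FDR sweep counts false predictions by manual enumeration", {
  th_values <- c(0.1, 0.2, 0.4, 0.5, 0.7, 0.9)
  truth <- c(0, 0, 0, 1, 0, 1)  # NE NE NE E NE E
  cohort <- cohort_with_theta(th_values, status = truth)
  sweep <- fdr_sweep(cohort,
                     grid = tibble::tibble(t_low = 0.3535354,
                                           t_high = 0.6363636))
  expect_equal(sweep$n_predicted, 4L)
  expect_equal(sweep$n_false, 1L)     # the 0.7 nonengrafter called engrafter
  expect_equal(sweep$fdr, 0.25)
  expect_equal(sweep$no_prediction_fraction, 2 / 6)

  # domain edge: everything abstains, FDR defined as 0
  edge <- fdr_sweep(cohort, grid = tibble::tibble(t_low = 0, t_high = 1))
  expect_equal(edge$n_predicted, 0L)
  expect_equal(edge$fdr, 0)
  expect_equal(edge$no_prediction_fraction, 1)

  # perfectly ranked cohort: a cut through the gap makes no false call
  ranked <- cohort_with_theta(c(0.1, 0.2, 0.8, 0.9), status = c(0, 0, 1, 1))
  clean <- fdr_sweep(ranked, grid = tibble::tibble(t_low = 0.5, t_high = 0.51))
  expect_equal(clean$fdr, 0)
  expect_equal(clean$n_predicted, 4L)
})

test_that("predicted plus abstained equals the cohort size at every grid pair", {
  cohort <- simulate_cohort(300, seed = 41)
  sweep <- fdr_sweep(cohort)
  n <- attr(sweep, "n_samples")
  expect_equal(n, 300)
  abstained <- round(sweep$no_prediction_fraction * n)
  expect_true(all(sweep$n_predicted + abstained == n))
  expect_true(all(sweep$fdr >= 0 & sweep$fdr <= 1))
  expect_true(all(sweep$n_false <= sweep$n_predicted))
})

test_that("threshold calibration follows the stated selection and fallback rules", {
  sweep <- tibble::tibble(
    t_low = c(0.2, 0.3, 0.4),
    t_high = c(0.8, 0.7, 0.6),
    n_predicted = c(10L, 12L, 14L),
    n_false = c(0L, 1L, 3L),
    fdr = c(0.0, 1 / 12, 3 / 14),
    no_prediction_fraction = c(0.5, 0.4, 0.3)
  )
  # only the first row qualifies at 5%
  got <- calibrate_thresholds(sweep, fdr_target = 0.05)
  expect_equal(got$t_low, 0.2)
  expect_true(attr(got, "target_met"))

  # two qualifying rows: the smaller abstention wins
  got2 <- calibrate_thresholds(sweep, fdr_target = 0.10)
  expect_equal(got2$t_low, 0.3)

  # no qualifying row: minimal-FDR fallback, flagged
  got3 <- calibrate_thresholds(dplyr::mutate(sweep, fdr = fdr + 0.5),
                               fdr_target = 0.05)
  expect_equal(got3$t_low, 0.2)
  expect_false(attr(got3, "target_met"))

  expect_error(calibrate_thresholds(sweep[0, ]), "empty")
})

test_that("refitting data generated from a fit's own coefficients is self-consistent", {
  fit1 <- fit_engraftment_model(simulate_cohort(2000, seed = 61))
  cohort2 <- simulate_cohort(2000, coefficients = fit1$coefficients, seed = 62)
  fit2 <- fit_engraftment_model(cohort2)
  for (term in names(fit1$estimates)) {
    expect_lt(abs(fit2$estimates[[term]] - fit1$estimates[[term]]),
              3 * sqrt(fit1$std_errors[[term]]^2 + fit2$std_errors[[term]]^2))
  }
})
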