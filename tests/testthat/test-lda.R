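# Brute-force log-likelihood oracle, written independently of the package's
# implementation: direct summation of the binomial single-hit terms.
oracle_loglik <- function(f, experiment) {
  p_neg <- exp(-f * experiment$dose)
  pos <- experiment$wells - experiment$negative_wells
  sum(experiment$negative_wells * log(p_neg)) +
    sum(ifelse(pos > 0, pos * log(1 - p_neg), 0))
}

oracle_grid_mle <- function(experiment, lo = 1e-6, hi = 1e-1, n = 1e6) {
  f <- seq(lo, hi, length.out = n)
  # vectorized direct evaluation over the grid
  ll <- rep(0, n)
  for (i in seq_len(nrow(experiment))) {
    p_neg <- exp(-f * experiment$dose[i])
    pos <- experiment$wells[i] - experiment$negative_wells[i]
    ll <- ll + experiment$negative_wells[i] * log(p_neg)
    if (pos > 0) ll <- ll + pos * log(1 - p_neg)
  }
  f[which.max(ll)]
}

test_that("the single-hit log-likelihood matches closed forms", {
  all_neg <- tibble::tibble(dose = c(50, 500), wells = c(10, 10),
                            negative_wells = c(10, 10))
  expect_equal(lda_loglik(0, all_neg), 0)

  half <- tibble::tibble(dose = 100, wells = 20, negative_wells = 10)
  expect_equal(lda_loglik(log(2) / 100, half), -20 * log(2), tolerance = 1e-12)

  empty <- tibble::tibble(dose = 100, wells = 0, negative_wells = 0)
  expect_equal(lda_loglik(c(0, 1e-3, 0.5), empty), c(0, 0, 0))

  expect_error(lda_loglik(-1e-6, half), "nonnegative")
  # f = 0 with positive wells present has zero likelihood
  expect_equal(lda_loglik(0, half), -Inf)
})

test_that("single-dose fits reproduce the closed form exactly", {
  fit <- fit_limiting_dilution(
    tibble::tibble(dose = 100, wells = 20, negative_wells = 10)
  )
  expect_equal(fit$frequency_hat, log(2) / 100, tolerance = 1e-12)
  expect_equal(fit$one_in, 100 / log(2), tolerance = 1e-12)
  expect_equal(fit$status, "ok")
  expect_lte(fit$ci_low, fit$frequency_hat)
  expect_gte(fit$ci_high, fit$frequency_hat)
})

test_that("degenerate well outcomes are flagged rather than fitted", {
  all_neg <- fit_limiting_dilution(
    tibble::tibble(dose = c(100, 1000), wells = c(20, 20),
                   negative_wells = c(20, 20))
  )
  expect_equal(all_neg$status, "boundary_zero")
  expect_equal(all_neg$frequency_hat, 0)
  expect_equal(all_neg$ci_low, 0)
  expect_gt(all_neg$ci_high, 0)

  all_pos <- fit_limiting_dilution(
    tibble::tibble(dose = c(100, 1000), wells = c(20, 20),
                   negative_wells = c(0, 0))
  )
  expect_equal(all_pos$status, "no_finite_mle")
  expect_equal(all_pos$frequency_hat, Inf)
  expect_gt(all_pos$ci_low, 0)
})

test_that("the optimizer agrees with a dense grid-search oracle", {
  two_dose <- tibble::tibble(dose = c(100, 1000), wells = c(20, 20),
                             negative_wells = c(15, 2))
  fit <- fit_limiting_dilution(two_dose)
  grid_mle <- oracle_grid_mle(two_dose)
  expect_equal(signif(fit$frequency_hat, 4), signif(grid_mle, 4))

  # randomized small designs against a coarser grid
  set.seed(99)
  for (i in 1:8) {
    doses <- sort(10^runif(3, 1.5, 3.5))
    wells <- rep(20L, 3)
    truef <- 10^runif(1, -3.2, -2)
    neg <- rbinom(3, wells, exp(-truef * doses))
    exp_tbl <- tibble::tibble(dose = doses, wells = wells,
                              negative_wells = neg)
    if (sum(neg) == 0 || sum(wells - neg) == 0) next
    fit_i <- fit_limiting_dilution(exp_tbl)
    grid_i <- oracle_grid_mle(exp_tbl, lo = 1e-5, hi = 1e-1, n = 2e5)
    expect_equal(fit_i$frequency_hat, grid_i, tolerance = 1e-3)
    expect_lte(fit_i$ci_low, fit_i$frequency_hat)
    expect_gte(fit_i$ci_high, fit_i$frequency_hat)
  }
})

test_that("more negative wells never increases the estimated frequency", {
  base <- tibble::tibble(dose = c(100, 1000), wells = c(20, 20),
                         negative_wells = c(5, 1))
  prev <- Inf
  for (neg1 in 1:19) {
    exp_tbl <- base
    exp_tbl$negative_wells[1] <- neg1
    fhat <- fit_limiting_dilution(exp_tbl)$frequency_hat
    expect_lte(fhat, prev + 1e-12)
    prev <- fhat
  }
})

test_that("the estimator is consistent at large well counts", {
  truef <- 1 / 1000
  exp_tbl <- simulate_lda_wells(truef, doses = c(250, 1000, 4000),
                                replicates = 3334L, seed = 12)
  fit <- fit_limiting_dilution(exp_tbl)
  expect_lt(abs(fit$frequency_hat - truef) / truef, 0.05)
})

test_that("invalid designs are rejected", {
  expect_error(fit_limiting_dilution(
    tibble::tibble(dose = numeric(0), wells = integer(0),
                   negative_wells = integer(0))), "dose")
  expect_error(fit_limiting_dilution(
    tibble::tibble(dose = -10, wells = 20, negative_wells = 3)), "positive")
  expect_error(fit_limiting_dilution(
    tibble::tibble(dose = 10, wells = 20, negative_wells = 25)),
    "cannot exceed")
})
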