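# Shared fixtures, built in code.

# Six hand-written events exercising each gate rule exactly once under the
# default gating_config(): one feeder-high, one CD45-negative, one
# CD45-high/SSC-low lymphocyte, one Annexin-V-high, two clean viable blasts.
toy_event_table <- function() {
  tibble::tibble(
    sample_id = "toy",
    timepoint = "day7",
    cfse = c(1000, 1100, 1200, 1300, 1400, 1500),
    cd45 = c(1000, 100, 5000, 1000, 1000, 1000),
    ssc = c(1000, 1000, 200, 1000, 1000, 1000),
    feeder_marker = c(5000, 50, 50, 50, 50, 50),
    annexin_v = c(100, 100, 100, 5000, 100, 100),
    dapi = c(100, 100, 100, 100, 100, 100)
  )
}

# Random well-formed event table for property-style checks.
random_event_table <- function(n, seed) {
  withr_seed <- seed  # plain set.seed is fine inside tests
  set.seed(withr_seed)
  tibble::tibble(
    sample_id = "rand",
    timepoint = "day7",
    cfse = rlnorm(n, log(2000), 0.6),
    cd45 = rlnorm(n, log(800), 1.0),
    ssc = rlnorm(n, log(700), 0.8),
    feeder_marker = rlnorm(n, log(300), 1.2),
    annexin_v = rlnorm(n, log(300), 1.1),
    dapi = rlnorm(n, log(300), 1.1)
  )
}

# Cohort whose theta values are chosen exactly: viability pinned at 100 and
# FDF solved from the inverse logit of the default coefficients.
cohort_with_theta <- function(theta_values, status = NULL) {
  stopifnot(all(theta_values > 0 & theta_values < 1))
  eta <- qlogis(theta_values)
  co <- default_coefficients()
  fdf <- (eta - co$intercept - co$viability * 100) / (co$interaction * 100)
  stopifnot(all(fdf > 0))
  out <- tibble::tibble(
    sample_id = sprintf("T%03d", seq_along(theta_values)),
    viability = 100,
    fdf = fdf
  )
  if (!is.null(status)) out$status <- status
  out
}
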