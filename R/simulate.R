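# Synthetic-data generators. These define the study conditions under which
# the pipeline is exercised and validated: every downstream stage can be
# round-tripped against the parameters used here.

#' Specification of one synthetic flow-cytometry sample
#'
#' Describes the two-timepoint CFSE dye-dilution acquisition of one AML
#' sample on a feeder co-culture: a mixture of human hematopoietic blasts,
#' residual normal lymphocytes (CD45-high/SSC-low) and feeder cells
#' (feeder-marker-high), with CFSE halving per division and an apoptotic
#' (Annexin-V- and/or DAPI-positive) fraction appearing by day 7.
#'
#' @param sample_id Sample identifier.
#' @param n_events Number of events per timepoint.
#' @param target_fdf Median dye-dilution ratio the day-7 acquisition should
#'   produce (>= 1; 1 means no division).
#' @param target_viability Percent of day-7 human hematopoietic events that
#'   are viable, in \[0, 100\].
#' @param feeder_fraction,lymphocyte_fraction Contaminating event fractions
#'   in \[0, 1); together with the hematopoietic fraction they sum to 1.
#' @param cfse_log_mean,cfse_log_sd Log-normal parameters of the 18-hour
#'   CFSE intensity (broad staining: division peaks overlap and cannot be
#'   resolved individually).
#' @param division_log2_sd Spread (in divisions) of the per-cell division
#'   count around `log2(target_fdf)`.
#' @param seed Integer RNG seed.
#' @return A `flow_sample_spec` object.
#' @export
flow_sample_spec <- function(sample_id,
                             n_events = 20000L,
                             target_fdf = 2,
                             target_viability = 80,
                             feeder_fraction = 0.10,
                             lymphocyte_fraction = 0.05,
                             cfse_log_mean = log(5000),
                             cfse_log_sd = 0.5,
                             division_log2_sd = 0.7,
                             seed = 1L) {
  check_scalar_number(n_events, "n_events")
  check_scalar_number(target_fdf, "target_fdf")
  check_scalar_number(target_viability, "target_viability")
  check_scalar_number(feeder_fraction, "feeder_fraction")
  check_scalar_number(lymphocyte_fraction, "lymphocyte_fraction")
  check_scalar_number(cfse_log_mean, "cfse_log_mean")
  check_scalar_number(cfse_log_sd, "cfse_log_sd")
  check_scalar_number(division_log2_sd, "division_log2_sd")
  check_scalar_number(seed, "seed")
  if (n_events < 1 || n_events != round(n_events)) {
    abort("`n_events` must be a positive integer.")
  }
  if (target_fdf < 1) abort("`target_fdf` must be >= 1 for generated samples.")
  if (target_viability < 0 || target_viability > 100) {
    abort("`target_viability` must lie in [0, 100].")
  }
  if (feeder_fraction < 0 || feeder_fraction >= 1 ||
      lymphocyte_fraction < 0 || lymphocyte_fraction >= 1 ||
      feeder_fraction + lymphocyte_fraction >= 1) {
    abort("Feeder and lymphocyte fractions must lie in [0, 1) and leave a positive hematopoietic fraction.")
  }
  if (cfse_log_sd <= 0 || division_log2_sd < 0) {
    abort("`cfse_log_sd` must be positive and `division_log2_sd` nonnegative.")
  }
  structure(
    list(
      sample_id = as.character(sample_id), n_events = as.integer(n_events),
      target_fdf = target_fdf, target_viability = target_viability,
      feeder_fraction = feeder_fraction,
      lymphocyte_fraction = lymphocyte_fraction,
      cfse_log_mean = cfse_log_mean, cfse_log_sd = cfse_log_sd,
      division_log2_sd = division_log2_sd, seed = as.integer(seed)
    ),
    class = "flow_sample_spec"
  )
}

# Channel conventions (arbitrary units) for the three event categories.
# Distributions are well separated relative to the default gating_config()
# cuts so that spec fractions survive or fail the intended gates.
sim_channel <- function(n, meanlog, sdlog = 0.3) rlnorm(n, meanlog, sdlog)

sim_events_one_timepoint <- function(spec, timepoint) {
  n <- spec$n_events
  category <- sample(
    c("hematopoietic", "feeder", "lymphocyte"), n, replace = TRUE,
    prob = c(1 - spec$feeder_fraction - spec$lymphocyte_fraction,
             spec$feeder_fraction, spec$lymphocyte_fraction)
  )
  is_hem <- category == "hematopoietic"
  is_feed <- category == "feeder"
  is_lym <- category == "lymphocyte"

  cfse <- numeric(n)
  # patient cells (blasts and lymphocytes) are CFSE-stained; feeders are not
  cfse[!is_feed] <- rlnorm(sum(!is_feed), spec$cfse_log_mean, spec$cfse_log_sd)
  cfse[is_feed] <- sim_channel(sum(is_feed), log(30), 0.5)
  if (timepoint == "day7") {
    # division count per blast: rounded normal around log2(target_fdf);
    # not truncated, so the gated median ratio is unbiased at target_fdf = 1
    k <- round(rnorm(sum(is_hem), log2(spec$target_fdf), spec$division_log2_sd))
    cfse[is_hem] <- cfse[is_hem] * 2^(-k)
  }

  cd45 <- numeric(n)
  cd45[is_hem] <- sim_channel(sum(is_hem), log(1000))
  cd45[is_lym] <- sim_channel(sum(is_lym), log(10000), 0.25)
  cd45[is_feed] <- sim_channel(sum(is_feed), log(30), 0.5)

  ssc <- numeric(n)
  ssc[is_hem] <- sim_channel(sum(is_hem), log(1000))
  ssc[is_lym] <- sim_channel(sum(is_lym), log(150))
  ssc[is_feed] <- sim_channel(sum(is_feed), log(1200))

  feeder_marker <- numeric(n)
  feeder_marker[is_feed] <- sim_channel(sum(is_feed), log(8000))
  feeder_marker[!is_feed] <- sim_channel(sum(!is_feed), log(50), 0.5)

  # apoptosis appears on day-7 hematopoietic events only; 18-h acquisitions
  # are generated fully viable
  annexin_v <- sim_channel(n, log(80), 0.5)
  dapi <- sim_channel(n, log(80), 0.5)
  if (timepoint == "day7") {
    dead <- is_hem & (runif(n) < (100 - spec$target_viability) / 100)
    mode <- sample(c("annexin", "dapi", "both"), n, replace = TRUE)
    hit_a <- dead & mode %in% c("annexin", "both")
    hit_d <- dead & mode %in% c("dapi", "both")
    annexin_v[hit_a] <- sim_channel(sum(hit_a), log(8000), 0.4)
    dapi[hit_d] <- sim_channel(sum(hit_d), log(8000), 0.4)
  }

  tibble(
    sample_id = spec$sample_id,
    timepoint = timepoint,
    cfse = cfse, cd45 = cd45, ssc = ssc,
    feeder_marker = feeder_marker, annexin_v = annexin_v, dapi = dapi
  )
}

#' Simulate a two-timepoint flow-cytometry acquisition
#'
#' Generates event tables at 18 hours and day 7 according to a
#' [flow_sample_spec()]. The day-7 CFSE intensity of each blast is a fresh
#' log-normal draw divided by `2^k`, with the division count `k` a rounded
#' normal around `log2(target_fdf)`; gating the output and forming the MFI
#' ratio recovers `target_fdf` (within median sampling error at large
#' `n_events`). The apoptotic, feeder and lymphocyte event fractions match
#' the spec within binomial error. Identical spec and seed give identical
#' output.
#'
#' @param spec A [flow_sample_spec()].
#' @return A list with tibbles `events_18h` and `events_day7` (columns
#'   `sample_id`, `timepoint`, `cfse`, `cd45`, `ssc`, `feeder_marker`,
#'   `annexin_v`, `dapi`).
#' @examples
#' ev <- simulate_flow_sample(flow_sample_spec("s1", n_events = 1000,
#'                                             target_fdf = 4, seed = 3))
#' head(ev$events_day7)
#' @export
simulate_flow_sample <- function(spec) {
  stopifnot(inherits(spec, "flow_sample_spec"))
  with_seed(spec$seed, {
    list(
      events_18h = sim_events_one_timepoint(spec, "18h"),
      events_day7 = sim_events_one_timepoint(spec, "day7")
    )
  })
}

#' Simulate a cohort of (viability, FDF, engraftment) triples
#'
#' Draws day-7 viability and FDF uniformly over the stated ranges and
#' engraftment status as Bernoulli with probability
#' `theta(viability, fdf, coefficients)` — the generative twin of the
#' logistic engraftment model, used for coefficient-recovery and
#' threshold-calibration experiments.
#'
#' @param n_samples Number of samples.
#' @param coefficients A [model_coefficients] object (finite; defaults to
#'   the shipped reference model).
#' @param viability_range,fdf_range Non-degenerate uniform ranges;
#'   viability within \[0, 100\], FDF at least 1.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `sample_id`, `viability`, `fdf`,
#'   `true_status` (1 = engrafter), and `status` (alias of `true_status`
#'   for direct use in [fit_engraftment_model()] and [fdr_sweep()]).
#' @examples
#' simulate_cohort(n_samples = 5, seed = 42)
#' @export
simulate_cohort <- function(n_samples,
                            coefficients = default_coefficients(),
                            viability_range = c(20, 100),
                            fdf_range = c(1, 6),
                            seed = 1L) {
  stopifnot(inherits(coefficients, "model_coefficients"))
  check_scalar_number(n_samples, "n_samples")
  check_scalar_number(seed, "seed")
  if (n_samples < 1 || n_samples != round(n_samples)) {
    abort("`n_samples` must be a positive integer.")
  }
  if (length(viability_range) != 2 || diff(viability_range) <= 0 ||
      viability_range[1] < 0 || viability_range[2] > 100) {
    abort("`viability_range` must be a non-degenerate interval within [0, 100].")
  }
  if (length(fdf_range) != 2 || diff(fdf_range) <= 0 || fdf_range[1] < 1) {
    abort("`fdf_range` must be a non-degenerate interval with lower end >= 1.")
  }
  with_seed(seed, {
    viability <- runif(n_samples, viability_range[1], viability_range[2])
    fdf <- runif(n_samples, fdf_range[1], fdf_range[2])
    th <- theta(viability, fdf, coefficients)
    status <- rbinom(n_samples, 1L, th)
    tibble(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      viability = viability,
      fdf = fdf,
      true_status = as.integer(status),
      status = as.integer(status)
    )
  })
}

#' Simulate limiting-dilution well outcomes
#'
#' Under the single-hit Poisson model each well seeded with `dose` cells is
#' negative (no colonies) with probability `exp(-true_frequency * dose)`,
#' independently across wells.
#'
#' @param true_frequency Nonnegative per-cell frequency of
#'   culture-initiating cells.
#' @param doses Positive vector of cells/well, one per dose group.
#' @param replicates Wells per dose group (default 20).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `dose`, `wells`, `negative_wells`.
#' @examples
#' simulate_lda_wells(1 / 1000, doses = c(250, 1000, 4000), seed = 7)
#' @export
simulate_lda_wells <- function(true_frequency, doses, replicates = 20L,
                               seed = 1L) {
  check_scalar_number(true_frequency, "true_frequency")
  check_scalar_number(replicates, "replicates")
  check_scalar_number(seed, "seed")
  if (true_frequency < 0) abort("`true_frequency` must be nonnegative.")
  if (length(doses) == 0) abort("`doses` must be a nonempty vector.")
  if (!is.numeric(doses) || anyNA(doses) || any(doses <= 0)) {
    abort("`doses` must be positive.")
  }
  if (replicates < 0 || replicates != round(replicates)) {
    abort("`replicates` must be a nonnegative integer.")
  }
  with_seed(seed, {
    tibble(
      dose = as.numeric(doses),
      wells = as.integer(rep(replicates, length(doses))),
      negative_wells = as.integer(
        rbinom(length(doses), replicates, exp(-true_frequency * doses))
      )
    )
  })
}

#' Simulate censored survival times for a cohort
#'
#' Draws exponential survival times with a status-specific hazard and
#' administratively censors at a horizon: engrafting samples carry the
#' higher hazard (worse patient outcome), mirroring the observed negative
#' association between xenograft potential and survival.
#'
#' @param cohort Data frame with a `true_status` (or `status`) column
#'   (1 = engrafter) and optionally `sample_id`.
#' @param hazard_engrafter,hazard_nonengrafter Positive hazards (1/months);
#'   `hazard_engrafter` must be at least `hazard_nonengrafter` (equality
#'   permits null simulations). Defaults: median
#'   overall survival 24 months for engrafters, 60 for nonengrafters.
#' @param censor_horizon Nonnegative administrative censoring time (months).
#' @param seed Integer RNG seed.
#' @return Tibble of survival records: `sample_id`, `time`, `event`
#'   (1 = death observed), `group` (`"engrafter"`/`"nonengrafter"` from the
#'   true status).
#' @examples
#' cohort <- simulate_cohort(10, seed = 3)
#' simulate_survival(cohort, seed = 4)
#' @export
simulate_survival <- function(cohort,
                              hazard_engrafter = log(2) / 24,
                              hazard_nonengrafter = log(2) / 60,
                              censor_horizon = 60,
                              seed = 1L) {
  status_col <- if ("true_status" %in% names(cohort)) "true_status" else "status"
  check_columns(cohort, status_col, "cohort table")
  check_scalar_number(hazard_engrafter, "hazard_engrafter")
  check_scalar_number(hazard_nonengrafter, "hazard_nonengrafter")
  check_scalar_number(censor_horizon, "censor_horizon")
  check_scalar_number(seed, "seed")
  if (hazard_engrafter <= 0 || hazard_nonengrafter <= 0) {
    abort("Hazards must be positive.")
  }
  # engrafters have the worse outcome; equality is allowed so null
  # (no-difference) calibration experiments can be simulated
  if (hazard_engrafter < hazard_nonengrafter) {
    abort("`hazard_engrafter` must be at least `hazard_nonengrafter` (engrafters have worse outcome).")
  }
  if (censor_horizon < 0) abort("`censor_horizon` must be nonnegative.")
  status <- as_binary_status(cohort[[status_col]])
  n <- length(status)
  ids <- if ("sample_id" %in% names(cohort)) {
    as.character(cohort$sample_id)
  } else {
    sprintf("S%04d", seq_len(n))
  }
  with_seed(seed, {
    hazard <- ifelse(status == 1, hazard_engrafter, hazard_nonengrafter)
    raw <- rexp(n, hazard)
    tibble(
      sample_id = ids,
      time = pmin(raw, censor_horizon),
      event = as.integer(raw < censor_horizon),
      group = ifelse(status == 1, "engrafter", "nonengrafter")
    )
  })
}
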