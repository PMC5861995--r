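test_that("every generator is deterministic under a fixed seed", {
  expect_identical(simulate_cohort(4, seed = 1), simulate_cohort(4, seed = 1))

  spec <- flow_sample_spec("d", n_events = 500, target_fdf = 2, seed = 9)
  expect_identical(simulate_flow_sample(spec), simulate_flow_sample(spec))

  expect_identical(simulate_lda_wells(1e-3, c(100, 1000), seed = 2),
                   simulate_lda_wells(1e-3, c(100, 1000), seed = 2))

  cohort <- simulate_cohort(20, seed = 3)
  expect_identical(simulate_survival(cohort, seed = 4),
                   simulate_survival(cohort, seed = 4))

  # and the generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_cohort(10, seed = 99)); after <- runif(1)
  expect_identical(before, after)
})

test_that("cohort engraftment fractions follow the logistic probabilities", {
  null <- simulate_cohort(10000, coefficients = model_coefficients(0, 0, 0),
                          seed = 7)
  expect_lt(abs(mean(null$true_status) - 0.5), 0.02)

  # near-degenerate ranges pin (viability, fdf); the engrafter fraction then
  # matches direct evaluation of theta at that point
  fixed <- simulate_cohort(10000,
                           viability_range = c(99.999, 100),
                           fdf_range = c(5.0, 5.0001), seed = 8)
  expect_lt(abs(mean(fixed$true_status) - theta(100, 5.0)), 0.01)

  expect_error(
    simulate_cohort(10, coefficients = structure(
      list(intercept = Inf, viability = 0, interaction = 0),
      class = "model_coefficients"), seed = 1),
    "finite"
  )
  expect_error(simulate_cohort(10, viability_range = c(50, 50)), "interval")
})

test_that("flow samples recover their dilution, viability and composition targets", {
  # no division: day-7 gated median matches the 18-h median within 2%
  spec1 <- flow_sample_spec("f1", n_events = 20000, target_fdf = 1,
                            target_viability = 90, seed = 101)
  ev1 <- simulate_flow_sample(spec1)
  a1 <- assay_from_events(ev1$events_18h, ev1$events_day7)
  expect_lt(abs(a1$fdf - 1), 0.02)

  spec4 <- flow_sample_spec("f4", n_events = 20000, target_fdf = 4,
                            target_viability = 80, seed = 102)
  ev4 <- simulate_flow_sample(spec4)
  a4 <- assay_from_events(ev4$events_18h, ev4$events_day7)
  expect_gte(a4$fdf, 3.8)
  expect_lte(a4$fdf, 4.2)

  # feeder_fraction controls the share failing the feeder-exclusion gate
  spec_f <- flow_sample_spec("ff", n_events = 20000, target_fdf = 2,
                             feeder_fraction = 0.3, seed = 103)
  ev_f <- simulate_flow_sample(spec_f)
  pop <- apply_gates(ev_f$events_day7)
  feeder_share <- 1 - pop$stage_counts[["feeder_excluded"]] /
    pop$stage_counts[["input"]]
  expect_lt(abs(feeder_share - 0.3), 0.02)

  # lymphocyte fraction appears as the CD45-high/SSC-low loss at stage 3
  spec_l <- flow_sample_spec("fl", n_events = 20000, target_fdf = 2,
                             lymphocyte_fraction = 0.15, seed = 104)
  ev_l <- simulate_flow_sample(spec_l)
  pop_l <- apply_gates(ev_l$events_day7)
  lymph_share <- (pop_l$stage_counts[["cd45_positive"]] -
                    pop_l$stage_counts[["lymphocyte_excluded"]]) /
    pop_l$stage_counts[["input"]]
  expect_lt(abs(lymph_share - 0.15), 0.02)

  expect_error(flow_sample_spec("x", target_viability = 130), "\\[0, 100\\]")
  expect_error(flow_sample_spec("x", target_fdf = 0.5), ">= 1")
  expect_error(flow_sample_spec("x", feeder_fraction = 0.7,
                                lymphocyte_fraction = 0.4), "fraction")
})

test_that("limiting-dilution wells follow the single-hit Poisson law", {
  none <- simulate_lda_wells(0, doses = c(10, 100, 1000), seed = 5)
  expect_true(all(none$negative_wells == none$wells))

  all_pos <- simulate_lda_wells(1, doses = 1e4, replicates = 50, seed = 6)
  expect_true(all(all_pos$negative_wells == 0))

  big <- simulate_lda_wells(1 / 100, doses = 100, replicates = 10000L,
                            seed = 7)
  # binomial closed form: negative fraction ~ e^-1 with sd sqrt(p(1-p)/n)
  tol <- 3.5 * sqrt(exp(-1) * (1 - exp(-1)) / 10000)
  expect_lt(abs(big$negative_wells / big$wells - exp(-1)), tol)

  expect_error(simulate_lda_wells(1e-3, numeric(0)), "nonempty")
  expect_error(simulate_lda_wells(-1, 100), "nonnegative")
})

test_that("survival times respect hazards, censoring and the outcome ordering", {
  cohort <- simulate_cohort(2000, seed = 9)

  zero_horizon <- simulate_survival(cohort, censor_horizon = 0, seed = 10)
  expect_true(all(zero_horizon$time == 0))
  expect_true(all(zero_horizon$event == 0))

  rec <- simulate_survival(cohort, seed = 11)
  expect_true(all(rec$time <= 60))
  expect_setequal(unique(rec$group), c("engrafter", "nonengrafter"))
  # engrafters (higher hazard) die earlier on average among observed events
  med_e <- median(rec$time[rec$group == "engrafter" & rec$event == 1])
  med_ne <- median(rec$time[rec$group == "nonengrafter" & rec$event == 1])
  expect_lt(med_e, med_ne)

  expect_error(simulate_survival(cohort, hazard_engrafter = -1), "positive")
  expect_error(simulate_survival(cohort, hazard_engrafter = 0.01,
                                 hazard_nonengrafter = 0.02), "at least")
})

test_that("a strong hazard ratio is detected by the log-rank test in most replicates", {
  cohort <- simulate_cohort(200, seed = 13)
  hits <- 0
  for (i in 1:50) {
    rec <- simulate_survival(cohort, hazard_engrafter = log(2) / 12,
                             hazard_nonengrafter = log(2) / 48,
                             seed = 1000 + i)
    if (twogroup_test(rec)$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
})
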