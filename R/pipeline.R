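#' Pipeline configuration
#'
#' Bundles everything a reproducible end-to-end run needs: gating cuts,
#' model coefficients, decision thresholds, FDR target, simulation sizes
#' and seed, optional stage switches, and the output directory. The
#' configuration is self-validating and serializable to YAML or JSON via
#' [write_pipeline_config()].
#'
#' @param gating A [gating_config].
#' @param coefficients A [model_coefficients].
#' @param thresholds A [decision_thresholds].
#' @param fdr_target Empirical-FDR target in (0, 1) for
#'   [calibrate_thresholds()].
#' @param n_samples Cohort size when simulating.
#' @param n_events Events per timepoint per simulated flow sample.
#' @param viability_range,fdf_range Cohort simulation ranges (see
#'   [simulate_cohort()]).
#' @param lda_doses,lda_replicates Limiting-dilution design used when the
#'   LDA stage runs.
#' @param lda_frequency_engrafter,lda_frequency_nonengrafter True
#'   culture-initiating-cell frequencies per status group for the simulated
#'   LDA stage (engrafters are L-LTC-IC-enriched).
#' @param hazard_engrafter,hazard_nonengrafter,censor_horizon Survival
#'   generator settings (see [simulate_survival()]).
#' @param run_lda,run_survival Stage switches.
#' @param cohort_csv Optional path to an existing sample-level cohort CSV
#'   with columns `sample_id`, `viability`, `fdf`; when given, the
#'   simulation stage is skipped and the classifier runs on the file.
#' @param output_dir Directory for result files (created if needed); `NULL`
#'   suppresses file output.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(gating = gating_config(),
                            coefficients = default_coefficients(),
                            thresholds = default_thresholds(),
                            fdr_target = 0.05,
                            n_samples = 40L,
                            n_events = 20000L,
                            viability_range = c(20, 100),
                            fdf_range = c(1, 6),
                            lda_doses = c(250, 1000, 4000),
                            lda_replicates = 20L,
                            lda_frequency_engrafter = 1 / 500,
                            lda_frequency_nonengrafter = 1 / 4000,
                            hazard_engrafter = log(2) / 24,
                            hazard_nonengrafter = log(2) / 60,
                            censor_horizon = 60,
                            run_lda = TRUE,
                            run_survival = TRUE,
                            cohort_csv = NULL,
                            output_dir = NULL,
                            seed = 1L) {
  stopifnot(inherits(gating, "gating_config"),
            inherits(coefficients, "model_coefficients"),
            inherits(thresholds, "decision_thresholds"))
  check_scalar_number(fdr_target, "fdr_target")
  if (fdr_target <= 0 || fdr_target >= 1) abort("`fdr_target` must lie in (0, 1).")
  check_scalar_number(seed, "seed")
  structure(
    list(
      gating = gating, coefficients = coefficients, thresholds = thresholds,
      fdr_target = fdr_target, n_samples = as.integer(n_samples),
      n_events = as.integer(n_events),
      viability_range = viability_range, fdf_range = fdf_range,
      lda_doses = lda_doses, lda_replicates = as.integer(lda_replicates),
      lda_frequency_engrafter = lda_frequency_engrafter,
      lda_frequency_nonengrafter = lda_frequency_nonengrafter,
      hazard_engrafter = hazard_engrafter,
      hazard_nonengrafter = hazard_nonengrafter,
      censor_horizon = censor_horizon,
      run_lda = isTRUE(run_lda), run_survival = isTRUE(run_survival),
      cohort_csv = cohort_csv, output_dir = output_dir,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$gating <- unclass(out$gating)
  out$coefficients <- unclass(out$coefficients)
  out$thresholds <- unclass(out$thresholds)
  out
}

#' Read or write a pipeline configuration
#'
#' Serialized as YAML (`.yml`/`.yaml`) or JSON (`.json`) by file extension.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- config_as_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(lst, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    abort("Config path must end in .yml, .yaml, or .json.")
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Config path must end in .yml, .yaml, or .json.")
  }
  pipeline_config(
    gating = do.call(gating_config, lst$gating),
    coefficients = do.call(model_coefficients, lst$coefficients),
    thresholds = do.call(decision_thresholds, lst$thresholds),
    fdr_target = lst$fdr_target,
    n_samples = lst$n_samples, n_events = lst$n_events,
    viability_range = unlist(lst$viability_range),
    fdf_range = unlist(lst$fdf_range),
    lda_doses = unlist(lst$lda_doses), lda_replicates = lst$lda_replicates,
    lda_frequency_engrafter = lst$lda_frequency_engrafter,
    lda_frequency_nonengrafter = lst$lda_frequency_nonengrafter,
    hazard_engrafter = lst$hazard_engrafter,
    hazard_nonengrafter = lst$hazard_nonengrafter,
    censor_horizon = lst$censor_horizon,
    run_lda = lst$run_lda, run_survival = lst$run_survival,
    cohort_csv = lst$cohort_csv, output_dir = lst$output_dir,
    seed = lst$seed
  )
}

#' Read and write event tables as CSV
#'
#' Documented header: `sample_id`, `timepoint`, `cfse`, `cd45`, `ssc`,
#' `feeder_marker`, `annexin_v`, `dapi` — one row per event, intensities in
#' arbitrary units. Tables round-trip without loss.
#'
#' @param events An event table.
#' @param path CSV path.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns a tibble.
#' @export
write_events_csv <- function(events, path) {
  validate_event_table(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Event CSV not found: %s", path))
  events <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_event_table(events)
  events
}

# Line-oriented log: "LEVEL message". No timestamps, so identical runs
# produce byte-identical artifacts.
pipeline_log <- function(lines, level, msg) {
  c(lines, sprintf("%s %s", level, msg))
}

#' Run the end-to-end engraftment-prediction pipeline
#'
#' Drives the full workflow on one configuration. In simulation mode (no
#' `cohort_csv`), a cohort of (viability, FDF, status) targets is drawn,
#' each sample's two-timepoint flow acquisition is generated and gated, the
#' assay summary (MFI ratio, viability) is measured, and every sample is
#' scored with theta and the three-way decision rule. Optional stages fit a
#' limiting-dilution experiment per status group and stratify simulated
#' survival by the *predicted* label. With `cohort_csv` given, the
#' classifier runs directly on the file's (viability, fdf) rows.
#'
#' Per-sample gating failures are logged and skipped, never fatal. Rerunning
#' an identical configuration reproduces outputs exactly; the run log
#' records a configuration hash, the seed, and stage counts.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `cohort` (per-sample results tibble),
#'   `lda` (named list of [fit_limiting_dilution()] results or `NULL`),
#'   `survival` (list with `records`, `curve`, `test`, or `NULL`), `log`
#'   (character lines), `config_hash`, and `files` (paths written, if an
#'   output directory was set).
#' @examples
#' res <- run_pipeline(pipeline_config(n_samples = 4, n_events = 2000,
#'                                     run_lda = FALSE, run_survival = FALSE))
#' res$cohort
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  config_hash <- rlang::hash(config_as_list(config))
  log_lines <- character()
  log_lines <- pipeline_log(log_lines, "INFO",
                            sprintf("config hash %s seed %d", config_hash, config$seed))

  if (!is.null(config$cohort_csv)) {
    if (!file.exists(config$cohort_csv)) {
      abort(sprintf("Cohort CSV not found: %s", config$cohort_csv))
    }
    cohort <- readr::read_csv(config$cohort_csv, show_col_types = FALSE,
                              progress = FALSE)
    check_columns(cohort, c("sample_id", "viability", "fdf"), "cohort CSV")
    results <- predict_engraftment(cohort, config$coefficients, config$thresholds)
    log_lines <- pipeline_log(log_lines, "INFO",
                              sprintf("scored %d samples from %s",
                                      nrow(results), config$cohort_csv))
    truth <- NULL
  } else {
    truth <- simulate_cohort(
      n_samples = config$n_samples, coefficients = config$coefficients,
      viability_range = config$viability_range, fdf_range = config$fdf_range,
      seed = config$seed
    )
    sample_seeds <- with_seed(config$seed + 1L,
                              sample.int(.Machine$integer.max - 1L, nrow(truth)))
    assay_one <- function(i) {
      row <- truth[i, ]
      spec <- flow_sample_spec(
        sample_id = row$sample_id, n_events = config$n_events,
        target_fdf = row$fdf, target_viability = row$viability,
        seed = sample_seeds[i]
      )
      ev <- simulate_flow_sample(spec)
      assay_from_events(ev$events_18h, ev$events_day7, config$gating)
    }
    assays <- purrr::map(seq_len(nrow(truth)), function(i) {
      tryCatch(assay_one(i), error = function(e) {
        msg <- conditionMessage(e)
        structure(list(sample_id = truth$sample_id[i], error = msg),
                  class = "assay_failure")
      })
    })
    failed <- purrr::map_lgl(assays, inherits, "assay_failure")
    for (a in assays[failed]) {
      log_lines <- pipeline_log(log_lines, "WARN",
                                sprintf("sample %s skipped: %s", a$sample_id, a$error))
    }
    assay_tbl <- dplyr::bind_rows(assays[!failed])
    log_lines <- pipeline_log(log_lines, "INFO",
                              sprintf("assayed %d/%d samples", sum(!failed), nrow(truth)))
    measured <- dplyr::rename(assay_tbl, viability = "viability_day7")
    results <- predict_engraftment(measured, config$coefficients, config$thresholds)
    results <- dplyr::left_join(
      results,
      dplyr::select(truth, "sample_id", target_viability = "viability",
                    target_fdf = "fdf", "true_status"),
      by = "sample_id"
    )
  }
  log_lines <- pipeline_log(log_lines, "INFO", sprintf(
    "labels: engrafter=%d nonengrafter=%d no_prediction=%d",
    sum(results$label == "engrafter"), sum(results$label == "nonengrafter"),
    sum(results$label == "no_prediction")
  ))

  lda_out <- NULL
  if (config$run_lda && !is.null(truth)) {
    lda_out <- list(
      engrafter = fit_limiting_dilution(simulate_lda_wells(
        config$lda_frequency_engrafter, config$lda_doses,
        config$lda_replicates, seed = config$seed + 2L
      )),
      nonengrafter = fit_limiting_dilution(simulate_lda_wells(
        config$lda_frequency_nonengrafter, config$lda_doses,
        config$lda_replicates, seed = config$seed + 3L
      ))
    )
    log_lines <- pipeline_log(log_lines, "INFO", sprintf(
      "LDA frequencies: engrafter 1 in %.3g, nonengrafter 1 in %.3g",
      lda_out$engrafter$one_in, lda_out$nonengrafter$one_in
    ))
  }

  survival_out <- NULL
  if (config$run_survival && !is.null(truth)) {
    records <- simulate_survival(
      truth, hazard_engrafter = config$hazard_engrafter,
      hazard_nonengrafter = config$hazard_nonengrafter,
      censor_horizon = config$censor_horizon, seed = config$seed + 4L
    )
    # stratify by the classifier's prediction, dropping abstentions
    predicted <- dplyr::inner_join(
      dplyr::select(records, "sample_id", "time", "event"),
      dplyr::select(results, "sample_id", "label"),
      by = "sample_id"
    )
    predicted <- dplyr::filter(predicted, .data$label != "no_prediction")
    predicted <- dplyr::rename(predicted, group = "label")
    survival_out <- list(records = records, curve = NULL, test = NULL)
    if (length(unique(predicted$group)) == 2 && sum(predicted$event) > 0) {
      survival_out$curve <- km_estimate(predicted)
      survival_out$test <- twogroup_test(predicted, "logrank")
      log_lines <- pipeline_log(log_lines, "INFO", sprintf(
        "log-rank by predicted status: chi-square %.3f, p = %.4g",
        survival_out$test$statistic, survival_out$test$p.value
      ))
    } else {
      log_lines <- pipeline_log(log_lines, "WARN",
                                "survival test skipped: need two predicted groups with events")
    }
  }

  files <- character()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    cohort_path <- file.path(config$output_dir, "cohort_results.csv")
    readr::write_csv(results, cohort_path)
    files <- c(cohort = cohort_path)
    if (!is.null(lda_out)) {
      lda_path <- file.path(config$output_dir, "lda_results.csv")
      readr::write_csv(
        dplyr::bind_rows(purrr::map(lda_out, tidy), .id = "group"), lda_path
      )
      files <- c(files, lda = lda_path)
    }
    if (!is.null(survival_out) && !is.null(survival_out$test)) {
      surv_path <- file.path(config$output_dir, "survival_test.json")
      jsonlite::write_json(
        list(statistic = survival_out$test$statistic,
             p_value = survival_out$test$p.value,
             weighting = survival_out$test$weighting),
        surv_path, auto_unbox = TRUE, digits = NA
      )
      files <- c(files, survival = surv_path)
    }
    log_path <- file.path(config$output_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    files <- c(files, log = log_path)
  }

  structure(
    list(cohort = results, lda = lda_out, survival = survival_out,
         log = log_lines, config_hash = config_hash, files = files),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run %s: %d samples\n", x$config_hash, nrow(x$cohort)))
  print(table(x$cohort$label))
  invisible(x)
}
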