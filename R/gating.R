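#' Gating configuration
#'
#' Per-channel intensity cuts for the fixed four-stage gating sequence:
#' (1) exclude feeder cells (feeder marker above threshold: Sca-1 for MS-5,
#' CD56 for SaOS-2, CD31 for HUVEC co-cultures), (2) keep human hematopoietic
#' cells (CD45 above threshold), (3) exclude residual normal lymphocytes
#' (CD45-high AND SSC-low), (4) viability (Annexin-V and DAPI both at or
#' below threshold). All intensities are in arbitrary fluorescence units.
#'
#' @param feeder_positive_threshold Events with feeder-marker intensity
#'   strictly above this are dropped.
#' @param cd45_positive_threshold Events with CD45 strictly above this are
#'   kept as human hematopoietic.
#' @param annexin_positive_threshold,dapi_positive_threshold Events at or
#'   below both thresholds are viable.
#' @param lymphocyte_cd45_high_threshold,lymphocyte_ssc_low_threshold Events
#'   with CD45 strictly above the high cut AND SSC strictly below the low cut
#'   are excluded as lymphocytes. The CD45-high cut must be at least the
#'   CD45-positive cut.
#' @return A `gating_config` object.
#' @examples
#' gating_config()
#' @export
gating_config <- function(feeder_positive_threshold = 1000,
                          cd45_positive_threshold = 200,
                          annexin_positive_threshold = 1000,
                          dapi_positive_threshold = 1000,
                          lymphocyte_cd45_high_threshold = 3000,
                          lymphocyte_ssc_low_threshold = 400) {
  vals <- list(
    feeder_positive_threshold = feeder_positive_threshold,
    cd45_positive_threshold = cd45_positive_threshold,
    annexin_positive_threshold = annexin_positive_threshold,
    dapi_positive_threshold = dapi_positive_threshold,
    lymphocyte_cd45_high_threshold = lymphocyte_cd45_high_threshold,
    lymphocyte_ssc_low_threshold = lymphocyte_ssc_low_threshold
  )
  for (nm in names(vals)) {
    x <- vals[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x) || x < 0) {
      abort(sprintf("`%s` must be a single finite nonnegative number.", nm))
    }
  }
  if (vals$lymphocyte_cd45_high_threshold < vals$cd45_positive_threshold) {
    abort("lymphocyte_cd45_high_threshold must be >= cd45_positive_threshold.")
  }
  structure(vals, class = "gating_config")
}

#' @export
print.gating_config <- function(x, ...) {
  cat("Gating configuration (intensity cuts, a.u.):\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-32s %g\n", nm, x[[nm]]))
  invisible(x)
}

event_channels <- c("cfse", "cd45", "ssc", "feeder_marker", "annexin_v", "dapi")

validate_event_table <- function(events) {
  check_columns(events, event_channels, "event table")
  if (nrow(events) == 0) abort("Event table is empty.")
  for (ch in event_channels) {
    x <- events[[ch]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
      abort(sprintf("Channel `%s` must be numeric and nonnegative.", ch))
    }
  }
  invisible(events)
}

#' Apply the sequential gating scheme
#'
#' Gates an event table through the fixed stage order: feeder exclusion,
#' CD45-positive selection, lymphocyte exclusion, Annexin-V/DAPI viability.
#' Each stage operates on the survivors of the previous one, so stage
#' memberships are nested and stage counts are weakly decreasing. If no
#' event survives the CD45 stage the population is flagged
#' `no_hematopoietic` (downstream MFI and viability are then undefined).
#'
#' @param events A data frame with one row per event and numeric channels
#'   `cfse`, `cd45`, `ssc`, `feeder_marker`, `annexin_v`, `dapi`.
#' @param config A [gating_config].
#' @return A `gated_population`: the event table, a logical membership
#'   matrix with one column per stage (`input`, `feeder_excluded`,
#'   `cd45_positive`, `lymphocyte_excluded`, `viable`), stage counts, and
#'   the `no_hematopoietic` flag. Use [gated_events()] to extract a stage
#'   and [tidy()] for the stage-count table.
#' @examples
#' spec <- flow_sample_spec("s1", n_events = 2000, target_fdf = 2,
#'                          target_viability = 85, seed = 1)
#' pop <- apply_gates(simulate_flow_sample(spec)$events_day7)
#' tidy(pop)
#' @export
apply_gates <- function(events, config = gating_config()) {
  stopifnot(inherits(config, "gating_config"))
  validate_event_table(events)
  events <- as_tibble(events)

  input <- rep(TRUE, nrow(events))
  feeder_excluded <- input & !(events$feeder_marker > config$feeder_positive_threshold)
  cd45_positive <- feeder_excluded & (events$cd45 > config$cd45_positive_threshold)
  lymphocyte <- events$cd45 > config$lymphocyte_cd45_high_threshold &
    events$ssc < config$lymphocyte_ssc_low_threshold
  lymphocyte_excluded <- cd45_positive & !lymphocyte
  viable <- lymphocyte_excluded &
    events$annexin_v <= config$annexin_positive_threshold &
    events$dapi <= config$dapi_positive_threshold

  membership <- cbind(
    input = input,
    feeder_excluded = feeder_excluded,
    cd45_positive = cd45_positive,
    lymphocyte_excluded = lymphocyte_excluded,
    viable = viable
  )
  structure(
    list(
      events = events,
      membership = membership,
      stage_counts = colSums(membership),
      no_hematopoietic = sum(cd45_positive) == 0
    ),
    class = "gated_population"
  )
}

#' @export
print.gated_population <- function(x, ...) {
  cat("Gated population:\n")
  print(tidy(x))
  if (x$no_hematopoietic) cat("  [flag] no hematopoietic population\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gated_population <- function(x, ...) {
  tibble(
    stage = names(x$stage_counts),
    n_events = as.integer(x$stage_counts),
    fraction_of_input = as.numeric(x$stage_counts / x$stage_counts[["input"]])
  )
}

#' Extract the events surviving a gate stage
#'
#' @param pop A [apply_gates()] result.
#' @param stage One of `"input"`, `"feeder_excluded"`, `"cd45_positive"`,
#'   `"lymphocyte_excluded"`, `"viable"`.
#' @return Tibble of surviving events.
#' @export
gated_events <- function(pop, stage = "viable") {
  stopifnot(inherits(pop, "gated_population"))
  stage <- match.arg(stage, colnames(pop$membership))
  pop$events[pop$membership[, stage], , drop = FALSE]
}

#' Median fluorescence intensity of a channel
#'
#' The sample median of one channel over an event subset (for an even event
#' count, the mean of the two central order statistics). This is the "MFI"
#' statistic of CFSE dye-dilution analysis.
#'
#' @param events A nonempty event subset (data frame).
#' @param channel Channel column name, e.g. `"cfse"`.
#' @return The median intensity.
#' @examples
#' median_fluorescence(tibble::tibble(cfse = c(100, 200, 300, 400)), "cfse")
#' @export
median_fluorescence <- function(events, channel = "cfse") {
  if (!channel %in% names(events)) {
    abort(sprintf("Channel `%s` not present in the event table.", channel))
  }
  x <- events[[channel]]
  if (length(x) == 0) abort("undefined MFI: empty event subset.")
  median(x)
}

#' Day-7 viability within the hematopoietic population
#'
#' The percentage of Annexin-V- and DAPI-negative events within the
#' lymphocyte-excluded human hematopoietic population.
#'
#' @param pop A [apply_gates()] result with a nonempty lymphocyte-excluded
#'   stage.
#' @return Percent in \[0, 100\].
#' @export
viability_fraction <- function(pop) {
  stopifnot(inherits(pop, "gated_population"))
  denom <- pop$stage_counts[["lymphocyte_excluded"]]
  if (denom == 0) abort("undefined viability: no hematopoietic events after lymphocyte exclusion.")
  100 * pop$stage_counts[["viable"]] / denom
}
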