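#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct observed
#' times. Ties between events and censorings at the same time are resolved
#' by processing events first: a subject censored at `t` is still at risk
#' for events at `t`. If the records carry a `group` column, one curve is
#' returned per group.
#'
#' @param records Data frame with nonnegative numeric `time`, integer
#'   `event` (1 = death observed, 0 = censored), and optionally `group`.
#' @return A `km_curve` tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (plus `group` when grouped), one row per
#'   distinct observed time. Survival starts at 1 before the first event,
#'   is nonincreasing, and stays in \[0, 1\].
#' @examples
#' rec <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
#' km_estimate(rec)
#' @export
km_estimate <- function(records) {
  check_columns(records, c("time", "event"), "survival records")
  if (nrow(records) == 0) abort("Survival records are empty.")
  if (anyNA(records$time) || any(records$time < 0)) {
    abort("Survival times must be nonnegative.")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death observed).")
  }
  one_curve <- function(time, event) {
    ts <- sort(unique(time))
    n_risk <- vapply(ts, function(t) sum(time >= t), numeric(1))
    n_event <- vapply(ts, function(t) sum(time == t & event == 1), numeric(1))
    n_censor <- vapply(ts, function(t) sum(time == t & event == 0), numeric(1))
    tibble(
      time = ts,
      n_risk = as.integer(n_risk),
      n_event = as.integer(n_event),
      n_censor = as.integer(n_censor),
      survival = cumprod(1 - n_event / n_risk)
    )
  }
  out <- if ("group" %in% names(records)) {
    records |>
      as_tibble() |>
      dplyr::group_by(.data$group) |>
      dplyr::reframe(one_curve(.data$time, .data$event))
  } else {
    one_curve(records$time, records$event)
  }
  structure(out, class = c("km_curve", class(out)))
}

#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(unclass(object))
  grouped <- "group" %in% names(df)
  add_origin <- function(d) {
    dplyr::bind_rows(
      tibble(time = 0, survival = 1),
      d[c("time", "survival")]
    )
  }
  if (grouped) {
    df <- df |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ add_origin(.x)) |>
      dplyr::ungroup()
    mapping <- ggplot2::aes(x = .data$time, y = .data$survival,
                            colour = .data$group)
  } else {
    df <- add_origin(df)
    mapping <- ggplot2::aes(x = .data$time, y = .data$survival)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = "Predicted status") +
    ggplot2::theme_minimal()
}

#' Two-group weighted log-rank test
#'
#' Compares survival between two groups with the weighted log-rank family.
#' At each distinct event time the observed-minus-expected event count of
#' group 1 and its hypergeometric variance are accumulated with weight
#' `w = 1` (Mantel-Cox log-rank) or `w =` total number at risk
#' (Gehan-Wilcoxon, emphasizing early differences); the statistic
#' \eqn{(\sum w (O_1 - E_1))^2 / \sum w^2 V} is referred to the upper tail
#' of \eqn{\chi^2_1}.
#'
#' @param records Data frame with `time`, `event`, and a two-level `group`
#'   column; both groups must be nonempty.
#' @param weighting `"logrank"` or `"gehan_wilcoxon"`.
#' @return A `logrank_test` object with `statistic`, `p.value`,
#'   `weighting`, and per-group observed/expected event counts. Has a
#'   [tidy()] method.
#' @examples
#' rec <- tibble::tibble(time = c(1, 2), event = c(1, 1),
#'                       group = c("a", "b"))
#' twogroup_test(rec)  # chi-square = 1
#' @export
twogroup_test <- function(records, weighting = c("logrank", "gehan_wilcoxon")) {
  weighting <- match.arg(weighting)
  check_columns(records, c("time", "event", "group"), "survival records")
  if (anyNA(records$time) || any(records$time < 0)) {
    abort("Survival times must be nonnegative.")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death observed).")
  }
  groups <- sort(unique(as.character(records$group)))
  if (length(groups) != 2) abort("Exactly two nonempty groups are required.")
  if (sum(records$event) == 0) abort("test undefined: no events observed.")

  time <- records$time
  event <- records$event
  g1 <- as.character(records$group) == groups[1]
  event_times <- sort(unique(time[event == 1]))

  num <- 0
  den <- 0
  obs1 <- 0
  exp1 <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    e1 <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- if (weighting == "logrank") 1 else n
    num <- num + w * (d1 - e1)
    den <- den + w^2 * v
    obs1 <- obs1 + d1
    exp1 <- exp1 + e1
  }
  if (den == 0) abort("test undefined: no variance in event allocation.")
  statistic <- num^2 / den
  structure(
    list(
      statistic = statistic,
      p.value = pchisq(statistic, df = 1, lower.tail = FALSE),
      weighting = weighting,
      groups = groups,
      observed = c(obs1, sum(event) - obs1),
      expected = c(exp1, sum(event) - exp1),
      n = nrow(records)
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  label <- if (x$weighting == "logrank") "Mantel-Cox log-rank" else "Gehan-Wilcoxon"
  cat(sprintf("%s test: chi-square = %.4f (1 df), p = %.4g\n",
              label, x$statistic, x$p.value))
  cat(sprintf("  groups: %s (O=%g, E=%.2f) vs %s (O=%g, E=%.2f)\n",
              x$groups[1], x$observed[1], x$expected[1],
              x$groups[2], x$observed[2], x$expected[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logrank_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = 1,
    p.value = x$p.value,
    method = x$weighting
  )
}
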