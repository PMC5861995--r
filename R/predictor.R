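#' Logistic engraftment-model coefficients
#'
#' The engraftment classifier scores each sample with a logistic probability
#' \eqn{\theta = \mathrm{logit}^{-1}(\beta_0 + \beta_v \cdot \mathrm{viability}
#' + \beta_{vf} \cdot \mathrm{viability} \times \mathrm{FDF})}, where
#' viability is the day-7 percentage of viable cells within the gated human
#' hematopoietic population (0-100 scale) and FDF is the CFSE fluorescence
#' dilution factor. `model_coefficients()` builds a coefficient set;
#' `default_coefficients()` returns the published reference model
#' (intercept -7.09e-2, viability -7.09e-2 per percent, interaction
#' 3.96e-2 per percent per FDF unit).
#'
#' @param intercept,viability,interaction Finite real coefficients. The
#'   viability coefficient is per percent viability; the interaction
#'   coefficient is per (percent viability x FDF unit).
#'
#' @return A `model_coefficients` object (named list of the three terms).
#' @examples
#' default_coefficients()
#' model_coefficients(0, 0, 0)
#' @export
model_coefficients <- function(intercept, viability, interaction) {
  check_scalar_number(intercept, "intercept")
  check_scalar_number(viability, "viability")
  check_scalar_number(interaction, "interaction")
  structure(
    list(intercept = intercept, viability = viability, interaction = interaction),
    class = "model_coefficients"
  )
}

#' @rdname model_coefficients
#' @export
default_coefficients <- function() {
  model_coefficients(intercept = -7.09e-2, viability = -7.09e-2, interaction = 3.96e-2)
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat("Engraftment model coefficients:\n")
  cat(sprintf("  intercept          % .6g\n", x$intercept))
  cat(sprintf("  viability          % .6g  (per %% viability)\n", x$viability))
  cat(sprintf("  viability x FDF    % .6g  (per %% viability per FDF unit)\n", x$interaction))
  invisible(x)
}

#' Abstention thresholds for the three-way decision rule
#'
#' The classifier predicts "engrafter" when \eqn{\theta >} `t_high`,
#' "nonengrafter" when \eqn{\theta <} `t_low`, and abstains
#' ("no_prediction") when \eqn{\theta} falls in the closed interval
#' \[`t_low`, `t_high`\]. `default_thresholds()` returns the published
#' decision rule (0.3535354 / 0.6363636); both printed thresholds are exact
#' multiples of 1/99, which is why [threshold_grid()] defaults to that grid.
#'
#' @param t_low,t_high Reals in (0, 1) with `t_low < t_high`.
#' @return A `decision_thresholds` object.
#' @examples
#' default_thresholds()
#' @export
decision_thresholds <- function(t_low, t_high) {
  check_scalar_number(t_low, "t_low")
  check_scalar_number(t_high, "t_high")
  if (t_low <= 0 || t_high >= 1 || t_low >= t_high) {
    abort("Thresholds must satisfy 0 < t_low < t_high < 1.")
  }
  structure(list(t_low = t_low, t_high = t_high), class = "decision_thresholds")
}

#' @rdname decision_thresholds
#' @export
default_thresholds <- function() {
  decision_thresholds(t_low = 0.3535354, t_high = 0.6363636)
}

#' @export
print.decision_thresholds <- function(x, ...) {
  cat(sprintf(
    "Decision thresholds: nonengrafter < %.7f <= abstain <= %.7f < engrafter\n",
    x$t_low, x$t_high
  ))
  invisible(x)
}

#' Engraftment probability theta
#'
#' Evaluates the logistic engraftment probability for given day-7 viability
#' (percent, 0-100) and fluorescence dilution factor. Numerically stable for
#' arbitrarily large linear predictors.
#'
#' @param viability Numeric vector of percentages in \[0, 100\].
#' @param fdf Numeric vector of positive dilution factors (recycled against
#'   `viability`).
#' @param coefficients A [model_coefficients] object.
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' theta(80, 2)          # ~0.644 under the default model
#' theta(0, 5)           # viability 0 collapses both viability terms
#' @export
theta <- function(viability, fdf, coefficients = default_coefficients()) {
  stopifnot(inherits(coefficients, "model_coefficients"))
  if (!all(vapply(unclass(coefficients), is.finite, logical(1)))) {
    abort("Model coefficients must be finite.")
  }
  if (!is.numeric(viability) || !is.numeric(fdf) ||
      anyNA(viability) || anyNA(fdf) ||
      any(!is.finite(viability)) || any(!is.finite(fdf))) {
    abort("`viability` and `fdf` must be finite numeric vectors.")
  }
  if (any(viability < 0 | viability > 100)) {
    abort("`viability` must lie in [0, 100] (percent scale).")
  }
  if (any(fdf <= 0)) abort("`fdf` must be positive.")
  eta <- coefficients$intercept +
    coefficients$viability * viability +
    coefficients$interaction * viability * fdf
  plogis(eta)
}

#' Three-way classification of theta values
#'
#' Applies the reject-option decision rule: values above `t_high` are
#' labelled `"engrafter"`, values below `t_low` `"nonengrafter"`, and
#' values in the closed abstention interval `"no_prediction"` (both
#' boundaries abstain).
#'
#' @param theta_value Numeric vector of probabilities in (0, 1).
#' @param thresholds A [decision_thresholds] object.
#' @return Character vector of labels.
#' @examples
#' classify_theta(c(0.30, 0.50, 0.70))
#' @export
classify_theta <- function(theta_value, thresholds = default_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  if (!is.numeric(theta_value) || anyNA(theta_value) ||
      any(theta_value <= 0 | theta_value >= 1)) {
    abort("`theta_value` must be numeric in (0, 1).")
  }
  out <- rep("no_prediction", length(theta_value))
  out[theta_value > thresholds$t_high] <- "engrafter"
  out[theta_value < thresholds$t_low] <- "nonengrafter"
  out
}

#' Score and classify a cohort table
#'
#' Data-frame-first wrapper composing [theta()] and [classify_theta()]:
#' takes a cohort table with `viability` and `fdf` columns and appends
#' `theta` and `label` columns.
#'
#' @param data A data frame with numeric `viability` (percent) and `fdf`
#'   columns.
#' @inheritParams theta
#' @inheritParams classify_theta
#' @return The input as a tibble with `theta` and `label` columns added.
#' @examples
#' cohort <- tibble::tibble(sample_id = c("a", "b"),
#'                          viability = c(90, 30), fdf = c(4, 1.2))
#' predict_engraftment(cohort)
#' @export
predict_engraftment <- function(data,
                                coefficients = default_coefficients(),
                                thresholds = default_thresholds()) {
  check_columns(data, c("viability", "fdf"), "cohort table")
  out <- as_tibble(data)
  out$theta <- theta(out$viability, out$fdf, coefficients)
  out$label <- classify_theta(out$theta, thresholds)
  out
}

#' Fit the three-term logistic engraftment model
#'
#' Maximum-likelihood fit of the logistic model with exactly the terms
#' intercept, viability, and viability x FDF, by Newton scoring
#' (iteratively reweighted least squares). Convergence is declared when the
#' relative change in log-likelihood falls below `tol` (default 1e-10);
#' standard errors come from the observed information at the optimum.
#' Complete separation (no finite maximum-likelihood estimate) and
#' single-class cohorts are rejected with explicit errors.
#'
#' @param data A data frame with columns `viability`, `fdf`, and `status`
#'   (0/1, logical, or "engrafter"/"nonengrafter"); at least 3 rows and both
#'   classes present.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An `engraftment_fit` object with components `coefficients`
#'   (a [model_coefficients]), `estimates`, `std_errors`, `vcov`, `loglik`,
#'   `iterations`, `converged`, `n`. Has [tidy()] and [glance()] methods.
#' @examples
#' cohort <- simulate_cohort(n_samples = 500, seed = 1)
#' fit <- fit_engraftment_model(cohort)
#' tidy(fit)
#' @export
fit_engraftment_model <- function(data, tol = 1e-10, max_iter = 100L) {
  check_columns(data, c("viability", "fdf", "status"), "cohort table")
  y <- as_binary_status(data$status)
  n <- length(y)
  if (n < 3) abort("Need at least 3 samples to fit the model.")
  if (length(unique(y)) < 2) {
    abort("Cohort contains a single engraftment class; model not identifiable.")
  }
  v <- as.numeric(data$viability)
  f <- as.numeric(data$fdf)
  if (anyNA(v) || anyNA(f) || any(!is.finite(v)) || any(!is.finite(f))) {
    abort("`viability` and `fdf` must be finite.")
  }
  X <- cbind("(Intercept)" = 1, viability = v, "viability:fdf" = v * f)

  beta <- c(0, 0, 0)
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1pexp(eta))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    p <- plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    step <- tryCatch(
      solve(info, crossprod(X, y - p)),
      error = function(e) abort(
        "Information matrix is singular; the model cannot be fitted (possible separation or collinear inputs)."
      )
    )
    beta <- beta + drop(step)
    eta <- drop(X %*% beta)
    ll_new <- sum(y * eta - log1pexp(eta))
    if (ll_new > -1e-6) {
      abort("Complete separation detected: no finite maximum-likelihood estimate.")
    }
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  p <- plogis(eta)
  if (all(abs(y - p) < 1e-8)) {
    abort("Complete separation detected: no finite maximum-likelihood estimate.")
  }
  info <- crossprod(X, X * (p * (1 - p)))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  estimates <- setNames(beta, colnames(X))

  structure(
    list(
      coefficients = model_coefficients(
        intercept = estimates[["(Intercept)"]],
        viability = estimates[["viability"]],
        interaction = estimates[["viability:fdf"]]
      ),
      estimates = estimates,
      std_errors = se,
      vcov = vcov,
      loglik = ll,
      iterations = iter,
      converged = converged,
      n = n
    ),
    class = "engraftment_fit"
  )
}

#' @export
print.engraftment_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic engraftment model (n = %d, logLik = %.4f, %d iterations%s)\n",
    x$n, x$loglik, x$iterations, if (x$converged) "" else ", NOT converged"
  ))
  print(cbind(estimate = x$estimates, std.error = x$std_errors))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.engraftment_fit <- function(x, ...) {
  z <- x$estimates / x$std_errors
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors),
    statistic = unname(z),
    p.value = unname(2 * pnorm(abs(z), lower.tail = FALSE))
  )
}

#' @exportS3Method generics::glance
glance.engraftment_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * length(x$estimates),
    nobs = x$n,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Default threshold grid for FDR sweeps
#'
#' All ordered pairs of multiples of 1/99 in (0, 1). The shipped default
#' decision thresholds (35/99 and 63/99) lie on this grid.
#'
#' @param denominator Grid denominator (default 99).
#' @return A tibble of `(t_low, t_high)` pairs with `t_low < t_high`.
#' @export
threshold_grid <- function(denominator = 99L) {
  ticks <- seq_len(denominator - 1L) / denominator
  grid <- tidyr::expand_grid(t_low = ticks, t_high = ticks)
  dplyr::filter(grid, .data$t_low < .data$t_high)
}

#' Empirical false-discovery-rate sweep over abstention thresholds
#'
#' For each candidate `(t_low, t_high)` pair, classifies every sample in a
#' cohort with known engraftment status and counts false predictions
#' (predicted engrafter but truly nonengrafter, and vice versa). The
#' empirical FDR is false predictions over predictions made (0 when no
#' prediction is made); abstentions are counted separately.
#'
#' @param data Cohort data frame with `viability`, `fdf`, and `status`
#'   columns (true engraftment status).
#' @param coefficients A [model_coefficients] object used to score samples.
#' @param grid Data frame of `(t_low, t_high)` pairs; defaults to
#'   [threshold_grid()].
#' @return An `fdr_sweep` tibble with columns `t_low`, `t_high`,
#'   `n_predicted`, `n_false`, `fdr`, `no_prediction_fraction`.
#' @examples
#' cohort <- simulate_cohort(n_samples = 200, seed = 8)
#' sweep <- fdr_sweep(cohort, grid = tibble::tibble(t_low = 0.3535354,
#'                                                  t_high = 0.6363636))
#' sweep
#' @export
fdr_sweep <- function(data, coefficients = default_coefficients(),
                      grid = threshold_grid()) {
  check_columns(data, c("viability", "fdf", "status"), "cohort table")
  check_columns(grid, c("t_low", "t_high"), "threshold grid")
  if (nrow(grid) == 0) abort("Threshold grid is empty.")
  # grid pairs may touch the domain edges (0 or 1), where every sample
  # abstains; decision_thresholds() itself stays strict
  if (any(grid$t_low >= grid$t_high) ||
      any(grid$t_low < 0) || any(grid$t_high > 1)) {
    abort("Every grid pair must satisfy 0 <= t_low < t_high <= 1.")
  }
  y <- as_binary_status(data$status)
  th <- theta(data$viability, data$fdf, coefficients)
  n <- length(th)

  # Counting via the empirical cdf of theta, split by true status.
  th_e <- sort(th[y == 1])
  th_ne <- sort(th[y == 0])
  n_above <- function(sorted, t) length(sorted) - findInterval(t, sorted)
  n_below <- function(sorted, t) findInterval(t, sorted, left.open = TRUE)

  pred_e <- n_above(th_e, grid$t_high) + n_above(th_ne, grid$t_high)
  pred_ne <- n_below(th_e, grid$t_low) + n_below(th_ne, grid$t_low)
  false_e <- n_above(th_ne, grid$t_high)   # called engrafter, truly NE
  false_ne <- n_below(th_e, grid$t_low)    # called nonengrafter, truly E

  n_predicted <- pred_e + pred_ne
  n_false <- false_e + false_ne
  out <- tibble(
    t_low = grid$t_low,
    t_high = grid$t_high,
    n_predicted = as.integer(n_predicted),
    n_false = as.integer(n_false),
    fdr = ifelse(n_predicted > 0, n_false / n_predicted, 0),
    no_prediction_fraction = (n - n_predicted) / n
  )
  structure(out, class = c("fdr_sweep", class(out)), n_samples = n)
}

#' Calibrate abstention thresholds to an FDR target
#'
#' Among sweep rows with empirical FDR at or below `fdr_target`, returns the
#' pair minimizing the no-prediction fraction; ties are broken by the
#' narrower abstention interval, then by the lower `t_low`. If no pair
#' attains the target, the minimal-FDR pair is returned and the result is
#' flagged (`attr(x, "target_met")` is `FALSE`).
#'
#' @param sweep An [fdr_sweep()] result (non-empty).
#' @param fdr_target Target empirical FDR in (0, 1); default 0.05.
#' @return A [decision_thresholds] object with attributes `target_met`,
#'   `fdr`, and `no_prediction_fraction`.
#' @export
calibrate_thresholds <- function(sweep, fdr_target = 0.05) {
  check_columns(sweep, c("t_low", "t_high", "fdr", "no_prediction_fraction"),
                "threshold sweep")
  if (nrow(sweep) == 0) abort("Threshold sweep is empty.")
  check_scalar_number(fdr_target, "fdr_target")
  ok <- sweep$fdr <= fdr_target
  target_met <- any(ok)
  cand <- if (target_met) sweep[ok, , drop = FALSE] else sweep
  o <- if (target_met) {
    order(cand$no_prediction_fraction, cand$t_high - cand$t_low, cand$t_low)
  } else {
    order(cand$fdr, cand$no_prediction_fraction, cand$t_high - cand$t_low, cand$t_low)
  }
  best <- cand[o[1], , drop = FALSE]
  out <- decision_thresholds(best$t_low, best$t_high)
  attr(out, "target_met") <- target_met
  attr(out, "fdr") <- best$fdr
  attr(out, "no_prediction_fraction") <- best$no_prediction_fraction
  out
}

#' @exportS3Method ggplot2::autoplot
#' @importFrom stats pnorm
autoplot.fdr_sweep <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = 100 * .data$no_prediction_fraction, y = .data$fdr)
  ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(
      x = "Samples with no prediction (%)",
      y = "Empirical false discovery rate",
      title = "Abstention-coverage trade-off of the engraftment classifier"
    ) +
    ggplot2::theme_minimal()
}

#' Decision regions of the engraftment classifier
#'
#' Plots the three-way decision rule over the (viability, FDF) plane:
#' predicted engrafter, predicted nonengrafter, and the abstention zone.
#'
#' @inheritParams predict_engraftment
#' @param viability_range,fdf_range Plot ranges.
#' @param n Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_decision_regions <- function(coefficients = default_coefficients(),
                                  thresholds = default_thresholds(),
                                  viability_range = c(0, 100),
                                  fdf_range = c(1, 8),
                                  n = 200) {
  grid <- tidyr::expand_grid(
    viability = seq(viability_range[1], viability_range[2], length.out = n),
    fdf = seq(fdf_range[1], fdf_range[2], length.out = n)
  )
  grid <- predict_engraftment(grid, coefficients, thresholds)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$viability, y = .data$fdf,
                                     fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      engrafter = "#d7301f", no_prediction = "grey85", nonengrafter = "#2b8cbe"
    )) +
    ggplot2::labs(x = "Day-7 viability (%)", y = "FDF",
                  fill = "Prediction") +
    ggplot2::theme_minimal()
}
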