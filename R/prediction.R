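#' Estimate the equilibrium concentration from the series tail
#'
#' Arithmetic mean of the last `tail` concentrations. Intended for a series
#' that has visibly reached its plateau (typically the fastest-agitated
#' experiment); a warning is issued when the tail still spans more than 10%
#' of its mean, suggesting the kinetics had not yet equilibrated.
#'
#' @param series A [kinetics_series()].
#' @param tail Number of trailing observations to average (default 3).
#' @return Estimated equilibrium concentration (mg/100 g).
#' @examples
#' s <- generate_series(synthetic_spec("page", c(a = 0.3047, b = 0.7336),
#'                                     noise_sigma = 0))
#' estimate_equilibrium(s)  # ~13.1
#' @export
estimate_equilibrium <- function(series, tail = 3L) {
  stopifnot(inherits(series, "kinetics_series"))
  n <- length(series$concentrations)
  if (!is.numeric(tail) || length(tail) != 1L || tail < 1L) {
    stop("`tail` must be a positive integer", call. = FALSE)
  }
  if (tail > n) {
    stop(sprintf("`tail` (%d) exceeds the number of observations (%d)",
                 as.integer(tail), n), call. = FALSE)
  }
  tv <- utils::tail(series$concentrations, tail)
  m <- mean(tv)
  if (tail > 1L && m > 0 && diff(range(tv)) > 0.1 * m) {
    warning(sprintf(
      "tail of '%s' spans %.3g mg/100 g (> 10%% of its mean): series may not have reached equilibrium",
      series$condition_label, diff(range(tv))
    ))
  }
  m
}

#' Extraction-rate curve from a fitted model
#'
#' Samples the instantaneous extraction rate `dX/dt = -x_eq * df/dt`
#' (mg/100 g per minute) over a time grid. Rates are reported with a
#' positive sign (material entering the solvent); the raw signed derivative
#' is available with `signed = TRUE`. Models whose rate diverges at `t = 0`
#' should be sampled from a small positive `t` (the pipeline default starts
#' grids at 0.1 min).
#'
#' @inheritParams evaluate_dimensionless
#' @param x_eq Equilibrium concentration (mg/100 g).
#' @param t_grid Times (minutes, `> 0` for models singular at the origin).
#' @param signed If `TRUE`, return the signed derivative `x_eq * df/dt`
#'   (nonpositive) instead of the positive rate.
#' @return Data frame with columns `time` and `rate`.
#' @export
extraction_rate_curve <- function(model, params, x_eq, t_grid,
                                  signed = FALSE) {
  stopifnot(is.numeric(x_eq), length(x_eq) == 1L, x_eq > 0)
  dfdt <- dimensionless_rate(model, params, t_grid)
  data.frame(
    time = t_grid,
    rate = if (signed) x_eq * dfdt else -x_eq * dfdt
  )
}

#' Process time to reach a fraction of equilibrium
#'
#' Time at which the extracted concentration reaches
#' `fraction * x_eq`, i.e. the closed-form inverse evaluated at
#' `x_star = 1 - fraction`. The conventional industrial target is 97% of
#' equilibrium (`x_star = 0.03`).
#'
#' @inheritParams evaluate_dimensionless
#' @param fraction Target fraction of the equilibrium concentration, in
#'   `(0, 1)`.
#' @return Time in minutes (unrounded; reports round to the nearest minute).
#' @examples
#' time_to_fraction("page", c(a = 0.3047, b = 0.7336), 0.97)  # ~28 min
#' @export
time_to_fraction <- function(model, params, fraction = 0.97) {
  if (!is.numeric(fraction) || any(fraction <= 0) || any(fraction >= 1)) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  time_to_dimensionless(model, params, 1 - fraction)
}

#' Percentage of equilibrium extracted at a given time
#'
#' `100 * (1 - f(t))`: the extracted concentration at time `t` as a
#' percentage of the equilibrium concentration.
#'
#' @inheritParams evaluate_dimensionless
#' @param t Time(s) in minutes, `>= 0`.
#' @return Percentage(s) in `[0, 100]` for the exponential-family models.
#' @examples
#' percent_extracted_at("page", c(a = 0.3047, b = 0.7336), 28)  # ~97.0
#' @export
percent_extracted_at <- function(model, params, t) {
  100 * (1 - evaluate_dimensionless(model, params, t))
}

#' Assemble a prediction report from fitted models
#'
#' For one fitted (or supplied) model per condition, computes the derived
#' quantities of an extraction-kinetics analysis: process time to a target
#' fraction of equilibrium, percentage extracted at a comparison time, and a
#' sampled extraction-rate curve.
#'
#' @param fits Named list (by condition) of `kin_fit` objects, or of lists
#'   with elements `model_id` and `params`.
#' @param x_eq Equilibrium concentration used for rate curves; defaults to
#'   the first fit's `x_eq`.
#' @param fraction Target fraction of equilibrium (default 0.97).
#' @param at_time Comparison time in minutes (default 28).
#' @param t_grid Time grid for rate curves; defaults to 0.1--130 min.
#' @param tail Tail size recorded alongside `x_eq` (metadata).
#' @return A `prediction_report` list with elements `x_eq`, `fraction`,
#'   `at_time`, `process_times` (with both raw minutes and nearest-minute
#'   rounding), `percent_extracted`, and `rate_curves`.
#' @export
prediction_report <- function(fits, x_eq = NULL, fraction = 0.97,
                              at_time = 28, t_grid = seq(0.1, 130, by = 0.5),
                              tail = NA_integer_) {
  stopifnot(length(fits) >= 1L)
  if (inherits(fits, "kin_fit")) fits <- list(fits)
  labels <- names(fits)
  if (is.null(labels)) {
    labels <- vapply(fits, function(f) {
      if (!is.null(f$condition_label)) f$condition_label else "unlabelled"
    }, character(1))
    names(fits) <- labels
  }
  if (is.null(x_eq)) x_eq <- fits[[1]]$x_eq
  stopifnot(is.numeric(x_eq), x_eq > 0)

  times_raw <- vapply(fits, function(f) {
    time_to_fraction(f$model_id, f$params, fraction)
  }, numeric(1))
  pct <- vapply(fits, function(f) {
    percent_extracted_at(f$model_id, f$params, at_time)
  }, numeric(1))
  curves <- lapply(fits, function(f) {
    extraction_rate_curve(f$model_id, f$params, x_eq, t_grid)
  })
  structure(
    list(
      x_eq = x_eq,
      tail = tail,
      fraction = fraction,
      at_time = at_time,
      process_times = data.frame(
        condition = labels,
        model = vapply(fits, function(f) f$model_id, character(1)),
        minutes = unname(times_raw),
        minutes_rounded = round(unname(times_raw)),
        stringsAsFactors = FALSE
      ),
      percent_extracted = data.frame(
        condition = labels,
        model = vapply(fits, function(f) f$model_id, character(1)),
        percent = unname(pct),
        stringsAsFactors = FALSE
      ),
      rate_curves = curves
    ),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_report> x_eq = %.4g mg/100 g; target fraction %.2f; comparison at %g min\n",
    x$x_eq, x$fraction, x$at_time
  ))
  cat("process times (min):\n")
  print.data.frame(x$process_times, digits = 4, row.names = FALSE)
  cat(sprintf("percent extracted at %g min:\n", x$at_time))
  print.data.frame(x$percent_extracted, digits = 4, row.names = FALSE)
  invisible(x)
}
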