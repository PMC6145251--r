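#' Goodness-of-fit indicators
#'
#' Computes the two indicators used to rank fitted models: `chi_square`,
#' defined here as the unweighted residual sum of squares
#' `sum((obs - pred)^2)` (an optional `weights` vector of known
#' per-observation variances turns it into the weighted form
#' `sum((obs - pred)^2 / w)`), and `r_squared = 1 - RSS/TSS` with the total
#' sum of squares taken about the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`
#'   (concentrations, mg/100 g).
#' @param weights Optional positive per-observation variances.
#' @return List with `chi_square` and `r_squared`. For constant observations
#'   (zero total sum of squares) `r_squared` is `NA`.
#' @examples
#' goodness_of_fit(c(0, 1, 2), c(0, 1, 3))  # chi^2 = 1, R^2 = 0.5
#' @export
goodness_of_fit <- function(observed, predicted, weights = NULL) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("`observed` and `predicted` must have equal length >= 2", call. = FALSE)
  }
  res <- observed - predicted
  if (is.null(weights)) {
    chi2 <- sum(res^2)
  } else {
    stopifnot(length(weights) == length(res), all(weights > 0))
    chi2 <- sum(res^2 / weights)
  }
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss == 0) {
    warning("constant observations: total sum of squares is zero, R^2 undefined")
    NA_real_
  } else {
    1 - sum(res^2) / tss
  }
  list(chi_square = chi2, r_squared = r2)
}

# Deterministic, derivative-free initial guesses from linearizations of each
# model. Points with X* <= 0 or >= 1 are excluded from initialization only.
initial_guess <- function(model, times, concentrations, x_eq) {
  model <- kin_model(model)
  xstar <- 1 - concentrations / x_eq
  ok <- times > 0 & xstar > 0 & xstar < 1
  clamp <- function(v, lo = 1e-6) pmax(v, lo)
  lewis_a <- if (sum(ok) >= 1L) {
    # -ln X* = a t through the origin
    y <- -log(xstar[ok]); tt <- times[ok]
    clamp(sum(tt * y) / sum(tt^2))
  } else 0.01
  switch(model$model_id,
    lewis = c(a = lewis_a),
    henderson_pabis = c(a = 1, b = lewis_a),
    silva = c(a = lewis_a, b = 0.01),
    page = {
      if (sum(ok) >= 2L) {
        # log(-ln X*) = log a + b log t
        fit <- stats::lm.fit(cbind(1, log(times[ok])), log(-log(xstar[ok])))
        c(a = clamp(exp(fit$coefficients[[1]])), b = clamp(fit$coefficients[[2]]))
      } else {
        c(a = lewis_a, b = 1)
      }
    },
    peleg = {
      grow <- ok & concentrations > 0
      if (sum(grow) >= 2L) {
        # t / (1 - X*) = a + b t
        y <- times[grow] / (concentrations[grow] / x_eq)
        fit <- stats::lm.fit(cbind(1, times[grow]), y)
        c(a = clamp(fit$coefficients[[1]]), b = clamp(fit$coefficients[[2]]))
      } else {
        c(a = 1 / lewis_a, b = 1)
      }
    }
  )
}

#' Fit an empirical kinetic model to a series
#'
#' Fits `X(t) = x_eq * (1 - f(t, a, b))` to the observed concentrations by
#' bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]),
#' with the equilibrium concentration `x_eq` held fixed. Setting
#' `fix_x_eq = FALSE` frees `x_eq` as an additional parameter for
#' sensitivity analysis. Starting values come from deterministic
#' linearizations of each model, so the fit is reproducible with no random
#' restarts.
#'
#' @param series A [kinetics_series()].
#' @param model Model id or `kin_model`.
#' @param x_eq Equilibrium concentration (mg/100 g); defaults to the
#'   series' own `x_eq` field.
#' @param start Optional named starting values overriding the automatic
#'   initialization.
#' @param fix_x_eq If `FALSE`, `x_eq` is estimated alongside the kinetic
#'   parameters (initialized at the supplied value).
#' @param weights Optional per-observation variances passed to
#'   [goodness_of_fit()].
#' @param control A [minpack.lm::nls.lm.control()] list; the defaults use
#'   relative tolerances `1e-10` and at most `1e4` function evaluations.
#' @return A `kin_fit` object: `model_id`, fitted `params`, `x_eq`,
#'   `chi_square`, `r_squared`, `n_obs`, `converged`, `residuals`, `fitted`,
#'   and the series' `condition_label`.
#' @examples
#' s <- generate_series(synthetic_spec("page", c(a = 0.05, b = 0.9),
#'                                     noise_sigma = 0))
#' fit_kinetics(s, "page", x_eq = 13.1)
#' @export
fit_kinetics <- function(series, model, x_eq = series$x_eq, start = NULL,
                         fix_x_eq = TRUE, weights = NULL,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxfev = 10000,
                           maxiter = 1024)) {
  stopifnot(inherits(series, "kinetics_series"))
  model <- kin_model(model)
  if (is.null(x_eq)) {
    stop("`x_eq` must be supplied (or set on the series); see estimate_equilibrium()",
         call. = FALSE)
  }
  stopifnot(is.numeric(x_eq), length(x_eq) == 1L, x_eq > 0)
  n <- length(series$times)
  if (n < model$n_params + 2L) {
    stop(sprintf(
      "too few observations: %d given, model '%s' needs at least %d",
      n, model$model_id, model$n_params + 2L
    ), call. = FALSE)
  }
  if (all(series$concentrations == 0)) {
    stop("degenerate series: all concentrations are zero, nothing to fit",
         call. = FALSE)
  }

  p0 <- initial_guess(model, series$times, series$concentrations, x_eq)
  if (!is.null(start)) {
    start <- check_params(model, start)
    p0[names(start)] <- start
  }
  lower <- model$param_lower
  if (!fix_x_eq) {
    p0 <- c(p0, x_eq = x_eq)
    lower <- c(lower, x_eq = 1e-10)
  }

  resid_fn <- function(p) {
    xe <- if (fix_x_eq) x_eq else p[["x_eq"]]
    kp <- p[model$param_names]
    series$concentrations - xe * (1 - evaluate_dimensionless(model, kp, series$times))
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, fn = resid_fn,
                            control = control)
  est <- fit$par
  xe_hat <- if (fix_x_eq) x_eq else est[["x_eq"]]
  params <- est[model$param_names]
  fitted <- xe_hat * (1 - evaluate_dimensionless(model, params, series$times))
  gof <- goodness_of_fit(series$concentrations, fitted, weights = weights)
  structure(
    list(
      model_id = model$model_id,
      params = params,
      x_eq = xe_hat,
      x_eq_fixed = fix_x_eq,
      chi_square = gof$chi_square,
      r_squared = gof$r_squared,
      n_obs = n,
      converged = fit$info %in% 1:4,
      residuals = series$concentrations - fitted,
      fitted = fitted,
      condition_label = series$condition_label
    ),
    class = "kin_fit"
  )
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf(
    "<kin_fit> %s on '%s': %s | chi^2 = %.4g, R^2 = %.4f, n = %d%s\n",
    x$model_id, x$condition_label,
    paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
    x$chi_square, x$r_squared, x$n_obs,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

#' Fit several models to one series
#'
#' @inheritParams fit_kinetics
#' @param models Character vector of model ids (default: all five).
#' @param ... Passed on to [fit_kinetics()].
#' @return Named list of `kin_fit` objects.
#' @export
fit_all_models <- function(series, x_eq = series$x_eq,
                           models = kin_model_ids(), ...) {
  stats::setNames(
    lapply(models, function(m) fit_kinetics(series, m, x_eq = x_eq, ...)),
    models
  )
}

#' Rank fitted models by goodness of fit
#'
#' Orders fit results by `chi_square` ascending; ties are broken by
#' `r_squared` descending, then by fewer parameters (parsimony).
#'
#' @param results A list of `kin_fit` objects (possibly across conditions).
#' @return A `kin_ranking` data frame with columns `condition`, `model`,
#'   `a`, `b`, `r_squared`, `chi_square`, `n_params`, `converged` and
#'   `rank` (assigned within each condition).
#' @export
rank_models <- function(results) {
  if (inherits(results, "kin_fit")) results <- list(results)
  if (length(results) < 1L) {
    stop("`results` must contain at least one fit", call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "kin_fit")))
  tab <- do.call(rbind, lapply(results, function(f) {
    data.frame(
      condition = f$condition_label,
      model = f$model_id,
      a = f$params[["a"]],
      b = if ("b" %in% names(f$params)) f$params[["b"]] else NA_real_,
      r_squared = f$r_squared,
      chi_square = f$chi_square,
      n_params = length(f$params),
      converged = f$converged,
      stringsAsFactors = FALSE
    )
  }))
  tab <- do.call(rbind, lapply(split(tab, tab$condition), function(g) {
    ord <- order(g$chi_square, -g$r_squared, g$n_params)
    g <- g[ord, , drop = FALSE]
    g$rank <- seq_len(nrow(g))
    g
  }))
  rownames(tab) <- NULL
  class(tab) <- c("kin_ranking", "data.frame")
  tab
}

#' @export
print.kin_ranking <- function(x, ...) {
  cat("<kin_ranking> models ordered by chi^2 within condition\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
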