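#' Empirical kinetic model registry
#'
#' Five empirical model families are available for describing solid-liquid
#' extraction kinetics in dimensionless form, where the dimensionless
#' concentration `X*(t) = (X - Xeq) / (Xi - Xeq)` decays from 1 at the start
#' of extraction towards 0 at equilibrium:
#'
#' \describe{
#'   \item{lewis}{`exp(-a t)` (one parameter)}
#'   \item{henderson_pabis}{`a exp(-b t)`}
#'   \item{peleg}{`1 - t / (a + b t)`}
#'   \item{page}{`exp(-a t^b)` (stretched exponential)}
#'   \item{silva}{`exp(-a t - b sqrt(t))`}
#' }
#'
#' Every model satisfies `f(0) = 1` except Henderson-Pabis, whose intercept
#' is its own parameter `a`. All parameters are constrained positive; time is
#' in minutes throughout.
#'
#' @param model_id One of `"lewis"`, `"henderson_pabis"`, `"peleg"`,
#'   `"page"`, `"silva"` (or a `kin_model` object, returned unchanged).
#' @return A `kin_model` object: a list with `model_id`, `n_params`,
#'   `param_names`, `param_lower` (lower bounds used during fitting) and
#'   `param_units` metadata.
#' @examples
#' kin_model("page")
#' kin_model_ids()
#' @export
kin_model <- function(model_id) {
  if (inherits(model_id, "kin_model")) {
    return(model_id)
  }
  if (!is.character(model_id) || length(model_id) != 1L) {
    stop("`model_id` must be a single model name string", call. = FALSE)
  }
  reg <- .kin_model_registry()
  if (!model_id %in% names(reg)) {
    stop(sprintf(
      "unknown model '%s'; available models: %s",
      model_id, paste(names(reg), collapse = ", ")
    ), call. = FALSE)
  }
  reg[[model_id]]
}

#' @rdname kin_model
#' @export
kin_model_ids <- function() {
  names(.kin_model_registry())
}

.kin_model_registry <- function() {
  mk <- function(id, params, units) {
    structure(
      list(
        model_id    = id,
        n_params    = length(params),
        param_names = params,
        param_lower = stats::setNames(rep(1e-10, length(params)), params),
        param_units = units
      ),
      class = "kin_model"
    )
  }
  list(
    lewis           = mk("lewis", "a", c(a = "1/min")),
    henderson_pabis = mk("henderson_pabis", c("a", "b"),
                         c(a = "dimensionless", b = "1/min")),
    peleg           = mk("peleg", c("a", "b"),
                         c(a = "min", b = "dimensionless")),
    page            = mk("page", c("a", "b"),
                         c(a = "1/min^b", b = "dimensionless")),
    silva           = mk("silva", c("a", "b"),
                         c(a = "1/min", b = "1/min^(1/2)"))
  )
}

#' @export
print.kin_model <- function(x, ...) {
  cat(sprintf(
    "<kin_model> %s (%d parameter%s: %s)\n",
    x$model_id, x$n_params, if (x$n_params > 1L) "s" else "",
    paste(sprintf("%s [%s]", x$param_names, x$param_units), collapse = ", ")
  ))
  invisible(x)
}

# Validates a parameter vector against a model: named (or positionally
# named), finite, strictly positive, b present iff the model has two
# parameters.
check_params <- function(model, params) {
  model <- kin_model(model)
  params <- unlist(params)
  if (!is.numeric(params)) {
    stop("parameters must be numeric", call. = FALSE)
  }
  if (is.null(names(params)) || all(names(params) == "")) {
    if (length(params) != model$n_params) {
      stop(sprintf(
        "model '%s' takes %d parameter(s) (%s), got %d",
        model$model_id, model$n_params,
        paste(model$param_names, collapse = ", "), length(params)
      ), call. = FALSE)
    }
    names(params) <- model$param_names
  }
  missing <- setdiff(model$param_names, names(params))
  if (length(missing)) {
    stop(sprintf(
      "model '%s' requires parameter(s): %s",
      model$model_id, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  extra <- setdiff(names(params), model$param_names)
  if (length(extra)) {
    stop(sprintf(
      "model '%s' does not take parameter(s): %s",
      model$model_id, paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  params <- params[model$param_names]
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop(sprintf(
      "parameter-domain error: all parameters of '%s' must be finite and > 0 (got %s)",
      model$model_id,
      paste(sprintf("%s = %g", names(params), params), collapse = ", ")
    ), call. = FALSE)
  }
  params
}

check_time <- function(t, allow_zero = TRUE) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric minutes", call. = FALSE)
  }
  if (allow_zero) {
    if (any(t < 0)) stop("parameter-domain error: `t` must be >= 0 min", call. = FALSE)
  } else {
    if (any(t <= 0)) stop("`t` must be > 0 min", call. = FALSE)
  }
  t
}

#' Dimensionless concentration under an empirical kinetic model
#'
#' Evaluates `X* = f(t, a, b)` for one of the registered models.
#' `X*` starts at 1 (Henderson-Pabis: at `a`) and decays towards the model's
#' asymptote: 0 for the exponential-family models, `1 - 1/b` for Peleg.
#'
#' @param model Model id string or `kin_model` object.
#' @param params Named numeric vector of positive parameters (`a`, and `b`
#'   for two-parameter models).
#' @param t Vector of times in minutes, `>= 0`.
#' @return Numeric vector of dimensionless concentrations.
#' @examples
#' evaluate_dimensionless("page", c(a = 0.3047, b = 0.7336), 28)
#' @seealso [dimensionless_rate()], [time_to_dimensionless()]
#' @export
evaluate_dimensionless <- function(model, params, t) {
  model <- kin_model(model)
  p <- check_params(model, params)
  t <- check_time(t, allow_zero = TRUE)
  switch(model$model_id,
    lewis           = exp(-p[["a"]] * t),
    henderson_pabis = p[["a"]] * exp(-p[["b"]] * t),
    peleg           = 1 - t / (p[["a"]] + p[["b"]] * t),
    page            = exp(-p[["a"]] * t^p[["b"]]),
    silva           = exp(-p[["a"]] * t - p[["b"]] * sqrt(t))
  )
}

#' Analytic time derivative of the dimensionless concentration
#'
#' Returns `df/dt` (per minute), which is `<= 0` everywhere on the valid
#' domain: extraction only removes solute from the solid. The Page model
#' with `b < 1` and the Silva model have a `t^(b-1)` / `t^(-1/2)` factor
#' that diverges at `t = 0`; evaluation at 0 is rejected for those models.
#'
#' @inheritParams evaluate_dimensionless
#' @param t Vector of times in minutes; must be `> 0` for models singular at
#'   the origin (page with `b < 1`, silva).
#' @return Numeric vector of nonpositive rates (1/min).
#' @examples
#' dimensionless_rate("lewis", c(a = 0.02843), 1e-9)  # ~ -a
#' @export
dimensionless_rate <- function(model, params, t) {
  model <- kin_model(model)
  p <- check_params(model, params)
  t <- check_time(t, allow_zero = TRUE)
  singular <- switch(model$model_id,
    page  = p[["b"]] < 1,
    silva = TRUE,
    FALSE
  )
  if (singular && any(t == 0)) {
    stop(sprintf(
      "rate of model '%s' is singular at t = 0 (diverges to -Inf); evaluate at t > 0",
      model$model_id
    ), call. = FALSE)
  }
  switch(model$model_id,
    lewis           = -p[["a"]] * exp(-p[["a"]] * t),
    henderson_pabis = -p[["a"]] * p[["b"]] * exp(-p[["b"]] * t),
    peleg           = -p[["a"]] / (p[["a"]] + p[["b"]] * t)^2,
    page            = -p[["a"]] * p[["b"]] * t^(p[["b"]] - 1) *
                        exp(-p[["a"]] * t^p[["b"]]),
    silva           = -(p[["a"]] + p[["b"]] / (2 * sqrt(t))) *
                        exp(-p[["a"]] * t - p[["b"]] * sqrt(t))
  )
}

#' Closed-form inverse: time to reach a dimensionless concentration
#'
#' Solves `f(t) = x_star` for `t` using each model's closed-form inverse:
#' \describe{
#'   \item{lewis}{`t = -ln(x*) / a`}
#'   \item{henderson_pabis}{`t = -ln(x*/a) / b`, requiring `x*/a` in (0, 1]}
#'   \item{peleg}{`t = a (1 - x*) / (1 - b + b x*)`; concentrations beyond
#'     the asymptote `1 - 1/b` are unreachable}
#'   \item{page}{`t = (-ln(x*) / a)^(1/b)`}
#'   \item{silva}{`t = u^2` with `u` the positive root of
#'     `a u^2 + b u + ln(x*) = 0`}
#' }
#'
#' @inheritParams evaluate_dimensionless
#' @param x_star Target dimensionless concentration(s) in `(0, 1]`.
#' @return Time(s) in minutes, `>= 0`.
#' @examples
#' time_to_dimensionless("page", c(a = 0.05171, b = 0.8319), 0.03)  # ~159 min
#' @export
time_to_dimensionless <- function(model, params, x_star) {
  model <- kin_model(model)
  p <- check_params(model, params)
  if (!is.numeric(x_star) || any(!is.finite(x_star)) ||
      any(x_star <= 0) || any(x_star > 1)) {
    stop("`x_star` must lie in (0, 1]", call. = FALSE)
  }
  switch(model$model_id,
    lewis = -log(x_star) / p[["a"]],
    henderson_pabis = {
      r <- x_star / p[["a"]]
      if (any(r > 1)) {
        stop(sprintf(
          "x_star = %g exceeds the henderson_pabis intercept a = %g; time would be negative",
          max(x_star), p[["a"]]
        ), call. = FALSE)
      }
      -log(r) / p[["b"]]
    },
    peleg = {
      den <- 1 - p[["b"]] + p[["b"]] * x_star
      if (any(den <= 0)) {
        stop(sprintf(
          "unreachable concentration: peleg X* approaches its asymptote 1 - 1/b = %g only as t -> Inf; x_star = %g is not attained",
          1 - 1 / p[["b"]], min(x_star)
        ), call. = FALSE)
      }
      p[["a"]] * (1 - x_star) / den
    },
    page = (-log(x_star) / p[["a"]])^(1 / p[["b"]]),
    silva = {
      # positive root of a u^2 + b u + ln(x*) = 0 in u = sqrt(t)
      u <- (-p[["b"]] + sqrt(p[["b"]]^2 - 4 * p[["a"]] * log(x_star))) /
        (2 * p[["a"]])
      u^2
    }
  )
}

# Serializes a validated parameter vector as a flat name -> value list,
# ready for jsonlite.
params_to_list <- function(model, params) {
  as.list(check_params(model, params))
}
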