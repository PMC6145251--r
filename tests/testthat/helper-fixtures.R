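# Shared fixtures: representative valid parameter sets per model (spanning
# slow and fast kinetics) and a central finite-difference rate oracle.

model_param_cases <- function() {
  list(
    lewis           = list(c(a = 0.02843), c(a = 0.1882)),
    henderson_pabis = list(c(a = 0.9465, b = 0.0261), c(a = 1.001, b = 0.176)),
    peleg           = list(c(a = 24.88, b = 0.8592), c(a = 2.978, b = 0.9535)),
    page            = list(c(a = 0.05171, b = 0.8319), c(a = 0.3047, b = 0.7336)),
    silva           = list(c(a = 0.01989, b = 0.04722), c(a = 0.08739, b = 0.2430))
  )
}

fd_rate <- function(model, params, t, h = 1e-4) {
  (evaluate_dimensionless(model, params, t + h) -
     evaluate_dimensionless(model, params, t - h)) / (2 * h)
}

noiseless_page_series <- function(a = 0.05, b = 0.9, x_eq = 13.1) {
  generate_series(synthetic_spec("page", c(a = a, b = b), x_eq = x_eq,
                                 noise_sigma = 0))
}
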