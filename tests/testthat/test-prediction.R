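test_that("equilibrium is the arithmetic mean of the tail", {
  s <- generate_series(synthetic_spec("page", c(a = 0.3047, b = 0.7336),
                                      x_eq = 13.1, noise_sigma = 0))
  expect_equal(estimate_equilibrium(s, tail = 3), 13.1, tolerance = 1e-3)
  # tail = n gives the global mean (and warns: the whole series is no plateau)
  expect_warning(eq_all <- estimate_equilibrium(s, tail = length(s$times)),
                 "equilibrium")
  expect_equal(eq_all, mean(s$concentrations))
  const <- kinetics_series(c(0, 5, 10, 20), rep(7.5, 4))
  expect_equal(estimate_equilibrium(const, tail = 2), 7.5)
  expect_error(estimate_equilibrium(s, tail = 100), "exceeds")
  # a still-rising series triggers the plateau warning
  rising <- kinetics_series(c(0, 10, 20, 30), c(0, 3, 6, 9))
  expect_warning(estimate_equilibrium(rising, tail = 3), "equilibrium")
})

test_that("rate curves scale the dimensionless rate by x_eq with positive sign", {
  x_eq <- 13.1
  # lewis rate at t -> 0 is x_eq * a
  rc <- extraction_rate_curve("lewis", c(a = 0.05), x_eq, c(1e-9, 1, 10))
  expect_equal(rc$rate[1], x_eq * 0.05, tolerance = 1e-8)
  # matches -x_eq times the finite-difference slope of the dimensionless curve
  tgrid <- c(0.5, 2, 10, 40, 100)
  for (m in names(model_param_cases())) {
    p <- model_param_cases()[[m]][[1]]
    rc <- extraction_rate_curve(m, p, x_eq, tgrid)
    expect_equal(rc$rate, -x_eq * fd_rate(m, p, tgrid), tolerance = 1e-5)
    expect_true(all(rc$rate > 0))
    signed <- extraction_rate_curve(m, p, x_eq, tgrid, signed = TRUE)
    expect_equal(signed$rate, -rc$rate)
  }
})

test_that("faster agitation gives higher early rates and decreasing curves", {
  ref <- jambolan_page_params()
  tgrid <- seq(0.1, 130, by = 0.1)
  early <- vapply(seq_len(nrow(ref)), function(i) {
    extraction_rate_curve("page", c(a = ref$a[i], b = ref$b[i]), 13.1, 1)$rate
  }, numeric(1))
  expect_true(all(diff(early) > 0))   # 0 < 50 < 100 < 150 rpm at t = 1 min
  for (i in seq_len(nrow(ref))) {
    rc <- extraction_rate_curve("page", c(a = ref$a[i], b = ref$b[i]), 13.1, tgrid)
    expect_true(all(diff(rc$rate) < 0))
    expect_true(all(rc$rate >= 0))
  }
})

test_that("process times and percentages agree with the closed forms", {
  expect_equal(round(time_to_fraction("page", c(a = 0.05171, b = 0.8319), 0.97)),
               159)
  expect_equal(round(time_to_fraction("page", c(a = 0.06161, b = 0.9027), 0.97)),
               88)
  expect_equal(round(time_to_fraction("page", c(a = 0.1486, b = 0.7538), 0.97)),
               66)
  expect_equal(percent_extracted_at("page", c(a = 0.05171, b = 0.8319), 28),
               56.3, tolerance = 1e-3)
  expect_equal(percent_extracted_at("page", c(a = 0.06161, b = 0.9027), 28),
               71.3, tolerance = 1e-3)
  expect_equal(percent_extracted_at("lewis", c(a = 0.1), 0), 0)
  expect_error(time_to_fraction("page", c(a = 0.1, b = 0.8), 1), "\\(0, 1\\)")
})

test_that("time_to_fraction and percent_extracted_at are mutually consistent", {
  for (m in names(model_param_cases())) {
    p <- model_param_cases()[[m]][[1]]
    if (m == "henderson_pabis" && p[["a"]] < 1) {
      fracs <- seq(1 - p[["a"]] + 0.01, 0.99, length.out = 20)
    } else if (m == "peleg") {
      # stay above the model's reachable asymptote
      reach_max <- 1 - max(0, 1 - 1 / p[["b"]])
      fracs <- seq(0.05, min(0.99, reach_max - 0.01), length.out = 20)
    } else {
      fracs <- seq(0.01, 0.99, length.out = 20)
    }
    t_at <- time_to_fraction(m, p, fracs)
    expect_equal(percent_extracted_at(m, p, t_at), 100 * fracs,
                 tolerance = 1e-6)
  }
  # small target fractions give vanishing times
  expect_lt(time_to_fraction("page", c(a = 0.3, b = 0.73), 1e-6), 1e-3)
})

test_that("prediction_report collates times, percentages and rate curves", {
  ref <- jambolan_page_params()
  fits <- lapply(seq_len(nrow(ref)), function(i) {
    list(model_id = "page", params = c(a = ref$a[i], b = ref$b[i]),
         x_eq = 13.1, condition_label = ref$condition[i])
  })
  names(fits) <- ref$condition
  rep <- prediction_report(fits, x_eq = 13.1)
  expect_equal(rep$process_times$minutes_rounded, c(159, 88, 66, 28))
  expect_equal(round(rep$percent_extracted$percent, 1), c(56.3, 71.3, 84.0, 97.0))
  expect_true(all(rep$percent_extracted$percent >= 0 &
                    rep$percent_extracted$percent <= 100))
  expect_true(all(rep$process_times$minutes > 0))
  expect_true(all(vapply(rep$rate_curves, function(rc) all(rc$rate >= 0),
                         logical(1))))
})
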