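test_that("goodness_of_fit computes unweighted chi-square and R^2", {
  g <- goodness_of_fit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(g$chi_square, 1)
  expect_equal(g$r_squared, 0.5)
  perfect <- goodness_of_fit(c(2, 5, 9), c(2, 5, 9))
  expect_equal(perfect$chi_square, 0)
  expect_equal(perfect$r_squared, 1)
  expect_warning(g0 <- goodness_of_fit(c(3, 3, 3), c(3, 3, 2)), "constant")
  expect_true(is.na(g0$r_squared))
  # optional known variances give the weighted form
  gw <- goodness_of_fit(c(0, 1, 2), c(0, 1, 3), weights = c(1, 1, 4))
  expect_equal(gw$chi_square, 0.25)
})

test_that("chi-square is permutation-invariant and scales quadratically", {
  obs <- c(0, 3.1, 6.4, 9.2, 11.5)
  pred <- c(0.2, 3.0, 6.0, 9.5, 11.3)
  g <- goodness_of_fit(obs, pred)
  perm <- c(4, 1, 5, 2, 3)
  expect_equal(goodness_of_fit(obs[perm], pred[perm])$chi_square, g$chi_square)
  g10 <- goodness_of_fit(10 * obs, 10 * pred)
  expect_equal(g10$chi_square, 100 * g$chi_square)
  expect_equal(g10$r_squared, g$r_squared)
})

test_that("noiseless series are recovered to numerical precision by every model", {
  x_eq <- 13.1
  truth <- list(
    lewis = c(a = 0.08),
    henderson_pabis = c(a = 0.95, b = 0.07),
    peleg = c(a = 14, b = 0.9),
    page = c(a = 0.05, b = 0.9),
    silva = c(a = 0.03, b = 0.05)
  )
  for (m in names(truth)) {
    s <- generate_series(synthetic_spec(m, truth[[m]], x_eq = x_eq,
                                        noise_sigma = 0))
    f <- fit_kinetics(s, m, x_eq = x_eq)
    expect_true(f$converged)
    expect_equal(f$params, truth[[m]], tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
    expect_lt(f$chi_square, 1e-15 * f$n_obs)
  }
})

test_that("fitting page to a lewis-generated series drives b to 1", {
  s <- generate_series(synthetic_spec("lewis", c(a = 0.1), noise_sigma = 0))
  f <- fit_kinetics(s, "page", x_eq = 13.1)
  expect_equal(f$params[["a"]], 0.1, tolerance = 1e-4)
  expect_equal(f$params[["b"]], 1, tolerance = 1e-4)
})

test_that("refitting from the optimum is a fixed point of the optimizer", {
  s <- generate_series(synthetic_spec("page", c(a = 0.06, b = 0.85),
                                      noise_sigma = 0.2, seed = 7))
  f1 <- fit_kinetics(s, "page", x_eq = 13.1)
  f2 <- fit_kinetics(s, "page", x_eq = 13.1, start = f1$params)
  expect_equal(f2$chi_square, f1$chi_square, tolerance = 1e-10)
})

test_that("mean recovered parameters are within 10% of truth at sigma = 0.2", {
  truth <- c(a = 0.05, b = 0.9)
  fits <- vapply(1:100, function(seed) {
    s <- generate_series(synthetic_spec("page", truth, noise_sigma = 0.2,
                                        seed = seed))
    fit_kinetics(s, "page", x_eq = 13.1)$params
  }, numeric(2))
  means <- rowMeans(fits)
  expect_lt(abs(means[["a"]] - truth[["a"]]) / truth[["a"]], 0.10)
  expect_lt(abs(means[["b"]] - truth[["b"]]) / truth[["b"]], 0.10)
})

test_that("recovery bias shrinks as measurement noise shrinks", {
  truth <- c(a = 0.06, b = 0.85)
  bias_at <- function(sigma) {
    fits <- vapply(1:30, function(seed) {
      s <- generate_series(synthetic_spec("page", truth, noise_sigma = sigma,
                                          seed = 1000 + seed))
      fit_kinetics(s, "page", x_eq = 13.1)$params
    }, numeric(2))
    sum(abs(rowMeans(fits) - truth) / truth)
  }
  b <- vapply(c(0.5, 0.1, 0.02), bias_at, numeric(1))
  expect_true(b[3] < b[1])
  expect_lt(b[3], 0.01)
})

test_that("freeing x_eq recovers the generating equilibrium on clean data", {
  s <- generate_series(synthetic_spec("page", c(a = 0.2, b = 0.8),
                                      x_eq = 13.1, noise_sigma = 0))
  f <- fit_kinetics(s, "page", x_eq = 10, fix_x_eq = FALSE)
  expect_equal(f$x_eq, 13.1, tolerance = 1e-5)
  expect_equal(f$params, c(a = 0.2, b = 0.8), tolerance = 1e-5)
})

test_that("degenerate and undersized inputs are rejected before fitting", {
  zero <- kinetics_series(c(0, 10, 20, 30, 40), rep(0, 5))
  expect_error(fit_kinetics(zero, "page", x_eq = 13.1), "degenerate")
  tiny <- kinetics_series(c(0, 10, 20), c(0, 5, 8))
  expect_error(fit_kinetics(tiny, "page", x_eq = 13.1), "too few observations")
  full <- kinetics_series(c(0, 10, 20, 40), c(0, 5, 8, 10))
  expect_error(fit_kinetics(full, "page"), "x_eq")
})

test_that("rank_models orders by chi-square with R^2 and parsimony tie-breaks", {
  mkfit <- function(model, chi2, r2, np) {
    structure(list(model_id = model, params = stats::setNames(rep(0.1, np),
                                                              c("a", "b")[1:np]),
                   x_eq = 13.1, chi_square = chi2, r_squared = r2,
                   n_obs = 19L, converged = TRUE, residuals = numeric(0),
                   fitted = numeric(0), condition_label = "c1"),
              class = "kin_fit")
  }
  r <- rank_models(list(mkfit("lewis", 2.0, 0.99, 1),
                        mkfit("page", 1.0, 0.995, 2),
                        mkfit("silva", 1.0, 0.997, 2)))
  expect_equal(r$model, c("silva", "page", "lewis"))   # chi2 tie -> higher R^2
  expect_equal(r$rank, 1:3)
  # equal chi2 and R^2 -> fewer parameters first
  r2 <- rank_models(list(mkfit("page", 1.0, 0.99, 2), mkfit("lewis", 1.0, 0.99, 1)))
  expect_equal(r2$model, c("lewis", "page"))
  # single result is rank 1
  expect_equal(rank_models(mkfit("peleg", 3, 0.9, 2))$rank, 1L)
  expect_error(rank_models(list()), "at least one")
})

test_that("the generating model wins the ranking on low-noise data", {
  wins <- vapply(1:100, function(seed) {
    s <- generate_series(synthetic_spec("page", c(a = 0.3047, b = 0.7336),
                                        noise_sigma = 0.05, seed = seed))
    fits <- fit_all_models(s, x_eq = 13.1)
    rank_models(fits)$model[1] == "page"
  }, logical(1))
  expect_gte(sum(wins), 90)
})
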