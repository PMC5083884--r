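test_that("power fitter recovers exact curves and validates input", {
  s <- growth_series(c(1, 2, 3, 4), c(1, 2, 3, 4), variable = "y")
  m <- fit_power(s, growth_series(c(1, 2, 3, 4), c(1, 2, 3, 4), variable = "x"))
  expect_equal(m$a, 1, tolerance = 1e-12)
  expect_equal(m$b, 1, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_power(growth_series(1:3, c(1, -2, 3))), "non-positive")
  expect_error(fit_power(growth_series(1:2, 1:2)), "insufficient")
  expect_error(growth_series(c(0, 1), c(1, 1)), "positive")
})

test_that("published reference equations round-trip through the fitters", {
  tab <- reference_growth_models()
  expect_identical(nrow(tab), 10L)
  for (i in seq_len(nrow(tab))) {
    sp <- tab$species[i]
    m <- reference_model(sp, tab$source[i])
    s <- simulate_series(m, reference_days(sp))
    fit <- if (m$family == "power") fit_power(s) else fit_log(s)
    expect_equal(fit$a, m$a, tolerance = 1e-6)
    expect_equal(fit$b, m$b, tolerance = 1e-6)
  }
})

test_that("log-log OLS agrees with a direct nonlinear least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  truth <- structure(list(family = "power", a = 0.002, b = 1.75,
                          r_squared = NA_real_, x_label = "time",
                          y_label = "biomass", x_range = c(5, 60)),
                     class = "growth_model")
  s <- simulate_series(truth, seq(5, 60, length.out = 20),
                       noise_sigma = 0.1, seed = 99)
  ours <- fit_power(s)
  orac <- minpack.lm::nlsLM(v ~ a * t^b,
                            data = data.frame(t = s$day, v = s$value),
                            start = list(a = 0.001, b = 1.5))
  ci <- suppressMessages(stats::confint(orac, level = 0.95))
  expect_gte(ours$b, ci["b", 1])
  expect_lte(ours$b, ci["b", 2])
  expect_gte(ours$a, ci["a", 1])
  expect_lte(ours$a, ci["a", 2])
})

test_that("log fitter handles exact, noisy and degenerate series", {
  t <- c(2, 5, 9, 20)
  m <- fit_log(growth_series(t, log(t), variable = "y"))
  expect_equal(m$a, 1, tolerance = 1e-10)
  expect_equal(m$b, 0, tolerance = 1e-10)

  const <- fit_log(growth_series(t, rep(3.5, 4), variable = "y"))
  expect_equal(const$a, 0, tolerance = 1e-12)
  expect_equal(const$b, 3.5, tolerance = 1e-12)
  expect_true(is.na(const$r_squared))
})

test_that("prediction evaluates each family and rejects x <= 0", {
  pw <- structure(list(family = "power", a = 1, b = 2, r_squared = NA_real_,
                       x_label = "x", y_label = "y"), class = "growth_model")
  expect_equal(predict(pw, 3), 9)
  pw$a <- 2; pw$b <- 0
  expect_equal(predict(pw, c(0.5, 17)), c(2, 2))
  lg <- structure(list(family = "log", a = 1, b = 0, r_squared = NA_real_,
                       x_label = "x", y_label = "y"), class = "growth_model")
  expect_equal(predict(lg, exp(1)), 1)
  expect_error(predict(pw, -1), "positive")
})

test_that("power-power composition closed form matches pointwise chaining", {
  outer <- structure(list(family = "power", a = 2, b = 2, r_squared = NA_real_,
                          x_label = "height", y_label = "biomass",
                          x_range = c(1, 20)), class = "growth_model")
  inner <- structure(list(family = "power", a = 3, b = 1, r_squared = NA_real_,
                          x_label = "time", y_label = "height",
                          x_range = c(1, 50)), class = "growth_model")
  comp <- compose_models(outer, inner)
  expect_equal(comp$a, 18)
  expect_equal(comp$b, 2)
  expect_true(is.na(comp$r_squared))
  # identity outer leaves the inner model unchanged
  ident <- structure(list(family = "power", a = 1, b = 1, r_squared = NA_real_,
                          x_label = "height", y_label = "biomass"),
                     class = "growth_model")
  same <- compose_models(ident, inner)
  expect_equal(same$a, inner$a)
  expect_equal(same$b, inner$b)
  # closed form vs pointwise chaining on a grid
  xs <- seq(0.3, 60, length.out = 100)
  expect_equal(predict(comp, xs), predict(outer, predict(inner, xs)),
               tolerance = 1e-12)
  expect_error(compose_models(outer,
    structure(list(family = "power", a = 1, b = 1, r_squared = NA_real_,
                   x_label = "time", y_label = "greenness"),
              class = "growth_model")), "label mismatch")
})

test_that("power-over-log composition is fit numerically on the inner range", {
  lg <- structure(list(family = "log", a = 0.3118, b = -0.884,
                       r_squared = NA_real_, x_label = "time",
                       y_label = "greenness", x_range = c(21, 49)),
                  class = "growth_model")
  pw <- structure(list(family = "power", a = 0.5, b = 1.2,
                       r_squared = NA_real_, x_label = "greenness",
                       y_label = "biomass"), class = "growth_model")
  comp <- compose_models(pw, lg)
  expect_identical(comp$family, "power")
  # oracle: the log-log least-squares power fit of the exact chain on the
  # same sampling grid
  grid <- seq(21, 49, length.out = 100)
  exact <- predict(pw, predict(lg, grid))
  ols <- lm(log(exact) ~ log(grid))
  expect_equal(comp$a, exp(unname(coef(ols)[1])), tolerance = 1e-9)
  expect_equal(comp$b, unname(coef(ols)[2]), tolerance = 1e-9)
  # unsupported family pair with consistent labels
  lg2 <- structure(list(family = "log", a = 1, b = 0, r_squared = NA_real_,
                        x_label = "greenness", y_label = "biomass"),
                   class = "growth_model")
  pw2 <- structure(list(family = "power", a = 1, b = 1, r_squared = NA_real_,
                        x_label = "time", y_label = "greenness",
                        x_range = c(1, 10)), class = "growth_model")
  expect_error(compose_models(lg2, pw2), "unsupported")
})

test_that("relative RMSE and bias follow their closed forms and invariants", {
  t <- c(10, 20, 30, 40)
  y <- growth_series(t, c(2, 4, 7, 11), variable = "biomass")
  x <- growth_series(t, t, variable = "time")
  # a model predicting exactly the observations
  perfect <- fit_power(y, x)
  yhat <- predict(perfect, t)
  # build observations equal to predictions: zero error
  y0 <- growth_series(t, yhat, variable = "biomass")
  m0 <- evaluate_model(perfect, x, y0)
  expect_equal(m0$rmse_pct, 0, tolerance = 1e-9)
  expect_equal(m0$bias_pct, 0, tolerance = 1e-9)
  # predictions offset by exactly 10% of the observed mean: both metrics 10
  mu <- mean(yhat) / 1.1   # so that mean(obs) = mu and yhat = obs + 0.1 mu
  off <- growth_series(t, yhat - 0.1 * mu, variable = "biomass")
  m10 <- evaluate_model(perfect, x, off)
  expect_equal(m10$rmse_pct, 10, tolerance = 1e-9)
  expect_equal(m10$bias_pct, 10, tolerance = 1e-9)

  # random residuals: rmse >= |bias|, and scale invariance
  set.seed(8)
  for (i in 1:10) {
    obs <- growth_series(t, yhat * exp(rnorm(4, 0, 0.2)), variable = "biomass")
    m <- evaluate_model(perfect, x, obs)
    expect_gte(m$rmse_pct, abs(m$bias_pct))
    k <- runif(1, 0.1, 9)
    scaled_model <- perfect; scaled_model$a <- perfect$a * k
    obs_k <- growth_series(t, obs$value * k, variable = "biomass")
    mk <- evaluate_model(scaled_model, x, obs_k)
    expect_equal(mk$rmse_pct, m$rmse_pct, tolerance = 1e-9)
    expect_equal(mk$bias_pct, m$bias_pct, tolerance = 1e-9)
  }
  zero <- growth_series(t, c(-1, 1, -1, 1), variable = "biomass")
  expect_error(evaluate_model(perfect, x, zero), "undefined")
})

test_that("random power models round-trip from noise-free samples", {
  set.seed(17)
  for (i in 1:20) {
    a <- exp(runif(1, -8, 2)); b <- runif(1, -2, 3)
    truth <- structure(list(family = "power", a = a, b = b,
                            r_squared = NA_real_, x_label = "time",
                            y_label = "y"), class = "growth_model")
    d <- sort(runif(5, 1, 60))
    fit <- fit_power(simulate_series(truth, d))
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    lt <- structure(list(family = "log", a = b, b = a, r_squared = NA_real_,
                         x_label = "time", y_label = "y"),
                    class = "growth_model")
    lfit <- fit_log(simulate_series(lt, d))
    expect_equal(lfit$a, b, tolerance = 1e-6)
    expect_equal(lfit$b, a, tolerance = 1e-6)
  }
})

test_that("growth CSV and model JSON round-trip through their readers", {
  s <- growth_series(c(14, 21, 28, 42), c(0.02, 0.05, 0.11, 0.3),
                     variable = "biomass", species = "Picea abies")
  f <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(s, f)
  back <- as_growth_series(read_growth_csv(f), "biomass", "Picea abies")
  expect_equal(back$day, s$day)
  expect_equal(back$value, s$value)

  m <- fit_power(s)
  fj <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, fj)
  m2 <- read_model_json(fj)
  expect_equal(m2$a, m$a, tolerance = 1e-12)
  expect_equal(m2$b, m$b, tolerance = 1e-12)
  expect_identical(m2$family, "power")
})
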