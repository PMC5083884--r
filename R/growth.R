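#' Growth time-series
#'
#' One measured variable of one species over time: pairs of (day, value),
#' e.g. total biomass (g), plant height (cm) or greenness (%) at each
#' sampling date.
#'
#' @param day sampling times in days, strictly positive.
#' @param value measurements, same length as `day`.
#' @param variable label of the measured variable (e.g. `"biomass"`).
#' @param species species label.
#' @return an object of class `growth_series`.
#' @export
growth_series <- function(day, value, variable = "value", species = "") {
  day <- as.numeric(day); value <- as.numeric(value)
  if (length(day) != length(value))
    tv_data_error("growth_series: day and value lengths differ")
  if (anyNA(day) || anyNA(value))
    tv_data_error("growth_series: missing values are not allowed")
  if (any(day <= 0))
    tv_data_error("growth_series: all sampling times must be positive days")
  structure(list(day = day, value = value, variable = as.character(variable),
                 species = as.character(species)),
            class = "growth_series")
}

# a series whose value is time itself, for trait-over-time fits
time_axis <- function(series) {
  growth_series(series$day, series$day, variable = "time",
                species = series$species)
}

check_pair <- function(x, y, min_n, positive_x = TRUE, positive_y = TRUE) {
  stopifnot(inherits(x, "growth_series"), inherits(y, "growth_series"))
  if (length(x$day) != length(y$day) || !isTRUE(all.equal(x$day, y$day)))
    tv_data_error("series are not paired: sampling days differ")
  n <- length(x$value)
  if (n < min_n)
    tv_data_error(sprintf("insufficient data: %d records, need >= %d", n, min_n))
  if (positive_x && any(x$value <= 0))
    tv_data_error(sprintf("non-positive x value at day %g", x$day[which(x$value <= 0)[1]]))
  if (positive_y && any(y$value <= 0))
    tv_data_error(sprintf("non-positive y value at day %g", y$day[which(y$value <= 0)[1]]))
  n
}

new_growth_model <- function(family, a, b, r_squared, x_label, y_label,
                             x_range = NULL) {
  if (family == "power" && a <= 0)
    tv_data_error("growth_model: power family requires a > 0")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    tv_data_error("growth_model: r_squared must be in [0, 1] or NA")
  structure(list(family = family, a = a, b = b, r_squared = r_squared,
                 x_label = x_label, y_label = y_label, x_range = x_range),
            class = "growth_model")
}

#' Fit an allometric power-law model
#'
#' Fits `y = a * x^b` by ordinary least squares on the log-log scale
#' (`ln y ~ ln x`), the standard allometric procedure: `a` is the
#' exponentiated intercept, `b` the slope, and the coefficient of
#' determination is reported on the fitting (log) scale. Noise-free data on
#' a power curve is recovered exactly.
#'
#' @param y `growth_series` of the response (e.g. biomass).
#' @param x `growth_series` of the predictor, paired with `y` by sampling
#'   day. Omitted: time itself is the predictor.
#' @return a `growth_model` of family `"power"`.
#' @export
fit_power <- function(y, x = NULL) {
  if (is.null(x)) x <- time_axis(y)
  check_pair(x, y, min_n = 3L)
  fit <- lm(log(y$value) ~ log(x$value))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_growth_model("power", a = unname(exp(coef(fit)[1])),
                   b = unname(coef(fit)[2]),
                   r_squared = if (is.finite(r2)) r2 else NA_real_,
                   x_label = x$variable, y_label = y$variable,
                   x_range = range(x$value))
}

#' Fit a logarithmic model
#'
#' Fits `y = a * ln(x) + b` by ordinary least squares on `(ln x, y)`; `a`
#' is the slope, `b` the intercept. With constant `y` the slope is 0, the
#' intercept the mean, and the coefficient of determination undefined
#' (reported `NA`).
#'
#' @inheritParams fit_power
#' @return a `growth_model` of family `"log"`.
#' @export
fit_log <- function(y, x = NULL) {
  if (is.null(x)) x <- time_axis(y)
  check_pair(x, y, min_n = 3L, positive_y = FALSE)
  fit <- lm(y$value ~ log(x$value))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_growth_model("log", a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                   r_squared = if (is.finite(r2)) r2 else NA_real_,
                   x_label = x$variable, y_label = y$variable,
                   x_range = range(x$value))
}

#' Evaluate a growth model at new predictor values
#'
#' @param object a `growth_model`.
#' @param x positive predictor values.
#' @param ... unused.
#' @return predicted response values.
#' @export
predict.growth_model <- function(object, x, ...) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x) || any(x <= 0))
    tv_data_error("predict: x must be positive")
  switch(object$family,
         power = object$a * x^object$b,
         log = object$a * log(x) + object$b,
         tv_data_error(paste0("unknown model family: ", object$family)))
}

#' @export
print.growth_model <- function(x, ...) {
  cat(format_model_equation(x), "\n")
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f (fitting scale)\n", x$r_squared))
  invisible(x)
}

#' Display form of a growth model equation
#'
#' @param model a `growth_model`.
#' @return a string such as `"biomass = 2e-05 x time^1.8344"`.
#' @export
format_model_equation <- function(model) {
  xl <- if (nzchar(model$x_label)) model$x_label else "x"
  yl <- if (nzchar(model$y_label)) model$y_label else "y"
  if (model$family == "power")
    sprintf("%s = %.6g × %s^%.4f", yl, model$a, xl, model$b)
  else
    sprintf("%s = %.4f × ln(%s) %s %.4f", yl, model$a, xl,
            if (model$b < 0) "−" else "+", abs(model$b))
}

#' Compose biomass-vs-trait with trait-vs-time models
#'
#' Builds the growth model `biomass = f(g(time))` from an allometric outer
#' model `biomass = f(trait)` and an inner model `trait = g(time)`. The
#' labels must chain (`inner$y_label == outer$x_label`). Two power models
#' compose in closed form: outer `(a1, b1)` over inner `(c, d)` gives
#' `a1 * c^b1 * x^(b1 d)`, with the coefficient of determination reported
#' absent. A power outer over a log inner has no closed form in either
#' family; the composition is sampled on a time grid and refit as a power
#' model.
#'
#' @param outer,inner `growth_model`s.
#' @param grid time grid for the numeric path; defaults to 100 points
#'   spanning the inner model's fitted range.
#' @return a `growth_model`.
#' @export
compose_models <- function(outer, inner, grid = NULL) {
  stopifnot(inherits(outer, "growth_model"), inherits(inner, "growth_model"))
  if (!identical(inner$y_label, outer$x_label))
    tv_data_error(sprintf(
      "compose_models: label mismatch, inner predicts '%s' but outer expects '%s'",
      inner$y_label, outer$x_label))
  if (outer$family == "power" && inner$family == "power") {
    return(new_growth_model("power", a = outer$a * inner$a^outer$b,
                            b = outer$b * inner$b, r_squared = NA_real_,
                            x_label = inner$x_label, y_label = outer$y_label,
                            x_range = inner$x_range))
  }
  if (outer$family == "power" && inner$family == "log") {
    if (is.null(grid)) {
      if (is.null(inner$x_range))
        tv_data_error("compose_models: supply a time grid (inner model has no fitted range)")
      grid <- seq(inner$x_range[1], inner$x_range[2], length.out = 100)
    }
    trait <- predict(inner, grid)
    if (any(trait <= 0))
      tv_data_error("compose_models: inner model non-positive on the grid")
    yy <- growth_series(grid, outer$a * trait^outer$b,
                        variable = outer$y_label)
    m <- fit_power(yy, growth_series(grid, grid, variable = inner$x_label))
    m$r_squared <- NA_real_
    return(m)
  }
  tv_data_error(sprintf("compose_models: unsupported family pair %s(%s)",
                        outer$family, inner$family))
}

#' Relative RMSE and bias of model predictions
#'
#' Compares model predictions against observations, both normalized by the
#' observed mean and expressed as percentages:
#' `RMSE% = 100 * sqrt(mean((pred - obs)^2)) / mean(obs)` and
#' `BIAS% = 100 * mean(pred - obs) / mean(obs)`. Evaluation is restricted
#' to predictors inside the observed range (no extrapolation); with the
#' observed pairs themselves that is all of them. `RMSE% >= |BIAS%|`
#' always, and both are invariant to rescaling observed and predicted
#' values together.
#'
#' @param model a `growth_model` predicting `y` from `x`.
#' @param x `growth_series` of observed predictor values.
#' @param y `growth_series` of observed responses, paired with `x`.
#' @return an object of class `eval_metrics`: `rmse_pct`, `bias_pct`, `n`,
#'   `x_range`.
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "growth_model"))
  check_pair(x, y, min_n = 1L, positive_y = FALSE)
  keep <- x$value >= min(x$value) & x$value <= max(x$value)
  xv <- x$value[keep]; yv <- y$value[keep]
  if (mean(yv) == 0)
    tv_data_error("evaluate_model: observed mean is zero, relative metrics undefined")
  pred <- predict(model, xv)
  err <- pred - yv
  structure(list(rmse_pct = 100 * sqrt(mean(err^2)) / mean(yv),
                 bias_pct = 100 * mean(err) / mean(yv),
                 n = length(yv), x_range = range(xv)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("RMSE%% = %.2f, BIAS%% = %.2f (n = %d, x in [%g, %g])\n",
              x$rmse_pct, x$bias_pct, x$n, x$x_range[1], x$x_range[2]))
  invisible(x)
}

# ---- CSV / JSON interchange --------------------------------------------

#' Read / write long-format growth CSV
#'
#' The interchange format for series: columns `species`, `day`, `variable`,
#' `value`, one row per measurement.
#'
#' @param path CSV file path.
#' @param series a `growth_series` (for writing).
#' @param species,variable filters used when extracting one series.
#' @return `read_growth_csv()` returns the full data frame;
#'   `as_growth_series()` extracts one `growth_series` from it.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) tv_data_error(paste0("cannot read CSV: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "day", "variable", "value")
  if (!all(need %in% names(df)))
    tv_data_error(paste0("growth CSV must have columns: ",
                         paste(need, collapse = ", ")))
  df
}

#' @rdname read_growth_csv
#' @param df a data frame as returned by `read_growth_csv()`.
#' @export
as_growth_series <- function(df, variable, species = NULL) {
  rows <- df$variable == variable
  if (!is.null(species)) rows <- rows & df$species == species
  if (!any(rows))
    tv_data_error(sprintf("no rows with variable '%s'%s", variable,
                          if (is.null(species)) "" else paste0(" and species '", species, "'")))
  sub <- df[rows, ]
  sub <- sub[order(sub$day), ]
  growth_series(sub$day, sub$value, variable = variable,
                species = if (is.null(species)) sub$species[1] else species)
}

#' @rdname read_growth_csv
#' @export
write_growth_csv <- function(series, path) {
  stopifnot(inherits(series, "growth_series"))
  write.csv(data.frame(species = series$species, day = series$day,
                       variable = series$variable, value = series$value),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write a growth model as JSON
#'
#' @param model a `growth_model`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "growth_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) tv_data_error(paste0("cannot read model JSON: ", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_growth_model(m$family, m$a, m$b,
                   if (is.null(m$r_squared)) NA_real_ else m$r_squared,
                   m$x_label, m$y_label,
                   if (is.null(m$x_range)) NULL else as.numeric(m$x_range))
}

#' Reference allometric growth equations
#'
#' The published biomass growth equations for seedlings of four tree
#' species (Picea abies, Pinus sylvestris, Fagus sylvatica, Quercus ilex)
#' that ship with the package: for each species the model fitted to
#' destructively measured biomass and the models predicted from the
#' optical height and greenness traits, together with the species'
#' sampling days. Power rows are `biomass = a * time^b`; log rows are
#' `biomass = a * ln(time) + b`. These equations are the quantitative
#' backbone of the package's round-trip tests and of
#' [simulate_series()] defaults.
#'
#' @return a data frame with columns `species`, `source` (`measured`,
#'   `greenness`, `height`), `family`, `a`, `b`, `r_squared`,
#'   `sampling_days` (semicolon-separated).
#' @export
reference_growth_models <- function() {
  path <- system.file("extdata", "reference_growth_models.csv",
                      package = "trayvision", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_growth_models
#' @param species,source row selectors.
#' @return `reference_model()` returns the selected row as a
#'   `growth_model` (with the sampling days as `x_range` endpoints);
#'   `reference_days()` the species' sampling days.
#' @export
reference_model <- function(species, source = "measured") {
  tab <- reference_growth_models()
  row <- tab[tab$species == species & tab$source == source, ]
  if (nrow(row) != 1L)
    tv_data_error(sprintf("no reference model for %s / %s", species, source))
  days <- reference_days(species)
  new_growth_model(row$family, row$a, row$b, row$r_squared,
                   x_label = "time", y_label = "biomass",
                   x_range = range(days))
}

#' @rdname reference_growth_models
#' @export
reference_days <- function(species) {
  tab <- reference_growth_models()
  row <- tab[tab$species == species, ]
  if (nrow(row) == 0L) tv_data_error(paste0("unknown species: ", species))
  as.numeric(strsplit(row$sampling_days[1], ";")[[1]])
}
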