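# Regression-based inference on campaign/plot mean fluxes:
# reference-year efflux-temperature fits, drought-year residuals and
# percent-of-expected, linear-vs-exponential model comparison, between-species
# growth-respiration regression, and Pearson correlations.

new_rs_fit <- function(model, kind, coefs, r_squared, n, residual_se, flag = "ok") {
  structure(
    list(
      model = model, kind = kind, coefficients = coefs,
      r_squared = r_squared, n = n, residual_se = residual_se, flag = flag
    ),
    class = "rs_fit"
  )
}

#' Ordinary-least-squares line fit with classical standard errors
#'
#' Core regression engine for the efflux-temperature and growth-respiration
#' analyses: OLS slope and intercept with their standard errors,
#' `R^2 = 1 - SSE/SST` and the residual standard error. Inputs are typically
#' campaign/plot means (see [campaign_plot_means()]).
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`; `x` must vary.
#' @return An object of class `rs_fit` with [tidy()] and [glance()] methods.
#'   A flat response (`SST = 0`) reports `r_squared = 0` with
#'   `flag = "flat_response"`.
#' @examples
#' fit_linear(1:3, 1:3) # slope 1, intercept 0, R^2 1
#' @export
fit_linear <- function(x, y) {
  check_xy(x, y, min_n = 2)
  if (var(x) == 0) {
    abort_degenerate_fit("`x` has zero variance; slope undefined.")
  }
  fit <- lm(y ~ x)
  sm <- quiet_summary(fit)
  sst <- sum((y - mean(y))^2)
  flag <- "ok"
  r2 <- sm$r.squared
  if (sst == 0) {
    r2 <- 0
    flag <- "flat_response"
  }
  co <- sm$coefficients
  new_rs_fit(
    fit, "linear",
    tibble(
      term = c("intercept", "slope"),
      estimate = unname(co[, "Estimate"]),
      std_error = unname(co[, "Std. Error"]),
      statistic = unname(co[, "t value"]),
      p_value = unname(co[, "Pr(>|t|)"])
    ),
    r_squared = r2, n = length(x), residual_se = sm$sigma, flag = flag
  )
}

#' Exponential (log-linear) fit with original-scale R-squared
#'
#' Fits `ln(y) = a + b x` by OLS and back-transforms to
#' `y = scale * exp(rate * x)`. To compare fairly with [fit_linear()], the
#' reported `r_squared` is computed on the *original* scale
#' (`1 - SSE/SST` of `y` against the back-transformed prediction), not on the
#' log scale.
#'
#' @param x,y Numeric vectors, `n >= 2`; all `y > 0`.
#' @return An `rs_fit` of kind `"exponential"`; `coefficients` holds the
#'   back-transformed `scale` and the `rate` (per unit `x`).
#' @export
fit_exponential <- function(x, y) {
  check_xy(x, y, min_n = 2)
  if (any(y <= 0)) {
    abort_domain("`y` must be strictly positive for an exponential fit.")
  }
  if (var(x) == 0) {
    abort_degenerate_fit("`x` has zero variance; rate undefined.")
  }
  fit <- lm(log(y) ~ x)
  sm <- quiet_summary(fit)
  co <- sm$coefficients
  pred <- exp(unname(co[1, "Estimate"]) + unname(co[2, "Estimate"]) * x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - pred)^2) / sst
  new_rs_fit(
    fit, "exponential",
    tibble(
      term = c("scale", "rate"),
      estimate = c(exp(unname(co[1, "Estimate"])), unname(co[2, "Estimate"])),
      std_error = unname(co[, "Std. Error"]),
      statistic = unname(co[, "t value"]),
      p_value = unname(co[, "Pr(>|t|)"])
    ),
    r_squared = r2, n = length(x), residual_se = sm$sigma
  )
}

check_xy <- function(x, y, min_n = 2) {
  check_number(x, "x")
  check_number(y, "y")
  if (length(x) != length(y)) {
    abort_validation("`x` and `y` must have equal length.")
  }
  if (length(x) < min_n) {
    abort_insufficient_data(sprintf(
      "Need at least %d observations, got %d.", min_n, length(x)
    ))
  }
  invisible(NULL)
}

#' Predict from a fitted `rs_fit`
#'
#' @param object An `rs_fit`.
#' @param newdata Numeric vector of predictor values.
#' @param ... Unused.
#' @return Predicted response values.
#' @export
predict.rs_fit <- function(object, newdata, ...) {
  est <- object$coefficients$estimate
  if (object$kind == "linear") est[1] + est[2] * newdata
  else est[1] * exp(est[2] * newdata)
}

#' @export
print.rs_fit <- function(x, ...) {
  cat(sprintf(
    "<rs_fit: %s> n = %d, R^2 = %.3f%s\n", x$kind, x$n, x$r_squared,
    if (x$flag != "ok") paste0(" [", x$flag, "]") else ""
  ))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.rs_fit <- function(x, ...) x$coefficients

#' @export
glance.rs_fit <- function(x, ...) {
  tibble(
    kind = x$kind, r_squared = x$r_squared, residual_se = x$residual_se,
    n = x$n, flag = x$flag
  )
}

#' Campaign/plot mean fluxes
#'
#' Aggregates per-sprout flux estimates to the plot x date x species means
#' that the regression analyses consume (each regression point is the mean of
#' the sprouts measured on one plot on one date). Negative-slope measurements
#' are excluded by default.
#'
#' @param fluxes Output of [compute_fluxes()].
#' @param drop_flags Quality flags excluded from the means
#'   (default `"negative_slope"`).
#' @return Tibble with `date`, `species`, `plot_id`, mean `tstem_c`,
#'   `rs_volume`, `rs_surface`, `r15` and the sprout count `n_sprouts`.
#' @export
campaign_plot_means <- function(fluxes, drop_flags = "negative_slope") {
  check_columns(fluxes, c(
    "date", "species", "plot_id", "tstem_c", "rs_volume", "r15", "quality_flag"
  ), "flux table")
  fluxes %>%
    filter(!(.data$quality_flag %in% drop_flags)) %>%
    group_by(.data$date, .data$species, .data$plot_id) %>%
    summarise(
      tstem_c = mean(.data$tstem_c),
      rs_volume = mean(.data$rs_volume),
      rs_surface = mean(.data$rs_surface),
      r15 = mean(.data$r15),
      n_sprouts = n(),
      .groups = "drop"
    )
}

#' Drought-year efflux residuals and percent-of-expected
#'
#' Quantifies the drought effect on stem CO2 efflux by comparing drought-year
#' measurements against the efflux expected from a reference-year
#' efflux-temperature regression at the observed stem temperature:
#' `residual = rs - predicted` and `percent = 100 * rs / predicted`, computed
#' per plot and then summarised as mean and SD across plots for each date and
#' species. Points with non-positive predicted efflux (possible below the
#' x-intercept of a steep linear fit) have undefined percent; they are
#' excluded from the percent summary with a warning and counted in
#' `n_excluded`.
#'
#' @param points Drought-year plot means: tibble with columns `date`,
#'   `species`, `plot_id`, `tstem_c`, `rs_volume`
#'   (from [campaign_plot_means()]).
#' @param reference_fits Named list of `rs_fit` objects keyed by species (a
#'   single `rs_fit` is recycled for all species).
#' @return Tibble per date x species: `residual_mean`, `residual_sd`,
#'   `percent_mean`, `percent_sd`, `n_plots`, `n_excluded`. Residual and
#'   percent satisfy `residual = predicted * (percent/100 - 1)` per point.
#' @export
drought_effect <- function(points, reference_fits) {
  check_columns(points, c("date", "species", "plot_id", "tstem_c", "rs_volume"),
                "drought-year points")
  if (inherits(reference_fits, "rs_fit")) {
    reference_fits <- setNames(
      rep(list(reference_fits), length(unique(points$species))),
      unique(points$species)
    )
  }
  missing_sp <- setdiff(unique(points$species), names(reference_fits))
  if (length(missing_sp) > 0) {
    abort_missing_input(sprintf(
      "No reference fit for species: %s.", paste(missing_sp, collapse = ", ")
    ))
  }
  per_point <- points %>%
    mutate(
      predicted = purrr::map2_dbl(
        .data$species, .data$tstem_c,
        function(sp, t) predict(reference_fits[[sp]], t)
      ),
      residual = .data$rs_volume - .data$predicted,
      percent = if_else(.data$predicted > 0,
                        100 * .data$rs_volume / .data$predicted, NA_real_)
    )
  n_bad <- sum(per_point$predicted <= 0)
  if (n_bad > 0) {
    warn(sprintf(
      "%d point(s) with non-positive predicted efflux excluded from percent-of-expected.",
      n_bad
    ))
  }
  per_point %>%
    group_by(.data$date, .data$species) %>%
    summarise(
      residual_mean = mean(.data$residual),
      residual_sd = sd(.data$residual),
      percent_mean = mean(.data$percent, na.rm = TRUE),
      percent_sd = sd(.data$percent, na.rm = TRUE),
      n_plots = n(),
      n_excluded = sum(is.na(.data$percent)),
      .groups = "drop"
    )
}

#' Between-species growth-respiration regression
#'
#' Regresses temperature-normalized efflux (R15) on the mean stem increment
#' rate with a species indicator and its interaction — a single OLS that is
#' mathematically the classical ANCOVA comparison of intercepts (maintenance
#' respiration at zero increment) and slopes (growth-respiration coupling)
#' between two species.
#'
#' @param data Tibble with columns `species` (exactly 1 or 2 levels),
#'   `increment_um_d` (mean increment rate, um day^-1) and `r15`.
#' @return Object of class `growth_fit`: per-species `slope`/`intercept`
#'   table, the intercept- and slope-difference tests (estimate, SE, t,
#'   two-sided p), and the underlying `lm`. With a single species the
#'   comparison falls back to a plain fit with a warning. Has [tidy()],
#'   [glance()] and [autoplot()] methods; see also [ratio_at_rate()].
#' @export
compare_species_growth_fit <- function(data) {
  check_columns(data, c("species", "increment_um_d", "r15"), "growth-respiration data")
  data <- as_tibble(data) %>%
    filter(!is.na(.data$increment_um_d), !is.na(.data$r15))
  sp_levels <- sort(unique(as.character(data$species)))
  counts <- table(as.character(data$species))
  if (any(counts < 3)) {
    abort_insufficient_data("Need >= 3 points per species for the comparison.")
  }

  if (length(sp_levels) == 1) {
    warn("Only one species present; returning a single-species fit without comparison.")
    base <- fit_linear(data$increment_um_d, data$r15)
    est <- base$coefficients$estimate
    out <- structure(
      list(
        model = base$model,
        per_species = tibble(
          species = sp_levels, intercept = est[1], slope = est[2]
        ),
        comparison = tibble(
          term = character(), estimate = double(), std_error = double(),
          statistic = double(), p_value = double()
        ),
        species = sp_levels, n = nrow(data)
      ),
      class = "growth_fit"
    )
    return(out)
  }
  if (length(sp_levels) > 2) {
    abort_validation("Species comparison supports exactly two species.")
  }

  df <- mutate(data, species = factor(.data$species, levels = sp_levels))
  fit <- lm(r15 ~ species * increment_um_d, data = df)
  co <- quiet_summary(fit)$coefficients
  b <- coef(fit)
  sp2 <- paste0("species", sp_levels[2])
  inter <- paste0(sp2, ":increment_um_d")
  per_species <- tibble(
    species = sp_levels,
    intercept = c(b[["(Intercept)"]], b[["(Intercept)"]] + b[[sp2]]),
    slope = c(b[["increment_um_d"]], b[["increment_um_d"]] + b[[inter]])
  )
  comparison <- tibble(
    term = c("intercept_difference", "slope_difference"),
    estimate = c(b[[sp2]], b[[inter]]),
    std_error = c(co[sp2, "Std. Error"], co[inter, "Std. Error"]),
    statistic = c(co[sp2, "t value"], co[inter, "t value"]),
    p_value = c(co[sp2, "Pr(>|t|)"], co[inter, "Pr(>|t|)"])
  )
  structure(
    list(model = fit, per_species = per_species, comparison = comparison,
         species = sp_levels, n = nrow(df)),
    class = "growth_fit"
  )
}

#' Normalized efflux at a given increment rate, relative to zero increment
#'
#' For a fitted [compare_species_growth_fit()] line, expresses R15 at a given
#' increment rate as a percentage of R15 at zero increment (the maintenance
#' component): `100 * (intercept + slope * rate) / intercept`. At rate 0 this
#' is 100% by construction.
#'
#' @param fit A `growth_fit`.
#' @param rate Increment rate(s), um day^-1.
#' @param species Species label(s); default all fitted species.
#' @return Tibble with `species`, `rate`, `ratio_pct`.
#' @export
ratio_at_rate <- function(fit, rate, species = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  ps <- fit$per_species
  if (!is.null(species)) ps <- filter(ps, .data$species %in% !!species)
  tidyr::crossing(ps, rate = rate) %>%
    mutate(ratio_pct = 100 * (.data$intercept + .data$slope * .data$rate) / .data$intercept) %>%
    select("species", "rate", "ratio_pct")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> n = %d\n", x$n))
  print(x$per_species)
  if (nrow(x$comparison) > 0) print(x$comparison)
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::pivot_longer(x$per_species, c("intercept", "slope"),
                        names_to = "term", values_to = "estimate"),
    mutate(x$comparison, species = NA_character_)
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    r_squared = sm$r.squared, residual_se = sm$sigma, n = x$n,
    intercept_diff_p = if (nrow(x$comparison)) x$comparison$p_value[1] else NA_real_,
    slope_diff_p = if (nrow(x$comparison)) x$comparison$p_value[2] else NA_real_
  )
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Sample Pearson correlation and its two-sided p-value from the t-transform
#' `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom; used to test
#' normalized efflux against sprout diameter and 7-day increment averages.
#' Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors; at least 3 complete pairs, both varying.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  check_xy(x, y, min_n = 3)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort_insufficient_data("Need at least 3 complete pairs.")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort_degenerate_fit("Correlation undefined: zero variance in `x` or `y`.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
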