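#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Computes VPD with the Magnus saturation vapour pressure formula
#' \deqn{VPD = 0.6108 \cdot e^{17.2694 \, T_a / (237.3 + T_a)} \cdot (1 - RH/100)}
#' which yields kPa; the default output is hPa (the unit conventionally
#' reported alongside hourly forest micrometeorology), i.e. the kPa value
#' multiplied by 10. Set `units = "kpa"` for the raw Magnus value.
#'
#' @param ta Air temperature in degrees Celsius. Must exceed -237.3 (the
#'   Magnus denominator must stay positive).
#' @param rh Relative humidity in percent, in \[0, 100\].
#' @param units Output units, `"hpa"` (default) or `"kpa"`.
#' @return Numeric vector of VPD values, non-negative wherever defined.
#'   `NA` inputs give `NA` outputs.
#' @examples
#' compute_vpd(20, 100) # saturation: 0
#' compute_vpd(20, 50)  # ~11.69 hPa
#' @export
compute_vpd <- function(ta, rh, units = c("hpa", "kpa")) {
  units <- arg_match(units)
  check_number(ta, "ta")
  check_number(rh, "rh")
  ok <- !is.na(rh)
  if (any(rh[ok] < 0 | rh[ok] > 100)) {
    abort_validation("`rh` must lie in [0, 100] percent.")
  }
  if (any(ta[!is.na(ta)] <= -237.3)) {
    abort_domain("`ta` must exceed -237.3 degC (Magnus denominator must be positive).")
  }
  es_kpa <- 0.6108 * exp(17.2694 * ta / (237.3 + ta))
  vpd <- es_kpa * (1 - rh / 100)
  if (units == "hpa") vpd <- vpd * 10
  vpd
}

#' Add a VPD column to a micrometeorological table
#'
#' Convenience wrapper around [compute_vpd()] for hourly micromet tables with
#' `ta_c` and `rh_pct` columns; adds `vpd_hpa` (or `vpd_kpa`).
#'
#' @param data Data frame with columns `ta_c` and `rh_pct`.
#' @inheritParams compute_vpd
#' @return The input as a tibble with the VPD column appended.
#' @export
add_vpd <- function(data, units = c("hpa", "kpa")) {
  units <- arg_match(units)
  check_columns(data, c("ta_c", "rh_pct"), "micromet table")
  out <- as_tibble(data)
  out[[paste0("vpd_", units)]] <- compute_vpd(out$ta_c, out$rh_pct, units = units)
  out
}

#' Calibrate deep soil water content against a shallow co-sensor
#'
#' Fits, separately for each treatment plot, an ordinary-least-squares line
#' predicting the deep (e.g. 25 cm) volumetric soil water content from a
#' shallow (e.g. 0-6 cm) sensor, using time-matched paired observations.
#' The calibration is later used by [gapfill_swc()] to reconstruct deep SWC
#' over periods when the deep probe was missing or malfunctioning.
#'
#' Pairs are formed by nearest-timestamp matching within
#' `match_tolerance_min` minutes; unmatched observations are dropped.
#'
#' @param shallow Data frame with columns `timestamp`, `plot_id`, `swc_pct`
#'   (shallow sensor).
#' @param deep Data frame with the same columns (deep sensor); rows with
#'   missing `swc_pct` are ignored.
#' @param match_tolerance_min Maximum timestamp mismatch for a pair, in
#'   minutes (default 30).
#' @return A tibble of class `swc_calibration` with one row per plot:
#'   `plot_id`, `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
fit_swc_calibration <- function(shallow, deep, match_tolerance_min = 30) {
  check_columns(shallow, c("timestamp", "plot_id", "swc_pct"), "shallow SWC table")
  check_columns(deep, c("timestamp", "plot_id", "swc_pct"), "deep SWC table")
  shallow <- filter(shallow, !is.na(.data$swc_pct))
  deep <- filter(deep, !is.na(.data$swc_pct))

  fit_one <- function(sh, dp, plot) {
    if (nrow(sh) == 0 || nrow(dp) == 0) {
      abort_insufficient_data(sprintf("No SWC observations to pair for plot %s.", plot))
    }
    idx <- vapply(as.numeric(sh$timestamp), function(t) {
      which.min(abs(as.numeric(dp$timestamp) - t))
    }, integer(1))
    dt_min <- abs(as.numeric(dp$timestamp[idx]) - as.numeric(sh$timestamp)) / 60
    keep <- dt_min <= match_tolerance_min
    x <- sh$swc_pct[keep]
    y <- dp$swc_pct[idx][keep]
    if (length(x) < 2) {
      abort_insufficient_data(sprintf(
        "Fewer than 2 time-matched SWC pairs for plot %s (got %d).", plot, length(x)
      ))
    }
    if (var(x) == 0) {
      abort_degenerate_fit(sprintf(
        "Shallow SWC has zero variance for plot %s; calibration slope undefined.", plot
      ))
    }
    fit <- lm(y ~ x)
    tibble(
      plot_id = plot,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = quiet_summary(fit)$r.squared,
      n_points = length(x)
    )
  }

  plots <- sort(unique(shallow$plot_id))
  out <- purrr::map_dfr(plots, function(p) {
    fit_one(filter(shallow, .data$plot_id == p), filter(deep, .data$plot_id == p), p)
  })
  class(out) <- c("swc_calibration", class(out))
  out
}

#' Gap-fill deep soil water content from a shallow sensor
#'
#' Predicts deep SWC as `slope * shallow + intercept` using the per-plot
#' calibration from [fit_swc_calibration()], fills only the missing entries of
#' `swc_pct`, clips predictions to \[0, 100\] percent, and flags filled rows
#' in a logical `swc_filled` column.
#'
#' @param data Micromet table with columns `timestamp`, `plot_id`, `swc_pct`
#'   (deep SWC, `NA` where missing) and `shallow_swc_pct`.
#' @param calibration A `swc_calibration` tibble.
#' @return `data` as a tibble with `swc_pct` filled where possible and a
#'   `swc_filled` flag column.
#' @export
gapfill_swc <- function(data, calibration) {
  if (missing(calibration) || is.null(calibration)) {
    abort_missing_input("`calibration` is required; run fit_swc_calibration() first.")
  }
  check_columns(data, c("plot_id", "swc_pct", "shallow_swc_pct"), "micromet table")
  check_columns(calibration, c("plot_id", "slope", "intercept"), "SWC calibration")
  out <- as_tibble(data) %>%
    left_join(
      select(as_tibble(calibration), "plot_id", "slope", "intercept"),
      by = "plot_id"
    ) %>%
    mutate(
      .pred = pmin(pmax(.data$slope * .data$shallow_swc_pct + .data$intercept, 0), 100),
      swc_filled = is.na(.data$swc_pct) & !is.na(.data$.pred),
      swc_pct = if_else(.data$swc_filled, .data$.pred, .data$swc_pct)
    ) %>%
    select(-"slope", -"intercept", -".pred")
  out
}

#' Validate an hourly micrometeorological table
#'
#' Checks the schema and physical ranges of an hourly micromet table:
#' strictly increasing timestamps within each plot, relative humidity in
#' \[0, 100\], non-negative precipitation, and SWC in \[0, 100\] where
#' present. Violations raise a classed validation error naming the offending
#' column and row.
#'
#' @param data Data frame with columns `timestamp`, `ta_c`, `rh_pct`,
#'   `precip_mm` and optionally `swc_pct`, `plot_id`.
#' @return The input, invisibly, as a tibble.
#' @export
validate_micromet <- function(data) {
  check_columns(data, c("timestamp", "ta_c", "rh_pct", "precip_mm"), "micromet table")
  data <- as_tibble(data)
  groups <- if ("plot_id" %in% names(data)) split(data, data$plot_id) else list(data)
  for (g in groups) check_strictly_increasing(g$timestamp, "timestamp", "micromet series")
  bad_rh <- which(!is.na(data$rh_pct) & (data$rh_pct < 0 | data$rh_pct > 100))
  if (length(bad_rh) > 0) {
    abort_validation(sprintf("`rh_pct` outside [0, 100] at row %d.", bad_rh[1]))
  }
  bad_p <- which(!is.na(data$precip_mm) & data$precip_mm < 0)
  if (length(bad_p) > 0) {
    abort_validation(sprintf("`precip_mm` negative at row %d.", bad_p[1]))
  }
  if ("swc_pct" %in% names(data)) {
    bad_s <- which(!is.na(data$swc_pct) & (data$swc_pct < 0 | data$swc_pct > 100))
    if (length(bad_s) > 0) {
      abort_validation(sprintf("`swc_pct` outside [0, 100] at row %d.", bad_s[1]))
    }
  }
  invisible(data)
}
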