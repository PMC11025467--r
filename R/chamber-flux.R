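# Closed-chamber stem CO2 efflux estimation.
#
# The closed dynamic chamber records CO2 concentration at 1 Hz for about one
# minute; the efflux per wood volume follows the ideal-gas chamber equation
#   Rs = P * V1 * (dc/dt) / (R * T * V2)
# with P air pressure (Pa), V1 system volume (m^3), T sample air temperature
# (K), V2 enclosed stem segment volume (m^3), dc/dt the linear concentration
# slope (ppm s^-1 = umol mol^-1 s^-1), and R the molar gas constant.

GAS_CONSTANT <- 8.314 # J mol^-1 K^-1

#' Fit the linear concentration slope of a chamber trace
#'
#' Ordinary-least-squares fit of CO2 concentration on time for a 1-Hz closed
#' chamber trace. The slope (ppm s^-1) is the `dc/dt` input of
#' [compute_flux()]. Traces whose fit explains little variance are flagged
#' `low_r2`; negative slopes are flagged `negative_slope` (still reported).
#'
#' @param trace Data frame with columns `time_s` (strictly increasing) and
#'   `co2_ppm`.
#' @param deadband Seconds discarded from the start of the trace before
#'   fitting (chamber-closure artefacts); default 0.
#' @param r2_threshold Fits with r-squared below this are flagged `low_r2`
#'   (default 0.9). A constant trace has undefined r-squared; it is reported
#'   as 0 and flagged.
#' @return One-row tibble: `slope`, `slope_se`, `r_squared`, `n_samples`,
#'   `quality_flag` (`"ok"`, `"low_r2"` or `"negative_slope"`).
#' @examples
#' tr <- tibble::tibble(time_s = 0:59, co2_ppm = 400 + 0.5 * (0:59))
#' fit_trace_slope(tr)
#' @export
fit_trace_slope <- function(trace, deadband = 0, r2_threshold = 0.9) {
  check_columns(trace, c("time_s", "co2_ppm"), "chamber trace")
  check_strictly_increasing(trace$time_s, "time_s", "chamber trace")
  tr <- filter(as_tibble(trace), .data$time_s >= deadband, !is.na(.data$co2_ppm))
  if (nrow(tr) < 10) {
    abort_insufficient_data(sprintf(
      "Chamber trace has %d valid samples after deadband removal; >= 10 required.",
      nrow(tr)
    ))
  }
  fit <- lm(co2_ppm ~ time_s, data = tr)
  sm <- quiet_summary(fit)
  sst <- sum((tr$co2_ppm - mean(tr$co2_ppm))^2)
  r2 <- if (sst == 0) 0 else sm$r.squared
  slope <- unname(coef(fit)[2])
  flag <- if (sst == 0) "low_r2" # flat trace: slope 0, r2 undefined
  else if (slope < 0) "negative_slope"
  else if (r2 < r2_threshold) "low_r2"
  else "ok"
  tibble(
    slope = slope,
    slope_se = sm$coefficients["time_s", "Std. Error"],
    r_squared = r2,
    n_samples = nrow(tr),
    quality_flag = flag
  )
}

#' Stem segment volume and lateral surface from two orthogonal diameters
#'
#' The enclosed segment is treated as an elliptical cylinder:
#' `volume = pi * (d1/2) * (d2/2) * length`. The lateral surface uses the
#' mean-diameter circular cylinder `pi * (d1 + d2)/2 * length` (within 1% of
#' the elliptic perimeter at field eccentricities, and consistent with the
#' circular surface/volume ratio `4/d`). End faces are excluded: they are
#' sealed by the chamber collar, not exchanging surface.
#'
#' @param d1,d2 Orthogonal segment diameters (m), > 0.
#' @param length Segment length (m), > 0. Study-like segments are 0.05-0.08 m;
#'   values outside that range only warn.
#' @return Tibble with `volume_m3` and `surface_m2` (vectorized over inputs).
#' @examples
#' segment_geometry(0.04, 0.04, 0.05)
#' @export
segment_geometry <- function(d1, d2, length) {
  check_number(d1, "d1", positive = TRUE)
  check_number(d2, "d2", positive = TRUE)
  check_number(length, "length", positive = TRUE)
  out_of_range <- length < 0.05 | length > 0.08
  if (any(out_of_range)) {
    warn(sprintf(
      "%d segment length(s) outside the typical 0.05-0.08 m chamber range.",
      sum(out_of_range)
    ))
  }
  tibble(
    volume_m3 = pi * (d1 / 2) * (d2 / 2) * length,
    surface_m2 = pi * ((d1 + d2) / 2) * length
  )
}

#' Stem CO2 efflux from one chamber measurement
#'
#' Applies the closed-chamber ideal-gas equation to a fitted concentration
#' slope and segment geometry:
#' `rs_volume = P * V1 * slope / (R * T * V2)` in umol m^-3 s^-1 (per wood
#' volume), and `rs_surface = rs_volume * V2 / A` in umol m^-2 s^-1 (per stem
#' surface), so that `rs_surface * A == rs_volume * V2` exactly (total efflux
#' of the segment is conserved between the two bases).
#'
#' @param measurement A one-row data frame (or list) with fields
#'   `pressure_pa`, `v1_m3` (system volume), `tair_k`, `d1_m`, `d2_m`,
#'   `length_m`, and either a `trace` list-column / element holding the
#'   1-Hz trace or precomputed `slope`.
#' @inheritParams fit_trace_slope
#' @return One-row tibble with the slope diagnostics of [fit_trace_slope()],
#'   `volume_m3`, `surface_m2`, `rs_volume` and `rs_surface`.
#' @examples
#' m <- list(
#'   pressure_pa = 101325, v1_m3 = 0.002, tair_k = 298.15,
#'   d1_m = 0.04, d2_m = 0.04, length_m = 0.0796,
#'   trace = tibble::tibble(time_s = 0:59, co2_ppm = 400 + 1 * (0:59))
#' )
#' compute_flux(m) # rs_volume ~ 817.5 / (V2 / 1e-4)
#' @export
compute_flux <- function(measurement, deadband = 0, r2_threshold = 0.9) {
  m <- as.list(measurement)
  needed <- c("pressure_pa", "v1_m3", "tair_k", "d1_m", "d2_m", "length_m")
  missing_f <- setdiff(needed, names(m))
  if (length(missing_f) > 0) {
    abort_validation(sprintf(
      "Chamber measurement is missing field(s): %s.", paste(missing_f, collapse = ", ")
    ))
  }
  for (f in needed) check_number(m[[f]], f, positive = TRUE)

  if (!is.null(m$trace)) {
    tr <- m$trace
    if (is.list(tr) && !is.data.frame(tr)) tr <- tr[[1]]
    sl <- fit_trace_slope(tr, deadband = deadband, r2_threshold = r2_threshold)
  } else if (!is.null(m$slope)) {
    sl <- tibble(
      slope = m$slope, slope_se = NA_real_, r_squared = NA_real_,
      n_samples = NA_integer_,
      quality_flag = if (m$slope < 0) "negative_slope" else "ok"
    )
  } else {
    abort_validation("Chamber measurement needs a `trace` or a precomputed `slope`.")
  }

  geom <- segment_geometry(m$d1_m, m$d2_m, m$length_m)
  rs_volume <- m$pressure_pa * m$v1_m3 * sl$slope /
    (GAS_CONSTANT * m$tair_k * geom$volume_m3)
  dplyr::bind_cols(
    sl, geom,
    tibble(
      rs_volume = rs_volume,
      rs_surface = rs_volume * geom$volume_m3 / geom$surface_m2
    )
  )
}

#' Compute fluxes for a whole campaign manifest
#'
#' Maps [compute_flux()] over the rows of a campaign manifest, fitting each
#' trace and appending Q10-normalized efflux at the reference temperature
#' ([normalize_q10()] of `rs_volume` at the measured stem temperature).
#'
#' @param manifest Data frame with one row per chamber measurement: columns
#'   `sprout_id`, `plot_id`, `species`, `date`, `d1_mm`, `d2_mm`,
#'   `length_mm`, `v1_m3`, `pressure_pa`, `tair_k`, `tstem_c`, `trace_file`.
#' @param traces Named list of trace tibbles keyed by `trace_file`.
#' @param q10 Q10 factor for normalization (default 2).
#' @param t_ref Reference temperature, degC (default 15).
#' @param literal_exponent Passed to [normalize_q10()].
#' @inheritParams fit_trace_slope
#' @return Tibble with one row per measurement: manifest identifiers, fit
#'   diagnostics, geometry, `rs_volume`, `rs_surface` and `r15` (normalized
#'   efflux, umol m^-3 s^-1).
#' @export
compute_fluxes <- function(manifest, traces, q10 = 2, t_ref = 15,
                           deadband = 0, r2_threshold = 0.9,
                           literal_exponent = FALSE) {
  check_columns(manifest, c(
    "sprout_id", "plot_id", "species", "date", "d1_mm", "d2_mm", "length_mm",
    "v1_m3", "pressure_pa", "tair_k", "tstem_c", "trace_file"
  ), "campaign manifest")
  missing_tr <- setdiff(manifest$trace_file, names(traces))
  if (length(missing_tr) > 0) {
    abort_missing_input(sprintf(
      "Trace file(s) not found for manifest: %s.",
      paste(head(missing_tr, 3), collapse = ", ")
    ))
  }
  out <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    est <- compute_flux(
      list(
        pressure_pa = row$pressure_pa, v1_m3 = row$v1_m3, tair_k = row$tair_k,
        d1_m = row$d1_mm / 1000, d2_m = row$d2_mm / 1000,
        length_m = row$length_mm / 1000,
        trace = traces[[row$trace_file]]
      ),
      deadband = deadband, r2_threshold = r2_threshold
    )
    dplyr::bind_cols(
      select(row, "sprout_id", "plot_id", "species", "date", "tstem_c"), est
    )
  })
  mutate(out, r15 = normalize_q10(
    .data$rs_volume, .data$tstem_c,
    t_ref = t_ref, q10 = q10, literal_exponent = literal_exponent
  ))
}

#' Normalize stem CO2 efflux to a reference temperature with a Q10 factor
#'
#' Removes the within-campaign stem temperature signal from measured efflux
#' so that plots measured hours apart (and thus at different stem
#' temperatures) are comparable:
#' \deqn{R_{ref} = R_s \cdot Q_{10}^{(T_{ref} - T_s)/10}}
#' With Q10 = 2 a measurement taken 10 degC above the reference is halved.
#' `literal_exponent = TRUE` flips the exponent sign to
#' `(ts - t_ref)/10` — the opposite printed convention found in parts of the
#' literature — in which warmer-than-reference measurements are scaled up.
#'
#' @param rs Measured efflux (any unit; the factor is multiplicative).
#' @param ts Stem temperature at measurement, degC.
#' @param t_ref Reference temperature, degC (default 15, the convention for
#'   the R15 statistic).
#' @param q10 Proportional change of efflux per 10 degC (default 2, the mean
#'   reported for oak species).
#' @param literal_exponent Use the `(ts - t_ref)/10` sign convention.
#' @return Normalized efflux, same units as `rs`.
#' @examples
#' normalize_q10(100, ts = 25) # 50: one Q10 decade above reference
#' normalize_q10(100, ts = 5)  # 200
#' @export
normalize_q10 <- function(rs, ts, t_ref = 15, q10 = 2, literal_exponent = FALSE) {
  check_number(rs, "rs")
  check_number(ts, "ts")
  check_number(q10, "q10", positive = TRUE)
  expo <- if (literal_exponent) (ts - t_ref) / 10 else (t_ref - ts) / 10
  rs * q10^expo
}
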