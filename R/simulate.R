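# Seeded synthetic-data generator.
#
# Emulates the measurement structure of a two-season coppice campaign study:
# hourly micrometeorology for a wet and a drought growing season, hourly
# dendrometer series for 2 species x 4 treatment plots x 6 sprouts with a
# double-peaked seasonal growth course and VPD-coupled diel shrink/swell,
# and campaign-style chamber measurements (6 wet-year and 4 drought-year
# campaigns) whose 1-Hz concentration traces are generated as the exact
# inverse of the closed-chamber flux equation, so every downstream estimate
# can be checked against recorded ground truth.

#' Scenario configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator with defaults that reproduce the
#' study conditions the analysis chain assumes: four treatment plots
#' (control/thinned x ambient/reduced throughfall), six sprouts per species
#' per plot, six wet-year and four drought-year campaigns, reference-year
#' efflux-temperature coefficients of 23.3 / -271.5 (oak) and 30.5 / -374.2
#' (hornbeam) umol m^-3 s^-1 per degC, wet-year annual stem increments around
#' 7 mm halved under drought, and a rainless mid-June-to-August drought
#' window during which campaign fluxes are multiplicatively suppressed by
#' `suppression_factor`.
#'
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param plots Treatment plot labels.
#' @param species Species labels (two).
#' @param n_sprouts Sprouts per species per plot.
#' @param wet_year,drought_year Calendar years of the two seasons.
#' @param season_start,season_end Month-day strings bounding the monitored
#'   growing season.
#' @param campaign_md_wet,campaign_md_drought Month-day strings of the
#'   chamber campaigns in each season.
#' @param drought_window Month-day start/end of the rainless high-VPD window
#'   in the drought year.
#' @param flux_slope,flux_intercept Named per-species coefficients of the
#'   true efflux-temperature relation (umol m^-3 s^-1 per degC; umol m^-3
#'   s^-1).
#' @param min_flux Floor on true efflux (umol m^-3 s^-1), keeping cold-edge
#'   campaigns positive.
#' @param suppression_factor Multiplicative drought suppression `f` applied
#'   to campaign fluxes (and growth) inside the drought window, in (0, 1].
#' @param annual_growth_um Named per-species wet-year annual increment (um).
#' @param drought_growth_factor Drought-year scaling of the seasonal growth
#'   rate (default 0.5: peaks half the wet-year size).
#' @param growth_peak_doys,growth_peak_sds,growth_peak_weights Day-of-year
#'   centers, widths and weights of the two Gaussian growth-rate pulses.
#' @param diel_shrink_um_per_hpa Named per-species diel shrink amplitude per
#'   unit daily-mean VPD (um hPa^-1); oak larger than hornbeam.
#' @param max_diel_shrink_um Cap on the daily shrink amplitude (um).
#' @param drought_shrink_um Scale of sustained drought shrinkage at full soil
#'   water depletion (um).
#' @param dendro_noise_um SD of dendrometer observation noise (um).
#' @param growth_sdlog,plot_sdlog,sprout_sdlog,measurement_sdlog Lognormal
#'   variability (sdlog; meanlog chosen so each factor has mean 1) for
#'   sprout growth rate, plot x date flux level, sprout flux level, and
#'   single-measurement flux noise.
#' @param trace_noise_ppm SD of the 1-Hz trace noise (ppm).
#' @param trace_seconds Trace duration (s).
#' @param trace_c0_ppm Mean starting CO2 concentration (ppm).
#' @param diameter_range_mm Named per-species range of sprout diameters (mm).
#' @param length_range_mm Range of chamber segment lengths (mm).
#' @param v1_range_m3 Range of system volumes V1 (m^3).
#' @param pressure_pa_mean,pressure_pa_sd Air pressure distribution (Pa).
#' @param swc_mask_until Date (wet year) before which the deep SWC probe is
#'   treated as malfunctioning (values withheld; to be gap-filled from the
#'   shallow co-sensor).
#' @param q10,t_ref Q10 factor and reference temperature used when the
#'   generator records normalized ground truth.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    seed = 1,
    plots = c("C-0", "T-0", "C-r", "T-r"),
    species = c("oak", "hornbeam"),
    n_sprouts = 6,
    wet_year = 2016,
    drought_year = 2017,
    season_start = "04-01",
    season_end = "10-31",
    campaign_md_wet = c("05-10", "06-07", "07-04", "08-01", "09-04", "10-05"),
    campaign_md_drought = c("06-07", "07-04", "08-01", "09-04"),
    drought_window = c("06-15", "08-31"),
    flux_slope = c(oak = 23.3, hornbeam = 30.5),
    flux_intercept = c(oak = -271.5, hornbeam = -374.2),
    min_flux = 6,
    suppression_factor = 0.3,
    annual_growth_um = c(oak = 7120, hornbeam = 6300),
    drought_growth_factor = 0.5,
    growth_peak_doys = c(160, 240),
    growth_peak_sds = c(18, 22),
    growth_peak_weights = c(0.45, 0.55),
    diel_shrink_um_per_hpa = c(oak = 6, hornbeam = 4),
    max_diel_shrink_um = 120,
    drought_shrink_um = 350,
    dendro_noise_um = 2,
    growth_sdlog = 0.15,
    plot_sdlog = 0.12,
    sprout_sdlog = 0.25,
    measurement_sdlog = 0.08,
    trace_noise_ppm = 0.5,
    trace_seconds = 60,
    trace_c0_ppm = 410,
    diameter_range_mm = list(oak = c(46.9, 57.4), hornbeam = c(35.7, 47.1)),
    length_range_mm = c(50, 80),
    v1_range_m3 = c(0.0015, 0.0025),
    pressure_pa_mean = 98500,
    pressure_pa_sd = 300,
    swc_mask_until = NULL,
    q10 = 2,
    t_ref = 15) {
  if (suppression_factor <= 0 || suppression_factor > 1) {
    abort_validation("`suppression_factor` must lie in (0, 1].")
  }
  if (length(species) != 2) abort_validation("Exactly two species are expected.")
  for (nm in c("flux_slope", "flux_intercept", "annual_growth_um",
               "diel_shrink_um_per_hpa")) {
    v <- get(nm)
    if (!all(species %in% names(v))) {
      abort_validation(sprintf("`%s` must be named for every species.", nm))
    }
  }
  if (is.null(swc_mask_until)) swc_mask_until <- sprintf("%d-07-10", wet_year)
  cfg <- as.list(environment())
  structure(cfg, class = "scenario_config")
}

season_hours <- function(year, config) {
  start <- as.POSIXct(sprintf("%d-%s 00:00:00", year, config$season_start), tz = "UTC")
  end <- as.POSIXct(sprintf("%d-%s 23:00:00", year, config$season_end), tz = "UTC")
  seq(start, end, by = "hour")
}

in_drought_window <- function(dates, year, config) {
  lo <- as.Date(sprintf("%d-%s", year, config$drought_window[1]))
  hi <- as.Date(sprintf("%d-%s", year, config$drought_window[2]))
  as.Date(dates) >= lo & as.Date(dates) <= hi
}

# plot-level contrasts: thinning raises SWC slightly, throughfall reduction
# lowers it; magnitudes are qualitative realism, not study claims
plot_swc_offset <- function(plot_id) {
  c("C-0" = 0, "T-0" = 2, "C-r" = 1, "T-r" = -1)[plot_id]
}

#' Generate hourly micrometeorology for both seasons
#'
#' Hourly air temperature (seasonal plus diel sinusoid with AR(1) day-level
#' weather noise), relative humidity anticorrelated with temperature,
#' precipitation as a marked Bernoulli process, and deep soil water content
#' from a bucket model (precipitation refill, VPD-proportional drawdown
#' toward a residual minimum), per treatment plot. The drought year gets a
#' warmer, rainless, drier-air window (`config$drought_window`) so summer
#' SWC falls below 10 percent. For the wet year a shallow co-sensor series
#' is produced and the deep probe is withheld before `config$swc_mask_until`
#' (emulating a probe malfunction bridged later by linear cross-calibration).
#'
#' @param config A [scenario_config()].
#' @return List with `micromet` (tibble: `timestamp`, `plot_id`, `year`,
#'   `ta_c`, `rh_pct`, `precip_mm`, `swc_pct` with the masked gap,
#'   `shallow_swc_pct`) and `swc_truth` (the unmasked deep series).
#' @export
simulate_micromet <- function(config = scenario_config()) {
  withr::with_seed(derive_seed(config$seed, 1L), {
    years <- c(config$wet_year, config$drought_year)
    out <- purrr::map(years, function(year) {
      drought <- year == config$drought_year
      ts <- season_hours(year, config)
      doy <- as.integer(strftime(ts, "%j", tz = "UTC"))
      hour <- as.integer(strftime(ts, "%H", tz = "UTC"))
      n <- length(ts)
      in_window <- drought & in_drought_window(ts, year, config)

      # day-level AR(1) weather noise shared by all hours of a day
      days <- unique(as.Date(ts))
      eps <- rnorm(length(days), 0, 1.5)
      day_noise <- Reduce(function(a, b) 0.7 * a + b, eps, accumulate = TRUE)
      day_noise <- day_noise[match(as.Date(ts), days)]

      ta <- 1 + 19 * sin(pi * (doy - 88) / 234) +
        6 * cos(2 * pi * (hour - 14) / 24) +
        day_noise + rnorm(n, 0, 0.5) +
        if_else(in_window, 2.5, 0)
      rh <- pmin(pmax(98 - 2.4 * ta + rnorm(n, 0, 3) -
                        if_else(in_window, 8, 0), 20), 100)
      vpd <- compute_vpd(ta, rh)
      p_rain <- if_else(in_window, 0.003, 0.05)
      precip <- rbinom(n, 1, p_rain) * rexp(n, 1 / 1.2)

      plot_frames <- purrr::map(config$plots, function(pl) {
        s <- numeric(n)
        s0 <- 33 + plot_swc_offset(pl) + rnorm(1, 0, 0.5)
        prev <- s0
        for (i in seq_len(n)) {
          refill <- 1.2 * precip[i] * max(0, 1 - prev / 45)
          draw <- 0.003 * vpd[i] * max(0, prev - 3) / 30
          prev <- min(max(prev + refill - draw, 2), 45)
          s[i] <- prev
        }
        tibble(
          timestamp = ts, plot_id = pl, year = year,
          ta_c = ta, rh_pct = rh, precip_mm = precip,
          swc_true = s + rnorm(n, 0, 0.15)
        )
      })
      dplyr::bind_rows(plot_frames)
    })
    mm <- dplyr::bind_rows(out)

    # shallow 0-6 cm co-sensor (wet year only), affinely related to the deep
    # probe with plot-specific coefficients and noise
    sh_a <- setNames(c(0.92, 0.88, 0.85, 0.90), config$plots)
    sh_b <- setNames(c(1.0, 2.0, 3.0, 1.5), config$plots)
    sh_sd <- setNames(c(0.05, 0.35, 0.50, 0.28), config$plots)
    mm <- mm %>%
      mutate(
        shallow_swc_pct = if_else(
          .data$year == config$wet_year,
          (.data$swc_true - sh_b[.data$plot_id]) / sh_a[.data$plot_id] +
            rnorm(dplyr::n(), 0, sh_sd[.data$plot_id]),
          NA_real_
        )
      )
    mask <- mm$year == config$wet_year &
      as.Date(mm$timestamp) < as.Date(config$swc_mask_until)
    mm$swc_pct <- ifelse(mask, NA_real_, mm$swc_true)
    swc_truth <- select(mm, "timestamp", "plot_id", "year", "swc_true")
    mm <- select(mm, "timestamp", "plot_id", "year", "ta_c", "rh_pct",
                 "precip_mm", "swc_pct", "shallow_swc_pct")
    list(micromet = mm, swc_truth = swc_truth)
  })
}

growth_rate_um_day <- function(doy, annual_um, config, drought) {
  w <- config$growth_peak_weights / sum(config$growth_peak_weights)
  shape <- w[1] * stats::dnorm(doy, config$growth_peak_doys[1], config$growth_peak_sds[1]) +
    w[2] * stats::dnorm(doy, config$growth_peak_doys[2], config$growth_peak_sds[2])
  rate <- annual_um * shape
  if (drought) rate <- rate * config$drought_growth_factor
  rate
}

#' Generate hourly dendrometer series with recorded ground truth
#'
#' For every sprout: diameter displacement = baseline + true cumulative
#' growth (hourly integral of a double-peaked seasonal rate, halved in the
#' drought year, lognormally scaled per sprout) minus a diel shrink whose
#' daily amplitude follows daily-mean VPD (zero at midnight, peaking at
#' midday) minus a sustained drought shrinkage proportional to soil water
#' depletion, plus Gaussian observation noise.
#'
#' @param config A [scenario_config()].
#' @param micromet Output of [simulate_micromet()] (list or its `micromet`
#'   element plus truth; the unmasked SWC truth drives drought shrinkage).
#' @return List with `dendro` (tibble: `sprout_id`, `plot_id`, `species`,
#'   `year`, `timestamp`, `diameter_um`) and `sprout_truth` (per sprout and
#'   year: true annual growth, maximum diel amplitude, baseline diameter).
#' @export
simulate_diameter_series <- function(config = scenario_config(),
                                     micromet = simulate_micromet(config)) {
  mm <- micromet$micromet
  swc_truth <- micromet$swc_truth
  withr::with_seed(derive_seed(config$seed, 2L), {
    grid <- tidyr::crossing(
      plot_id = config$plots, species = config$species,
      k = seq_len(config$n_sprouts)
    ) %>%
      mutate(
        sprout_id = sprintf("%s_%s_%02d", .data$plot_id, .data$species, .data$k),
        growth_factor = exp(rnorm(dplyr::n(), -config$growth_sdlog^2 / 2,
                                  config$growth_sdlog)),
        baseline_um = purrr::map_dbl(.data$species, function(sp) {
          r <- config$diameter_range_mm[[sp]]
          runif(1, r[1], r[2]) * 1000
        })
      )

    met_env <- mm %>%
      filter(.data$plot_id == config$plots[1]) %>%
      mutate(vpd_hpa = compute_vpd(.data$ta_c, .data$rh_pct)) %>%
      select("timestamp", "year", "vpd_hpa")
    daily_vpd <- met_env %>%
      group_by(date = as.Date(.data$timestamp), .data$year) %>%
      summarise(vpd_day = mean(.data$vpd_hpa), .groups = "drop")

    years <- c(config$wet_year, config$drought_year)
    frames <- vector("list", nrow(grid) * length(years))
    truths <- vector("list", nrow(grid) * length(years))
    idx <- 0L
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      swc_plot <- filter(swc_truth, .data$plot_id == g$plot_id)
      carry_um <- 0 # growth accumulated in earlier seasons persists in the stem
      for (year in years) {
        drought <- year == config$drought_year
        ts <- season_hours(year, config)
        n <- length(ts)
        doy <- as.integer(strftime(ts, "%j", tz = "UTC"))
        hour <- as.integer(strftime(ts, "%H", tz = "UTC"))
        rate <- growth_rate_um_day(
          doy, config$annual_growth_um[[g$species]] * g$growth_factor,
          config, drought
        )
        # growth accrues between observations: none before the first sample
        growth_cum <- carry_um + c(0, cumsum(rate[-1] / 24))
        amp_day <- pmin(
          config$diel_shrink_um_per_hpa[[g$species]] *
            daily_vpd$vpd_day[match(as.Date(ts), daily_vpd$date)],
          config$max_diel_shrink_um
        )
        shrink <- amp_day * 0.5 * (1 - cos(2 * pi * hour / 24))
        swc <- swc_plot$swc_true[match(ts, swc_plot$timestamp)]
        drought_shrink <- config$drought_shrink_um *
          pmin(pmax((15 - swc) / 12, 0), 1)
        noise <- rnorm(n, 0, config$dendro_noise_um)
        idx <- idx + 1L
        frames[[idx]] <- tibble(
          sprout_id = g$sprout_id, plot_id = g$plot_id, species = g$species,
          year = year, timestamp = ts,
          diameter_um = g$baseline_um + growth_cum - shrink -
            drought_shrink + noise
        )
        truths[[idx]] <- tibble(
          sprout_id = g$sprout_id, plot_id = g$plot_id, species = g$species,
          year = year,
          true_annual_growth_um = growth_cum[n] - carry_um,
          max_diel_amplitude_um = max(amp_day),
          baseline_um = g$baseline_um,
          noise_um = config$dendro_noise_um
        )
        carry_um <- growth_cum[n]
      }
    }
    list(dendro = dplyr::bind_rows(frames), sprout_truth = dplyr::bind_rows(truths))
  })
}

#' Generate a 1-Hz chamber concentration trace with a known true flux
#'
#' Exact inverse of the closed-chamber equation used by [compute_flux()]:
#' the trace slope is `true_flux * R * T * V2 / (P * V1)` (ppm s^-1) and the
#' trace is `c0 + slope * t` plus Gaussian noise. Draws from the current RNG
#' stream; seed via `set.seed()` or `withr::with_seed()` for reproducibility.
#'
#' @param true_flux True efflux per wood volume, umol m^-3 s^-1.
#' @param pressure_pa Air pressure, Pa.
#' @param v1_m3 System volume, m^3.
#' @param tair_k Sample air temperature, K.
#' @param volume_m3 Enclosed segment volume V2, m^3.
#' @param noise_sd Trace noise SD, ppm (0 gives an exact line).
#' @param c0_ppm Starting concentration, ppm.
#' @param duration_s Trace length, seconds (1-Hz sampling at t = 0, 1, ...).
#' @return Tibble with `time_s`, `co2_ppm`.
#' @export
simulate_chamber_trace <- function(true_flux, pressure_pa, v1_m3, tair_k,
                                   volume_m3, noise_sd = 0.5, c0_ppm = 410,
                                   duration_s = 60) {
  check_number(true_flux, "true_flux")
  for (nm in c("pressure_pa", "v1_m3", "tair_k", "volume_m3")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  slope <- true_flux * GAS_CONSTANT * tair_k * volume_m3 / (pressure_pa * v1_m3)
  t <- seq(0, duration_s - 1)
  tibble(
    time_s = t,
    co2_ppm = c0_ppm + slope * t +
      if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
  )
}

simulate_campaigns <- function(config, micromet) {
  mm <- micromet$micromet
  withr::with_seed(derive_seed(config$seed, 3L), {
    years <- c(config$wet_year, config$drought_year)
    campaign_dates <- c(
      as.Date(sprintf("%d-%s", config$wet_year, config$campaign_md_wet)),
      as.Date(sprintf("%d-%s", config$drought_year, config$campaign_md_drought))
    )
    # plots are visited in a fixed order over the ~4 h campaign morning
    plot_hour <- setNames(c(9, 10, 11, 12), c("C-0", "T-0", "T-r", "C-r"))
    sprout_grid <- tidyr::crossing(
      plot_id = config$plots, species = config$species,
      k = seq_len(config$n_sprouts)
    ) %>%
      mutate(
        sprout_id = sprintf("%s_%s_%02d", .data$plot_id, .data$species, .data$k),
        sprout_factor = exp(rnorm(dplyr::n(), -config$sprout_sdlog^2 / 2,
                                  config$sprout_sdlog)),
        d1_mm = purrr::map_dbl(.data$species, function(sp) {
          r <- config$diameter_range_mm[[sp]]
          runif(1, r[1], r[2])
        }),
        d2_mm = .data$d1_mm * (1 + rnorm(dplyr::n(), 0, 0.04)),
        v1_m3 = runif(dplyr::n(), config$v1_range_m3[1], config$v1_range_m3[2]),
        length_mm = runif(dplyr::n(), config$length_range_mm[1],
                          config$length_range_mm[2])
      )

    rows <- list()
    traces <- list()
    truth <- list()
    for (date in as.list(campaign_dates)) {
      year <- as.integer(strftime(date, "%Y", tz = "UTC"))
      drought_date <- year == config$drought_year &&
        in_drought_window(date, year, config)
      f <- if (drought_date) config$suppression_factor else 1
      plot_date_factor <- setNames(
        exp(rnorm(length(config$plots) * 2, -config$plot_sdlog^2 / 2,
                  config$plot_sdlog)),
        paste(rep(config$plots, each = 2), rep(config$species, length(config$plots)))
      )
      for (i in seq_len(nrow(sprout_grid))) {
        g <- sprout_grid[i, ]
        hr <- plot_hour[[g$plot_id]]
        ta_row <- mm %>%
          filter(.data$plot_id == g$plot_id,
                 .data$timestamp == as.POSIXct(date, tz = "UTC") + 3600 * hr)
        tstem <- ta_row$ta_c[1] + 0.5 + rnorm(1, 0, 0.3)
        base_rs <- max(
          config$flux_slope[[g$species]] * tstem + config$flux_intercept[[g$species]],
          config$min_flux
        )
        true_rs <- base_rs * f *
          plot_date_factor[[paste(g$plot_id, g$species)]] *
          g$sprout_factor *
          exp(rnorm(1, -config$measurement_sdlog^2 / 2, config$measurement_sdlog))
        geom <- segment_geometry(g$d1_mm / 1000, g$d2_mm / 1000, g$length_mm / 1000)
        pressure <- rnorm(1, config$pressure_pa_mean, config$pressure_pa_sd)
        tair_k <- ta_row$ta_c[1] + 1 + 273.15
        trace_file <- sprintf("traces/%s_%s.csv", strftime(date, "%Y%m%d"), g$sprout_id)
        traces[[trace_file]] <- simulate_chamber_trace(
          true_rs, pressure, g$v1_m3, tair_k, geom$volume_m3,
          noise_sd = config$trace_noise_ppm,
          c0_ppm = config$trace_c0_ppm + rnorm(1, 0, 5),
          duration_s = config$trace_seconds
        )
        rows[[length(rows) + 1L]] <- tibble(
          sprout_id = g$sprout_id, plot_id = g$plot_id, species = g$species,
          date = as.Date(date), d1_mm = g$d1_mm, d2_mm = g$d2_mm,
          length_mm = g$length_mm, v1_m3 = g$v1_m3, pressure_pa = pressure,
          tair_k = tair_k, tstem_c = tstem, trace_file = trace_file
        )
        truth[[length(truth) + 1L]] <- tibble(
          sprout_id = g$sprout_id, plot_id = g$plot_id, species = g$species,
          date = as.Date(date), true_flux = true_rs,
          suppression_factor = f, base_flux = base_rs
        )
      }
    }
    list(
      manifest = dplyr::bind_rows(rows),
      traces = traces,
      flux_truth = dplyr::bind_rows(truth)
    )
  })
}

#' Generate the full synthetic scenario bundle
#'
#' Runs all generators under one configuration: micrometeorology, dendrometer
#' series (optional) and campaign chamber measurements, plus the ground truth
#' each recovery test compares against. Ground truth is never consumed by the
#' pipeline itself.
#'
#' @param config A [scenario_config()].
#' @param dendrometer Generate the hourly dendrometer series (default TRUE;
#'   disable for flux-only studies).
#' @return List of class `stemflux_scenario`: `config`, `micromet`,
#'   `dendro` (or NULL), `manifest`, `traces` (named list of trace tibbles),
#'   and `ground_truth` (list: `fluxes`, `sprouts`, `swc`).
#' @export
simulate_scenario <- function(config = scenario_config(), dendrometer = TRUE) {
  met <- simulate_micromet(config)
  den <- if (dendrometer) simulate_diameter_series(config, met) else NULL
  camp <- simulate_campaigns(config, met)
  structure(
    list(
      config = config,
      micromet = met$micromet,
      dendro = if (dendrometer) den$dendro else NULL,
      manifest = camp$manifest,
      traces = camp$traces,
      ground_truth = list(
        fluxes = camp$flux_truth,
        sprouts = if (dendrometer) den$sprout_truth else NULL,
        swc = met$swc_truth
      )
    ),
    class = "stemflux_scenario"
  )
}

#' Write a synthetic scenario to disk in the pipeline's CSV formats
#'
#' Writes `micromet_<year>.csv`, `dendro_<sprout>.csv`, `manifest_<year>.csv`,
#' `traces/*.csv` and `ground_truth.json` under `dir`, in the exact formats
#' the pipeline readers consume.
#'
#' @param scenario Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "stemflux_scenario"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  cfg <- scenario$config
  for (year in c(cfg$wet_year, cfg$drought_year)) {
    readr::write_csv(
      filter(scenario$micromet, .data$year == !!year) %>% select(-"year"),
      file.path(dir, sprintf("micromet_%d.csv", year))
    )
    readr::write_csv(
      filter(scenario$manifest, lubridate::year(.data$date) == !!year),
      file.path(dir, sprintf("manifest_%d.csv", year))
    )
  }
  if (!is.null(scenario$dendro)) {
    for (sp in unique(scenario$dendro$sprout_id)) {
      readr::write_csv(
        filter(scenario$dendro, .data$sprout_id == sp) %>%
          select("sprout_id", "plot_id", "species", "timestamp", "diameter_um"),
        file.path(dir, sprintf("dendro_%s.csv", sp))
      )
    }
  }
  for (nm in names(scenario$traces)) {
    readr::write_csv(scenario$traces[[nm]], file.path(dir, nm))
  }
  gt <- scenario$ground_truth
  jsonlite::write_json(
    list(
      fluxes = gt$fluxes,
      sprouts = gt$sprouts,
      seed = cfg$seed,
      suppression_factor = cfg$suppression_factor
    ),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", digits = NA, null = "null"
  )
  invisible(dir)
}

#' Read a scenario directory back into the in-memory bundle shape
#'
#' Counterpart of [write_scenario()]: reads micromet, manifests, traces and
#' dendrometer CSVs from `dir`. Ground truth is not read (the pipeline never
#' consumes it).
#'
#' @param dir Directory written by [write_scenario()] or laid out the same
#'   way.
#' @return List with `micromet`, `dendro` (NULL if absent), `manifest`,
#'   `traces`.
#' @export
read_scenario <- function(dir) {
  met_files <- list.files(dir, "^micromet_\\d+\\.csv$", full.names = TRUE)
  man_files <- list.files(dir, "^manifest_\\d+\\.csv$", full.names = TRUE)
  if (length(met_files) == 0 || length(man_files) == 0) {
    abort_missing_input(sprintf(
      "Scenario directory %s lacks micromet_<year>.csv or manifest_<year>.csv.", dir
    ))
  }
  micromet <- purrr::map_dfr(met_files, function(f) {
    mutate(read_micromet_csv(f),
           year = as.integer(sub(".*micromet_(\\d+)\\.csv$", "\\1", f)))
  })
  manifest <- purrr::map_dfr(man_files, read_campaign_manifest)
  traces <- setNames(
    purrr::map(manifest$trace_file, function(tf) {
      path <- file.path(dir, tf)
      if (!file.exists(path)) {
        abort_missing_input(sprintf("Trace file %s listed in manifest not found.", path))
      }
      read_chamber_trace(path)
    }),
    manifest$trace_file
  )
  den_files <- list.files(dir, "^dendro_.*\\.csv$", full.names = TRUE)
  dendro <- if (length(den_files) > 0) {
    purrr::map_dfr(den_files, read_dendro_csv)
  } else {
    NULL
  }
  list(micromet = micromet, dendro = dendro, manifest = manifest, traces = traces)
}
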