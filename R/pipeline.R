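# End-to-end orchestration: simulate (or read) -> micromet -> flux ->
# partition -> analyze, with validated CSV I/O and a machine-readable run
# report.

#' Run the full analysis pipeline
#'
#' Executes the stages of the stem-carbon drought analysis in order:
#' \enumerate{
#'   \item \strong{simulate} — generate the synthetic scenario (skipped when
#'     `input_dir` points at an existing scenario directory);
#'   \item \strong{micromet} — validate the hourly series, derive VPD, fit
#'     the per-treatment SWC cross-calibration and gap-fill the deep probe;
#'   \item \strong{flux} — fit every chamber trace, apply the closed-chamber
#'     equation and Q10-normalize to `t_ref`;
#'   \item \strong{partition} — zero-growth partition each dendrometer
#'     series and derive daily increment / TWD statistics;
#'   \item \strong{analyze} — campaign/plot means, reference-year
#'     efflux-temperature fits (linear and exponential), drought-year
#'     residuals and percent-of-expected, the between-species
#'     growth-respiration regression, Pearson correlations, and the
#'     analysis-ready long table for mixed-model fitting elsewhere.
#' }
#' Any stage failure raises a classed condition and aborts downstream
#' stages. Outputs are plain CSV plus a `run_report.json`; with unchanged
#' config and seed a rerun reproduces byte-identical tables.
#'
#' @param config A [scenario_config()]; its seed drives all randomness and
#'   its year labels define the reference (wet) and drought years.
#' @param out_dir Output directory (created if needed).
#' @param input_dir Optional scenario directory (see [write_scenario()]);
#'   when given, the simulate stage is replaced by reading these inputs.
#' @param q10,t_ref,literal_exponent Normalization settings, see
#'   [normalize_q10()].
#' @param ma_window,gap_hours Daily-statistics settings, see
#'   [daily_growth_stats()] and [zero_growth_partition()].
#' @param deadband,r2_threshold Trace-fit settings, see [fit_trace_slope()].
#' @param dendrometer Include the dendrometer stages (default TRUE).
#' @param write_inputs Also write the generated inputs under
#'   `out_dir/inputs` (default FALSE).
#' @param quiet Suppress progress messages.
#' @return The run report, invisibly: a list with per-stage status, record
#'   counts and collected warnings, also written to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir,
                         input_dir = NULL,
                         q10 = config$q10, t_ref = config$t_ref,
                         literal_exponent = FALSE,
                         ma_window = 7, gap_hours = 6,
                         deadband = 0, r2_threshold = 0.9,
                         dendrometer = TRUE, write_inputs = FALSE,
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(status = "ok", seed = config$seed, stages = list())
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character()

  run_stage <- function(name, expr) {
    res <- withCallingHandlers(
      expr,
      warning = function(w) {
        warnings_log <<- c(warnings_log, sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    res
  }

  # --- simulate / load inputs -----------------------------------------
  if (is.null(input_dir)) {
    say("[simulate] generating synthetic scenario (seed %d)", config$seed)
    scen <- run_stage("simulate", simulate_scenario(config, dendrometer = dendrometer))
    inputs <- list(
      micromet = scen$micromet, dendro = scen$dendro,
      manifest = scen$manifest, traces = scen$traces
    )
    if (write_inputs) write_scenario(scen, file.path(out_dir, "inputs"))
    report$stages$simulate <- list(
      status = "ok",
      n_micromet = nrow(inputs$micromet),
      n_measurements = nrow(inputs$manifest),
      n_dendro = if (is.null(inputs$dendro)) 0L else nrow(inputs$dendro)
    )
  } else {
    say("[load] reading scenario from %s", input_dir)
    inputs <- run_stage("load", read_scenario(input_dir))
    report$stages$load <- list(status = "ok", n_measurements = nrow(inputs$manifest))
  }

  # --- micromet --------------------------------------------------------
  say("[micromet] deriving VPD and gap-filling SWC (%d rows)", nrow(inputs$micromet))
  met <- run_stage("micromet", {
    m <- validate_micromet(inputs$micromet)
    m <- add_vpd(m)
    have_shallow <- "shallow_swc_pct" %in% names(m) && any(!is.na(m$shallow_swc_pct))
    if (have_shallow) {
      overlap <- filter(m, !is.na(.data$shallow_swc_pct), !is.na(.data$swc_pct))
      calib <- fit_swc_calibration(
        shallow = select(overlap, "timestamp", "plot_id", swc_pct = "shallow_swc_pct"),
        deep = select(overlap, "timestamp", "plot_id", "swc_pct")
      )
      m <- gapfill_swc(m, calib)
    } else {
      calib <- NULL
      m$swc_filled <- FALSE
    }
    list(micromet = m, calibration = calib)
  })
  readr::write_csv(met$micromet, file.path(out_dir, "micromet_processed.csv"))
  if (!is.null(met$calibration)) {
    readr::write_csv(met$calibration, file.path(out_dir, "swc_calibrations.csv"))
  }
  report$stages$micromet <- list(
    status = "ok", n_rows = nrow(met$micromet),
    n_filled = sum(met$micromet$swc_filled)
  )

  # --- flux ------------------------------------------------------------
  say("[flux] fitting %d chamber traces", nrow(inputs$manifest))
  fluxes <- run_stage("flux", compute_fluxes(
    inputs$manifest, inputs$traces,
    q10 = q10, t_ref = t_ref, deadband = deadband,
    r2_threshold = r2_threshold, literal_exponent = literal_exponent
  ))
  fluxes <- fluxes %>%
    left_join(
      inputs$manifest %>%
        mutate(diameter_mm = (.data$d1_mm + .data$d2_mm) / 2) %>%
        select("sprout_id", "date", "diameter_mm"),
      by = c("sprout_id", "date")
    )
  readr::write_csv(fluxes, file.path(out_dir, "fluxes.csv"))
  report$stages$flux <- list(
    status = "ok", n_measurements = nrow(fluxes),
    n_flagged = sum(fluxes$quality_flag != "ok")
  )

  # --- partition -------------------------------------------------------
  daily <- NULL
  if (dendrometer && !is.null(inputs$dendro)) {
    say("[partition] zero-growth partitioning %d sprout series",
        length(unique(inputs$dendro$sprout_id)))
    part <- run_stage("partition", zero_growth_partition(
      inputs$dendro, gap_hours = gap_hours
    ))
    daily <- run_stage("partition", daily_growth_stats(part, window = ma_window))
    sprout_meta <- distinct(inputs$dendro, .data$sprout_id, .data$plot_id, .data$species)
    daily <- left_join(daily, sprout_meta, by = "sprout_id")
    readr::write_csv(
      select(part, dplyr::any_of(c(
        "sprout_id", "plot_id", "species", "timestamp", "diameter_um",
        "gro_um", "twd_um", "after_gap", "jump_flag"
      ))),
      file.path(out_dir, "partitioned.csv")
    )
    readr::write_csv(daily, file.path(out_dir, "daily_stats.csv"))
    report$stages$partition <- list(
      status = "ok", n_sprouts = length(unique(part$sprout_id)),
      n_daily = nrow(daily)
    )
  } else {
    report$stages$partition <- list(status = "skipped")
  }

  # --- analyze ---------------------------------------------------------
  say("[analyze] reference fits, drought effects and correlations")
  ana <- run_stage("analyze", analyze_stage(
    fluxes, daily,
    reference_year = config$wet_year, drought_year = config$drought_year
  ))
  for (nm in names(ana$tables)) {
    readr::write_csv(ana$tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  report$stages$analyze <- list(
    status = "ok",
    tables = names(ana$tables),
    n_drought_rows = nrow(ana$tables$drought_effect)
  )

  report$warnings <- warnings_log
  jsonlite::write_json(
    report, file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  say("[done] outputs in %s", out_dir)
  invisible(c(ana["fits"], list(report = report)))
}

# The analyze stage as a pure function over the flux and daily-stat tables.
analyze_stage <- function(fluxes, daily, reference_year, drought_year) {
  means <- campaign_plot_means(fluxes)
  means$year <- lubridate::year(means$date)
  ref_means <- filter(means, .data$year == reference_year)
  dro_means <- filter(means, .data$year == drought_year)
  if (nrow(ref_means) == 0) {
    abort_insufficient_data(sprintf(
      "No campaign means in reference year %d.", reference_year
    ))
  }

  species <- sort(unique(means$species))
  ref_fits <- list()
  ref_rows <- list()
  for (sp in species) {
    d <- filter(ref_means, .data$species == sp)
    lf <- fit_linear(d$tstem_c, d$rs_volume)
    ef <- fit_exponential(d$tstem_c, d$rs_volume)
    ref_fits[[sp]] <- lf
    ref_rows[[sp]] <- tibble(
      species = sp,
      model = c("linear", "exponential"),
      intercept = c(lf$coefficients$estimate[1], ef$coefficients$estimate[1]),
      slope = c(lf$coefficients$estimate[2], ef$coefficients$estimate[2]),
      intercept_se = c(lf$coefficients$std_error[1], ef$coefficients$std_error[1]),
      slope_se = c(lf$coefficients$std_error[2], ef$coefficients$std_error[2]),
      r_squared = c(lf$r_squared, ef$r_squared),
      n = c(lf$n, ef$n)
    )
  }
  reference_fits <- dplyr::bind_rows(ref_rows)

  de <- if (nrow(dro_means) > 0) {
    drought_effect(dro_means, ref_fits)
  } else {
    tibble(date = as.Date(character()), species = character(),
           residual_mean = double(), residual_sd = double(),
           percent_mean = double(), percent_sd = double(),
           n_plots = integer(), n_excluded = integer())
  }

  tables <- list(
    campaign_means = means,
    reference_fits = reference_fits,
    drought_effect = de
  )
  fits <- list(reference = ref_fits)

  if (!is.null(daily)) {
    # campaign-date increment averages per species (7-day MA across sprouts)
    incr_by_species <- daily %>%
      filter(.data$date %in% unique(means$date)) %>%
      group_by(.data$date, .data$species) %>%
      summarise(increment_um_d = mean(.data$increment_um_d_ma7, na.rm = TRUE),
                .groups = "drop")
    growth_data <- means %>%
      group_by(.data$date, .data$species) %>%
      summarise(r15 = mean(.data$r15), .groups = "drop") %>%
      left_join(incr_by_species, by = c("date", "species")) %>%
      filter(!is.na(.data$increment_um_d))
    gf <- compare_species_growth_fit(growth_data)
    tables$growth_fit <- tidy(gf)
    fits$growth <- gf

    sprout_daily <- daily %>%
      filter(.data$date %in% unique(means$date)) %>%
      select("sprout_id", "date", "increment_um_d_ma7")
    sprout_level <- fluxes %>%
      left_join(sprout_daily, by = c("sprout_id", "date"))
    # within species per date, so the between-species size/flux contrast
    # cannot masquerade as a diameter effect
    corr <- purrr::map_dfr(
      split(sprout_level, list(sprout_level$date, sprout_level$species)),
      function(d) {
        if (nrow(d) == 0) return(NULL)
        out <- list()
        if (sum(!is.na(d$diameter_mm)) >= 3) {
          out$diameter <- dplyr::bind_cols(
            tibble(date = d$date[1], species = d$species[1],
                   variable = "sprout_diameter_mm"),
            pearson_correlation(d$r15, d$diameter_mm)
          )
        }
        if (sum(stats::complete.cases(d$r15, d$increment_um_d_ma7)) >= 3) {
          out$incr <- dplyr::bind_cols(
            tibble(date = d$date[1], species = d$species[1],
                   variable = "increment_um_d_ma7"),
            pearson_correlation(d$r15, d$increment_um_d_ma7)
          )
        }
        dplyr::bind_rows(out)
      }
    )
    tables$correlations <- corr

    tables$mixedmodel_input <- sprout_level %>%
      mutate(
        year = lubridate::year(.data$date),
        thinning = startsWith(.data$plot_id, "T"),
        throughfall_reduction = endsWith(.data$plot_id, "r")
      ) %>%
      select("sprout_id", "plot_id", "species", "thinning",
             "throughfall_reduction", "date", "year", "tstem_c",
             "rs_volume", "rs_surface", "r15", "diameter_mm",
             "increment_um_d_ma7")
  }

  list(tables = tables, fits = fits)
}
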