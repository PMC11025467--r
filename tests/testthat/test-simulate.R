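test_that("generation is fully deterministic under a fixed seed", {
  cfg <- quick_config(seed = 91)
  a <- simulate_scenario(cfg, dendrometer = FALSE)
  b <- simulate_scenario(cfg, dendrometer = FALSE)
  expect_identical(a$micromet, b$micromet)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$traces, b$traces)
  expect_identical(a$ground_truth$fluxes, b$ground_truth$fluxes)
  c <- simulate_scenario(quick_config(seed = 92), dendrometer = FALSE)
  expect_false(identical(a$manifest$tstem_c, c$manifest$tstem_c))
})

test_that("the drought season is drier than the wet season in summer soil water", {
  met <- simulate_micromet(quick_config(seed = 12))
  mm <- met$micromet
  summer <- dplyr::filter(mm, format(timestamp, "%m") %in% c("06", "07", "08"))
  by_year <- dplyr::summarise(
    dplyr::group_by(summer, year),
    swc_min = min(swc_pct, na.rm = TRUE),
    precip = sum(precip_mm)
  )
  wet <- by_year[by_year$year == 2016, ]
  dro <- by_year[by_year$year == 2017, ]
  expect_lt(dro$swc_min, wet$swc_min)
  expect_lt(dro$swc_min, 10) # drought summers deplete below 10 %
  expect_lt(dro$precip, wet$precip)
  # physical ranges hold everywhere
  expect_true(all(mm$rh_pct >= 0 & mm$rh_pct <= 100))
  expect_true(all(mm$precip_mm >= 0))
  expect_true(all(is.na(mm$swc_pct) | (mm$swc_pct >= 0 & mm$swc_pct <= 100)))
})

test_that("the deep SWC gap is confined to the wet year before the mask date and is fillable", {
  cfg <- quick_config(seed = 13)
  met <- simulate_micromet(cfg)
  mm <- met$micromet
  masked <- dplyr::filter(mm, is.na(swc_pct))
  expect_true(all(masked$year == cfg$wet_year))
  expect_true(all(as.Date(masked$timestamp) < as.Date(cfg$swc_mask_until)))
  overlap <- dplyr::filter(mm, !is.na(swc_pct), !is.na(shallow_swc_pct))
  cal <- fit_swc_calibration(
    shallow = dplyr::select(overlap, timestamp, plot_id, swc_pct = shallow_swc_pct),
    deep = dplyr::select(overlap, timestamp, plot_id, swc_pct)
  )
  expect_equal(sort(cal$plot_id), sort(cfg$plots))
  expect_true(all(cal$r_squared > 0.8))
  filled <- gapfill_swc(mm, cal)
  expect_false(any(is.na(filled$swc_pct)))
  # reconstruction tracks the generator's withheld truth
  truth <- dplyr::left_join(
    dplyr::filter(filled, swc_filled),
    met$swc_truth, by = c("timestamp", "plot_id", "year")
  )
  expect_lt(stats::median(abs(truth$swc_pct - truth$swc_true)), 1.5)
})

test_that("chamber trace generation inverts the flux equation", {
  tr <- simulate_chamber_trace(817.5264, 101325, 0.002, 298.15, 1e-4,
                               noise_sd = 0)
  fit <- fit_trace_slope(tr)
  expect_equal(fit$slope, 1, tolerance = 1e-6)

  est <- compute_flux(list(
    pressure_pa = 98000, v1_m3 = 0.0018, tair_k = 291.3,
    d1_m = 0.05, d2_m = 0.046, length_m = 0.06,
    trace = simulate_chamber_trace(
      123.4, 98000, 0.0018, 291.3,
      segment_geometry(0.05, 0.046, 0.06)$volume_m3, noise_sd = 0
    )
  ))
  expect_equal(est$rs_volume, 123.4, tolerance = 1e-12)
})

test_that("noise-free, shrink-free diameter series partition back to the true growth", {
  cfg <- quick_config(
    seed = 31, n_sprouts = 1,
    diel_shrink_um_per_hpa = c(oak = 0, hornbeam = 0),
    drought_shrink_um = 0, dendro_noise_um = 0
  )
  den <- simulate_diameter_series(cfg, simulate_micromet(cfg))
  one_id <- den$dendro$sprout_id[1]
  d <- dplyr::filter(den$dendro, sprout_id == one_id, year == cfg$wet_year)
  p <- zero_growth_partition(dplyr::select(d, timestamp, diameter_um))
  truth <- dplyr::filter(den$sprout_truth, sprout_id == one_id,
                         year == cfg$wet_year)
  expect_equal(max(p$gro_um), truth$true_annual_growth_um, tolerance = 1e-9)
  expect_true(all(p$twd_um == 0))
})

test_that("recovered annual growth stays within the diel-shrink / noise band", {
  cfg <- quick_config(seed = 32, n_sprouts = 1)
  den <- simulate_diameter_series(cfg, simulate_micromet(cfg))
  truth <- den$sprout_truth
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    d <- dplyr::filter(den$dendro, sprout_id == tr$sprout_id, year == tr$year)
    p <- zero_growth_partition(dplyr::select(d, timestamp, diameter_um))
    noise_bound <- tr$noise_um * (2 * sqrt(2 * log(nrow(d))) + 2)
    expect_gt(max(p$gro_um), tr$true_annual_growth_um - tr$max_diel_amplitude_um)
    expect_lt(max(p$gro_um), tr$true_annual_growth_um + noise_bound)
  }
})

test_that("the default scenario has the campaign structure of the study design", {
  cfg <- scenario_config(seed = 1)
  scen <- simulate_scenario(cfg, dendrometer = FALSE)
  man <- scen$manifest
  expect_equal(length(unique(man$sprout_id)), 4 * 2 * 6)
  expect_equal(sort(unique(man$plot_id)), sort(c("C-0", "T-0", "C-r", "T-r")))
  dates <- unique(man$date)
  expect_equal(sum(format(dates, "%Y") == "2016"), 6)
  expect_equal(sum(format(dates, "%Y") == "2017"), 4)
  expect_equal(nrow(man), 48 * 10)
  expect_true(all(man$length_mm >= 50 & man$length_mm <= 80))
  # suppression applies exactly inside the drought window of the drought year
  gt <- scen$ground_truth$fluxes
  july_aug <- gt$date %in% as.Date(c("2017-07-04", "2017-08-01"))
  expect_true(all(gt$suppression_factor[july_aug] == cfg$suppression_factor))
  expect_true(all(gt$suppression_factor[!july_aug] == 1))
})

test_that("written scenario files parse back through the readers unchanged", {
  cfg <- quick_config(seed = 61)
  scen <- simulate_scenario(cfg)
  dir <- withr::local_tempdir()
  write_scenario(scen, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- NULL
  expect_no_warning(back <- read_scenario(dir))
  expect_equal(nrow(back$manifest), nrow(scen$manifest))
  expect_equal(sort(names(back$traces)), sort(names(scen$traces)))
  expect_equal(nrow(back$dendro), nrow(scen$dendro))
  expect_equal(back$micromet$ta_c,
               scen$micromet$ta_c[order(scen$micromet$year)],
               tolerance = 1e-9)
})
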