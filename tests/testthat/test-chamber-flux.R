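make_trace <- function(slope, n = 60, c0 = 400, noise = 0) {
  t <- seq(0, n - 1)
  tibble::tibble(time_s = t, co2_ppm = c0 + slope * t +
                   if (noise > 0) rnorm(n, 0, noise) else 0)
}

test_that("trace slope fitting recovers an exact line and flags flat traces", {
  fit <- fit_trace_slope(make_trace(0.5))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$quality_flag, "ok")

  flat <- fit_trace_slope(make_trace(0))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$quality_flag, "low_r2")

  expect_error(fit_trace_slope(make_trace(1, n = 5)),
               class = "stemflux_insufficient_data_error")
  # deadband removal can push a trace under the minimum
  expect_error(fit_trace_slope(make_trace(1, n = 15), deadband = 10),
               class = "stemflux_insufficient_data_error")
})

test_that("trace slope estimator concentrates near truth as the OLS variance formula predicts", {
  t <- 0:59
  se_oracle <- 0.5 / sqrt(sum((t - mean(t))^2))
  withr::with_seed(202, {
    slopes <- replicate(300, fit_trace_slope(make_trace(1, noise = 0.5))$slope)
  })
  expect_lt(abs(mean(slopes) - 1), 4 * se_oracle / sqrt(300))
  expect_equal(sd(slopes), se_oracle, tolerance = 0.2)
  expect_gt(mean(slopes > 0.95 & slopes < 1.05), 0.95)
})

test_that("segment geometry gives elliptical-cylinder volume and mean-diameter surface", {
  g <- segment_geometry(0.04, 0.04, 0.05)
  expect_equal(g$volume_m3, pi * 0.02^2 * 0.05, tolerance = 1e-12)
  expect_equal(g$surface_m2, pi * 0.04 * 0.05, tolerance = 1e-12)
  expect_equal(g$volume_m3, 6.2832e-5, tolerance = 1e-4)
  expect_equal(g$surface_m2, 6.2832e-3, tolerance = 1e-4)

  g2 <- segment_geometry(0.04, 0.06, 0.07)
  expect_equal(g2$volume_m3, 1.3195e-4, tolerance = 1e-4)

  # circular cylinder identity surface/volume = 4/d
  for (d in c(0.03, 0.045, 0.057)) {
    g3 <- segment_geometry(d, d, 0.06)
    expect_equal(g3$surface_m2 / g3$volume_m3, 4 / d, tolerance = 1e-12)
  }

  expect_error(segment_geometry(-0.04, 0.04, 0.05),
               class = "stemflux_validation_error")
  expect_warning(segment_geometry(0.04, 0.04, 0.2), "0.05-0.08")
})

base_measurement <- function(slope = 1, ...) {
  # length chosen so V2 = pi * 0.02^2 * L = 1e-4 m^3
  defaults <- list(
    pressure_pa = 101325, v1_m3 = 0.002, tair_k = 298.15,
    d1_m = 0.04, d2_m = 0.04, length_m = 1e-4 / (pi * 4e-4),
    trace = make_trace(slope)
  )
  utils::modifyList(defaults, list(...))
}

test_that("flux equation reproduces the dimensional-analysis worked example", {
  est <- suppressWarnings(compute_flux(base_measurement()))
  # 101325 * 0.002 / (8.314 * 298.15 * 1e-4)
  expect_equal(est$rs_volume, 817.5264, tolerance = 1e-6)
  expect_equal(est$volume_m3, 1e-4, tolerance = 1e-12)

  zero <- suppressWarnings(compute_flux(base_measurement(slope = 0)))
  expect_equal(zero$rs_volume, 0)

  neg <- suppressWarnings(compute_flux(base_measurement(slope = -0.2)))
  expect_lt(neg$rs_volume, 0)
  expect_equal(neg$quality_flag, "negative_slope")
})

test_that("flux scales linearly in slope and V1, inversely in T and V2", {
  est <- suppressWarnings(compute_flux(base_measurement()))
  est2 <- suppressWarnings(compute_flux(base_measurement(slope = 2)))
  expect_equal(est2$rs_volume, 2 * est$rs_volume, tolerance = 1e-9)
  estv1 <- suppressWarnings(compute_flux(base_measurement(v1_m3 = 0.004)))
  expect_equal(estv1$rs_volume, 2 * est$rs_volume, tolerance = 1e-9)
  estt <- suppressWarnings(compute_flux(base_measurement(tair_k = 2 * 298.15)))
  expect_equal(estt$rs_volume, est$rs_volume / 2, tolerance = 1e-9)
  estv2 <- suppressWarnings(compute_flux(
    base_measurement(length_m = 2 * 1e-4 / (pi * 4e-4))
  ))
  expect_equal(estv2$rs_volume, est$rs_volume / 2, tolerance = 1e-9)
})

test_that("per-surface and per-volume efflux conserve the segment total", {
  withr::with_seed(33, {
    for (i in 1:20) {
      m <- base_measurement(
        slope = runif(1, 0.05, 1.5),
        d1_m = runif(1, 0.03, 0.06), d2_m = runif(1, 0.03, 0.06),
        length_m = runif(1, 0.05, 0.08)
      )
      est <- compute_flux(m)
      expect_equal(est$rs_surface * est$surface_m2,
                   est$rs_volume * est$volume_m3, tolerance = 1e-12)
    }
  })
  # circular segment: rs_surface = rs_volume * d / 4, the low end of the
  # field range (6 per volume ~ 0.06 per surface at d = 0.04 m)
  g <- segment_geometry(0.04, 0.04, 0.06)
  expect_equal(6 * g$volume_m3 / g$surface_m2, 0.06, tolerance = 1e-12)
})

test_that("Q10 normalization halves, doubles and round-trips exactly", {
  expect_equal(normalize_q10(100, ts = 15), 100)
  expect_equal(normalize_q10(100, ts = 25), 50)
  expect_equal(normalize_q10(100, ts = 5), 200)
  # literal printed sign convention scales warm measurements up instead
  expect_equal(normalize_q10(100, ts = 25, literal_exponent = TRUE), 200)

  withr::with_seed(44, {
    rs <- runif(200, 1, 700)
    ts <- runif(200, 0, 35)
  })
  back <- normalize_q10(normalize_q10(rs, ts), t_ref = ts, ts = 15)
  expect_equal(back, rs, tolerance = 1e-12)
  expect_error(normalize_q10(100, 20, q10 = -1), class = "stemflux_validation_error")
})

test_that("manifest-level flux computation joins traces and flags missing files", {
  cfg <- quick_config(seed = 5)
  scen <- simulate_scenario(cfg, dendrometer = FALSE)
  fx <- compute_fluxes(scen$manifest, scen$traces)
  expect_equal(nrow(fx), nrow(scen$manifest))
  expect_true(all(c("rs_volume", "rs_surface", "r15", "quality_flag") %in% names(fx)))
  expect_error(
    compute_fluxes(scen$manifest, scen$traces[-1]),
    regexp = scen$manifest$trace_file[1],
    class = "stemflux_missing_input_error"
  )
})
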