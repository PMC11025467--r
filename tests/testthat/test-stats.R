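test_that("linear fit matches exact lines and flags flat responses", {
  f <- fit_linear(1:3, 1:3)
  expect_equal(f$coefficients$estimate, c(0, 1), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  flat <- fit_linear(1:3, c(2, 2, 2))
  expect_equal(flat$coefficients$estimate, c(2, 0), tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$flag, "flat_response")

  expect_error(fit_linear(c(1, 1, 1), 1:3), class = "stemflux_degenerate_fit_error")
  expect_error(fit_linear(1, 1), class = "stemflux_insufficient_data_error")
})

test_that("linear fit agrees with the normal-equations oracle on random designs", {
  withr::with_seed(909, {
    for (i in 1:25) {
      n <- sample(5:40, 1)
      x <- rnorm(n, 10, 4)
      y <- rnorm(n, 2 + 0.7 * x, 3)
      f <- fit_linear(x, y)
      o <- line_oracle(x, y)
      expect_equal(f$coefficients$estimate, unname(o$coef), tolerance = 1e-10)
      expect_equal(f$coefficients$std_error, unname(o$se), tolerance = 1e-10)
      expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
      expect_equal(f$residual_se, o$sigma, tolerance = 1e-10)
    }
  })
})

test_that("a field-scale noisy efflux-temperature fit recovers its slope", {
  withr::with_seed(15, {
    x <- runif(20, 12, 25)
    y <- 23.3 * x - 271.5 + rnorm(20, 0, 20)
  })
  f <- fit_linear(x, y)
  o <- line_oracle(x, y)
  expect_equal(f$coefficients$estimate[2], unname(o$coef[2]), tolerance = 1e-10)
  expect_true(f$coefficients$estimate[2] > 20 && f$coefficients$estimate[2] < 27)
})

test_that("exponential fit back-transforms exactly and loses to linear on linear data", {
  x <- seq(1, 10)
  f <- fit_exponential(x, 2 * exp(0.1 * x))
  expect_equal(f$coefficients$estimate, c(2, 0.1), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  y_lin <- x + 10
  r2_exp <- fit_exponential(x, y_lin)$r_squared
  r2_lin <- fit_linear(x, y_lin)$r_squared
  expect_lt(r2_exp, r2_lin)
  expect_equal(r2_lin, 1, tolerance = 1e-12)

  expect_error(fit_exponential(x, c(-1, 2:10)), class = "stemflux_domain_error")
  expect_error(fit_exponential(1, 2), class = "stemflux_insufficient_data_error")
})

test_that("rs_fit prediction, tidy and glance expose the fit consistently", {
  f <- fit_linear(c(1, 2, 3, 4), c(3, 5, 7, 9))
  expect_equal(predict(f, c(0, 10)), c(1, 21), tolerance = 1e-12)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value"))
  expect_equal(glance(f)$r_squared, 1, tolerance = 1e-12)
  e <- fit_exponential(1:5, 3 * exp(0.2 * (1:5)))
  expect_equal(predict(e, 2), 3 * exp(0.4), tolerance = 1e-8)
})

test_that("drought effect computes residuals and percent-of-expected per plot", {
  fit <- fit_linear(c(0, 10, 20, 30), c(0, 10, 20, 30)) # slope 1, intercept 0
  pts <- tibble::tibble(
    date = as.Date("2017-07-04"), species = "oak",
    plot_id = c("C-0", "T-0"), tstem_c = c(20, 20), rs_volume = c(20, 10)
  )
  de <- drought_effect(pts, list(oak = fit))
  expect_equal(de$residual_mean, mean(c(0, -10)))
  expect_equal(de$percent_mean, mean(c(100, 50)))
  expect_equal(de$n_plots, 2L)

  # per-point identity residual = predicted * (percent/100 - 1)
  withr::with_seed(77, {
    pts2 <- tibble::tibble(
      date = as.Date("2017-08-01"), species = "oak",
      plot_id = sprintf("P%d", 1:4),
      tstem_c = runif(4, 15, 25), rs_volume = runif(4, 10, 300)
    )
  })
  ref <- fit_linear(c(12, 18, 22, 26), c(10, 140, 240, 330))
  predicted <- predict(ref, pts2$tstem_c)
  de2 <- drought_effect(pts2, list(oak = ref))
  resid_pts <- pts2$rs_volume - predicted
  pct_pts <- 100 * pts2$rs_volume / predicted
  expect_equal(de2$residual_mean, mean(resid_pts), tolerance = 1e-12)
  expect_equal(resid_pts, predicted * (pct_pts / 100 - 1), tolerance = 1e-12)

  # a predicted efflux at or below zero cannot define a percent
  cold <- tibble::tibble(
    date = as.Date("2017-06-07"), species = "oak", plot_id = "C-0",
    tstem_c = 5, rs_volume = 10
  )
  steep <- fit_linear(c(15, 20, 25, 30), 23.3 * c(15, 20, 25, 30) - 271.5)
  expect_warning(out <- drought_effect(cold, list(oak = steep)), "non-positive")
  expect_equal(out$n_excluded, 1L)
  expect_true(is.nan(out$percent_mean) || is.na(out$percent_mean))
})

test_that("species comparison reproduces exact intercept and slope differences", {
  x <- rep(seq(0, 10, length.out = 6), 2)
  data <- tibble::tibble(
    species = rep(c("A", "B"), each = 6),
    increment_um_d = x,
    r15 = c(100 + x[1:6], 50 + 3 * x[7:12])
  )
  gf <- compare_species_growth_fit(data)
  expect_equal(gf$per_species$intercept, c(100, 50), tolerance = 1e-10)
  expect_equal(gf$per_species$slope, c(1, 3), tolerance = 1e-10)
  expect_equal(gf$comparison$estimate, c(-50, 2), tolerance = 1e-10)

  same <- dplyr::mutate(data, r15 = 100 + increment_um_d)
  gf0 <- compare_species_growth_fit(same)
  expect_equal(gf0$comparison$estimate, c(0, 0), tolerance = 1e-10)

  single <- dplyr::filter(data, species == "A")
  expect_warning(gf1 <- compare_species_growth_fit(single), "one species")
  expect_equal(gf1$per_species$slope, 1, tolerance = 1e-10)

  expect_error(compare_species_growth_fit(data[c(1, 2, 7, 8), ]),
               class = "stemflux_insufficient_data_error")
})

test_that("species comparison equals the normal-equations oracle with interaction", {
  withr::with_seed(404, {
    n <- 12
    x <- runif(2 * n, 0, 100)
    sp <- rep(c(0, 1), each = n)
    y <- 80 + 0.9 * x + 25 * sp + 0.6 * sp * x + rnorm(2 * n, 0, 10)
  })
  data <- tibble::tibble(
    species = ifelse(sp == 0, "oak", "hornbeam")[order(sp)],
    increment_um_d = x[order(sp)], r15 = y[order(sp)]
  )
  # oracle design: intercept, species indicator (level 2), x, interaction;
  # factor levels sort alphabetically: hornbeam = 0, oak = 1
  lev2 <- as.numeric(data$species == "oak")
  o <- ols_oracle(cbind(1, lev2, data$increment_um_d, lev2 * data$increment_um_d),
                  data$r15)
  gf <- compare_species_growth_fit(data)
  expect_equal(gf$comparison$estimate, unname(o$coef[c(2, 4)]), tolerance = 1e-10)
  expect_equal(gf$comparison$std_error, unname(o$se[c(2, 4)]), tolerance = 1e-10)
  expect_equal(gf$per_species$intercept,
               c(o$coef[1], o$coef[1] + o$coef[2]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("ratio at rate is anchored at 100 percent under zero increment", {
  data <- tibble::tibble(
    species = rep(c("A", "B"), each = 4),
    increment_um_d = rep(c(0, 20, 60, 100), 2),
    r15 = c(100 + 3 * c(0, 20, 60, 100), 50 + 2 * c(0, 20, 60, 100))
  )
  gf <- compare_species_growth_fit(data)
  r0 <- ratio_at_rate(gf, 0)
  expect_equal(r0$ratio_pct, c(100, 100), tolerance = 1e-10)
  rA <- ratio_at_rate(gf, 100, species = "A")
  expect_equal(rA$ratio_pct, 400, tolerance = 1e-10) # (100 + 300) / 100
})

test_that("Pearson correlation handles exact, null and degenerate relations", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  withr::with_seed(55, {
    x <- rnorm(1000)
    y <- rnorm(1000)
  })
  pc <- pearson_correlation(x, y)
  expect_lt(abs(pc$r), 0.1)
  expect_equal(pc$n, 1000L)
  expect_error(pearson_correlation(rep(1, 5), 1:5),
               class = "stemflux_degenerate_fit_error")
  expect_error(pearson_correlation(1:2, 1:2),
               class = "stemflux_insufficient_data_error")
})

test_that("campaign aggregation averages sprouts per plot and drops flagged fluxes", {
  fx <- tibble::tibble(
    date = as.Date("2016-06-07"), species = "oak", plot_id = "C-0",
    tstem_c = c(18, 18, 20), rs_volume = c(100, 200, -5),
    rs_surface = c(1, 2, -0.05), r15 = c(90, 180, -4),
    quality_flag = c("ok", "ok", "negative_slope")
  )
  m <- campaign_plot_means(fx)
  expect_equal(m$rs_volume, 150)
  expect_equal(m$n_sprouts, 2L)
})
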