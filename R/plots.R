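# ggplot2 graphics for the main result types.

#' Plot a partitioned dendrometer series
#'
#' Stacked panels of raw diameter, cumulative growth (GRO) and tree water
#' deficit (TWD) from [zero_growth_partition()].
#'
#' @param partitioned Output of [zero_growth_partition()] (one sprout, or
#'   faceted by `sprout_id` when present for up to 6 sprouts).
#' @return A ggplot object.
#' @export
plot_dendro_partition <- function(partitioned) {
  check_columns(partitioned, c("timestamp", "diameter_um", "gro_um", "twd_um"),
                "partitioned series")
  long <- partitioned %>%
    select(dplyr::any_of(c("sprout_id")), "timestamp", "diameter_um",
           "gro_um", "twd_um") %>%
    tidyr::pivot_longer(c("diameter_um", "gro_um", "twd_um"),
                        names_to = "component", values_to = "value") %>%
    mutate(component = factor(.data$component,
                              levels = c("diameter_um", "gro_um", "twd_um"),
                              labels = c("diameter", "growth (GRO)", "water deficit (TWD)")))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$timestamp, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "µm") +
    ggplot2::theme_minimal()
  if ("sprout_id" %in% names(long)) {
    p + ggplot2::facet_grid(component ~ sprout_id, scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y")
  }
}

#' Plot drought-year percent-of-expected efflux
#'
#' Per-date means with SD bars of the percent of efflux expected from the
#' reference-year efflux-temperature regression, by species; the 100 percent
#' line marks "no drought effect".
#'
#' @param effect Output of [drought_effect()].
#' @return A ggplot object.
#' @export
plot_drought_effect <- function(effect) {
  check_columns(effect, c("date", "species", "percent_mean", "percent_sd"),
                "drought effect table")
  ggplot2::ggplot(effect, ggplot2::aes(.data$date, .data$percent_mean,
                                       colour = .data$species)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$percent_mean - .data$percent_sd,
      ymax = .data$percent_mean + .data$percent_sd
    ), position = ggplot2::position_dodge(width = 2)) +
    ggplot2::labs(x = NULL, y = "Rs, % of expected from reference year",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_species_growth_fit Scatter of R15 against increment
#'   rate with the fitted per-species lines.
#' @param object A `growth_fit`.
#' @param data Optional original data (`species`, `increment_um_d`, `r15`)
#'   to draw as points; defaults to the model frame.
#' @param ... Unused.
#' @export
autoplot.growth_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    mf <- object$model$model
    data <- tibble(
      species = if ("species" %in% names(mf)) as.character(mf$species) else object$species,
      increment_um_d = mf$increment_um_d, r15 = mf$r15
    )
  }
  ggplot2::ggplot(data, ggplot2::aes(.data$increment_um_d, .data$r15,
                                     colour = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = object$per_species,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$species)
    ) +
    ggplot2::labs(x = "mean increment rate (µm day⁻¹)",
                  y = "R15 (µmol m⁻³ s⁻¹)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_linear Scatter with the fitted line (linear or
#'   back-transformed exponential).
#' @param object An `rs_fit`.
#' @param data Optional tibble with `x` and `y` columns to plot as points;
#'   defaults to the model frame.
#' @param ... Unused.
#' @export
autoplot.rs_fit <- function(object, data = NULL, ...) {
  mf <- object$model$model
  if (is.null(data)) {
    data <- tibble(x = mf[[2]], y = if (object$kind == "exponential") exp(mf[[1]]) else mf[[1]])
  }
  grid <- tibble(x = seq(min(data$x), max(data$x), length.out = 100))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::theme_minimal()
}
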