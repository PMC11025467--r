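# Zero-growth partitioning of dendrometer series.
#
# Band dendrometers record both irreversible radial growth and reversible
# water-related shrinking/swelling. Under the zero-growth assumption the stem
# grows only when its diameter exceeds the preceding maximum; every dip below
# the running maximum is tree water deficit (TWD), a proxy for stem
# dehydration. With M(t) = running max of diameter up to t:
#   GRO(t) = M(t) - diameter(first)   (cumulative growth, non-decreasing)
#   TWD(t) = M(t) - diameter(t)       (>= 0)
# so that diameter(t) = diameter(first) + GRO(t) - TWD(t) exactly.

#' Partition a dendrometer series into growth and tree water deficit
#'
#' Applies the zero-growth approach: diameter variation above the preceding
#' maximum is irreversible growth (`gro_um`), variation below it is tree
#' water deficit (`twd_um`). The running maximum carries across data gaps
#' (the stem does not reset); gaps longer than `gap_hours` mark the first
#' observation after the gap in `after_gap` so daily statistics can ignore
#' those days. Hour-to-hour jumps larger than `jump_threshold_um` are flagged
#' in `jump_flag` but never altered.
#'
#' @param data Data frame with columns `timestamp` (strictly increasing) and
#'   `diameter_um` (cumulative displacement, micrometers). An optional
#'   `sprout_id` column partitions each sprout independently.
#' @param gap_hours Gap length (hours) beyond which the following observation
#'   is flagged `after_gap` (default 6).
#' @param jump_threshold_um Absolute hourly change flagged as a probable
#'   sensor jump (default 500).
#' @return Tibble with the input identifiers plus `diameter_um`, `gro_um`,
#'   `twd_um`, `after_gap`, `jump_flag`. `gro_um` is non-decreasing and
#'   starts at 0; `twd_um >= 0` and starts at 0.
#' @examples
#' d <- tibble::tibble(
#'   timestamp = as.POSIXct("2016-06-01", tz = "UTC") + 3600 * (0:3),
#'   diameter_um = c(100, 101, 100.5, 102)
#' )
#' zero_growth_partition(d) # gro 0,1,1,2; twd 0,0,0.5,0
#' @export
zero_growth_partition <- function(data, gap_hours = 6, jump_threshold_um = 500) {
  check_columns(data, c("timestamp", "diameter_um"), "dendrometer series")
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    abort_insufficient_data("Dendrometer series is empty.")
  }

  partition_one <- function(d) {
    d <- filter(d, !is.na(.data$diameter_um))
    if (nrow(d) == 0) abort_insufficient_data("Dendrometer series has no valid observations.")
    check_strictly_increasing(d$timestamp, "timestamp", "dendrometer series")
    m <- cummax(d$diameter_um)
    dt_h <- c(0, diff(as.numeric(d$timestamp)) / 3600)
    step <- c(0, diff(d$diameter_um))
    mutate(d,
      gro_um = m - d$diameter_um[1],
      twd_um = m - d$diameter_um,
      after_gap = dt_h > gap_hours,
      jump_flag = abs(step) > jump_threshold_um
    )
  }

  if ("sprout_id" %in% names(data)) {
    data %>%
      group_by(.data$sprout_id) %>%
      dplyr::group_modify(~ partition_one(.x)) %>%
      ungroup()
  } else {
    partition_one(data)
  }
}

#' Daily growth and water-deficit statistics
#'
#' Per local calendar day: the daily increment rate (last `gro_um` of the day
#' minus last `gro_um` of the previous day with data, in um day^-1) and the
#' daily TWD maximum (um), plus their 7-day centered moving averages
#' (see [moving_average()]). Days directly after a flagged data gap get
#' `NA` increments (the difference would span the gap).
#'
#' @param partitioned Output of [zero_growth_partition()] for one sprout, or
#'   with a `sprout_id` column for several.
#' @param window Moving-average window in days (default 7).
#' @param min_periods Minimum non-missing days inside the window for the
#'   average to be defined (default 4).
#' @param align `"center"` (default) or `"right"` (trailing) window.
#' @return Tibble: `date`, `increment_um_d`, `twd_max_um`,
#'   `increment_um_d_ma7`, `twd_max_um_ma7` (and `sprout_id` if present).
#' @export
daily_growth_stats <- function(partitioned, window = 7, min_periods = 4,
                               align = c("center", "right")) {
  align <- arg_match(align)
  check_columns(partitioned, c("timestamp", "gro_um", "twd_um"), "partitioned series")

  stats_one <- function(d) {
    daily <- d %>%
      mutate(date = as.Date(.data$timestamp)) %>%
      group_by(.data$date) %>%
      summarise(
        gro_last = last(.data$gro_um),
        twd_max_um = max(.data$twd_um),
        any_gap = any(.data$after_gap),
        .groups = "drop"
      ) %>%
      arrange(.data$date)
    # complete the calendar so moving averages see missing days as missing
    full <- tibble(date = seq(min(daily$date), max(daily$date), by = "day")) %>%
      left_join(daily, by = "date") %>%
      mutate(
        increment_um_d = .data$gro_last - lag(.data$gro_last),
        increment_um_d = if_else(
          !is.na(.data$any_gap) & .data$any_gap, NA_real_, .data$increment_um_d
        )
      )
    full %>%
      mutate(
        increment_um_d_ma7 = moving_average(.data$increment_um_d, window, min_periods, align),
        twd_max_um_ma7 = moving_average(.data$twd_max_um, window, min_periods, align)
      ) %>%
      select("date", "increment_um_d", "twd_max_um",
             "increment_um_d_ma7", "twd_max_um_ma7")
  }

  if ("sprout_id" %in% names(partitioned)) {
    as_tibble(partitioned) %>%
      group_by(.data$sprout_id) %>%
      dplyr::group_modify(~ stats_one(.x)) %>%
      ungroup()
  } else {
    stats_one(as_tibble(partitioned))
  }
}

#' Moving average with a minimum-coverage rule
#'
#' Arithmetic moving average over a `window`-day window, centered by default
#' (a trailing variant is available). Windows holding fewer than
#' `min_periods` non-missing values yield `NA`; otherwise missing values are
#' dropped from the mean.
#'
#' @param x Numeric vector (daily series; may contain `NA`).
#' @param window Window length, >= 1 (default 7).
#' @param min_periods Minimum non-missing values required (default 4).
#' @param align `"center"` or `"right"`.
#' @return Numeric vector, same length as `x`.
#' @examples
#' moving_average(1:7)[4] # 4
#' @export
moving_average <- function(x, window = 7, min_periods = 4, align = c("center", "right")) {
  align <- arg_match(align)
  if (window < 1) abort_validation("`window` must be >= 1 day.")
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (align == "center") {
      lo <- i - (window - 1) %/% 2
      hi <- i + window %/% 2
    } else {
      lo <- i - window + 1
      hi <- i
    }
    vals <- x[max(1, lo):min(n, hi)]
    vals <- vals[!is.na(vals)]
    if (length(vals) >= min_periods) out[i] <- mean(vals)
  }
  out
}

#' Cumulative daily tree water deficit
#'
#' Running sum of the daily TWD maxima from a start date onward — the
#' quantity used to compare accumulated stem dehydration between seasons
#' (e.g. "cumulative TWD from July"). Missing days contribute zero.
#'
#' @param daily Output of [daily_growth_stats()] (optionally with
#'   `sprout_id`).
#' @param from_date Start date of the accumulation (anything `as.Date()`
#'   accepts). Defaults to the first date present.
#' @return `daily` restricted to `date >= from_date` with a monotone
#'   non-decreasing `twd_cum_um` column appended.
#' @export
cumulative_twd <- function(daily, from_date = NULL) {
  check_columns(daily, c("date", "twd_max_um"), "daily stats")
  daily <- as_tibble(daily)
  if (is.null(from_date)) from_date <- min(daily$date)
  from_date <- as.Date(from_date)
  if (from_date > max(daily$date)) {
    abort_validation("`from_date` lies after the end of the daily series.")
  }
  cum_one <- function(d) {
    d %>%
      filter(.data$date >= from_date) %>%
      arrange(.data$date) %>%
      mutate(twd_cum_um = cumsum(tidyr::replace_na(.data$twd_max_um, 0)))
  }
  if ("sprout_id" %in% names(daily)) {
    daily %>%
      group_by(.data$sprout_id) %>%
      dplyr::group_modify(~ cum_one(.x)) %>%
      ungroup()
  } else {
    cum_one(daily)
  }
}
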