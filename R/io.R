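# CSV readers for the pipeline's interchange formats. All files are UTF-8,
# comma-separated, "." decimal, ISO-8601 timestamps.

read_csv_strict <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort_missing_input(sprintf("%s file not found: %s.", what, path))
  }
  out <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort_validation(sprintf(
      "%s file %s has %d parsing problem(s); first at row %d, column %s.",
      what, path, nrow(prob), prob$row[1], prob$col[1]
    ))
  }
  out
}

#' Read an hourly micrometeorology CSV
#'
#' Expects columns `timestamp` (ISO-8601), `ta_c`, `rh_pct`, `precip_mm`,
#' `swc_pct` (nullable) and optionally `plot_id`, `shallow_swc_pct`. The
#' table is validated with [validate_micromet()].
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_micromet_csv <- function(path) {
  out <- read_csv_strict(path, readr::cols(
    timestamp = readr::col_datetime(),
    plot_id = readr::col_character(),
    ta_c = readr::col_double(),
    rh_pct = readr::col_double(),
    precip_mm = readr::col_double(),
    swc_pct = readr::col_double(),
    .default = readr::col_double()
  ), "Micromet")
  validate_micromet(out)
  out
}

#' Read a dendrometer CSV
#'
#' Expects columns `sprout_id`, `timestamp` (ISO-8601, strictly increasing
#' per sprout) and `diameter_um`; extra identifier columns (`plot_id`,
#' `species`) are kept.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_dendro_csv <- function(path) {
  out <- read_csv_strict(path, readr::cols(
    timestamp = readr::col_datetime(),
    diameter_um = readr::col_double(),
    .default = readr::col_character()
  ), "Dendrometer")
  check_columns(out, c("sprout_id", "timestamp", "diameter_um"),
                sprintf("dendrometer file %s", path))
  for (g in split(out, out$sprout_id)) {
    check_strictly_increasing(g$timestamp, "timestamp",
                              sprintf("dendrometer file %s", path))
  }
  out
}

#' Read a campaign manifest CSV
#'
#' One row per chamber measurement; see [compute_fluxes()] for the column
#' contract. Nonpositive geometry raises a validation error naming the file.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_campaign_manifest <- function(path) {
  out <- read_csv_strict(path, readr::cols(
    date = readr::col_date(),
    sprout_id = readr::col_character(),
    plot_id = readr::col_character(),
    species = readr::col_character(),
    trace_file = readr::col_character(),
    .default = readr::col_double()
  ), "Campaign manifest")
  check_columns(out, c(
    "sprout_id", "plot_id", "species", "date", "d1_mm", "d2_mm", "length_mm",
    "v1_m3", "pressure_pa", "tair_k", "tstem_c", "trace_file"
  ), sprintf("manifest %s", path))
  num <- c("d1_mm", "d2_mm", "length_mm", "v1_m3", "pressure_pa", "tair_k")
  for (cn in num) {
    bad <- which(!is.na(out[[cn]]) & out[[cn]] <= 0)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Manifest %s: `%s` must be positive (row %d).", path, cn, bad[1]
      ))
    }
  }
  out
}

#' Read a 1-Hz chamber trace CSV
#'
#' Expects columns `time_s` (strictly increasing) and `co2_ppm`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_chamber_trace <- function(path) {
  out <- read_csv_strict(path, readr::cols(
    time_s = readr::col_double(),
    co2_ppm = readr::col_double()
  ), "Chamber trace")
  check_columns(out, c("time_s", "co2_ppm"), sprintf("trace %s", path))
  out
}
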