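#' Long-term seamount monitoring site reference table
#'
#' Metadata for the twelve long-term monitoring sites on three Northeast
#' Pacific seamounts (NEPDEP 54, SG̲áan K̲ínghlas-Bowie, Explorer), established
#' in 2018 and resurveyed 3-5 years later. Mean dissolved oxygen
#' concentrations (mL/L) are survey-period averages from the vehicle's oxygen
#' sensor; four NEPDEP 54 revisit values are missing because of sensor
#' calibration problems and are `NA`.
#'
#' @return A tibble with one row per site: `site_id`, `seamount`, `latitude`,
#'   `longitude`, `depth_m` (positive down), `t0_year`, `t1_year`,
#'   `o2_t0_ml_l`, `o2_t1_ml_l`.
#' @examples
#' monitoring_sites()
#' dplyr::mutate(monitoring_sites(), zone = classify_zone(o2_t0_ml_l))
#' @export
monitoring_sites <- function() {
  tibble::tribble(
    ~site_id,  ~seamount,   ~latitude, ~longitude, ~depth_m, ~t0_year, ~t1_year, ~o2_t0_ml_l, ~o2_t1_ml_l,
    "N54-01",  "NEPDEP 54",  50.722,   -130.921,    833,      2018,     2021,     0.15,        0.27,
    "N54-02",  "NEPDEP 54",  50.757,   -130.888,    625,      2018,     2021,     0.30,        NA,
    "N54-03",  "NEPDEP 54",  50.7577,  -130.886,    640,      2018,     2021,     0.23,        NA,
    "N54-04",  "NEPDEP 54",  50.757,   -130.887,    633,      2018,     2021,     0.24,        NA,
    "N54-06",  "NEPDEP 54",  50.757,   -130.889,    607,      2018,     2021,     0.29,        NA,
    "SK-B-06", "SK-B",       53.322,   -135.536,    1111,     2018,     2022,     0.15,        0.39,
    "SK-B-07", "SK-B",       53.322,   -135.562,    644,      2018,     2022,     0.32,        0.39,
    "SK-B-08", "SK-B",       53.321,   -135.545,    828,      2018,     2022,     0.14,        0.34,
    "SK-B-11", "SK-B",       53.281,   -135.765,    467,      2018,     2022,     0.87,        0.95,
    "SK-B-12", "SK-B",       53.28,    -135.763,    350,      2018,     2023,     1.43,        1.22,
    "EX-01",   "Explorer",   49.058,   -130.942,    799,      2018,     2023,     0.13,        0.25,
    "EX-02",   "Explorer",   49.058,   -130.94,     868,      2018,     2023,     0.13,        0.25
  )
}

#' Read a site metadata table
#'
#' Reads a CSV of monitoring-site metadata and validates it. Required columns
#' are `site_id`, `seamount`, `latitude`, `longitude`, `depth_m`, `t0_year`,
#' `t1_year`; oxygen means and area columns are optional.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of site records.
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("Site metadata file not found: ", path))
  sites <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("site_id", "seamount", "latitude", "longitude", "depth_m",
                "t0_year", "t1_year")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    abort(paste0("Site metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sites$site_id)) abort("Duplicate site_id in site metadata.")
  if (any(sites$t1_year <= sites$t0_year)) {
    abort("t1_year must be greater than t0_year for every site.")
  }
  if (any(sites$depth_m <= 0)) abort("depth_m must be positive (metres below surface).")
  if (all(c("t0_area", "overlap_area") %in% names(sites))) {
    bad <- !is.na(sites$t0_area) & !is.na(sites$overlap_area) &
      (sites$overlap_area <= 0 | sites$overlap_area > sites$t0_area)
    if (any(bad)) abort("overlap_area must satisfy 0 < overlap_area <= t0_area.")
  }
  tibble::as_tibble(sites)
}
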