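#' Read and write the half-hourly flux CSV
#'
#' The interchange format for all pipeline stages: RFC 4180 CSV, UTF-8,
#' ISO-8601 timestamps (CET, UTC+1), dot decimals, and a leading comment
#' line documenting the sign convention (all fluxes micrometeorological,
#' negative = uptake). Required columns: `timestamp`, `nee`
#' (umol m-2 s-1), `fcos_eco` (pmol m-2 s-1), `chi_co2_ppm`, `chi_cos_ppt`,
#' `par`, `t_air`, `t_soil`, `swc`, `sw_soil`. Any further columns (e.g.
#' `true_*` truth columns of synthetic campaigns, or `fcos_canopy`) round-
#' trip untouched.
#'
#' Reading enforces strictly increasing half-hourly timestamps: duplicates
#' are an error, unsorted files are sorted with a warning, and missing
#' values in data columns are allowed (they stay `NA`). Mole-fraction
#' columns are renamed to the internal `chi_co2` / `chi_cos`.
#'
#' @param path File path.
#' @return Tibble of half-hourly records.
#' @export
read_flux_csv <- function(path) {
  req <- c("timestamp", "nee", "fcos_eco", "chi_co2_ppm", "chi_cos_ppt",
           "par", "t_air", "t_soil", "swc", "sw_soil")
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(timestamp = readr::col_character(),
                                                  .default = readr::col_guess()))
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    abort(paste0("Flux CSV is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  data$timestamp <- lubridate::ymd_hms(data$timestamp, tz = "Etc/GMT-1")
  if (anyNA(data$timestamp)) abort("Unparseable timestamp(s) in flux CSV.")
  if (anyDuplicated(data$timestamp)) {
    abort("Duplicate timestamps in flux CSV.")
  }
  if (is.unsorted(data$timestamp)) {
    warn("Flux CSV rows were not sorted by timestamp; sorting.")
    data <- arrange(data, .data$timestamp)
  }
  steps <- diff(as.numeric(data$timestamp))
  if (any(steps != 1800)) {
    warn(sprintf("%d gap(s) in the half-hourly timestamp sequence.",
                 sum(steps != 1800)))
  }
  data |> rename(chi_co2 = "chi_co2_ppm", chi_cos = "chi_cos_ppt")
}

#' @rdname read_flux_csv
#' @param data Half-hourly tibble (internal column names `chi_co2`,
#'   `chi_cos` are written out as `chi_co2_ppm`, `chi_cos_ppt`).
#' @export
write_flux_csv <- function(data, path) {
  data <- as_tibble(data)
  if ("chi_co2" %in% names(data)) data <- rename(data, chi_co2_ppm = "chi_co2")
  if ("chi_cos" %in% names(data)) data <- rename(data, chi_cos_ppt = "chi_cos")
  data$timestamp <- format(data$timestamp, "%Y-%m-%dT%H:%M:%S")
  writeLines(paste("# cosflux half-hourly records; fluxes in the",
                   "micrometeorological convention (negative = uptake);",
                   "chi_co2 in ppm, chi_cos in ppt; timestamps CET (UTC+1)"),
             path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write the soil chamber CSV
#'
#' Columns: `timestamp`, `q_lpm`, `temp_c`, `press_hpa`, `c_ambient_ppt`,
#' `c_chamber_ppt`, `area_m2`, `stable_flag`; extra columns round-trip.
#'
#' @param path File path.
#' @return Tibble of chamber measurements.
#' @export
read_chamber_csv <- function(path) {
  req <- c("timestamp", "q_lpm", "temp_c", "press_hpa", "c_ambient_ppt",
           "c_chamber_ppt", "area_m2", "stable_flag")
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(timestamp = readr::col_character(),
                                                  .default = readr::col_guess()))
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    abort(paste0("Chamber CSV is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  data$timestamp <- lubridate::ymd_hms(data$timestamp, tz = "Etc/GMT-1")
  data$stable_flag <- as.logical(data$stable_flag)
  data
}

#' @rdname read_chamber_csv
#' @param data Chamber tibble.
#' @export
write_chamber_csv <- function(data, path) {
  data <- as_tibble(data)
  data$timestamp <- format(data$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(data, path)
  invisible(path)
}

#' Published campaign reference estimates
#'
#' The site-level headline numbers reported for the four field campaigns
#' the scenario presets emulate: the optimal high-light LRU (`iota_opt`)
#' per site and the campaign percent difference of FP+ over FP GPP sums
#' (`gpp_pct_diff`, with its temporal-variability sd). Shipped so that the
#' cross-site summary arithmetic (mean optimal iota, mean and sd of the
#' percent differences) can be recomputed with the package's own summary
#' functions.
#'
#' @return Tibble with columns `site`, `iota_opt`, `gpp_pct_diff`,
#'   `gpp_pct_sd`.
#' @examples
#' campaign_reference_estimates() |>
#'   dplyr::summarise(iota_mean = mean(iota_opt),
#'                    diff_mean = mean(gpp_pct_diff),
#'                    diff_sd = sd(gpp_pct_diff))
#' @export
campaign_reference_estimates <- function() {
  tibble(
    site = c("GRA", "SAV", "DBF", "CRO"),
    iota_opt = c(1.02, 2.27, 2.22, 0.89),
    gpp_pct_diff = c(5.08, 6.08, 4.20, 1.79),
    gpp_pct_sd = c(1.23, 1.05, 0.13, 0.74)
  )
}
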