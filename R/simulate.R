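#' Site scenarios for synthetic half-hourly campaigns
#'
#' A scenario bundles everything needed to generate a synthetic measurement
#' campaign with known truth: diel meteorology scales, true process-model
#' parameters, a soil COS source/sink rule and observation noise. Four
#' presets emulate the four field campaigns behind the method — a managed
#' mountain grassland (`GRA`), a Mediterranean savanna (`SAV`), a temperate
#' beech forest (`DBF`) and a soybean crop (`CRO`) — with high-light LRU
#' values of 1.02, 2.27, 2.22 and 0.89 respectively, peak canopy COS uptake
#' of roughly 30-40 pmol m-2 s-1 (about twice that for the forest), and a
#' soil term that switches the savanna to net daytime COS emission under
#' high radiation load at the soil surface.
#'
#' @param preset One of `"GRA"`, `"SAV"`, `"DBF"`, `"CRO"`.
#' @param ... Named overrides for any scenario field (e.g. `n_days`,
#'   `sigma_nee`, `true_lru`, `nocturnal_frac`).
#' @param seed Integer seed controlling every random draw made from this
#'   scenario.
#' @return A `site_scenario` list. Fields: `site`, `n_days`, `daylength_h`,
#'   `par_max` (umol m-2 s-1), `t_mean`/`t_amplitude` (degC), `swc_mean`
#'   (m3 m-3), `chi_co2_mean` (ppm), `chi_cos_mean` (ppt), `true_light`,
#'   `true_resp`, `true_lru` (parameter bundles), `soil_baseline`
#'   (pmol m-2 s-1 uptake magnitude), `soil_slope` (pmol m-2 s-1 per W m-2),
#'   `sigma_nee` (umol m-2 s-1), `sigma_cos` (pmol m-2 s-1),
#'   `canopy_transmission` (0-1), `nocturnal_frac`, `chamber_noise_ppt`,
#'   `start_date`, `seed`.
#' @examples
#' site_scenario("GRA", n_days = 5, seed = 42)
#' @export
site_scenario <- function(preset = c("GRA", "SAV", "DBF", "CRO"), ..., seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    GRA = list(daylength_h = 15, par_max = 1800, t_mean = 14, t_amplitude = 8,
               swc_mean = 0.35,
               true_light = light_params(0.05, 30),
               true_resp = respiration_params(4, 150),
               true_lru = lru_params(1.02, 50),
               canopy_transmission = 0.05, soil_baseline = 1.0, soil_slope = 0.02),
    SAV = list(daylength_h = 13, par_max = 2000, t_mean = 20, t_amplitude = 10,
               swc_mean = 0.15,
               true_light = light_params(0.03, 12),
               true_resp = respiration_params(3, 120),
               true_lru = lru_params(2.27, 40),
               canopy_transmission = 0.50, soil_baseline = 1.0, soil_slope = 0.02),
    DBF = list(daylength_h = 16, par_max = 1700, t_mean = 18, t_amplitude = 6,
               swc_mean = 0.30,
               true_light = light_params(0.06, 35),
               true_resp = respiration_params(6, 180),
               true_lru = lru_params(2.22, 60),
               canopy_transmission = 0.05, soil_baseline = 2.8, soil_slope = 0.01),
    CRO = list(daylength_h = 15, par_max = 1900, t_mean = 22, t_amplitude = 9,
               swc_mean = 0.25,
               true_light = light_params(0.055, 40),
               true_resp = respiration_params(5, 130),
               true_lru = lru_params(0.89, 30),
               canopy_transmission = 0.30, soil_baseline = 1.5, soil_slope = 0.015)
  )[[preset]]
  s <- modifyList(
    c(list(site = preset, n_days = 30, chi_co2_mean = 400, chi_cos_mean = 500,
           sigma_nee = 1.0, sigma_cos = 3.0, nocturnal_frac = 0.2,
           chamber_noise_ppt = 2, start_date = "2015-06-01", seed = as.integer(seed)),
      base),
    list(...))
  stopifnot(s$n_days >= 1, s$par_max > 0, s$daylength_h > 0, s$daylength_h < 24,
            s$canopy_transmission >= 0, s$canopy_transmission <= 1,
            s$swc_mean >= 0, s$swc_mean <= 1,
            s$sigma_nee >= 0, s$sigma_cos >= 0,
            s$nocturnal_frac >= 0, s$nocturnal_frac <= 1)
  structure(s, class = "site_scenario")
}

#' @export
print.site_scenario <- function(x, ...) {
  cat(sprintf("<site_scenario %s: %d days, PARmax %g, iota %g, seed %d>\n",
              x$site, x$n_days, x$par_max, x$true_lru$iota, x$seed))
  invisible(x)
}

# PAR-to-shortwave conversion factor, umol photons per J
PAR_PER_SW <- 2.1

#' Simulate half-hourly campaign meteorology
#'
#' Drivers only: PAR follows a half-sine over the daylight window (peak
#' `par_max` at solar noon, zero at night), air temperature a diel sinusoid
#' lagged two hours behind solar noon, soil temperature a damped further-
#' lagged copy, soil moisture near-constant, shortwave radiation at the soil
#' surface `canopy_transmission * PAR / 2.1` (W m-2), and ambient mole
#' fractions their campaign means with a +-1% diel ripple. Deterministic
#' given the scenario.
#'
#' @param s A [site_scenario()].
#' @return Tibble with columns `timestamp` (half-hourly, CET), `par`,
#'   `t_air`, `t_soil`, `swc`, `sw_soil`, `chi_co2`, `chi_cos`.
#' @export
simulate_meteo <- function(s) {
  stopifnot(inherits(s, "site_scenario"))
  t0 <- as.POSIXct(paste(s$start_date, "00:00:00"), tz = "Etc/GMT-1")
  ts <- t0 + seq(0, s$n_days * 86400 - 1800, by = 1800)
  h <- lubridate::hour(ts) + lubridate::minute(ts) / 60
  sunrise <- 12 - s$daylength_h / 2
  phase <- (h - sunrise) / s$daylength_h
  par <- ifelse(phase > 0 & phase < 1, s$par_max * sin(pi * phase), 0)
  tibble(
    timestamp = ts,
    par = par,
    t_air = s$t_mean + s$t_amplitude * cos(2 * pi * (h - 14) / 24),
    t_soil = s$t_mean + 0.5 * s$t_amplitude * cos(2 * pi * (h - 17) / 24),
    swc = pmin(1, pmax(0, s$swc_mean + 0.01 * cos(2 * pi * (h - 6) / 24))),
    sw_soil = s$canopy_transmission * par / PAR_PER_SW,
    chi_co2 = s$chi_co2_mean * (1 + 0.01 * cos(2 * pi * (h - 4) / 24)),
    chi_cos = s$chi_cos_mean * (1 + 0.01 * cos(2 * pi * (h - 16) / 24))
  )
}

#' Attach noise-free process truth to simulated meteorology
#'
#' Evaluates the full forward model at the scenario's true parameters:
#' `true_gpp` from the light response, `true_reco` from Lloyd-Taylor,
#' `true_nee = true_reco - true_gpp`, `true_lru` from the light-dependent
#' LRU (daytime only; `NA` at night where the ratio is undefined), the soil
#' COS flux rule `true_f_soil = -baseline + slope * sw_soil` and the canopy
#' COS flux `true_fcos_canopy = -fcos_forward(...)` (micrometeorological
#' sign). Nights get a residual canopy COS uptake equal to
#' `nocturnal_frac` times the mean daytime uptake magnitude, emulating
#' incomplete stomatal closure; daytime-only fitting must tolerate it.
#' `true_fcos_eco = true_fcos_canopy + true_f_soil`.
#'
#' @param s A [site_scenario()].
#' @param meteo Output of [simulate_meteo()]; generated if omitted.
#' @return `meteo` with truth columns appended.
#' @export
simulate_truth <- function(s, meteo = simulate_meteo(s)) {
  stopifnot(inherits(s, "site_scenario"))
  day <- meteo$par > 0
  out <- meteo |>
    mutate(
      true_gpp = gpp_light_response(s$true_light, .data$par),
      true_reco = reco_lloyd_taylor(s$true_resp, .data$t_air),
      true_nee = .data$true_reco - .data$true_gpp,
      true_lru = NA_real_,
      true_f_soil = -s$soil_baseline + s$soil_slope * .data$sw_soil
    )
  out$true_lru[day] <- lru_light(s$true_lru, meteo$par[day])
  amb_day <- ambient_mole_fractions(meteo$chi_co2[day], meteo$chi_cos[day])
  uptake_day <- fcos_forward(out$true_gpp[day], out$true_lru[day], amb_day)
  out$true_fcos_canopy <- 0
  out$true_fcos_canopy[day] <- -uptake_day
  out$true_fcos_canopy[!day] <- -s$nocturnal_frac * mean(uptake_day)
  out |> mutate(true_fcos_eco = .data$true_fcos_canopy + .data$true_f_soil)
}

#' Add Gaussian observation noise to a truth campaign
#'
#' Observed NEE and ecosystem COS flux are the truth plus independent iid
#' Gaussian noise: `nee = true_nee + N(0, sigma_nee)`,
#' `fcos_eco = true_fcos_eco + N(0, sigma_cos)`. Columns carry the same
#' names the flux CSV dialect and the fitting functions use. Reproducible
#' per seed; different seeds change only the noise, never the truth.
#'
#' @param truth Output of [simulate_truth()].
#' @param sigma_nee,sigma_cos Noise standard deviations (umol m-2 s-1 and
#'   pmol m-2 s-1); must be >= 0.
#' @param seed Integer seed.
#' @return `truth` with observation columns `nee`, `fcos_eco` appended.
#' @export
simulate_observations <- function(truth, sigma_nee, sigma_cos, seed = 1L) {
  if (sigma_nee < 0 || sigma_cos < 0) abort("Noise sigmas must be >= 0.")
  n <- nrow(truth)
  set.seed(as.integer(seed))
  truth |>
    mutate(nee = .data$true_nee + rnorm(n, 0, sigma_nee),
           fcos_eco = .data$true_fcos_eco + rnorm(n, 0, sigma_cos))
}

#' Simulate a full campaign in one call
#'
#' Chains [simulate_meteo()], [simulate_truth()] and
#' [simulate_observations()] with the scenario's own noise levels and seed.
#'
#' @param s A [site_scenario()].
#' @return Half-hourly campaign tibble with drivers, `true_*` columns and
#'   observed `nee`, `fcos_eco`.
#' @examples
#' simulate_campaign(site_scenario("GRA", n_days = 3))
#' @export
simulate_campaign <- function(s) {
  simulate_truth(s) |>
    simulate_observations(s$sigma_nee, s$sigma_cos, seed = s$seed)
}

#' Simulate a soil chamber campaign
#'
#' Inverts the steady-state chamber equation: for each requested time, the
#' true soil flux implies a chamber mole-fraction step
#' `C2 = C1 + F * A / q`, to which ppt-scale measurement noise is added.
#' [chamber_flux()] on the output recovers the true flux within that noise
#' (exactly at zero noise).
#'
#' @param s A [site_scenario()].
#' @param times POSIXct vector of measurement times; must be a subset of the
#'   campaign timestamps. Defaults to every 4 hours.
#' @param n_chambers Number of chamber collars measured at each time.
#' @param seed Integer seed for the measurement noise.
#' @param area_m2 Soil area covered by the chamber (default 0.032).
#' @return Tibble of chamber measurements (`timestamp`, `chamber`, `q_lpm`,
#'   `temp_c`, `press_hpa`, `c_ambient_ppt`, `c_chamber_ppt`, `area_m2`,
#'   `stable_flag`, `true_f_soil`).
#' @export
simulate_chamber_campaign <- function(s, times = NULL, n_chambers = 3,
                                      seed = s$seed + 1L, area_m2 = 0.032) {
  stopifnot(inherits(s, "site_scenario"))
  truth <- simulate_truth(s)
  if (is.null(times)) {
    times <- truth$timestamp[seq(1, nrow(truth), by = 8)]
  }
  idx <- match(as.numeric(times), as.numeric(truth$timestamp))
  if (anyNA(idx)) abort("`times` must be a subset of the campaign timestamps.")
  rows <- truth[rep(idx, each = n_chambers), ]
  n <- nrow(rows)
  q <- molar_flow_from_volumetric(7, rows$t_air, 1013.25)
  set.seed(as.integer(seed))
  tibble(
    timestamp = rows$timestamp,
    chamber = rep(seq_len(n_chambers), times = length(idx)),
    q_lpm = 7, temp_c = rows$t_air, press_hpa = 1013.25,
    c_ambient_ppt = rows$chi_cos,
    c_chamber_ppt = rows$chi_cos + rows$true_f_soil * area_m2 / q +
      rnorm(n, 0, s$chamber_noise_ppt),
    area_m2 = area_m2, stable_flag = TRUE,
    true_f_soil = rows$true_f_soil,
    sw_soil = rows$sw_soil, t_soil = rows$t_soil, swc = rows$swc
  )
}
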