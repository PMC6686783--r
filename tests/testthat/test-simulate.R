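# Synthetic campaign generator: meteorology, truth, observations, chambers.

test_that("PAR follows a half-sine with the analytic daily integral", {
  s <- site_scenario("GRA", n_days = 4, seed = 1)
  m <- simulate_meteo(s)
  h <- lubridate::hour(m$timestamp) + lubridate::minute(m$timestamp) / 60
  expect_equal(m$par[h == 12], rep(s$par_max, 4))
  expect_true(all(m$par[h == 0] == 0))
  night <- h < 12 - s$daylength_h / 2 | h > 12 + s$daylength_h / 2
  expect_true(all(m$par[night] == 0))
  # analytic half-sine integral: (2/pi) * par_max * daylength
  daily <- sum(m$par[1:48]) * 0.5 # umol-hours
  expect_equal(daily, (2 / pi) * s$par_max * s$daylength_h, tolerance = 0.01)
})

test_that("meteorology is within scenario scales and bit-reproducible", {
  s <- site_scenario("DBF", n_days = 6, seed = 2)
  m1 <- simulate_meteo(s)
  m2 <- simulate_meteo(s)
  expect_identical(m1, m2)
  expect_equal(mean(m1$t_air), s$t_mean, tolerance = 0.01)
  expect_equal(max(m1$t_air) - min(m1$t_air), 2 * s$t_amplitude,
               tolerance = 0.01)
  expect_true(all(m1$swc >= 0 & m1$swc <= 1))
  expect_true(all(m1$sw_soil >= 0))
  expect_equal(max(m1$sw_soil), s$canopy_transmission * s$par_max / 2.1,
               tolerance = 1e-9)
  expect_true(all(abs(m1$chi_co2 / s$chi_co2_mean - 1) <= 0.01 + 1e-12))
})

test_that("truth fields satisfy the forward-model identities exactly", {
  s <- site_scenario("GRA", n_days = 5, seed = 3)
  tr <- simulate_truth(s)
  day <- tr$par > 0
  # night: no GPP, NEE is respiration, residual COS uptake persists
  expect_true(all(tr$true_gpp[!day] == 0))
  expect_identical(tr$true_nee[!day], tr$true_reco[!day])
  expect_true(all(tr$true_fcos_canopy[!day] < 0))
  expect_true(all(is.na(tr$true_lru[!day])))
  # daytime canopy COS flux is exactly the forward model, micromet sign
  amb <- ambient_mole_fractions(tr$chi_co2[day], tr$chi_cos[day])
  expect_identical(tr$true_fcos_canopy[day],
                   -fcos_forward(tr$true_gpp[day], tr$true_lru[day], amb))
  expect_identical(tr$true_nee, tr$true_reco - tr$true_gpp)
  expect_identical(tr$true_fcos_eco, tr$true_fcos_canopy + tr$true_f_soil)
  # nocturnal uptake is the configured fraction of the mean daytime uptake
  expect_equal(unique(tr$true_fcos_canopy[!day]),
               -s$nocturnal_frac * mean(-tr$true_fcos_canopy[day]))
})

test_that("presets reproduce the observed cross-site flux structure", {
  peaks <- sapply(c("GRA", "SAV", "DBF", "CRO"), function(p) {
    tr <- simulate_truth(site_scenario(p, n_days = 2))
    max(-tr$true_fcos_canopy)
  })
  # herbaceous/savanna sites peak around 30-40 pmol, the forest about twice
  expect_true(all(peaks[c("GRA", "SAV", "CRO")] > 20 &
                    peaks[c("GRA", "SAV", "CRO")] < 60))
  expect_gt(peaks["DBF"], 1.5 * max(peaks[c("GRA", "SAV", "CRO")]))
  # savanna soil: daytime emission, nighttime uptake
  sav <- simulate_truth(site_scenario("SAV", n_days = 2))
  day <- sav$par > 10
  expect_gt(median(sav$true_f_soil[day]), 0)
  expect_lt(median(sav$true_f_soil[!day]), 0)
  # NEE turns positive at night while COS uptake continues at reduced rate
  gra <- simulate_truth(site_scenario("GRA", n_days = 2))
  night <- gra$par == 0
  expect_true(all(gra$true_nee[night] > 0))
  expect_true(all(gra$true_fcos_canopy[night] < 0))
  expect_lt(mean(-gra$true_fcos_canopy[night]), max(-gra$true_fcos_canopy))
})

test_that("observation noise has the configured spread and leaves truth fixed", {
  s <- site_scenario("CRO", n_days = 210, seed = 5) # ~1e4 records
  tr <- simulate_truth(s)
  obs <- simulate_observations(tr, 1.0, 3.0, seed = 8)
  expect_gt(nrow(obs), 1e4)
  expect_equal(sd(obs$nee - obs$true_nee), 1.0, tolerance = 0.03)
  expect_equal(sd(obs$fcos_eco - obs$true_fcos_eco), 3.0, tolerance = 0.03)
  # zero noise reproduces truth exactly
  clean <- simulate_observations(tr, 0, 0, seed = 8)
  expect_identical(clean$nee, clean$true_nee)
  # different seeds: same truth, different noise
  o2 <- simulate_observations(tr, 1.0, 3.0, seed = 9)
  expect_identical(o2$true_nee, obs$true_nee)
  expect_false(any(o2$nee == obs$nee))
  expect_error(simulate_observations(tr, -1, 3), ">= 0")
})

test_that("whole campaigns are bit-reproducible from the scenario seed", {
  s <- site_scenario("SAV", n_days = 4, seed = 11)
  expect_identical(simulate_campaign(s), simulate_campaign(s))
  ch1 <- simulate_chamber_campaign(s)
  ch2 <- simulate_chamber_campaign(s)
  expect_identical(ch1, ch2)
})

test_that("chamber simulation inverts the chamber equation", {
  s <- site_scenario("GRA", n_days = 4, seed = 2, chamber_noise_ppt = 0)
  ch <- simulate_chamber_campaign(s)
  out <- chamber_flux(ch)
  # zero noise: exact round trip, and C2 = C1 wherever the flux is zero
  expect_equal(out$f_soil, out$true_f_soil, tolerance = 1e-9)
  s2 <- site_scenario("GRA", n_days = 2, seed = 2, chamber_noise_ppt = 0,
                      soil_baseline = 0, soil_slope = 0)
  ch0 <- simulate_chamber_campaign(s2)
  expect_equal(ch0$c_chamber_ppt, ch0$c_ambient_ppt)
  # times must belong to the campaign
  expect_error(
    simulate_chamber_campaign(s, times = as.POSIXct("1999-01-01", tz = "Etc/GMT-1")),
    "subset")
})

test_that("noisy chamber campaign still recovers the radiative emission slope sign", {
  s <- site_scenario("SAV", n_days = 10, seed = 3)
  ch <- chamber_flux(simulate_chamber_campaign(s, n_chambers = 4))
  expect_gt(nrow(ch), 200)
  m <- fit_soil_model(ch, seed = 1)
  hi <- predict_soil_flux(m, tibble::tibble(sw_soil = 400, t_soil = 20, swc = 0.15))
  lo <- predict_soil_flux(m, tibble::tibble(sw_soil = 0, t_soil = 20, swc = 0.15))
  expect_gt(hi$f_soil_pred, lo$f_soil_pred)
})
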