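# Shared fixtures, computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Campaign with the soil contribution removed using the generator truth,
# isolating the inversion from the soil regression.
truth_corrected_campaign <- function(scenario) {
  camp <- simulate_campaign(scenario)
  camp$fcos_canopy <- camp$fcos_eco - camp$true_f_soil
  camp
}

# The core recovery fixture: 30-day GRA campaign at the standard noise
# levels (sigma_NEE = 1.0, sigma_COS = 3.0), FP+ fit.
gra_fixture <- function() {
  cached("gra30", {
    s <- site_scenario("GRA", seed = 1)
    camp <- truth_corrected_campaign(s)
    fit <- fit_fpplus(camp, n_iter = 4000, seed = 1)
    list(scenario = s, campaign = camp, fit = fit)
  })
}

# End-to-end runs (simulate -> soil model -> both fits -> report) for all
# four presets at reduced campaign length.
preset_end_to_end <- function() {
  cached("e2e", {
    lapply(setNames(nm = c("GRA", "SAV", "DBF", "CRO")), function(p) {
      s <- site_scenario(p, n_days = 12, seed = 1)
      camp <- simulate_campaign(s)
      cham <- chamber_flux(simulate_chamber_campaign(s))
      soil <- fit_soil_model(cham, seed = 1)
      camp <- suppressWarnings(predict_soil_flux(soil, camp)) |>
        canopy_cos_flux()
      f_fp <- suppressWarnings(fit_fp(camp, n_iter = 2000, seed = 2))
      f_plus <- suppressWarnings(fit_fpplus(camp, n_iter = 2000, seed = 2))
      report <- campaign_report(camp, f_fp, f_plus, site = p, force = TRUE)
      list(scenario = s, campaign = camp, soil = soil,
           fit_fp = f_fp, fit_fpplus = f_plus, report = report)
    })
  })
}

# Fraction of records whose true GPP lies inside the 95% credible band.
band_coverage <- function(campaign, fit) {
  ps <- partition_series(campaign, fit, force = TRUE)
  mean(campaign$true_gpp >= ps$gpp_lo & campaign$true_gpp <= ps$gpp_hi)
}

# Hand-buildable posterior_chains object for summary/report unit tests.
make_chains <- function(draws_by_chain, log_post = NULL, burn = 0) {
  m <- length(draws_by_chain)
  n <- nrow(draws_by_chain[[1]])
  params <- colnames(draws_by_chain[[1]])
  samples <- array(NA_real_, c(m, n, length(params)),
                   dimnames = list(NULL, NULL, params))
  for (j in seq_len(m)) samples[j, , ] <- draws_by_chain[[j]]
  lp <- if (is.null(log_post)) matrix(0, m, n) else log_post
  rhat <- gelman_rubin(samples[, (burn + 1):n, , drop = FALSE])
  structure(
    list(samples = samples, log_post = lp, log_lik = lp, burn = burn,
         params = params, acceptance = rep(NA_real_, m), rhat = rhat,
         converged = all(rhat < 1.1), seed = 0L, priors = NULL,
         n_chains = m, n_iter = n),
    class = "posterior_chains")
}

# Minimal cos_fit wrapper around hand-made chains (for partition tests).
make_fit <- function(chains, e0, model = "fpplus", converged = TRUE) {
  res <- posterior_summary(chains)
  res$model <- model
  res$converged <- converged
  structure(
    list(model = model, e0 = list(e0 = e0, rb_night = NA, rmse = NA,
                                  n_night = NA),
         chains = chains, result = res, par_threshold = 10,
         n_day = NA, seed = 0L),
    class = "cos_fit")
}
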