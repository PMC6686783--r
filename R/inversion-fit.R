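#' Fit the FP or FP+ flux-partitioning model to a campaign
#'
#' One whole-campaign fit, the way the method reports one parameter set per
#' site: the respiration temperature sensitivity `e0` is first estimated
#' from nighttime NEE by RMSE minimization ([fit_e0_nighttime()]) and held
#' fixed; the remaining parameters are then sampled from their joint
#' posterior over the daytime records with the differential-evolution
#' multichain sampler ([sample_posterior()]).
#'
#' `fit_fp()` uses NEE alone (parameters `alpha`, `beta`, `rb`,
#' `sigma_nee`). `fit_fpplus()` adds the soil-corrected canopy COS flux as
#' a second, independent constraint (plus `iota`, `kappa`, `sigma_cos`),
#' so GPP is informed by both gases.
#'
#' @param data Half-hourly campaign tibble with columns `nee`, `par`,
#'   `t_air` (FP) plus `fcos_canopy`, `chi_co2`, `chi_cos` (FP+).
#' @param priors A [prior_spec()]; defaults to the model's standard priors.
#' @param par_threshold Daytime PAR threshold, umol m-2 s-1 (default 10).
#' @param n_chains,n_iter,seed Sampler settings, see [sample_posterior()].
#' @param ... Passed on to [sample_posterior()].
#' @return A `cos_fit` object: `model` ("fp"/"fpplus"), `e0` (nighttime
#'   fit), `chains` (`posterior_chains`), `result` (`fit_result`),
#'   `par_threshold`, `n_day`. Use [tidy()] / [glance()] to extract tidy
#'   summaries and [partition_series()] to turn the fit into GPP/Reco
#'   series.
#' @examples
#' \donttest{
#' camp <- simulate_campaign(site_scenario("GRA", n_days = 8))
#' camp$fcos_canopy <- camp$fcos_eco - camp$true_f_soil
#' fit <- fit_fpplus(camp, n_iter = 1500, seed = 7)
#' tidy(fit)
#' }
#' @export
fit_fp <- function(data, priors = prior_spec("fp"), par_threshold = 10,
                   n_chains = NULL, n_iter = 3000, seed = 1L, ...) {
  fit_impl(data, priors, par_threshold, n_chains, n_iter, seed,
           model = "fp", ...)
}

#' @rdname fit_fp
#' @export
fit_fpplus <- function(data, priors = prior_spec("fpplus"), par_threshold = 10,
                       n_chains = NULL, n_iter = 3000, seed = 1L, ...) {
  fit_impl(data, priors, par_threshold, n_chains, n_iter, seed,
           model = "fpplus", ...)
}

fit_impl <- function(data, priors, par_threshold, n_chains, n_iter, seed,
                     model, ...) {
  data <- as_tibble(data)
  if (model == "fpplus" && !"fcos_canopy" %in% names(data)) {
    abort(paste0("FP+ needs a soil-corrected `fcos_canopy` column; ",
                 "run predict_soil_flux() + canopy_cos_flux() first."))
  }
  e0_fit <- fit_e0_nighttime(data, par_threshold = par_threshold)
  ll <- if (model == "fp") {
    make_loglik_fp(data, e0_fit$e0, par_threshold)
  } else {
    make_loglik_fpplus(data, e0_fit$e0, par_threshold)
  }
  n_day <- nrow(daytime_subset(data, par_threshold, c("nee", "par", "t_air")))
  chains <- sample_posterior(ll, priors, n_chains = n_chains, n_iter = n_iter,
                             seed = seed, ...)
  result <- posterior_summary(chains)
  result$model <- model
  structure(
    list(model = model, e0 = e0_fit, chains = chains, result = result,
         par_threshold = par_threshold, n_day = n_day, seed = as.integer(seed)),
    class = "cos_fit")
}

#' @export
print.cos_fit <- function(x, ...) {
  cat(sprintf("<cos_fit %s: E0 = %.1f degC (n_night = %d), %d daytime records>\n",
              toupper(sub("plus", "+", x$model)), x$e0$e0, x$e0$n_night, x$n_day))
  if (!x$result$converged) cat("  ** UNCONVERGED **\n")
  print(x$result$summary, n = Inf)
  invisible(x)
}

#' Tidy per-parameter posterior summaries of a fit
#'
#' @param x A `cos_fit`.
#' @param ... Unused.
#' @return Tibble with `param`, posterior `median`, `mean`, equal-tailed
#'   95% interval `ci_lo`/`ci_hi`, and `rhat`.
#' @export
tidy.cos_fit <- function(x, ...) x$result$summary

#' One-row fit overview
#'
#' @param x A `cos_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `e0`, `n_night`, `n_day`, `converged`,
#'   `rhat_max`, `log_lik_map`, `n_retained`, `seed`.
#' @export
glance.cos_fit <- function(x, ...) {
  tibble(model = x$model, e0 = x$e0$e0, n_night = x$e0$n_night,
         n_day = x$n_day, converged = x$result$converged,
         rhat_max = max(x$result$summary$rhat),
         log_lik_map = x$result$log_lik_map,
         n_retained = x$result$n_retained, seed = x$seed)
}

#' Serialize a fit to a structured text file
#'
#' Writes the parameter table (median, 95% CI, R-hat), model tag, seed,
#' convergence status and prior specification as a plain TSV with a
#' commented header, so a fit is fully reconstructable from text.
#'
#' @param fit A `cos_fit`.
#' @param path Output file path.
#' @param chains_path Optional CSV path for the full chains
#'   (`chain, iteration, <parameters>, retained`).
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, path, chains_path = NULL) {
  stopifnot(inherits(fit, "cos_fit"))
  hdr <- c(
    sprintf("# cosflux fit: model=%s seed=%d converged=%s", fit$model,
            fit$seed, toupper(as.character(fit$result$converged))),
    sprintf("# e0=%.6g rb_night=%.6g n_night=%d n_day=%d par_threshold=%g",
            fit$e0$e0, fit$e0$rb_night, fit$e0$n_night, fit$n_day,
            fit$par_threshold),
    sprintf("# prior %s: %s(%g, %g) on [%g, %g]", fit$chains$priors$param,
            fit$chains$priors$dist, fit$chains$priors$p1, fit$chains$priors$p2,
            fit$chains$priors$lower, fit$chains$priors$upper),
    if (!fit$result$converged) "# UNCONVERGED"
  )
  writeLines(hdr, path)
  readr::write_tsv(tidy(fit), path, append = TRUE, col_names = TRUE)
  if (!is.null(chains_path)) {
    readr::write_csv(tidy(fit$chains), chains_path)
  }
  invisible(fit)
}
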