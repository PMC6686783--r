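#' Log-likelihoods for the FP and FP+ models
#'
#' Gaussian iid log-likelihoods of the daytime records under the forward
#' models, with the per-stream noise scales treated as free nuisance
#' parameters so the two data streams weight themselves.
#'
#' `loglik_fp()` scores NEE residuals against the daytime light-response +
#' Lloyd-Taylor model (parameters `alpha`, `beta`, `rb`, `sigma_nee`;
#' temperature sensitivity `e0` fixed from the nighttime fit).
#' `loglik_fpplus()` adds an independent second stream: the soil-corrected
#' canopy COS flux (micrometeorological sign) against minus the modelled
#' canopy COS uptake, composed from the light response, the light-dependent
#' LRU and the ambient mole-fraction ratio (additional parameters `iota`,
#' `kappa`, `sigma_cos`).
#'
#' @param theta Named numeric vector of parameters (see above).
#' @param e0 Fixed temperature sensitivity from [fit_e0_nighttime()].
#' @param data Daytime half-hourly tibble: columns `nee`, `par`, `t_air`
#'   (plus `fcos_canopy`, `chi_co2`, `chi_cos` for FP+). Records at or below
#'   `par_threshold` are excluded; an empty daytime subset is an error.
#' @param par_threshold Daytime PAR threshold, umol m-2 s-1.
#' @param t_ref,t0 Lloyd-Taylor constants.
#' @return The scalar log-likelihood (finite for all in-support `theta`).
#' @export
loglik_fp <- function(theta, e0, data, par_threshold = 10,
                      t_ref = 15, t0 = -46.02) {
  f <- make_loglik_fp(data, e0, par_threshold, t_ref, t0)
  f(theta)
}

#' @rdname loglik_fp
#' @export
loglik_fpplus <- function(theta, e0, data, par_threshold = 10,
                          t_ref = 15, t0 = -46.02) {
  f <- make_loglik_fpplus(data, e0, par_threshold, t_ref, t0)
  f(theta)
}

daytime_subset <- function(data, par_threshold, cols) {
  data <- as_tibble(data)
  miss <- setdiff(cols, names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  day <- data |> filter(.data$par > par_threshold)
  day <- day[stats::complete.cases(day[cols]), ]
  if (nrow(day) == 0) abort("No daytime records above the PAR threshold.")
  day
}

# Closure factories: precompute the data vectors once so the MCMC loop pays
# only the model algebra per evaluation.
make_loglik_fp <- function(data, e0, par_threshold = 10, t_ref = 15, t0 = -46.02) {
  day <- daytime_subset(data, par_threshold, c("nee", "par", "t_air"))
  nee <- day$nee
  par <- day$par
  gterm <- exp(e0 * (1 / (t_ref - t0) - 1 / (day$t_air - t0)))
  n <- length(nee)
  function(theta) {
    gpp <- theta[["alpha"]] * theta[["beta"]] * par /
      (theta[["alpha"]] * par + theta[["beta"]])
    resid <- nee - (theta[["rb"]] * gterm - gpp)
    s <- theta[["sigma_nee"]]
    -n * log(s) - 0.5 * n * log(2 * pi) - sum(resid^2) / (2 * s^2)
  }
}

make_loglik_fpplus <- function(data, e0, par_threshold = 10, t_ref = 15, t0 = -46.02) {
  day <- daytime_subset(data, par_threshold,
                        c("nee", "par", "t_air", "fcos_canopy", "chi_co2", "chi_cos"))
  nee <- day$nee
  par <- day$par
  fcos <- day$fcos_canopy
  gterm <- exp(e0 * (1 / (t_ref - t0) - 1 / (day$t_air - t0)))
  ratio <- (day$chi_co2 * 1e-6) / (day$chi_cos * 1e-12)
  n <- length(nee)
  function(theta) {
    gpp <- theta[["alpha"]] * theta[["beta"]] * par /
      (theta[["alpha"]] * par + theta[["beta"]])
    resid_nee <- nee - (theta[["rb"]] * gterm - gpp)
    lru <- theta[["iota"]] * exp(theta[["kappa"]] / par)
    # modelled canopy COS uptake magnitude, negated to micromet sign
    resid_cos <- fcos - (-(gpp * lru / ratio * 1e6))
    s1 <- theta[["sigma_nee"]]
    s2 <- theta[["sigma_cos"]]
    -n * log(s1) - sum(resid_nee^2) / (2 * s1^2) -
      n * log(s2) - sum(resid_cos^2) / (2 * s2^2) -
      n * log(2 * pi)
  }
}
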