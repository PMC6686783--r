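#' Parameter bundles for the process models
#'
#' Constructors for the three parameter sets the flux-partitioning models
#' share: ecosystem respiration (Lloyd–Taylor), canopy light response
#' (rectangular hyperbola) and the light-dependent leaf relative uptake
#' ratio (LRU). Each constructor validates its invariants and returns a
#' plain named list with a class tag, so bundles can be built inline in
#' pipelines and compared against generator truth in tests.
#'
#' @param rb Base ecosystem respiration at the reference temperature,
#'   umol CO2 m-2 s-1. Must be > 0.
#' @param e0 Temperature sensitivity, degrees C. Must be >= 0.
#' @param t_ref Reference temperature, degrees C (default 15).
#' @param t0 Lower temperature constant, degrees C (default -46.02).
#' @return A classed list of validated parameters.
#' @examples
#' respiration_params(rb = 3, e0 = 150)
#' light_params(alpha = 0.05, beta = 20)
#' lru_params(iota = 1.7, kappa = 50)
#' @export
respiration_params <- function(rb, e0, t_ref = 15, t0 = -46.02) {
  stopifnot(is.numeric(rb), is.numeric(e0), is.numeric(t_ref), is.numeric(t0))
  if (rb <= 0) abort("`rb` must be > 0 (base respiration is a magnitude).")
  if (e0 < 0) abort("`e0` must be >= 0.")
  if (t_ref <= t0) abort("`t_ref` must exceed the lower temperature constant `t0`.")
  structure(list(rb = rb, e0 = e0, t_ref = t_ref, t0 = t0),
            class = "respiration_params")
}

#' @rdname respiration_params
#' @param alpha Canopy light-utilization efficiency,
#'   umol CO2 per umol photons. Must be > 0.
#' @param beta Maximum canopy CO2 uptake at light saturation,
#'   umol CO2 m-2 s-1. Must be > 0.
#' @export
light_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (beta <= 0) abort("`beta` must be > 0.")
  structure(list(alpha = alpha, beta = beta), class = "light_params")
}

#' @rdname respiration_params
#' @param iota LRU at high light intensity, dimensionless. Must be > 0.
#' @param kappa Low-light increase parameter, umol m-2 s-1 (same units as
#'   PAR). Must be >= 0; `kappa = 0` gives a light-independent LRU.
#' @export
lru_params <- function(iota, kappa) {
  stopifnot(is.numeric(iota), is.numeric(kappa))
  if (iota <= 0) abort("`iota` must be > 0.")
  if (kappa < 0) abort("`kappa` must be >= 0.")
  structure(list(iota = iota, kappa = kappa), class = "lru_params")
}

#' Ambient mole fractions of CO2 and COS
#'
#' CO2 is carried in ppm (1e-6 mol/mol) and COS in ppt (1e-12 mol/mol), the
#' native units of the tower records; the two are put on a common mol/mol
#' scale only inside ratio computations.
#'
#' @param chi_co2 Ambient CO2 mole fraction, ppm; strictly positive.
#' @param chi_cos Ambient COS mole fraction, ppt; strictly positive.
#' @return A classed list with fields `chi_co2`, `chi_cos`.
#' @export
ambient_mole_fractions <- function(chi_co2, chi_cos) {
  stopifnot(is.numeric(chi_co2), is.numeric(chi_cos))
  if (any(chi_co2 <= 0) || any(chi_cos <= 0)) {
    abort("Ambient mole fractions must be strictly positive.")
  }
  structure(list(chi_co2 = chi_co2, chi_cos = chi_cos),
            class = "ambient_mole_fractions")
}

# chi_co2 [ppm] / chi_cos [ppt] on a common mol/mol scale -> dimensionless,
# typically ~8e5 for 400 ppm / 500 ppt.
co2_cos_ratio <- function(amb) {
  (amb$chi_co2 * 1e-6) / (amb$chi_cos * 1e-12)
}
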