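#' Lloyd–Taylor ecosystem respiration
#'
#' Exponential temperature response of ecosystem respiration,
#' \deqn{R_{eco} = r_b \exp\!\left[E_0\left(\frac{1}{T_{ref}-T_0} -
#'   \frac{1}{T_{air}-T_0}\right)\right],}
#' with the reference temperature fixed at 15 degrees C and the lower
#' temperature constant at -46.02 degrees C unless overridden in `p`.
#' Returns a non-negative magnitude (respiration is a release of CO2;
#' adapters add it with positive sign to NEE).
#'
#' @param p A [respiration_params()] bundle.
#' @param t_air Air temperature, degrees C. Vectorized.
#' @return Respiration, umol CO2 m-2 s-1, same length as `t_air`.
#' @examples
#' reco_lloyd_taylor(respiration_params(2, 100), t_air = 25)
#' @export
reco_lloyd_taylor <- function(p, t_air) {
  stopifnot(inherits(p, "respiration_params"), is.numeric(t_air))
  bad <- which(t_air <= p$t0)
  if (length(bad)) {
    abort(sprintf(
      "Lloyd-Taylor respiration undefined for t_air <= T0 (%.2f degC): record(s) %s (t_air = %s).",
      p$t0, paste(head(bad, 5), collapse = ", "),
      paste(signif(t_air[head(bad, 5)], 4), collapse = ", ")))
  }
  p$rb * exp(p$e0 * (1 / (p$t_ref - p$t0) - 1 / (t_air - p$t0)))
}

#' Rectangular-hyperbola canopy light response
#'
#' GPP as a saturating function of incoming PAR,
#' \deqn{GPP = \frac{\alpha\beta R_{PAR}}{\alpha R_{PAR} + \beta},}
#' zero in darkness and approaching `beta` at light saturation. Returns a
#' non-negative magnitude.
#'
#' @param p A [light_params()] bundle.
#' @param r_par Incoming photosynthetically active radiation,
#'   umol photons m-2 s-1, >= 0. Vectorized.
#' @return GPP magnitude, umol CO2 m-2 s-1.
#' @examples
#' gpp_light_response(light_params(0.05, 20), r_par = 1000)
#' @export
gpp_light_response <- function(p, r_par) {
  stopifnot(inherits(p, "light_params"), is.numeric(r_par))
  if (any(r_par < 0)) abort("`r_par` must be >= 0.")
  p$alpha * p$beta * r_par / (p$alpha * r_par + p$beta)
}

#' Forward NEE model (daytime light-response form)
#'
#' Net ecosystem exchange in the micrometeorological sign convention
#' (negative = uptake): `NEE = Reco - GPP`, with GPP from
#' [gpp_light_response()] and Reco from [reco_lloyd_taylor()]. The
#' decomposition holds exactly, to machine precision.
#'
#' @param lp A [light_params()] bundle.
#' @param rp A [respiration_params()] bundle.
#' @param r_par PAR, umol m-2 s-1.
#' @param t_air Air temperature, degrees C.
#' @return NEE, umol CO2 m-2 s-1, micrometeorological sign.
#' @export
nee_forward <- function(lp, rp, r_par, t_air) {
  reco_lloyd_taylor(rp, t_air) - gpp_light_response(lp, r_par)
}

#' Light-dependent leaf relative uptake ratio
#'
#' \deqn{LRU = \iota\, e^{\kappa / R_{PAR}},}
#' where `iota` is the LRU at high light and `kappa` (same units as PAR)
#' governs the increase at low light. The ratio tends to `iota` as PAR grows
#' and diverges as PAR approaches zero — COS uptake through carbonic
#' anhydrase is light-independent while CO2 fixation is not, so their ratio
#' blows up in near darkness. No clamping is applied; fitting code excludes
#' records below the daytime PAR threshold instead.
#'
#' @param p An [lru_params()] bundle.
#' @param r_par PAR, umol m-2 s-1, strictly positive. Vectorized.
#' @return LRU, dimensionless.
#' @examples
#' lru_light(lru_params(1.7, 100), r_par = 100)  # 1.7 * e
#' @export
lru_light <- function(p, r_par) {
  stopifnot(inherits(p, "lru_params"), is.numeric(r_par))
  if (any(r_par <= 0)) {
    abort("LRU is undefined at r_par <= 0 (no photosynthesis to take a ratio against).")
  }
  p$iota * exp(p$kappa / r_par)
}

#' Modelled canopy COS uptake from GPP
#'
#' \deqn{F_{COS} = GPP \cdot LRU \,/\, (\chi_{CO_2}/\chi_{COS}),}
#' the COS analogue of the light-response GPP: the CO2 uptake is scaled by
#' the leaf relative uptake ratio and the ambient mole-fraction ratio
#' (formed on a common mol/mol scale). Returns the canopy COS uptake as a
#' non-negative magnitude in pmol m-2 s-1; negate for the
#' micrometeorological convention.
#'
#' @param gpp GPP magnitude, umol CO2 m-2 s-1, >= 0.
#' @param lru Leaf relative uptake ratio, dimensionless, > 0.
#' @param amb An [ambient_mole_fractions()] bundle.
#' @return Canopy COS uptake magnitude, pmol m-2 s-1.
#' @examples
#' fcos_forward(18.8, 1.7, ambient_mole_fractions(400, 500))
#' @export
fcos_forward <- function(gpp, lru, amb) {
  stopifnot(is.numeric(gpp), is.numeric(lru),
            inherits(amb, "ambient_mole_fractions"))
  if (any(gpp < 0)) abort("`gpp` must be a non-negative magnitude.")
  if (any(lru <= 0)) abort("`lru` must be > 0.")
  # gpp [umol] * lru / ratio [-] is in umol of COS; umol -> pmol is 1e6
  gpp * lru / co2_cos_ratio(amb) * 1e6
}

#' GPP inferred from a canopy COS flux
#'
#' The rearrangement of [fcos_forward()] used when COS serves as a GPP
#' proxy: \deqn{GPP = F_{COS} (\chi_{CO_2}/\chi_{COS}) / LRU.} Exact
#' inverse of [fcos_forward()] (round trip to better than 1e-12 relative).
#'
#' @param f_cos_canopy Canopy COS uptake magnitude, pmol m-2 s-1.
#' @param lru Leaf relative uptake ratio, > 0.
#' @param amb An [ambient_mole_fractions()] bundle.
#' @return GPP magnitude, umol CO2 m-2 s-1.
#' @export
gpp_from_cos <- function(f_cos_canopy, lru, amb) {
  stopifnot(is.numeric(f_cos_canopy), is.numeric(lru),
            inherits(amb, "ambient_mole_fractions"))
  if (any(lru <= 0)) abort("`lru` must be > 0.")
  f_cos_canopy * co2_cos_ratio(amb) / lru * 1e-6
}
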