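#' Nighttime temperature-sensitivity estimation
#'
#' Fits the Lloyd-Taylor respiration model to nighttime NEE (which is pure
#' respiration in the absence of photosynthesis) by minimizing the RMSE, and
#' returns the temperature sensitivity `e0` together with the nighttime base
#' respiration `rb_night`. `e0` is subsequently held fixed in the daytime
#' Bayesian inversion; `rb` is re-estimated there as a daytime parameter.
#'
#' For a fixed `e0` the model is linear in `rb`, so `rb` is profiled out in
#' closed form and only `e0` is searched, with a bounded 1-D optimizer
#' started from a coarse grid (multi-start) to avoid local minima. An
#' optimum within 1% of the search bound triggers a warning naming the
#' bound; near-isothermal nights make `e0` unidentifiable and raise an
#' error.
#'
#' @param data Half-hourly tibble with columns `nee`, `par`, `t_air`.
#' @param par_threshold Daytime PAR threshold, umol m-2 s-1; records at or
#'   below it count as night (default 10).
#' @param e0_bounds Search interval for `e0`, degrees C.
#' @param t_ref,t0 Lloyd-Taylor constants (degrees C).
#' @return List with `e0`, `rb_night`, `rmse`, `n_night`.
#' @examples
#' s <- site_scenario("GRA", n_days = 5, sigma_nee = 0, sigma_cos = 0)
#' fit_e0_nighttime(simulate_campaign(s))
#' @export
fit_e0_nighttime <- function(data, par_threshold = 10, e0_bounds = c(0, 600),
                             t_ref = 15, t0 = -46.02) {
  data <- as_tibble(data)
  miss <- setdiff(c("nee", "par", "t_air"), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  night <- data |> filter(.data$par <= par_threshold, !is.na(.data$nee))
  if (nrow(night) < 30) {
    abort(sprintf("Only %d nighttime records; need >= 30 for E0 estimation.", nrow(night)))
  }
  if (any(night$t_air <= t0)) abort("Nighttime t_air at or below the Lloyd-Taylor T0.")
  if (sd(night$t_air) < 0.5) {
    abort("Nighttime temperatures are nearly isothermal; E0 is unidentifiable.")
  }
  y <- night$nee
  g <- 1 / (t_ref - t0) - 1 / (night$t_air - t0)

  profile <- function(e0) {
    x <- exp(e0 * g)
    rb <- sum(y * x) / sum(x * x)
    list(rb = rb, rmse = sqrt(mean((y - rb * x)^2)))
  }
  obj <- function(e0) profile(e0)$rmse

  # coarse multi-start grid, then refine the best bracket
  grid <- seq(e0_bounds[1], e0_bounds[2], length.out = 25)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, c(lo, hi), tol = 1e-6)
  e0 <- opt$minimum
  span <- diff(e0_bounds)
  if (e0 - e0_bounds[1] < 0.01 * span || e0_bounds[2] - e0 < 0.01 * span) {
    warn(sprintf("Nighttime E0 optimum (%.1f) is at the search bound [%g, %g].",
                 e0, e0_bounds[1], e0_bounds[2]))
  }
  prof <- profile(e0)
  if (prof$rb <= 0) warn("Profiled nighttime rb is non-positive; check the nighttime NEE sign.")
  list(e0 = e0, rb_night = prof$rb, rmse = prof$rmse, n_night = nrow(night))
}
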