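#' Partitioned GPP and Reco series with credible bands
#'
#' Propagates the posterior through the forward models: for each half hour,
#' GPP (light response) and Reco (Lloyd-Taylor with the fixed nighttime
#' `e0`) are evaluated over a subsample of posterior draws and summarized
#' as the median and equal-tailed 95% credible band. GPP is zero at night
#' (at or below the fit's PAR threshold) by construction. Both series are
#' non-negative magnitudes.
#'
#' @param data Half-hourly tibble with `timestamp`, `par`, `t_air`.
#' @param fit A converged `cos_fit`; an unconverged fit is refused unless
#'   `force = TRUE`.
#' @param n_draws Number of posterior draws to propagate (>= 500 by
#'   default).
#' @param force Evaluate despite non-convergence.
#' @return Tibble: `timestamp`, `par`, `gpp`, `gpp_lo`, `gpp_hi`, `reco`,
#'   `reco_lo`, `reco_hi`, `model`.
#' @export
partition_series <- function(data, fit, n_draws = 500, force = FALSE) {
  stopifnot(inherits(fit, "cos_fit"))
  if (!fit$result$converged && !force) {
    abort("Fit is unconverged; refusing to partition (use force = TRUE to override).")
  }
  data <- as_tibble(data)
  miss <- setdiff(c("timestamp", "par", "t_air"), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  draws <- posterior_draws(fit$chains)
  if (nrow(draws) > n_draws) {
    draws <- draws[round(seq(1, nrow(draws), length.out = n_draws)), , drop = FALSE]
  }
  par <- data$par
  day <- par > fit$par_threshold
  # records x draws matrices
  gpp <- outer(par, draws[, "alpha"]) * rep(draws[, "beta"], each = length(par)) /
    (outer(par, draws[, "alpha"]) + rep(draws[, "beta"], each = length(par)))
  gpp[!day, ] <- 0
  gterm <- exp(fit$e0$e0 * (1 / (15 + 46.02) - 1 / (data$t_air + 46.02)))
  reco <- outer(gterm, draws[, "rb"])
  qs <- function(m) {
    t(apply(m, 1, quantile, c(0.5, 0.025, 0.975), names = FALSE))
  }
  qg <- qs(gpp)
  qr <- qs(reco)
  tibble(
    timestamp = data$timestamp, par = par,
    gpp = qg[, 1], gpp_lo = qg[, 2], gpp_hi = qg[, 3],
    reco = qr[, 1], reco_lo = qr[, 2], reco_hi = qr[, 3],
    model = fit$model
  )
}

#' Nighttime-extrapolation GPP reference series
#'
#' The classical nighttime partitioning variant, included as a secondary
#' reference only: Reco is extrapolated from the whole-campaign nighttime
#' Lloyd-Taylor fit and daytime GPP retrieved as `Reco - NEE`. No moving
#' windows are used, so this is a simplified, non-faithful rendition of the
#' standard nighttime method; the daytime light-response fit
#' ([fit_fp()] + [partition_series()]) is the reference FP implementation.
#'
#' @param data Half-hourly tibble with `timestamp`, `nee`, `par`, `t_air`.
#' @param par_threshold Daytime PAR threshold (default 10).
#' @return Tibble: `timestamp`, `par`, `reco`, `gpp` (zero at night, can be
#'   slightly negative in noisy daytime records — left unclamped), `model`.
#' @export
partition_series_nighttime <- function(data, par_threshold = 10) {
  data <- as_tibble(data)
  e0_fit <- fit_e0_nighttime(data, par_threshold = par_threshold)
  rp <- respiration_params(e0_fit$rb_night, e0_fit$e0)
  reco <- reco_lloyd_taylor(rp, data$t_air)
  gpp <- ifelse(data$par > par_threshold, reco - data$nee, 0)
  tibble(timestamp = data$timestamp, par = data$par, reco = reco, gpp = gpp,
         model = "fp_nighttime")
}

#' Campaign totals of a half-hourly flux series
#'
#' Integrates half-hourly values over the campaign (value x 1800 s),
#' returned in mol m-2.
#'
#' @param x Numeric half-hourly series, umol m-2 s-1.
#' @return Campaign sum, mol m-2.
#' @export
campaign_sum <- function(x) sum(x, na.rm = TRUE) * 1800 * 1e-6

#' Percent difference between two campaign GPP series
#'
#' `100 * (sum(b) - sum(a)) / sum(a)` over the whole campaign, with the
#' spread given as the standard deviation of the same statistic computed
#' per sub-period (days by default, weeks optionally) — a measure of the
#' temporal variability of the model difference. Invariant to uniform
#' rescaling of both series.
#'
#' @param data Tibble with `timestamp` and the two series columns.
#' @param ref,alt Column names (strings) of the reference and alternative
#'   GPP series.
#' @param period `"day"` or `"week"` for the spread sub-periods.
#' @return One-row tibble: `pct_diff`, `spread_sd`, `n_periods`,
#'   `sum_ref`, `sum_alt` (mol m-2).
#' @examples
#' d <- tibble::tibble(
#'   timestamp = seq(as.POSIXct("2015-06-01", tz = "Etc/GMT-1"),
#'                   by = 1800, length.out = 96),
#'   a = 10, b = 10.5)
#' campaign_percent_difference(d, "a", "b")  # +5%
#' @export
campaign_percent_difference <- function(data, ref, alt, period = c("day", "week")) {
  period <- match.arg(period)
  data <- as_tibble(data)
  miss <- setdiff(c("timestamp", ref, alt), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  a <- data[[ref]]
  b <- data[[alt]]
  if (sum(a, na.rm = TRUE) <= 0) abort("Reference series sums to <= 0; percent difference undefined.")
  pct <- function(a, b) 100 * (sum(b, na.rm = TRUE) - sum(a, na.rm = TRUE)) / sum(a, na.rm = TRUE)
  grp <- if (period == "day") lubridate::date(data$timestamp) else
    lubridate::floor_date(data$timestamp, "week")
  per <- tibble(grp = grp, a = a, b = b) |>
    group_by(.data$grp) |>
    summarise(ok = sum(.data$a, na.rm = TRUE) > 0,
              p = if (sum(.data$a, na.rm = TRUE) > 0) pct(.data$a, .data$b) else NA_real_,
              .groups = "drop") |>
    filter(.data$ok)
  tibble(pct_diff = pct(a, b),
         spread_sd = sd(per$p),
         n_periods = nrow(per),
         sum_ref = campaign_sum(a),
         sum_alt = campaign_sum(b))
}

#' Mean diel composite of a half-hourly series
#'
#' Groups by hour of day (CET) and returns the mean, standard deviation and
#' count per hour — the standard way diel flux cycles are reported.
#' Idempotent on data that already has one value per hour of day.
#'
#' @param data Tibble with `timestamp` and the series column.
#' @param value Column name (string) of the series.
#' @return Tibble: `hour` (0-23), `mean`, `sd`, `n`.
#' @export
diel_composite <- function(data, value) {
  data <- as_tibble(data)
  miss <- setdiff(c("timestamp", value), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (length(unique(lubridate::date(data$timestamp))) < 2 &&
      nrow(data) > length(unique(lubridate::hour(data$timestamp)))) {
    warn("Fewer than 2 days of data; the composite is just the raw series.")
  }
  data |>
    mutate(hour = lubridate::hour(.data$timestamp)) |>
    group_by(.data$hour) |>
    summarise(mean = mean(.data[[value]], na.rm = TRUE),
              sd = if (sum(!is.na(.data[[value]])) > 1)
                sd(.data[[value]], na.rm = TRUE) else 0,
              n = sum(!is.na(.data[[value]])), .groups = "drop")
}

#' Limit-of-detection flags for a flux series
#'
#' Flags records whose magnitude cannot be distinguished from zero flux:
#' `|flux| < multiplier * sigma_noise`, with the default multiplier 1.96
#' (a two-sided 95% detection limit). Flags annotate, never remove, data.
#'
#' @param flux Numeric flux series.
#' @param sigma_noise Noise standard deviation: a scalar or one value per
#'   record; must be > 0.
#' @param multiplier Detection-limit multiplier (default 1.96).
#' @return Logical vector, `TRUE` = below the limit of detection.
#' @examples
#' lod_flag(c(0, -2, -10), sigma_noise = 3)
#' @export
lod_flag <- function(flux, sigma_noise, multiplier = 1.96) {
  stopifnot(is.numeric(flux), is.numeric(sigma_noise))
  if (any(sigma_noise <= 0)) abort("`sigma_noise` must be > 0.")
  abs(flux) < multiplier * sigma_noise
}

#' Assemble a campaign comparison report
#'
#' Runs [partition_series()] for an FP and an FP+ fit on the same records,
#' joins the two GPP series with their bands, and computes the campaign
#' percent difference. The returned object prints the summary block and
#' carries the full half-hourly table for writing or plotting.
#'
#' @param data Half-hourly campaign tibble (needs `timestamp`, `par`,
#'   `t_air`; `fcos_eco` and `sigma_cos`-scale noise only matter for LOD
#'   flags, see `lod_sigma`).
#' @param fit_fp,fit_fpplus `cos_fit` objects for the two models.
#' @param n_draws Posterior draws per series.
#' @param lod_sigma Optional noise scale (pmol m-2 s-1) to LOD-flag the
#'   `fcos_eco` column if present.
#' @param site Site tag carried into the result.
#' @param force Propagate unconverged fits.
#' @return A `campaign_result`: `series` tibble (per-record GPP/Reco with
#'   bands for both models, LOD flags), `comparison` (one-row tibble from
#'   [campaign_percent_difference()]), `site`, `fits` (glances).
#' @export
campaign_report <- function(data, fit_fp, fit_fpplus, n_draws = 500,
                            lod_sigma = NULL, site = "site", force = FALSE) {
  a <- partition_series(data, fit_fp, n_draws = n_draws, force = force) |>
    rename_with(~ paste0(.x, "_fp"), c("gpp", "gpp_lo", "gpp_hi",
                                       "reco", "reco_lo", "reco_hi")) |>
    select(-"model")
  b <- partition_series(data, fit_fpplus, n_draws = n_draws, force = force) |>
    rename_with(~ paste0(.x, "_fpplus"), c("gpp", "gpp_lo", "gpp_hi",
                                           "reco", "reco_lo", "reco_hi")) |>
    select(-"model", -"par")
  series <- left_join(a, b, by = "timestamp")
  if (!is.null(lod_sigma) && "fcos_eco" %in% names(data)) {
    series$below_lod <- lod_flag(data$fcos_eco, lod_sigma)
  }
  comparison <- campaign_percent_difference(series, "gpp_fp", "gpp_fpplus")
  structure(
    list(series = series, comparison = comparison, site = site,
         fits = bind_rows(glance(fit_fp), glance(fit_fpplus))),
    class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("<campaign_result %s: %d half hours>\n", x$site, nrow(x$series)))
  cat(sprintf("  GPP sums (mol m-2): FP %.2f, FP+ %.2f\n",
              x$comparison$sum_ref, x$comparison$sum_alt))
  cat(sprintf("  FP+ vs FP: %+.2f%% +- %.2f%% (sd over %d days)\n",
              x$comparison$pct_diff, x$comparison$spread_sd,
              x$comparison$n_periods))
  if (any(!x$fits$converged)) cat("  ** contains UNCONVERGED fits **\n")
  invisible(x)
}

#' @rdname campaign_report
#' @param x A `campaign_result`.
#' @param ... Unused.
#' @export
tidy.campaign_result <- function(x, ...) x$series

#' @rdname campaign_report
#' @export
glance.campaign_result <- function(x, ...) {
  bind_cols(tibble(site = x$site), x$comparison)
}
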