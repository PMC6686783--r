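#' Molar flow rate from a volumetric flow reading
#'
#' Converts the chamber pump's volumetric flow (L/min, as logged in the
#' field) to a molar flow via the ideal gas law, n = P V / (R T).
#'
#' @param v_flow Volumetric flow, L per minute, > 0.
#' @param temperature Gas temperature, degrees C.
#' @param pressure Ambient pressure, hPa.
#' @return Molar flow, mol s-1. Vectorized over all arguments.
#' @examples
#' molar_flow_from_volumetric(7, 25, 1013.25)
#' @export
molar_flow_from_volumetric <- function(v_flow, temperature, pressure) {
  stopifnot(is.numeric(v_flow), is.numeric(temperature), is.numeric(pressure))
  if (any(v_flow <= 0) || any(pressure <= 0) || any(temperature <= -273.15)) {
    abort("Flow and pressure must be positive and temperature above absolute zero.")
  }
  r_gas <- 8.314462618 # J mol-1 K-1
  (pressure * 100) * (v_flow / 1000 / 60) / (r_gas * (temperature + 273.15))
}

#' Steady-state chamber soil COS flux
#'
#' Flow-through chamber mass balance, `F = q (C2 - C1) / A`: the molar flow
#' through the chamber times the COS mole-fraction difference between
#' chamber air (C2) and ambient air above it (C1), per unit soil area.
#' Since ppt is pmol/mol, the product of mol s-1 and ppt is directly in
#' pmol s-1. Positive flux = soil emission, negative = soil uptake
#' (micrometeorological convention).
#'
#' The steady-state form is only valid for readings taken after the chamber
#' headspace stabilized; rows with `stable_flag == FALSE` get `NA` rather
#' than a misleading number. Stability is an input flag — this function does
#' not attempt to detect it.
#'
#' @param data Tibble of chamber measurements with columns `c_ambient_ppt`,
#'   `c_chamber_ppt`, `area_m2`, and either `q_mol_s` or the triplet
#'   `q_lpm`, `temp_c`, `press_hpa` (converted internally via
#'   [molar_flow_from_volumetric()]). An optional logical `stable_flag`
#'   marks steady-state readings (missing flag means all stable).
#' @return The input tibble with columns `q_mol_s` and `f_soil`
#'   (pmol m-2 s-1) appended.
#' @examples
#' tibble::tibble(q_lpm = 7, temp_c = 25, press_hpa = 1013.25,
#'                c_ambient_ppt = 500, c_chamber_ppt = 510,
#'                area_m2 = 0.032) |>
#'   chamber_flux()
#' @export
chamber_flux <- function(data) {
  data <- as_tibble(data)
  if (!"q_mol_s" %in% names(data)) {
    need <- c("q_lpm", "temp_c", "press_hpa")
    if (!all(need %in% names(data))) {
      abort("Provide either `q_mol_s` or the columns `q_lpm`, `temp_c`, `press_hpa`.")
    }
    data$q_mol_s <- molar_flow_from_volumetric(data$q_lpm, data$temp_c, data$press_hpa)
  }
  need <- c("c_ambient_ppt", "c_chamber_ppt", "area_m2")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Missing chamber column(s): ", paste(miss, collapse = ", ")))
  if (any(data$q_mol_s <= 0)) abort("Chamber molar flow `q_mol_s` must be > 0.")
  if (any(data$area_m2 <= 0)) abort("Chamber soil area `area_m2` must be > 0.")
  if (any(data$c_ambient_ppt < 0, na.rm = TRUE) ||
      any(data$c_chamber_ppt < 0, na.rm = TRUE)) {
    abort("COS mole fractions must be >= 0.")
  }
  stable <- if ("stable_flag" %in% names(data)) data$stable_flag else TRUE
  data |>
    mutate(f_soil = ifelse(stable,
                           .data$q_mol_s * (.data$c_chamber_ppt - .data$c_ambient_ppt) /
                             .data$area_m2,
                           NA_real_))
}

#' Fit a soil COS flux regression model
#'
#' Trains a random-forest regression of chamber-derived soil COS fluxes on
#' the three soil drivers — shortwave radiation incident at the soil surface,
#' soil temperature and volumetric soil moisture — so the sparse chamber
#' record can be extrapolated to the half-hourly timescale of the tower
#' fluxes. One model per site; never pool sites by default.
#'
#' Forest settings: 500 trees, one third of the drivers tried per split,
#' minimum node size 5, out-of-bag scoring; all recorded in the returned
#' object's metadata. Extra driver columns beyond the canonical three are
#' only used when `extra_drivers = TRUE`.
#'
#' @param data Tibble with driver columns `sw_soil` (W m-2), `t_soil`
#'   (degrees C), `swc` (m3 m-3) and the response column named by `flux`.
#' @param flux Name of the flux column, default `"f_soil"` (pmol m-2 s-1).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param extra_drivers If `TRUE`, any additional numeric columns in `data`
#'   are used as predictors too (off by default).
#' @return A `soil_flux_model` object with the fitted forest, the driver
#'   names, `n`, the out-of-bag R2 and the seed.
#' @export
fit_soil_model <- function(data, flux = "f_soil", seed = 1L, extra_drivers = FALSE) {
  data <- as_tibble(data)
  drivers <- c("sw_soil", "t_soil", "swc")
  miss <- setdiff(c(drivers, flux), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (extra_drivers) {
    extra <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                     c(drivers, flux, "timestamp"))
    drivers <- c(drivers, extra)
  }
  keep <- stats::complete.cases(data[c(drivers, flux)])
  data <- data[keep, ]
  n <- nrow(data)
  if (n < 20) {
    abort(sprintf(
      "Only %d complete soil observations; need >= 20. Consider pooling chamber collars within the site.", n))
  }
  y <- data[[flux]]
  x <- as.data.frame(data[drivers])
  constant <- isTRUE(sd(y) == 0)
  if (constant) {
    warn("Soil flux target is constant; the model will predict that constant.")
  }
  set.seed(seed)
  rf_call <- function() randomForest::randomForest(
    x = x, y = y,
    ntree = 500, mtry = max(1L, floor(length(drivers) / 3)),
    nodesize = 5, keep.inbag = FALSE)
  fit <- if (constant) suppressWarnings(rf_call()) else rf_call()
  oob_r2 <- if (constant) NA_real_ else 1 - mean((fit$predicted - y)^2) / var(y) * (n - 1) / n
  structure(
    list(forest = fit, drivers = drivers, n = n, oob_r2 = oob_r2,
         seed = seed, training_range = purrr::map(x, range)),
    class = "soil_flux_model")
}

#' @export
print.soil_flux_model <- function(x, ...) {
  cat("<soil_flux_model>\n")
  cat("  drivers:", paste(x$drivers, collapse = ", "), "\n")
  cat(sprintf("  n = %d, OOB R2 = %s, seed = %d\n", x$n,
              ifelse(is.na(x$oob_r2), "NA", sprintf("%.3f", x$oob_r2)), x$seed))
  invisible(x)
}

#' Predict half-hourly soil COS fluxes
#'
#' Evaluates a fitted [fit_soil_model()] on new driver rows. Predictions are
#' finite for any in-range drivers; rows outside the training hull trigger a
#' warning (random forests extrapolate flatly) but are still predicted.
#'
#' @param model A `soil_flux_model`.
#' @param data Tibble containing the model's driver columns.
#' @return The input tibble with a `f_soil_pred` column (pmol m-2 s-1,
#'   positive = emission) appended.
#' @export
predict_soil_flux <- function(model, data) {
  if (!inherits(model, "soil_flux_model")) abort("`model` must come from fit_soil_model().")
  data <- as_tibble(data)
  miss <- setdiff(model$drivers, names(data))
  if (length(miss)) abort(paste0("Missing driver column(s): ", paste(miss, collapse = ", ")))
  x <- as.data.frame(data[model$drivers])
  if (anyNA(x)) abort("Driver columns must be complete for prediction.")
  outside <- purrr::imap_lgl(model$training_range, function(rg, nm) {
    any(x[[nm]] < rg[1] | x[[nm]] > rg[2])
  })
  if (any(outside)) {
    warn(paste0("Drivers outside the training range: ",
                paste(names(outside)[outside], collapse = ", "),
                " — predictions there are flat extrapolations."))
  }
  data$f_soil_pred <- as.numeric(predict(model$forest, newdata = x))
  data
}

#' Correct ecosystem COS fluxes for the soil contribution
#'
#' Canopy COS flux = ecosystem COS flux minus soil COS flux, both in the
#' micrometeorological convention, aligned by timestamp. The conservation
#' identity ecosystem = canopy + soil holds exactly after correction.
#'
#' @param data Tibble with columns `timestamp`, the ecosystem flux column
#'   `fcos_eco` and the soil flux column `f_soil_pred` (both pmol m-2 s-1).
#'   Alternatively pass two tibbles via `soil`: they are joined on
#'   `timestamp`, and records missing from either side raise an error that
#'   lists the gaps.
#' @param soil Optional tibble with `timestamp` and `f_soil_pred`.
#' @return `data` with `fcos_canopy = fcos_eco - f_soil_pred` appended.
#' @export
canopy_cos_flux <- function(data, soil = NULL) {
  data <- as_tibble(data)
  if (!is.null(soil)) {
    soil <- as_tibble(soil)[c("timestamp", "f_soil_pred")]
    gaps <- setdiff(as.character(data$timestamp), as.character(soil$timestamp))
    if (length(gaps)) {
      abort(paste0("Soil series missing ", length(gaps), " timestamp(s), e.g. ",
                   paste(head(gaps, 3), collapse = "; ")))
    }
    data <- left_join(data, soil, by = "timestamp")
  }
  miss <- setdiff(c("fcos_eco", "f_soil_pred"), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  data |> mutate(fcos_canopy = .data$fcos_eco - .data$f_soil_pred)
}
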