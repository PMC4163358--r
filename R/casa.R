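#' Absorbed photosynthetically active radiation
#'
#' APAR(x, t) = SOL(x, t) * FPAR(x, t) * par_fraction. The PAR fraction
#' (default 0.5) is the share of total solar radiation in the 0.4-0.7 um band
#' usable by vegetation.
#'
#' @param sol monthly total solar surface radiation, MJ/m2 (`grid_stack`).
#' @param fpar monthly FPAR in \[0, 1\] (`grid_stack`), aligned with `sol`.
#' @param params a [casa_params()] object.
#' @return `grid_stack` of APAR in MJ/m2; nodata in either input propagates.
#' @export
compute_apar <- function(sol, fpar, params = casa_params()) {
  check_aligned(sol, fpar)
  validate_stack(fpar, "fpar")
  grid_like(sol, sol$values * fpar$values * params$par_fraction, units = "MJ/m2")
}

#' Optimal temperature
#'
#' Per cell, the monthly mean air temperature of the month of maximal
#' greenness. FPAR is the greenness proxy (it is the monotone canopy product
#' in the input set); ties are broken by the earliest month so the result is
#' deterministic. A cell whose FPAR is masked in all 12 months is masked.
#'
#' @param temperature monthly mean air temperature, degC (`grid_stack`, 12
#'   layers).
#' @param fpar monthly FPAR (`grid_stack`, 12 layers), aligned.
#' @return single-layer `grid_stack`, degC.
#' @export
compute_topt <- function(temperature, fpar) {
  check_aligned(temperature, fpar)
  stopifnot(n_layers(fpar) == 12L)
  d <- dim(fpar$values)
  fv <- matrix(fpar$values, d[1] * d[2], d[3])
  tv <- matrix(temperature$values, d[1] * d[2], d[3])
  topt <- rep(NA_real_, nrow(fv))
  ok <- rowSums(!is.na(fv)) > 0
  if (any(ok)) {
    # which.max ignores NA and returns the first index on ties
    idx <- apply(fv[ok, , drop = FALSE], 1, which.max)
    topt[ok] <- tv[cbind(which(ok), idx)]
  }
  grid_like(temperature, matrix(topt, d[1], d[2]), units = "degC")
}

#' First temperature stress scalar
#'
#' Te1 = 0.8 + 0.02*Topt - 0.0005*Topt^2, a downward parabola with maximum
#' 1.0 at Topt = 20 degC and value 0.8 at 0 and 40 degC. No clamp is applied:
#' the published form is the bare polynomial, so extreme optima producing
#' Te1 < 0 are reported by a warning rather than silently truncated.
#'
#' @param topt single-layer `grid_stack` of optimal temperature, degC.
#' @return single-layer dimensionless `grid_stack`.
#' @export
temperature_stress_1 <- function(topt) {
  v <- topt$values
  te1 <- 0.8 + 0.02 * v - 0.0005 * v^2
  n_neg <- sum(te1 < 0, na.rm = TRUE)
  if (n_neg > 0)
    warning("temperature_stress_1: ", n_neg,
            " cell(s) with Te1 < 0 (extreme optimal temperature)")
  grid_like(topt, te1, units = "dimensionless")
}

#' Second temperature stress scalar
#'
#' Te2(x, t) = 1.1814 / (1 + exp(0.2*(Topt - 10 - T))) /
#' (1 + exp(0.3*(-Topt - 10 + T))): a double-logistic response that peaks
#' near T = Topt and falls off faster on the cold side than the warm side.
#' Large exponents saturate (exp -> Inf gives a 0-valued factor), so very
#' cold or hot months yield Te2 ~ 0 without numeric faults.
#'
#' @param topt single-layer `grid_stack`, degC.
#' @param temperature monthly air temperature `grid_stack`, degC.
#' @param params a [casa_params()] object.
#' @return monthly dimensionless `grid_stack`, values in (0, te2_scale).
#' @export
temperature_stress_2 <- function(topt, temperature, params = casa_params()) {
  check_aligned(topt, temperature, layers = FALSE)
  d <- dim(temperature$values)
  to <- array(topt$values[, , 1], d)  # recycle the single layer over months
  tt <- temperature$values
  warm <- 1 + exp(params$te2_k_warm * (to - params$te2_offset - tt))
  cold <- 1 + exp(params$te2_k_cold * (-to - params$te2_offset + tt))
  grid_like(temperature, params$te2_scale / (warm * cold), units = "dimensionless")
}

#' Dew point from total precipitable water
#'
#' Inverts the regression ln(U) = 1.8084 + 0.0735 * Td linking column water
#' vapor U (mm) to dew point Td: Td = (ln(U) - intercept) / slope. Td here is
#' in degrees C (the only reading that gives plausible U); [run_casa()] adds
#' `svp_t0` before the vapor-pressure-deficit step, which needs Kelvin.
#'
#' @param u monthly total precipitable water, mm (`grid_stack`), > 0.
#' @param params a [casa_params()] object.
#' @return monthly `grid_stack` of dew point, degC. Non-positive U is masked
#'   with a warning.
#' @export
dew_point_from_precipitable_water <- function(u, params = casa_params()) {
  v <- u$values
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    warning("dew_point_from_precipitable_water: ", sum(bad),
            " cell-month(s) with U <= 0 masked")
    v[bad] <- NA_real_
  }
  grid_like(u, (log(v) - params$dew_intercept) / params$dew_slope, units = "degC")
}

#' Vapor pressure deficit
#'
#' D = 0.611 * \[exp(17.27*(Ts - 273)/(Ts - 36)) -
#' exp(17.27*(Td - 273)/(Td - 36))\] in kPa, with surface temperature Ts and
#' dew point Td in Kelvin; wherever Ts - Td < 0, D = 0 (saturated air exerts
#' no deficit). Temperatures at or below 36 K would make a denominator
#' degenerate and are masked with a warning.
#'
#' @param ts land-surface temperature `grid_stack`, K.
#' @param td dew point `grid_stack`, K, aligned with `ts`.
#' @param params a [casa_params()] object.
#' @return monthly `grid_stack` of D >= 0, kPa.
#' @export
vapor_pressure_deficit <- function(ts, td, params = casa_params()) {
  check_aligned(ts, td)
  validate_stack(ts, "kelvin"); validate_stack(td, "kelvin")
  tsv <- ts$values; tdv <- td$values
  degen <- (!is.na(tsv) & tsv <= params$svp_b) | (!is.na(tdv) & tdv <= params$svp_b)
  if (any(degen)) {
    warning("vapor_pressure_deficit: ", sum(degen),
            " cell-month(s) at or below ", params$svp_b, " K masked")
    tsv[degen] <- NA_real_; tdv[degen] <- NA_real_
  }
  svp <- function(tk)
    params$svp_coeff * exp(params$svp_a * (tk - params$svp_t0) / (tk - params$svp_b))
  d <- svp(tsv) - svp(tdv)
  d[!is.na(tsv) & !is.na(tdv) & tsv - tdv < 0] <- 0
  grid_like(ts, d, units = "kPa")
}

#' Moisture stress scalar
#'
#' We = 1.2 * exp(-0.35 * D) - 0.2, monotonically non-increasing in the
#' vapor-pressure deficit D, equal to 1 at D = 0. The raw expression turns
#' negative for D above ~5.1 kPa; it is clamped below at `we_floor` (default
#' 0) so efficiency and productivity stay non-negative. Clamp activations are
#' reported by a warning for auditability.
#'
#' @param d monthly vapor-pressure deficit `grid_stack`, kPa, >= 0.
#' @param params a [casa_params()] object.
#' @return monthly dimensionless `grid_stack` in \[we_floor, 1\].
#' @export
water_stress <- function(d, params = casa_params()) {
  v <- d$values
  if (any(v < 0, na.rm = TRUE))
    stop("water_stress: negative vapor-pressure deficit")
  we <- params$we_a * exp(-params$we_b * v) - params$we_c
  n_clamp <- sum(we < params$we_floor, na.rm = TRUE)
  if (n_clamp > 0)
    warning("water_stress: clamped ", n_clamp, " cell-month(s) at we_floor = ",
            params$we_floor)
  grid_like(d, pmax(we, params$we_floor), units = "dimensionless")
}

#' Light use efficiency
#'
#' LUE = Te1 * Te2 * We * eps_max (g/MJ): the unstressed maximum efficiency
#' for grass scaled down by the temperature and moisture stress scalars.
#'
#' @param te1 single-layer `grid_stack` from [temperature_stress_1()].
#' @param te2 monthly `grid_stack` from [temperature_stress_2()].
#' @param we monthly `grid_stack` from [water_stress()].
#' @param params a [casa_params()] object.
#' @return monthly `grid_stack`, g/MJ.
#' @export
compute_lue <- function(te1, te2, we, params = casa_params()) {
  check_aligned(te1, te2, layers = FALSE)
  check_aligned(te2, we)
  d <- dim(te2$values)
  t1 <- array(te1$values[, , 1], d)
  grid_like(te2, t1 * te2$values * we$values * params$eps_max, units = "g/MJ")
}

#' Net primary productivity
#'
#' NPP(x, t) = APAR(x, t) * LUE(x, t) per month, in gC/m2.
#'
#' @param apar monthly `grid_stack`, MJ/m2.
#' @param lue monthly `grid_stack`, g/MJ, aligned.
#' @return monthly `grid_stack`, gC/m2.
#' @export
compute_npp <- function(apar, lue) {
  check_aligned(apar, lue)
  grid_like(apar, apar$values * lue$values, units = "gC/m2")
}

#' Annual layer: sum of monthly layers
#'
#' Sums the 12 monthly layers per cell over unmasked months; a cell masked in
#' every month stays masked.
#'
#' @param stack monthly `grid_stack`.
#' @return single-layer `grid_stack` in the same units.
#' @export
annual_total <- function(stack) {
  s <- apply(stack$values, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
  grid_like(stack, s)
}

#' Run the full light-use-efficiency equation chain
#'
#' Chains optimal temperature, both temperature stress scalars, dew point
#' from precipitable water, vapor-pressure deficit (dew point converted degC
#' to K by adding `svp_t0`), moisture stress, light use efficiency, APAR and
#' monthly NPP, returning every intermediate for inspection. Masks are
#' unioned along the chain: a cell-month masked in any input is masked in NPP.
#'
#' @param inputs named list of aligned 12-layer `grid_stack`s:
#'   `sol` (MJ/m2), `fpar` (0-1), `temperature` (degC air temperature),
#'   `lst` (K land-surface temperature), `precipitable_water` (mm).
#' @param params a [casa_params()] object.
#' @return list of class `casa_outputs` with `apar`, `topt`, `te1`, `te2`,
#'   `d_vpd`, `we`, `lue`, `npp` and `npp_annual`.
#' @examples
#' scene <- generate_scene(scene_config(grid_shape = c(8, 8), seed = 1))
#' out <- run_casa(scene$inputs)
#' range(out$npp_annual$values, na.rm = TRUE)
#' @export
run_casa <- function(inputs, params = casa_params()) {
  need <- c("sol", "fpar", "temperature", "lst", "precipitable_water")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("configuration error: missing input layer(s): ", paste(miss, collapse = ", "))
  for (nm in need) {
    if (!inherits(inputs[[nm]], "grid_stack"))
      stop("configuration error: input '", nm, "' is not a grid_stack")
    if (n_layers(inputs[[nm]]) != 12L)
      stop("configuration error: input '", nm, "' does not have 12 monthly layers")
    tryCatch(check_aligned(inputs$sol, inputs[[nm]]),
             error = function(e)
               stop("configuration error in input '", nm, "': ",
                    conditionMessage(e), call. = FALSE))
  }
  topt <- compute_topt(inputs$temperature, inputs$fpar)
  te1 <- temperature_stress_1(topt)
  te2 <- temperature_stress_2(topt, inputs$temperature, params)
  td_c <- dew_point_from_precipitable_water(inputs$precipitable_water, params)
  td_k <- grid_like(td_c, td_c$values + params$svp_t0, units = "K")
  d_vpd <- vapor_pressure_deficit(inputs$lst, td_k, params)
  we <- water_stress(d_vpd, params)
  lue <- compute_lue(te1, te2, we, params)
  apar <- compute_apar(inputs$sol, inputs$fpar, params)
  npp <- compute_npp(apar, lue)
  out <- list(apar = apar, topt = topt, te1 = te1, te2 = te2, d_vpd = d_vpd,
              we = we, lue = lue, npp = npp, npp_annual = annual_total(npp))
  class(out) <- "casa_outputs"
  out
}
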