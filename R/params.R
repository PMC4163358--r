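#' Model parameters
#'
#' Every numeric constant of the light-use-efficiency model in one place, so a
#' run is fully determined by its inputs plus one parameter object.
#'
#' The defaults are the published grassland parameterisation: PAR is taken as
#' 0.5 x total solar radiation; the unstressed maximum light use efficiency
#' for grass is 0.604 g/MJ; the warm-side and cold-side logistic rates of the
#' second temperature scalar are 0.2 and 0.3 per degree C with a 10 degree C
#' offset and a 1.1814 normalising factor; the moisture scalar is
#' 1.2*exp(-0.35*D) - 0.2 of vapor-pressure deficit D (kPa), clamped below at
#' `we_floor`; saturation vapor pressure uses 0.611*exp(17.27*(T-273)/(T-36))
#' with T in Kelvin (273 as printed, not 273.15); dew point relates to total
#' precipitable water U (mm) through ln(U) = 1.8084 + 0.0735*Td with Td in
#' degrees C. Dry yield converts to carbon with fraction 0.45, and root:shoot
#' ratios (belowground/aboveground) allocate the unmeasured root production.
#'
#' @param ... overrides by name, e.g. `casa_params(eps_max = 0.5)`. Unknown
#'   names are rejected.
#' @return a list of class `casa_params`.
#' @examples
#' p <- casa_params()
#' p$eps_max
#' casa_params(eps_max = 0.5)$eps_max
#' @export
casa_params <- function(...) {
  p <- list(
    par_fraction   = 0.5,     # PAR / total solar radiation
    eps_max        = 0.604,   # g/MJ, grass
    te2_scale      = 1.1814,
    te2_k_warm     = 0.2,     # 1/degC
    te2_k_cold     = 0.3,     # 1/degC
    te2_offset     = 10,      # degC
    we_a           = 1.2,
    we_b           = 0.35,    # 1/kPa
    we_c           = 0.2,
    we_floor       = 0.0,     # lower clamp on the moisture scalar
    svp_coeff      = 0.611,   # kPa
    svp_a          = 17.27,
    svp_t0         = 273,     # K, as printed
    svp_b          = 36,      # K
    dew_intercept  = 1.8084,
    dew_slope      = 0.0735,  # 1/degC
    carbon_fraction = 0.45,   # gC per g dry matter
    root_shoot = c("mountain meadow" = 6.23,
                   "alpine meadow" = 7.92,
                   "alpine shrub meadow" = 7.92)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad) || is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; valid: ", paste(names(p), collapse = ", "))
    p[names(ov)] <- ov
  }
  num <- unlist(p[setdiff(names(p), "root_shoot")])
  if (any(!is.finite(num)) || any(num[setdiff(names(num), "we_floor")] < 0))
    stop("all numeric parameters must be finite and non-negative")
  if (p$par_fraction <= 0 || p$par_fraction > 1)
    stop("par_fraction must be in (0, 1]")
  if (any(p$root_shoot < 0)) stop("root:shoot ratios must be >= 0")
  class(p) <- "casa_params"
  p
}
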