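#' Scalar-loop reference evaluation of the equation chain
#'
#' A deliberately naive per-cell, per-month implementation of the full model
#' (optimal temperature, both temperature scalars, dew point, vapor-pressure
#' deficit, moisture scalar, LUE, APAR, NPP) using explicit loops and scalar
#' arithmetic only. It shares no code with the vectorised grid operations, so
#' agreement between the two is a genuine cross-check; the synthetic-scene
#' generator uses it to produce ground truth.
#'
#' @param sol,fpar,temperature,lst,u numeric rows x cols x 12 arrays: solar
#'   radiation (MJ/m2), FPAR (0-1), air temperature (degC), land-surface
#'   temperature (K), total precipitable water (mm).
#' @param params a [casa_params()] object.
#' @return list of plain arrays: topt, te1, te2, d_vpd, we, lue, apar, npp,
#'   npp_annual.
#' @export
oracle_casa <- function(sol, fpar, temperature, lst, u, params = casa_params()) {
  d <- dim(fpar)
  topt <- matrix(NA_real_, d[1], d[2])
  te1 <- matrix(NA_real_, d[1], d[2])
  te2 <- array(NA_real_, d); dv <- array(NA_real_, d); we <- array(NA_real_, d)
  lue <- array(NA_real_, d); apar <- array(NA_real_, d); npp <- array(NA_real_, d)
  npp_ann <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    best <- NA_integer_; bestf <- -Inf
    for (m in 1:12) {
      f <- fpar[i, j, m]
      if (!is.na(f) && f > bestf) { bestf <- f; best <- m }
    }
    if (!is.na(best)) {
      to <- temperature[i, j, best]
      topt[i, j] <- to
      if (!is.na(to)) te1[i, j] <- 0.8 + 0.02 * to - 0.0005 * to * to
    }
    ann <- NA_real_
    for (m in 1:12) {
      to <- topt[i, j]; tt <- temperature[i, j, m]
      if (!is.na(to) && !is.na(tt)) {
        te2[i, j, m] <- params$te2_scale /
          (1 + exp(params$te2_k_warm * (to - params$te2_offset - tt))) /
          (1 + exp(params$te2_k_cold * (-to - params$te2_offset + tt)))
      }
      uu <- u[i, j, m]; tk <- lst[i, j, m]
      if (!is.na(uu) && uu > 0 && !is.na(tk) && tk > params$svp_b) {
        td_c <- (log(uu) - params$dew_intercept) / params$dew_slope
        td_k <- td_c + params$svp_t0
        if (td_k > params$svp_b) {
          if (tk - td_k < 0) {
            dv[i, j, m] <- 0
          } else {
            e_s <- params$svp_coeff *
              exp(params$svp_a * (tk - params$svp_t0) / (tk - params$svp_b))
            e_d <- params$svp_coeff *
              exp(params$svp_a * (td_k - params$svp_t0) / (td_k - params$svp_b))
            dv[i, j, m] <- e_s - e_d
          }
          w <- params$we_a * exp(-params$we_b * dv[i, j, m]) - params$we_c
          we[i, j, m] <- max(w, params$we_floor)
        }
      }
      if (!is.na(te1[i, j]) && !is.na(te2[i, j, m]) && !is.na(we[i, j, m]))
        lue[i, j, m] <- te1[i, j] * te2[i, j, m] * we[i, j, m] * params$eps_max
      s <- sol[i, j, m]; f <- fpar[i, j, m]
      if (!is.na(s) && !is.na(f))
        apar[i, j, m] <- s * f * params$par_fraction
      if (!is.na(apar[i, j, m]) && !is.na(lue[i, j, m])) {
        npp[i, j, m] <- apar[i, j, m] * lue[i, j, m]
        ann <- if (is.na(ann)) npp[i, j, m] else ann + npp[i, j, m]
      }
    }
    npp_ann[i, j] <- ann
  }
  list(topt = topt, te1 = te1, te2 = te2, d_vpd = dv, we = we, lue = lue,
       apar = apar, npp = npp, npp_annual = npp_ann)
}
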