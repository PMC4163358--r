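#' 8-day composite series
#'
#' Container for a sequence of compositing periods (typically 8 days, shorter
#' at year end) to be aggregated to monthly stacks. Periods must be
#' non-overlapping and ascending, and all layers must share georeferencing.
#'
#' @param layers list of single-layer `grid_stack`s, one per period.
#' @param period_start `Date` vector, first day of each period.
#' @param period_length_days integer vector, days per period.
#' @return object of class `composite_series`.
#' @export
composite_series <- function(layers, period_start, period_length_days) {
  period_start <- as.Date(period_start)
  stopifnot(length(layers) == length(period_start),
            length(layers) == length(period_length_days),
            all(period_length_days >= 1))
  if (length(layers) > 1) {
    ends <- period_start + period_length_days - 1
    if (any(diff(period_start) <= 0) ||
        any(period_start[-1] <= ends[-length(ends)]))
      stop("periods must be non-overlapping and ascending")
    for (i in seq_along(layers)[-1]) check_aligned(layers[[1]], layers[[i]])
  }
  structure(list(layers = layers, period_start = period_start,
                 period_length_days = as.integer(period_length_days)),
            class = "composite_series")
}

#' Composite a period series to a monthly stack
#'
#' Month m of `year` is the day-overlap-weighted mean of all periods touching
#' it: a period contributes its layer weighted by the number of its days that
#' fall inside the month. A cell masked in a period is excluded from that
#' period's contribution (the remaining weights renormalise). A month with no
#' overlapping unmasked value is masked.
#'
#' @param series a [composite_series()].
#' @param year calendar year to composite (default: year of the first period).
#' @return 12-layer monthly `grid_stack`.
#' @export
composite_to_monthly <- function(series,
                                 year = as.integer(format(series$period_start[1], "%Y"))) {
  tmpl <- series$layers[[1]]
  d2 <- grid_dim(tmpl)
  out <- array(NA_real_, c(d2, 12L))
  starts <- series$period_start
  ends <- starts + series$period_length_days - 1
  for (m in 1:12) {
    m0 <- as.Date(sprintf("%04d-%02d-01", year, m))
    m1 <- if (m == 12) as.Date(sprintf("%04d-12-31", year)) else
      as.Date(sprintf("%04d-%02d-01", year, m + 1)) - 1
    ov <- as.numeric(pmin(ends, m1) - pmax(starts, m0) + 1)
    touch <- which(ov > 0)
    if (!length(touch)) next
    wsum <- matrix(0, d2[1], d2[2]); vsum <- matrix(0, d2[1], d2[2])
    for (i in touch) {
      v <- series$layers[[i]]$values[, , 1]
      valid <- !is.na(v)
      vsum[valid] <- vsum[valid] + ov[i] * v[valid]
      wsum[valid] <- wsum[valid] + ov[i]
    }
    lay <- vsum / wsum
    lay[wsum == 0] <- NA_real_
    out[, , m] <- lay
  }
  grid_stack(out, tmpl$extent, tmpl$crs, tmpl$units)
}

#' Temporal gap-filling by cubic spline
#'
#' Fills masked months per cell with a natural cubic spline through the
#' observed months. Observed values are never altered, and the spline is
#' exact for series that are linear in time. Missing months outside the
#' observed range are clamped to the nearest observed value rather than
#' extrapolated (cubic extrapolation on seasonal data diverges). Cells with
#' fewer than two observed months are left as they are.
#'
#' @param stack monthly `grid_stack` with `NA` gaps.
#' @return gap-filled `grid_stack`; the number of degenerate (<2 observed
#'   months) cells is reported via a message.
#' @export
gap_fill_time <- function(stack) {
  d <- dim(stack$values)
  v <- matrix(stack$values, d[1] * d[2], d[3])
  months <- seq_len(d[3])
  n_degenerate <- 0L
  for (i in seq_len(nrow(v))) {
    obs <- which(!is.na(v[i, ]))
    gaps <- which(is.na(v[i, ]))
    if (!length(gaps)) next
    if (length(obs) < 2L) { n_degenerate <- n_degenerate + 1L; next }
    interior <- gaps[gaps > min(obs) & gaps < max(obs)]
    if (length(interior)) {
      f <- stats::splinefun(obs, v[i, obs], method = "natural")
      v[i, interior] <- f(interior)
    }
    v[i, gaps[gaps < min(obs)]] <- v[i, min(obs)]
    v[i, gaps[gaps > max(obs)]] <- v[i, max(obs)]
  }
  if (n_degenerate > 0)
    message("gap_fill_time: ", n_degenerate,
            " cell(s) with < 2 observed months left masked")
  grid_like(stack, array(v, d))
}

#' Station table constructor
#'
#' @param station_id character ids.
#' @param lon,lat degrees.
#' @param elevation metres.
#' @param temps numeric matrix, one row per station, 12 monthly mean
#'   temperatures in degC (`NA` allowed).
#' @return data.frame with columns station_id, lon, lat, elevation_m,
#'   t01..t12 (the station-table exchange format).
#' @export
station_table <- function(station_id, lon, lat, elevation, temps) {
  temps <- as.matrix(temps)
  stopifnot(ncol(temps) == 12L, nrow(temps) == length(station_id),
            all(is.finite(elevation)))
  df <- data.frame(station_id = as.character(station_id), lon = lon, lat = lat,
                   elevation_m = elevation, stringsAsFactors = FALSE)
  colnames(temps) <- sprintf("t%02d", 1:12)
  cbind(df, as.data.frame(temps))
}

#' Elevation-aware interpolation of station temperatures
#'
#' Two-step scheme: (1) fit the lapse relation T = a + b * elevation across
#' stations by least squares; (2) interpolate the residuals over lon/lat with
#' a thin-plate regression spline (`mgcv::gam`); the output field is
#' a + b * DEM + interpolated residual. The scheme is testable by parameter
#' recovery: noise-free stations on a pure lapse field are reproduced
#' exactly. If station elevations are all equal the lapse fit is degenerate
#' and the method falls back to the spatial spline alone with a warning.
#'
#' @param stations a [station_table()] data.frame.
#' @param dem single-layer `grid_stack` of elevation, m.
#' @param month month 1..12 selecting the station temperature column.
#' @return single-layer `grid_stack` of temperature, degC, with attributes
#'   `lapse_rate` (degC per km, `NA` under the degenerate fallback) and
#'   `n_stations`.
#' @export
interpolate_station_temperature <- function(stations, dem, month) {
  stopifnot(month %in% 1:12)
  tcol <- sprintf("t%02d", month)
  st <- stations[is.finite(stations[[tcol]]), , drop = FALSE]
  if (nrow(st) < 3L)
    stop("need >= 3 stations with data for month ", month, "; have ", nrow(st))
  temp <- st[[tcol]]
  degenerate <- length(unique(st$elevation_m)) < 2L
  if (degenerate) {
    warning("station elevations are collinear; using spatial spline only")
    a <- mean(temp); b <- 0
    res <- temp - a
  } else {
    fit <- stats::lm(temp ~ elevation_m, data = st)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    res <- unname(stats::residuals(fit))
  }
  lon <- cell_lon(dem); lat <- cell_lat(dem)
  grd <- expand.grid(lat = lat, lon = lon)  # row-major over the matrix
  res_grid <- if (max(abs(res)) < 1e-10 || nrow(st) < 5L) {
    matrix(mean(res), length(lat), length(lon))
  } else {
    k <- min(nrow(st) - 1L, 30L)
    g <- mgcv::gam(res ~ s(lon, lat, bs = "tp", k = k),
                   data = data.frame(lon = st$lon, lat = st$lat, res = res))
    matrix(as.numeric(mgcv::predict.gam(g, newdata = grd)),
           length(lat), length(lon))
  }
  field <- a + b * dem$values[, , 1] + res_grid
  out <- grid_like(dem, field, units = "degC")
  attr(out, "lapse_rate") <- if (degenerate) NA_real_ else b * 1000
  attr(out, "n_stations") <- nrow(st)
  out
}

#' Interpolate all 12 months of station temperatures
#'
#' @inheritParams interpolate_station_temperature
#' @return 12-layer `grid_stack`, degC, with attribute `lapse_rate` (vector
#'   of 12 fitted rates, degC/km).
#' @export
interpolate_station_temperature_stack <- function(stations, dem) {
  d2 <- grid_dim(dem)
  out <- array(NA_real_, c(d2, 12L))
  rates <- numeric(12)
  for (m in 1:12) {
    g <- interpolate_station_temperature(stations, dem, m)
    out[, , m] <- g$values[, , 1]
    rates[m] <- attr(g, "lapse_rate")
  }
  res <- grid_stack(out, dem$extent, dem$crs, "degC")
  attr(res, "lapse_rate") <- rates
  res
}
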