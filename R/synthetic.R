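#' Synthetic scene configuration
#'
#' Parameters of the seeded synthetic landscape used to exercise every
#' pipeline stage without satellite downloads. The defaults sketch a
#' high-mountain grassland region: a 64 x 64 grid over a 4 x 4 degree
#' extent, elevations 2500-4500 m, an atmospheric lapse rate of -6.5 degC
#' per km, greenness (FPAR) peaking in August, three grassland types
#' stratified by elevation, and 41 temperature stations.
#'
#' @param grid_shape c(rows, cols), >= 4 x 4.
#' @param extent c(xmin, xmax, ymin, ymax) degrees.
#' @param seed integer; all randomness in the scene flows from it.
#' @param lapse_rate degC per km (negative: cooling with altitude).
#' @param fpar_peak_month month of maximal greenness, 1..12.
#' @param elev_range c(min, max) elevation, m.
#' @param fpar_gap_frac fraction of FPAR cell-months masked out (gaps).
#' @param station_noise_sd Gaussian noise on station temperatures, degC.
#' @param yield_noise_sd sdlog of the lognormal multiplicative noise on
#'   in-situ dry yields.
#' @param n_stations number of temperature stations.
#' @param n_per_type in-situ points per grassland type (named or in
#'   root:shoot table order).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(64, 64),
                         extent = c(100, 104, 30, 34),
                         seed = 1L,
                         lapse_rate = -6.5,
                         fpar_peak_month = 8L,
                         elev_range = c(2500, 4500),
                         fpar_gap_frac = 0,
                         station_noise_sd = 0,
                         yield_noise_sd = 0,
                         n_stations = 41L,
                         n_per_type = c("alpine meadow" = 100L,
                                        "alpine shrub meadow" = 30L,
                                        "mountain meadow" = 20L)) {
  cfg <- list(grid_shape = as.integer(grid_shape), extent = as.numeric(extent),
              seed = as.integer(seed), lapse_rate = lapse_rate,
              fpar_peak_month = as.integer(fpar_peak_month),
              elev_range = as.numeric(elev_range),
              fpar_gap_frac = fpar_gap_frac,
              station_noise_sd = station_noise_sd,
              yield_noise_sd = yield_noise_sd,
              n_stations = as.integer(n_stations), n_per_type = n_per_type)
  if (any(cfg$grid_shape < 4L)) stop("grid_shape must be at least 4 x 4")
  if (!cfg$fpar_peak_month %in% 1:12) stop("fpar_peak_month must be 1..12")
  if (cfg$fpar_gap_frac < 0 || cfg$fpar_gap_frac >= 1)
    stop("fpar_gap_frac must be in [0, 1)")
  if (cfg$station_noise_sd < 0 || cfg$yield_noise_sd < 0)
    stop("noise levels must be >= 0")
  if (diff(cfg$elev_range) <= 0) stop("elev_range must be increasing")
  class(cfg) <- "scene_config"
  cfg
}

# smooth random surface in [0, 1]: sum of seeded Gaussian bumps
smooth_surface <- function(nr, nc, n_bumps = 6) {
  r <- matrix(rep(seq_len(nr), nc), nr, nc) / nr
  c_ <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc
  s <- matrix(0, nr, nc)
  for (b in seq_len(n_bumps)) {
    cr <- stats::runif(1); cc <- stats::runif(1)
    w <- stats::runif(1, 0.15, 0.45); amp <- stats::runif(1, -1, 1)
    s <- s + amp * exp(-((r - cr)^2 + (c_ - cc)^2) / (2 * w^2))
  }
  (s - min(s)) / (max(s) - min(s))
}

#' Generate a complete synthetic scene with ground truth
#'
#' Builds an internally consistent input bundle and its exact model truth.
#' The DEM is a smooth random surface over the configured range; monthly air
#' temperature is a summer-peaking seasonal cycle plus the lapse term
#' `lapse_rate * DEM / 1000` and a smooth spatial anomaly; land-surface
#' temperature is air temperature + 2 K offset in Kelvin; total precipitable
#' water is generated forward through the dew-point regression from a dew
#' point a few degrees below air temperature (so the deficit is always
#' well defined); FPAR is a seasonal bell peaking at `fpar_peak_month`,
#' scaled per grassland type; solar radiation is a smooth seasonal cycle.
#' Truth fields (Topt, stress scalars, LUE, APAR, NPP) come from the
#' independent scalar-loop reference [oracle_casa()], never from the grid
#' code under test. Everything is reproducible from `config$seed`.
#'
#' @param config a [scene_config()].
#' @return list with `inputs` (named list of 12-layer `grid_stack`s: sol,
#'   fpar, temperature, lst, precipitable_water), `dem`, `type_map` (codes) +
#'   `type_labels`, `region_map` + `region_labels`, `truth` (oracle arrays),
#'   and `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  p <- casa_params()

  dem_m <- config$elev_range[1] + diff(config$elev_range) * smooth_surface(nr, nc)
  anom <- 2 * (smooth_surface(nr, nc) - 0.5)    # +-2 degC spatial anomaly

  months <- 1:12
  seasonal <- 10 + 11 * cos(2 * pi * (months - 7) / 12)   # degC, peak July
  sol_m <- 420 + 180 * cos(2 * pi * (months - 7) / 12)    # MJ/m2/month

  temperature <- array(NA_real_, c(nr, nc, 12))
  lst <- array(NA_real_, c(nr, nc, 12))
  u <- array(NA_real_, c(nr, nc, 12))
  fpar <- array(NA_real_, c(nr, nc, 12))
  sol <- array(NA_real_, c(nr, nc, 12))

  # grassland types stratified by elevation terciles
  qs <- stats::quantile(dem_m, c(1 / 3, 2 / 3))
  type_code <- matrix(1L, nr, nc)
  type_code[dem_m > qs[1]] <- 2L
  type_code[dem_m > qs[2]] <- 3L
  type_labels <- c("1" = "mountain meadow", "2" = "alpine shrub meadow",
                   "3" = "alpine meadow")
  fpar_amp <- c(0.75, 0.85, 0.65)[type_code]   # per-type canopy amplitude

  region_code <- matrix(rep(cut(seq_len(nc), 3, labels = FALSE), each = nr), nr, nc)
  region_labels <- c("1" = "west", "2" = "central", "3" = "east")

  for (m in months) {
    temperature[, , m] <- seasonal[m] + config$lapse_rate * dem_m / 1000 + anom
    lst[, , m] <- temperature[, , m] + 2 + p$svp_t0
    td_c <- temperature[, , m] - 5          # dew point 5 degC below air temp
    u[, , m] <- exp(p$dew_intercept + p$dew_slope * td_c)
    bell <- exp(-0.5 * ((m - config$fpar_peak_month) / 2)^2)
    fpar[, , m] <- pmin(pmax(fpar_amp * bell + 0.05, 0), 1)
    sol[, , m] <- sol_m[m] * (0.9 + 0.2 * smooth_surface(nr, nc))
  }

  if (config$fpar_gap_frac > 0) {
    n_gap <- round(config$fpar_gap_frac * length(fpar))
    fpar[sample(length(fpar), n_gap)] <- NA_real_
  }

  truth <- oracle_casa(sol, fpar, temperature, lst, u, p)

  mk <- function(v, un) grid_stack(v, config$extent, "EPSG:4326", un)
  list(
    inputs = list(sol = mk(sol, "MJ/m2"), fpar = mk(fpar, "dimensionless"),
                  temperature = mk(temperature, "degC"), lst = mk(lst, "K"),
                  precipitable_water = mk(u, "mm")),
    dem = mk(dem_m, "m"),
    type_map = mk(type_code, "class"), type_labels = type_labels,
    region_map = mk(region_code, "class"), region_labels = region_labels,
    truth = truth,
    config = config
  )
}

#' Sample synthetic temperature stations
#'
#' Draws `n` stations at random cells, with elevations from the DEM and
#' monthly temperatures equal to the true field plus Gaussian noise.
#'
#' @param truth_temperature rows x cols x 12 array or `grid_stack`, degC.
#' @param dem single-layer `grid_stack`, m.
#' @param n number of stations (>= 3).
#' @param noise_sd Gaussian noise standard deviation, degC.
#' @param seed integer seed.
#' @return a [station_table()] data.frame.
#' @export
generate_stations <- function(truth_temperature, dem, n = 41L, noise_sd = 0,
                              seed = 1L) {
  stopifnot(n >= 3L)
  tv <- if (inherits(truth_temperature, "grid_stack"))
    truth_temperature$values else truth_temperature
  set.seed(seed)
  d2 <- grid_dim(dem)
  cells <- sample(which(!is.na(dem$values[, , 1])), n)
  row <- (cells - 1L) %% d2[1] + 1L
  col <- (cells - 1L) %/% d2[1] + 1L
  lon <- cell_lon(dem)[col]; lat <- cell_lat(dem)[row]
  temps <- t(vapply(seq_len(n), function(k)
    tv[row[k], col[k], ] + stats::rnorm(12, 0, noise_sd), numeric(12)))
  station_table(sprintf("S%03d", seq_len(n)), lon, lat,
                dem$values[cbind(row, col, 1L)], temps)
}

#' Sample synthetic in-situ yield points
#'
#' Draws points per grassland type and generates dry yields by inverting the
#' carbon conversion from true annual NPP — yield = NPP / (0.45 * (1 + R))
#' with R the type's root:shoot ratio — then applies lognormal multiplicative
#' noise exp(N(0, rel_noise_sd^2)). With zero noise the validation report
#' recovers 100% precision exactly.
#'
#' @param truth_npp_annual rows x cols matrix or single-layer `grid_stack` of
#'   true annual NPP, gC/m2.
#' @param type_map single-layer `grid_stack` of type codes.
#' @param type_labels named vector code -> grassland-type label.
#' @param n_per_type named counts per label (default 100/30/20).
#' @param rel_noise_sd sdlog of the multiplicative noise.
#' @param seed integer seed.
#' @param params a [casa_params()] object.
#' @return an [insitu_table()] data.frame.
#' @export
generate_insitu_points <- function(truth_npp_annual, type_map, type_labels,
                                   n_per_type = c("alpine meadow" = 100L,
                                                  "alpine shrub meadow" = 30L,
                                                  "mountain meadow" = 20L),
                                   rel_noise_sd = 0, seed = 1L,
                                   params = casa_params()) {
  npp <- if (inherits(truth_npp_annual, "grid_stack"))
    truth_npp_annual$values[, , 1] else truth_npp_annual
  stopifnot(all(names(n_per_type) %in% names(params$root_shoot)),
            all(names(n_per_type) %in% type_labels))
  set.seed(seed)
  d2 <- grid_dim(type_map)
  codes <- type_map$values[, , 1]
  out <- NULL
  for (ty in names(n_per_type)) {
    code <- as.numeric(names(type_labels)[type_labels == ty])
    cand <- which(codes == code & !is.na(npp))
    if (length(cand) < n_per_type[[ty]])
      stop("not enough unmasked cells of type '", ty, "'")
    cells <- sample(cand, n_per_type[[ty]])
    row <- (cells - 1L) %% d2[1] + 1L
    col <- (cells - 1L) %/% d2[1] + 1L
    r <- params$root_shoot[[ty]]
    yield <- npp[cbind(row, col)] / (params$carbon_fraction * (1 + r))
    yield <- yield * exp(stats::rnorm(length(yield), 0, rel_noise_sd))
    out <- rbind(out, insitu_table(
      sprintf("%s-%03d", toupper(substr(gsub(" ", "", ty), 1, 2)),
              seq_along(cells)),
      cell_lon(type_map)[col], cell_lat(type_map)[row],
      as.Date("2011-08-15"), ty, yield))
  }
  rownames(out) <- NULL
  out
}
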