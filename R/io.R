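#' Read and write raster stacks as ESRI ASCII grids
#'
#' Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`), one file
#' per layer: a monthly stack `npp` becomes `npp_m01.asc` ... `npp_m12.asc`
#' plus a JSON sidecar `npp.json` recording units, CRS and layer order.
#' `NODATA_value` cells become `NA` and round-trip exactly; values are
#' written with full double precision. The format requires square cells, so
#' extents and shapes with unequal x/y resolution are rejected at write time.
#'
#' @param stack a `grid_stack`.
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @param nodata sentinel written for `NA` cells.
#' @return `write_raster_stack`: the sidecar path, invisibly.
#' @export
write_raster_stack <- function(stack, dir, name, nodata = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- cell_size(stack)
  if (abs(res[1] - res[2]) > 1e-9 * max(res))
    stop("ASCII grid output requires square cells; got ",
         res[1], " x ", res[2], " degrees")
  d <- dim(stack$values)
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    f <- file.path(dir, if (d[3] == 1) paste0(name, ".asc")
                   else sprintf("%s_m%02d.asc", name, k))
    files[k] <- basename(f)
    v <- stack$values[, , k]
    v[is.na(v)] <- nodata
    hdr <- c(paste("ncols", d[2]), paste("nrows", d[1]),
             paste("xllcorner", format(stack$extent[1], digits = 17)),
             paste("yllcorner", format(stack$extent[3], digits = 17)),
             paste("cellsize", format(res[1], digits = 17)),
             paste("NODATA_value", nodata))
    body <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
    writeLines(c(hdr, body), f)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(name = name, files = files, crs = stack$crs,
                            units = stack$units, n_layers = d[3]),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_raster_stack
#' @param expect_layers if not `NULL`, error unless the stack has exactly
#'   this many layers (e.g. 12 for a monthly stack).
#' @return `read_raster_stack`: the reconstructed `grid_stack`.
#' @export
read_raster_stack <- function(dir, name, expect_layers = NULL) {
  sidecar <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sidecar)) stop("no raster sidecar found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$crs) || !nzchar(meta$crs))
    stop("raster '", name, "' has no CRS in its sidecar")
  if (!is.null(expect_layers) && meta$n_layers != expect_layers)
    stop("raster '", name, "' has ", meta$n_layers, " layer(s); expected ",
         expect_layers, " (", sidecar, ")")
  layers <- lapply(file.path(dir, meta$files), read_ascii_grid)
  v <- array(NA_real_, c(dim(layers[[1]]$values), length(layers)))
  for (k in seq_along(layers)) v[, , k] <- layers[[k]]$values
  grid_stack(v, layers[[1]]$extent, meta$crs, meta$units)
}

# minimal ESRI ASCII grid reader (plain text; no raster package available)
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  v <- matrix(scan(text = lines[i:length(lines)], quiet = TRUE),
              hdr$nrows, hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  list(values = v,
       extent = c(hdr$xllcorner, hdr$xllcorner + hdr$ncols * hdr$cellsize,
                  hdr$yllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize))
}

#' Read/write the station and in-situ CSV formats
#'
#' Stations: `station_id, lon, lat, elevation_m, t01..t12`. In-situ points:
#' `point_id, lon, lat, date, grassland_type, dry_yield_g_m2`.
#'
#' @param path CSV path.
#' @return data.frame in the corresponding exchange format.
#' @export
read_stations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "elevation_m", sprintf("t%02d", 1:12))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("station CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_stations_csv
#' @param stations a [station_table()] data.frame.
#' @export
write_stations_csv <- function(stations, path) {
  utils::write.csv(stations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_stations_csv
#' @export
read_insitu_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "lon", "lat", "date", "grassland_type",
            "dry_yield_g_m2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("in-situ CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_stations_csv
#' @param points an [insitu_table()] data.frame.
#' @export
write_insitu_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML key-value file. Recognised keys: input paths (`scene_dir`,
#' `stations`, `insitu`, `dem`, plus raster basenames), `params` (a mapping
#' of [casa_params()] overrides), `breaks` (elevation band breaks, m),
#' `period` ("annual" or a month), `out_dir`. Unknown keys are rejected with
#' the list of valid ones; missing keys fall back to defaults (published
#' ratios, 0.45 carbon fraction, 0.604 g/MJ, breaks 1000..5000 m).
#'
#' @param path YAML file path; `NULL` or a missing file gives all defaults.
#' @return list of class `run_config` with element `params` a `casa_params`.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(scene_dir = ".", stations = NULL, insitu = NULL,
                   dem = "dem", params = list(),
                   breaks = c(1000, 2000, 3000, 4000, 5000),
                   period = "annual", out_dir = "out")
  cfg <- if (!is.null(path) && file.exists(path)) yaml::read_yaml(path) else list()
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(defaults), collapse = ", "))
  defaults[names(cfg)] <- cfg
  defaults$params <- do.call(casa_params, as.list(defaults$params))
  if (!identical(defaults$period, "annual"))
    defaults$period <- as.integer(defaults$period)
  class(defaults) <- "run_config"
  defaults
}

#' Write a full synthetic scene to disk
#'
#' Writes every input raster, the DEM, type/region maps with JSON legends,
#' station and in-situ CSVs, truth NPP, and a manifest recording seed and
#' configuration — the on-disk form consumed by the CLI stages.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scene$inputs))
    write_raster_stack(scene$inputs[[nm]], dir, nm)
  write_raster_stack(scene$dem, dir, "dem")
  write_raster_stack(scene$type_map, dir, "type_map")
  write_raster_stack(scene$region_map, dir, "region_map")
  tr <- scene$truth
  write_raster_stack(grid_like(scene$dem, tr$npp_annual, "gC/m2"),
                     dir, "truth_npp_annual")
  jsonlite::write_json(as.list(scene$type_labels),
                       file.path(dir, "type_legend.json"), auto_unbox = TRUE)
  jsonlite::write_json(as.list(scene$region_labels),
                       file.path(dir, "region_legend.json"), auto_unbox = TRUE)
  st <- generate_stations(scene$inputs$temperature, scene$dem,
                          n = scene$config$n_stations,
                          noise_sd = scene$config$station_noise_sd,
                          seed = scene$config$seed + 1L)
  write_stations_csv(st, file.path(dir, "stations.csv"))
  pts <- generate_insitu_points(
    grid_like(scene$dem, tr$npp_annual), scene$type_map, scene$type_labels,
    n_per_type = scene$config$n_per_type,
    rel_noise_sd = scene$config$yield_noise_sd,
    seed = scene$config$seed + 2L)
  write_insitu_csv(pts, file.path(dir, "insitu.csv"))
  manifest <- scene$config
  class(manifest) <- NULL
  manifest$n_per_type <- as.list(manifest$n_per_type)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene directory back into an input bundle
#'
#' @param dir a directory written by [write_scene()].
#' @return list with `inputs`, `dem`, `type_map`, `type_labels`,
#'   `region_map`, `region_labels`, `stations`, `insitu`, `manifest`.
#' @export
read_scene <- function(dir) {
  inputs <- lapply(stats::setNames(nm = c("sol", "fpar", "temperature", "lst",
                                          "precipitable_water")),
                   function(nm) read_raster_stack(dir, nm, expect_layers = 12))
  list(inputs = inputs,
       dem = read_raster_stack(dir, "dem"),
       type_map = read_raster_stack(dir, "type_map"),
       type_labels = unlist(jsonlite::read_json(
         file.path(dir, "type_legend.json"), simplifyVector = TRUE)),
       region_map = read_raster_stack(dir, "region_map"),
       region_labels = unlist(jsonlite::read_json(
         file.path(dir, "region_legend.json"), simplifyVector = TRUE)),
       stations = read_stations_csv(file.path(dir, "stations.csv")),
       insitu = read_insitu_csv(file.path(dir, "insitu.csv")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}
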