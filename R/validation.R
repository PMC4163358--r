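#' In-situ point table constructor
#'
#' @param point_id character ids.
#' @param lon,lat degrees.
#' @param date sampling date (`Date` or coercible).
#' @param grassland_type categorical type label; must appear in the
#'   root:shoot table to be usable.
#' @param dry_yield measured aboveground dry yield, g/m2, >= 0.
#' @return data.frame in the in-situ exchange format (point_id, lon, lat,
#'   date, grassland_type, dry_yield_g_m2).
#' @export
insitu_table <- function(point_id, lon, lat, date, grassland_type, dry_yield) {
  stopifnot(all(dry_yield >= 0))
  data.frame(point_id = as.character(point_id), lon = lon, lat = lat,
             date = as.Date(date), grassland_type = as.character(grassland_type),
             dry_yield_g_m2 = dry_yield, stringsAsFactors = FALSE)
}

#' Convert dry yield to total NPP carbon
#'
#' Measured dry yield is aboveground only, while modelled NPP includes roots.
#' Aboveground carbon = dry_yield * carbon_fraction (0.45 gC per g dry
#' matter); the root:shoot ratio R (belowground/aboveground) allocates the
#' unmeasured root production, so total = aboveground * (1 + R).
#'
#' @param dry_yield g/m2, >= 0 (vectorised).
#' @param grassland_type type label(s) present in `params$root_shoot`.
#' @param params a [casa_params()] object.
#' @return total NPP carbon, gC/m2.
#' @examples
#' dry_yield_to_npp(100, "alpine meadow")  # 45 gC aboveground * 8.92
#' @export
dry_yield_to_npp <- function(dry_yield, grassland_type, params = casa_params()) {
  r <- params$root_shoot[grassland_type]
  if (any(is.na(r)))
    stop("unknown grassland type(s): ",
         paste(unique(grassland_type[is.na(r)]), collapse = ", "),
         "; known: ", paste(names(params$root_shoot), collapse = ", "))
  unname(dry_yield * params$carbon_fraction * (1 + r))
}

#' Extract modelled NPP at point locations
#'
#' Reads, for each point, the value of the cell whose center is nearest the
#' point (NPP is a cell aggregate, so no bilinear smoothing). The temporal
#' layer is the annual total by default, or a single month. Points outside
#' the raster extent or on masked cells are excluded and reported.
#'
#' @param npp monthly NPP `grid_stack` (or any stack).
#' @param points an [insitu_table()] data.frame.
#' @param period `"annual"` (sum of the 12 monthly layers) or a month 1..12.
#' @return `points` with an added `modeled` column and attribute `excluded`
#'   (data.frame of dropped points with a reason).
#' @export
extract_modeled_at_points <- function(npp, points, period = "annual") {
  layer <- if (identical(period, "annual")) {
    if (n_layers(npp) > 1) annual_total(npp) else npp
  } else {
    stopifnot(period %in% seq_len(n_layers(npp)))
    grid_layer(npp, as.integer(period))
  }
  v <- layer$values[, , 1]
  ex <- npp$extent; res <- cell_size(npp)
  col <- floor((points$lon - ex[1]) / res[1]) + 1L
  row <- floor((ex[4] - points$lat) / res[2]) + 1L
  d2 <- grid_dim(npp)
  inside <- points$lon >= ex[1] & points$lon <= ex[2] &
    points$lat >= ex[3] & points$lat <= ex[4]
  col <- pmin(pmax(col, 1L), d2[2])  # points exactly on the max edge
  row <- pmin(pmax(row, 1L), d2[1])
  modeled <- rep(NA_real_, nrow(points))
  modeled[inside] <- v[cbind(row[inside], col[inside])]
  reason <- ifelse(!inside, "outside extent",
                   ifelse(is.na(modeled), "masked cell", NA_character_))
  keep <- is.na(reason)
  if (any(!keep))
    message("extract_modeled_at_points: excluded ", sum(!keep), " point(s): ",
            paste(points$point_id[!keep], reason[!keep], collapse = "; "))
  out <- points[keep, , drop = FALSE]
  out$modeled <- modeled[keep]
  attr(out, "excluded") <- data.frame(point_id = points$point_id[!keep],
                                      reason = reason[!keep])
  out
}

#' Relative validation error and precision
#'
#' Error = mean(|X1 - X2| / X2) * 100% over the N validation points, with X1
#' the modelled and X2 the observation-derived NPP; Precision = 100% - Error.
#' Points with X2 = 0 cannot enter the relative error and are excluded with a
#' warning.
#'
#' @param modeled numeric X1.
#' @param observed numeric X2, same length.
#' @return named numeric `c(error_pct, precision_pct)`.
#' @export
validation_error <- function(modeled, observed) {
  stopifnot(length(modeled) == length(observed), length(modeled) >= 1)
  zero <- observed == 0
  if (any(zero)) {
    warning("validation_error: excluded ", sum(zero), " point(s) with X2 = 0")
    modeled <- modeled[!zero]; observed <- observed[!zero]
  }
  if (!length(modeled)) stop("no usable validation points (all X2 = 0)")
  err <- mean(abs(modeled - observed) / observed) * 100
  c(error_pct = err, precision_pct = 100 - err)
}

#' Validation report by grassland type
#'
#' Converts in-situ dry yields to total NPP carbon, pairs each point with the
#' modelled NPP of its cell, groups by grassland type and computes the
#' relative error and precision per group plus a pooled "Total" row. Points
#' with a type absent from the root:shoot table are dropped with a warning.
#'
#' @param points an [insitu_table()] data.frame.
#' @param npp monthly NPP `grid_stack`, gC/m2.
#' @param params a [casa_params()] object.
#' @param period `"annual"` or a month 1..12, passed to
#'   [extract_modeled_at_points()].
#' @return data.frame with columns grassland_type, n_points, error_pct,
#'   precision_pct; the last row is "Total".
#' @export
validate_by_type <- function(points, npp, params = casa_params(),
                             period = "annual") {
  known <- points$grassland_type %in% names(params$root_shoot)
  if (any(!known)) {
    warning("validate_by_type: dropped ", sum(!known),
            " point(s) with unknown grassland type: ",
            paste(unique(points$grassland_type[!known]), collapse = ", "))
    points <- points[known, , drop = FALSE]
  }
  if (!nrow(points)) stop("no usable validation points")
  paired <- extract_modeled_at_points(npp, points, period)
  paired$observed <- dry_yield_to_npp(paired$dry_yield_g_m2,
                                      paired$grassland_type, params)
  rows <- lapply(split(paired, paired$grassland_type), function(g) {
    e <- validation_error(g$modeled, g$observed)
    data.frame(grassland_type = g$grassland_type[1], n_points = nrow(g),
               error_pct = e[["error_pct"]], precision_pct = e[["precision_pct"]])
  })
  e <- validation_error(paired$modeled, paired$observed)
  total <- data.frame(grassland_type = "Total", n_points = nrow(paired),
                      error_pct = e[["error_pct"]],
                      precision_pct = e[["precision_pct"]])
  out <- rbind(do.call(rbind, rows), total)
  rownames(out) <- NULL
  out
}
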