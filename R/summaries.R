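#' Spherical cell-area grid
#'
#' Per-cell area on the sphere for a regular lon/lat grid:
#' A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom)) with Earth radius
#' R = 6371.0088 km, so area shrinks with the cosine of latitude. Only
#' geographic CRSs are supported.
#'
#' @param grid any `grid_stack` supplying shape and extent.
#' @return single-layer `grid_stack` of cell areas, km2.
#' @export
cell_area_grid <- function(grid) {
  if (!grepl("4326|WGS ?84|longlat|geographic", grid$crs, ignore.case = TRUE))
    stop("cell_area_grid requires a geographic CRS, got: ", grid$crs)
  R <- 6371.0088
  d2 <- grid_dim(grid); res <- cell_size(grid)
  lat_top <- grid$extent[4] - (seq_len(d2[1]) - 1) * res[2]
  lat_bot <- lat_top - res[2]
  deg <- pi / 180
  row_area <- R^2 * (res[1] * deg) * (sin(lat_top * deg) - sin(lat_bot * deg))
  grid_like(grid, matrix(row_area, d2[1], d2[2]), units = "km2")
}

#' Partition (zonal) statistics
#'
#' Per class of a categorical raster: area (km2), area share, mean, maximum
#' and total of the value raster, plus each class's share of the global
#' total. Totals are Sum(value * cell area) scaled by `total_scale`; the
#' default 1e-6 converts gC/m2 * km2 into TgC (1 gC/m2 over 1 km2 is 1e6 gC
#' = 1e-6 TgC). Means are area-weighted by default because cell areas vary
#' with latitude; `weighted = FALSE` gives simple cell means. Cells masked in
#' either the values or the classes are excluded; empty classes are omitted
#' with a warning.
#'
#' @param values single-layer `grid_stack`.
#' @param classes single-layer `grid_stack` of class codes, or a
#'   character/factor matrix of labels.
#' @param areas single-layer `grid_stack` from [cell_area_grid()] (computed
#'   from `values` if omitted).
#' @param labels optional named vector mapping class codes to labels.
#' @param total_scale multiplier applied to Sum(value * area_km2).
#' @param weighted area-weighted means (default) or simple cell means.
#' @return data.frame with columns class_label, area_km2, area_pct,
#'   mean_value, max_value, total, total_pct.
#' @export
partition_stats <- function(values, classes, areas = cell_area_grid(values),
                            labels = NULL, total_scale = 1e-6,
                            weighted = TRUE) {
  if (inherits(classes, "grid_stack")) {
    check_aligned(values, classes, layers = FALSE)
    cls <- classes$values[, , 1]
  } else cls <- classes
  check_aligned(values, areas, layers = FALSE)
  v <- values$values[, , 1]; a <- areas$values[, , 1]
  ok <- !is.na(v) & !is.na(cls)
  if (!any(ok)) stop("no unmasked cells to summarise")
  v <- v[ok]; a <- a[ok]; cl <- cls[ok]
  if (!is.null(labels)) cl <- labels[as.character(cl)]
  lev <- sort(unique(cl))
  rows <- lapply(lev, function(L) {
    i <- cl == L
    data.frame(class_label = as.character(L),
               area_km2 = sum(a[i]),
               mean_value = if (weighted) sum(v[i] * a[i]) / sum(a[i]) else mean(v[i]),
               max_value = max(v[i]),
               total = sum(v[i] * a[i]) * total_scale)
  })
  out <- do.call(rbind, rows)
  out$area_pct <- 100 * out$area_km2 / sum(out$area_km2)
  gt <- sum(out$total)
  out$total_pct <- if (gt != 0) 100 * out$total / gt else NA_real_
  out[, c("class_label", "area_km2", "area_pct", "mean_value", "max_value",
          "total", "total_pct")]
}

#' Elevation-band partition statistics
#'
#' Classifies the DEM into half-open bands [lo, hi) — a cell at exactly a
#' break falls in the upper band — and delegates to [partition_stats()].
#' Default breaks 1000/2000/3000/4000/5000 m give the conventional bands
#' "<1000", "1000-2000", ..., ">5000".
#'
#' @param values single-layer `grid_stack`.
#' @param dem single-layer elevation `grid_stack`, m.
#' @param breaks strictly increasing break elevations, m.
#' @param ... passed to [partition_stats()].
#' @return data.frame as in [partition_stats()], rows ordered by elevation.
#' @export
elevation_band_stats <- function(values, dem,
                                 breaks = c(1000, 2000, 3000, 4000, 5000),
                                 ...) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  lab <- c(paste0("<", breaks[1]),
           if (length(breaks) > 1)
             paste0(breaks[-length(breaks)], "-", breaks[-1]),
           paste0(">", breaks[length(breaks)]))
  # findInterval with left-open=FALSE gives [lo, hi) bands
  band <- array(findInterval(dem$values, breaks, left.open = FALSE) + 1L,
                dim(dem$values))
  idx <- matrix(band[, , 1], grid_dim(dem)[1], grid_dim(dem)[2])
  cls <- matrix(lab[idx], nrow(idx), ncol(idx))
  out <- partition_stats(values, cls, ...)
  out[order(match(out$class_label, lab)), , drop = FALSE]
}

#' Monthly area-weighted series
#'
#' Per month, the total (Sum value * cell area, scaled by `total_scale`) and
#' area-weighted mean of a monthly stack over an optional mask (e.g. the
#' grassland mask for LUE/NPP, the whole scene for APAR).
#'
#' @param stack monthly `grid_stack`.
#' @param areas single-layer area `grid_stack` (computed if omitted).
#' @param mask optional logical matrix or single-layer `grid_stack`; TRUE /
#'   unmasked cells are included.
#' @param total_scale multiplier on Sum(value * area_km2); 1e-6 turns
#'   gC/m2 * km2 into TgC.
#' @return data.frame with columns month, total, mean.
#' @export
monthly_series <- function(stack, areas = cell_area_grid(stack), mask = NULL,
                           total_scale = 1e-6) {
  check_aligned(stack, areas, layers = FALSE)
  a <- areas$values[, , 1]
  keep <- if (is.null(mask)) {
    matrix(TRUE, nrow(a), ncol(a))
  } else if (inherits(mask, "grid_stack")) {
    !is.na(mask$values[, , 1])
  } else mask
  if (!any(keep)) stop("empty mask")
  nm <- n_layers(stack)
  tot <- numeric(nm); mn <- numeric(nm)
  for (m in seq_len(nm)) {
    v <- stack$values[, , m]
    ok <- keep & !is.na(v)
    tot[m] <- sum(v[ok] * a[ok]) * total_scale
    mn[m] <- sum(v[ok] * a[ok]) / sum(a[ok])
  }
  data.frame(month = seq_len(nm), total = tot, mean = mn)
}

#' Histogram statistics
#'
#' Counts of unmasked cells per [lo, hi) bin (the last bin is closed on both
#' sides), with min/max/mean summaries appended. Values outside the edges are
#' not counted but are included in the summaries.
#'
#' @param grid single-layer `grid_stack`.
#' @param bin_edges strictly increasing numeric edges.
#' @param mask optional logical matrix or single-layer `grid_stack`.
#' @return list with `counts` (data.frame bin_lo, bin_hi, count) and
#'   `summary` (named numeric min, max, mean, n).
#' @export
histogram_stats <- function(grid, bin_edges, mask = NULL) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  v <- grid$values[, , 1]
  if (!is.null(mask)) {
    keep <- if (inherits(mask, "grid_stack")) !is.na(mask$values[, , 1]) else mask
    v[!keep] <- NA_real_
  }
  v <- v[!is.na(v)]
  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    hi_ok <- if (b == nb) v <= bin_edges[b + 1] else v < bin_edges[b + 1]
    counts[b] <- sum(v >= bin_edges[b] & hi_ok)
  }
  list(counts = data.frame(bin_lo = bin_edges[-length(bin_edges)],
                           bin_hi = bin_edges[-1], count = counts),
       summary = c(min = min(v), max = max(v), mean = mean(v),
                   n = length(v)))
}
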