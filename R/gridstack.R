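#' Georeferenced raster stack
#'
#' A `grid_stack` is the package's in-memory raster container: a row x col x
#' layer numeric array on a regular lon/lat grid, with an extent, a geographic
#' CRS tag and a free-text unit string. Layer `k` of a monthly stack is month
#' `k`. Nodata cells are `NA`; there is no separate mask object. Row 1 is the
#' northernmost row (north-up), column 1 the westernmost column.
#'
#' @param values numeric matrix (single layer) or 3-D array (rows, cols,
#'   layers).
#' @param extent numeric length-4, `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param crs character CRS tag; only geographic CRSs are supported.
#' @param units free-text unit string carried through for provenance.
#' @return object of class `grid_stack`.
#' @examples
#' g <- grid_stack(array(runif(4 * 4 * 12), c(4, 4, 12)),
#'                 extent = c(100, 104, 30, 34), units = "dimensionless")
#' n_layers(g)
#' @export
grid_stack <- function(values, extent, crs = "EPSG:4326", units = "") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("extent must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  storage.mode(values) <- "double"
  structure(
    list(values = values, extent = extent, crs = crs, units = units),
    class = "grid_stack"
  )
}

#' @export
print.grid_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("grid_stack: %d rows x %d cols x %d layer(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  extent: %g..%g lon, %g..%g lat (%s)\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4], x$crs))
  cat(sprintf("  units: %s | NA cells: %d/%d\n",
              if (nzchar(x$units)) x$units else "<unset>",
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

#' @rdname grid_stack
#' @param x a `grid_stack`.
#' @export
n_layers <- function(x) dim(x$values)[3]

#' @rdname grid_stack
#' @export
grid_dim <- function(x) dim(x$values)[1:2]

#' Cell size in degrees, `c(xres, yres)`
#' @param x a `grid_stack`.
#' @export
cell_size <- function(x) {
  d <- dim(x$values)
  c((x$extent[2] - x$extent[1]) / d[2], (x$extent[4] - x$extent[3]) / d[1])
}

#' Longitude of column centers / latitude of row centers
#' @param x a `grid_stack`.
#' @export
cell_lon <- function(x) {
  res <- cell_size(x)[1]
  x$extent[1] + (seq_len(dim(x$values)[2]) - 0.5) * res
}

#' @rdname cell_lon
#' @export
cell_lat <- function(x) {
  res <- cell_size(x)[2]
  x$extent[4] - (seq_len(dim(x$values)[1]) - 0.5) * res
}

#' Extract one layer as a single-layer grid_stack
#' @param x a `grid_stack`.
#' @param k layer index.
#' @export
grid_layer <- function(x, k) {
  stopifnot(k >= 1, k <= n_layers(x))
  grid_stack(x$values[, , k, drop = FALSE], x$extent, x$crs, x$units)
}

#' Replace the value array, keeping georeferencing
#' @param x a `grid_stack` template.
#' @param values replacement matrix or array with matching row/col shape.
#' @param units unit string for the result.
#' @export
grid_like <- function(x, values, units = x$units) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(all(dim(values)[1:2] == dim(x$values)[1:2]))
  grid_stack(values, x$extent, x$crs, units)
}

#' Check that two grids share shape, extent and CRS
#'
#' @param a,b `grid_stack` objects.
#' @param layers if TRUE, layer counts must match too.
#' @param tol tolerance on extent coordinates (degrees).
#' @return TRUE invisibly; stops with an alignment error otherwise.
#' @export
check_aligned <- function(a, b, layers = TRUE, tol = 1e-9) {
  da <- dim(a$values); db <- dim(b$values)
  if (!all(da[1:2] == db[1:2]))
    stop("alignment error: grids differ in shape (",
         paste(da[1:2], collapse = "x"), " vs ", paste(db[1:2], collapse = "x"), ")")
  if (layers && da[3] != db[3])
    stop("alignment error: grids differ in layer count (", da[3], " vs ", db[3], ")")
  if (max(abs(a$extent - b$extent)) > tol)
    stop("alignment error: grids differ in extent")
  if (!identical(a$crs, b$crs))
    stop("alignment error: grids differ in CRS (", a$crs, " vs ", b$crs, ")")
  invisible(TRUE)
}

#' Validate domain invariants of a stack
#'
#' `kind = "fpar"` enforces values in \[0, 1\]; `"kelvin"` enforces strictly
#' positive values (land-surface or dew-point temperature stacks in K).
#'
#' @param x a `grid_stack`.
#' @param kind one of "any", "fpar", "kelvin".
#' @export
validate_stack <- function(x, kind = c("any", "fpar", "kelvin")) {
  kind <- match.arg(kind)
  v <- x$values[!is.na(x$values)]
  if (kind == "fpar" && length(v) && (min(v) < 0 || max(v) > 1))
    stop("FPAR stack has values outside [0, 1]")
  if (kind == "kelvin" && length(v) && min(v) <= 0)
    stop("temperature-in-Kelvin stack has non-positive values")
  invisible(TRUE)
}
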