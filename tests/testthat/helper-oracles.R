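# Independent scalar-loop oracles for the grid operations. These are written
# directly from the model equations with explicit per-cell loops and share no
# code with the package internals, so agreement is a genuine cross-check.

o_elementwise <- function(a, b, f) {
  out <- array(NA_real_, dim(a))
  for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2]))
    for (m in seq_len(dim(a)[3])) {
      x <- a[i, j, m]; y <- b[i, j, m]
      if (!is.na(x) && !is.na(y)) out[i, j, m] <- f(x, y)
    }
  out
}

o_topt <- function(temp, fpar) {
  d <- dim(fpar)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    best <- NA; bf <- -Inf
    for (m in seq_len(d[3])) {
      f <- fpar[i, j, m]
      if (!is.na(f) && f > bf) { bf <- f; best <- m }
    }
    if (!is.na(best)) out[i, j] <- temp[i, j, best]
  }
  out
}

o_te1 <- function(topt) 0.8 + 0.02 * topt - 0.0005 * topt^2

o_te2 <- function(topt, temp) {
  d <- dim(temp)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (m in seq_len(d[3])) {
    to <- topt[i, j]; tt <- temp[i, j, m]
    if (!is.na(to) && !is.na(tt))
      out[i, j, m] <- 1.1814 / (1 + exp(0.2 * (to - 10 - tt))) /
        (1 + exp(0.3 * (-to - 10 + tt)))
  }
  out
}

o_vpd <- function(ts, td) {
  o_elementwise(ts, td, function(s, d) {
    if (s - d < 0) return(0)
    0.611 * (exp(17.27 * (s - 273) / (s - 36)) -
               exp(17.27 * (d - 273) / (d - 36)))
  })
}

o_we <- function(d) {
  out <- array(NA_real_, dim(d))
  for (k in seq_along(d))
    if (!is.na(d[k])) out[k] <- max(1.2 * exp(-0.35 * d[k]) - 0.2, 0)
  out
}

o_partition <- function(v, cls, a) {
  labs <- sort(unique(cls[!is.na(v) & !is.na(cls)]))
  rows <- NULL
  for (L in labs) {
    area <- 0; tot <- 0; wsum <- 0; mx <- -Inf
    for (k in seq_along(v)) {
      if (is.na(v[k]) || is.na(cls[k]) || cls[k] != L) next
      area <- area + a[k]
      tot <- tot + v[k] * a[k]
      wsum <- wsum + v[k] * a[k]
      if (v[k] > mx) mx <- v[k]
    }
    rows <- rbind(rows, data.frame(class_label = as.character(L),
                                   area_km2 = area, mean_value = wsum / area,
                                   max_value = mx, total = tot * 1e-6))
  }
  rows$area_pct <- 100 * rows$area_km2 / sum(rows$area_km2)
  rows$total_pct <- 100 * rows$total / sum(rows$total)
  rows[, c("class_label", "area_km2", "area_pct", "mean_value", "max_value",
           "total", "total_pct")]
}

o_hist <- function(v, edges) {
  v <- v[!is.na(v)]
  counts <- integer(length(edges) - 1)
  for (x in v) for (b in seq_len(length(edges) - 1)) {
    hi <- if (b == length(edges) - 1) x <= edges[b + 1] else x < edges[b + 1]
    if (x >= edges[b] && hi) counts[b] <- counts[b] + 1L
  }
  counts
}

o_nearest_cell <- function(grid_vals, extent, lon, lat) {
  nr <- nrow(grid_vals); nc <- ncol(grid_vals)
  xres <- (extent[2] - extent[1]) / nc
  yres <- (extent[4] - extent[3]) / nr
  out <- numeric(length(lon))
  for (k in seq_along(lon)) {
    best <- NA_real_; bd <- Inf
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      cx <- extent[1] + (j - 0.5) * xres
      cy <- extent[4] - (i - 0.5) * yres
      dd <- (cx - lon[k])^2 + (cy - lat[k])^2
      if (dd < bd) { bd <- dd; best <- grid_vals[i, j] }
    }
    out[k] <- best
  }
  out
}

# small random monthly stack with optional NA holes
rand_stack <- function(nr = 6, nc = 5, nm = 12, lo = 0, hi = 1, na_frac = 0,
                       extent = c(100, 104, 30, 34)) {
  v <- array(runif(nr * nc * nm, lo, hi), c(nr, nc, nm))
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  grid_stack(v, extent)
}
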