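test_that("spherical cell areas behave like the cosine of latitude", {
  g <- grid_stack(array(1, c(18, 36, 1)), c(-180, 180, -45, 45))
  a <- cell_area_grid(g)$values[, , 1]
  lat <- cell_lat(grid_stack(array(1, c(18, 36, 1)), c(-180, 180, -45, 45)))
  # monotone decrease with |latitude|, equator-mirrored rows equal
  north <- a[1:9, 1]
  expect_true(all(diff(north) > 0))           # towards equator: growing
  expect_equal(a[1:9, 1], a[18:10, 1])        # symmetry about the equator
  # summing a 10x10 degree window against the closed-form spherical zone
  g2 <- grid_stack(array(1, c(40, 40, 1)), c(20, 30, 10, 20))
  tot <- sum(cell_area_grid(g2)$values)
  R <- 6371.0088; deg <- pi / 180
  closed <- R^2 * (10 * deg) * (sin(20 * deg) - sin(10 * deg))
  expect_equal(tot, closed, tolerance = 1e-9)
  bad <- g2; bad$crs <- "EPSG:32648"
  expect_error(cell_area_grid(bad), "geographic CRS")
})

test_that("unit conversion audit: gC/m2 x km2 x 1e-6 = TgC on one cell", {
  g <- grid_stack(matrix(200), c(0, 0.01, 0, 0.01))  # 200 gC/m2
  a <- cell_area_grid(g)
  st <- partition_stats(g, grid_like(g, matrix(1)), a)
  # total carbon = 200 g/m2 * area_m2 = 200 * area_km2 * 1e6 g = ... TgC
  expect_equal(st$total, 200 * a$values[1, 1, 1] * 1e6 / 1e12)
})

test_that("partition statistics match a per-cell accumulation oracle", {
  set.seed(31)
  for (rep in 1:3) {
    g <- rand_stack(4, 4, 1, lo = 0, hi = 500, na_frac = 0.1)
    cls <- grid_like(g, matrix(sample(1:3, 16, replace = TRUE), 4, 4))
    a <- cell_area_grid(g)
    got <- partition_stats(g, cls, a)
    want <- o_partition(g$values[, , 1], cls$values[, , 1], a$values[, , 1])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("partition invariants: shares sum to 100 and totals are conserved", {
  set.seed(32)
  g <- rand_stack(10, 10, 1, lo = 50, hi = 400)
  fine <- grid_like(g, matrix(sample(1:6, 100, replace = TRUE), 10, 10))
  coarse <- grid_like(g, matrix((fine$values[, , 1] + 1) %/% 2, 10, 10))
  a <- cell_area_grid(g)
  pf <- partition_stats(g, fine, a)
  pc <- partition_stats(g, coarse, a)
  expect_equal(sum(pf$area_pct), 100, tolerance = 0.01)
  expect_equal(sum(pf$total_pct), 100, tolerance = 0.01)
  global <- sum(g$values[, , 1] * a$values[, , 1]) * 1e-6
  expect_equal(sum(pf$total), global, tolerance = 1e-9 * abs(global))
  # nested partitions aggregate consistently: fine rows sum to coarse rows
  for (cc in pc$class_label) {
    members <- as.character(which((seq_len(6) + 1) %/% 2 == as.numeric(cc)))
    expect_equal(sum(pf$total[pf$class_label %in% members]),
                 pc$total[pc$class_label == cc], tolerance = 1e-12)
    expect_equal(sum(pf$area_km2[pf$class_label %in% members]),
                 pc$area_km2[pc$class_label == cc], tolerance = 1e-12)
  }
  # uniform value, single class
  u <- grid_like(g, matrix(7, 10, 10))
  one <- partition_stats(u, grid_like(g, matrix(1, 10, 10)), a)
  expect_equal(one$mean_value, 7)
  expect_equal(one$total, 7 * sum(a$values) * 1e-6)
  # two equal-area classes split the area share evenly
  half <- grid_like(g, matrix(rep(1:2, each = 50), 10, 10))
  ph <- partition_stats(g, half, a)
  expect_equal(ph$area_pct, c(50, 50))
})

test_that("elevation bands are half-open with the conventional breaks", {
  g <- rand_stack(6, 6, 1, lo = 10, hi = 20)
  a <- cell_area_grid(g)
  dem <- grid_like(g, matrix(3500, 6, 6))
  st <- elevation_band_stats(g, dem, areas = a)
  expect_equal(st$class_label, "3000-4000")
  expect_equal(st$area_pct, 100)
  # a cell at exactly 4000 m belongs to the 4000-5000 band
  dem2 <- grid_like(g, matrix(c(4000, rep(800, 35)), 6, 6))
  st2 <- elevation_band_stats(g, dem2, areas = a)
  expect_setequal(st2$class_label, c("<1000", "4000-5000"))
  expect_equal(sum(st2$area_pct), 100, tolerance = 0.01)
  expect_error(elevation_band_stats(g, dem, breaks = c(2000, 1000)),
               "strictly increasing")
})

test_that("monthly series conserve totals and find the greenness peak", {
  scene <- generate_scene(scene_config(grid_shape = c(16, 16), seed = 41,
                                       fpar_peak_month = 8))
  out <- run_casa(scene$inputs)
  a <- cell_area_grid(out$npp)
  ser <- monthly_series(out$npp, a)
  expect_equal(nrow(ser), 12)
  expect_equal(sum(ser$total),
               monthly_series(out$npp_annual, a)$total, tolerance = 1e-9)
  expect_equal(which.max(ser$total), 8)
  # constant stack: twelve equal totals
  const <- grid_like(out$npp, array(3, dim(out$npp$values)))
  expect_equal(unique(round(monthly_series(const, a)$total, 12)),
               round(3 * sum(a$values) * 1e-6, 12))
  expect_error(monthly_series(out$npp, a, mask = matrix(FALSE, 16, 16)),
               "empty mask")
})

test_that("histogram counts match naive counting and sum to the cell count", {
  set.seed(51)
  g <- rand_stack(7, 7, 1, lo = 0, hi = 100, na_frac = 0.15)
  edges <- c(0, 20, 40, 60, 80, 100)
  h <- histogram_stats(g, edges)
  expect_equal(h$counts$count, o_hist(g$values[, , 1], edges))
  expect_equal(sum(h$counts$count), sum(!is.na(g$values)))
  expect_equal(h$summary[["n"]], sum(!is.na(g$values)))
  expect_equal(h$summary[["mean"]], mean(g$values, na.rm = TRUE))
  # all values in one bin
  u <- grid_like(g, matrix(50, 7, 7))
  hu <- histogram_stats(u, edges)
  expect_equal(hu$counts$count, c(0, 0, 49, 0, 0))
})
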