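const_stack <- function(val, nm = 12, nr = 2, nc = 2)
  grid_stack(array(val, c(nr, nc, nm)), c(100, 104, 30, 34))

test_that("APAR is SOL x FPAR x 0.5 with nodata propagation", {
  expect_equal(compute_apar(const_stack(1000), const_stack(0.5))$values[1, 1, 1], 250)
  expect_equal(compute_apar(const_stack(1200), const_stack(1.0))$values[1, 1, 1], 600)
  expect_true(all(compute_apar(const_stack(800), const_stack(0))$values == 0))
  sol <- const_stack(1000); sol$values[1, 1, 3] <- NA
  fpar <- const_stack(0.5); fpar$values[2, 2, 7] <- NA
  a <- compute_apar(sol, fpar)
  expect_true(is.na(a$values[1, 1, 3]) && is.na(a$values[2, 2, 7]))
  expect_error(compute_apar(const_stack(1), rand_stack(3, 3, 12)), "alignment")
})

test_that("optimal temperature is the air temperature of the greenest month", {
  fpar <- const_stack(0.2)
  fpar$values[1, 1, 8] <- 0.9
  temp <- grid_stack(array(rep(1:12, each = 4), c(2, 2, 12)), c(100, 104, 30, 34))
  temp$values[1, 1, 8] <- 12.3
  topt <- compute_topt(temp, fpar)
  expect_equal(topt$values[1, 1, 1], 12.3)
  expect_equal(topt$values[2, 2, 1], 1)  # constant FPAR: earliest-month tie
  fpar$values[2, 1, ] <- NA
  expect_true(is.na(compute_topt(temp, fpar)$values[2, 1, 1]))
})

test_that("optimal temperature matches a brute-force argmax scan", {
  set.seed(42)
  for (rep in 1:5) {
    fpar <- rand_stack(6, 5, 12, na_frac = 0.1)
    temp <- rand_stack(6, 5, 12, lo = -10, hi = 25)
    got <- compute_topt(temp, fpar)$values[, , 1]
    expect_equal(got, o_topt(temp$values, fpar$values))
  }
})

test_that("first temperature scalar is the published parabola, unclamped", {
  tg <- function(x) grid_stack(matrix(x, 1, 1), c(0, 1, 0, 1))
  expect_equal(temperature_stress_1(tg(20))$values[1, 1, 1], 1.0)
  expect_equal(temperature_stress_1(tg(0))$values[1, 1, 1], 0.8)
  expect_equal(temperature_stress_1(tg(40))$values[1, 1, 1], 0.8)
  # no clamp below zero, but the event is reported
  expect_warning(v <- temperature_stress_1(tg(100))$values[1, 1, 1], "Te1 < 0")
  expect_lt(v, 0)
})

test_that("second temperature scalar matches hand evaluation and saturates", {
  topt <- grid_stack(matrix(20, 1, 1), c(0, 1, 0, 1))
  tt <- function(x) grid_stack(array(x, c(1, 1, 1)), c(0, 1, 0, 1))
  expect_equal(temperature_stress_2(topt, tt(20))$values[1, 1, 1],
               1.1814 / ((1 + exp(-2)) * (1 + exp(-3))))
  expect_equal(temperature_stress_2(topt, tt(20))$values[1, 1, 1], 0.9912,
               tolerance = 1e-4)
  expect_equal(temperature_stress_2(topt, tt(30))$values[1, 1, 1], 0.5801,
               tolerance = 1e-4)
  # extreme cold saturates to ~0 without numeric faults
  frozen <- temperature_stress_2(topt, tt(-40))$values[1, 1, 1]
  expect_true(is.finite(frozen) && frozen < 1e-4)
  expect_true(is.finite(temperature_stress_2(topt, tt(-4000))$values[1, 1, 1]))
})

test_that("second temperature scalar is unimodal with its peak near Topt", {
  for (to in c(5, 12, 20)) {
    topt <- grid_stack(matrix(to, 1, 1), c(0, 1, 0, 1))
    tgrid <- seq(to - 30, to + 30, by = 0.01)
    tstack <- grid_stack(array(tgrid, c(1, 1, length(tgrid))), c(0, 1, 0, 1))
    vals <- as.numeric(temperature_stress_2(topt, tstack)$values[1, 1, ])
    expect_true(all(vals > 0) && all(vals < 1.1814))
    # the asymmetric warm/cold rates put the true peak ~1.1 degC above Topt;
    # the value at T = Topt is within 1% of the global maximum
    peak <- tgrid[which.max(vals)]
    expect_lt(abs(peak - to), 1.5)
    expect_gt(vals[which.min(abs(tgrid - to))], 0.99 * max(vals))
    d <- diff(vals)
    expect_true(all(d[tgrid[-1] <= peak] >= 0))   # rising then falling
    expect_true(all(d[tgrid[-length(tgrid)] >= peak] <= 0))
  }
})

test_that("dew point inverts the precipitable-water regression", {
  ug <- function(u) grid_stack(array(u, c(1, 1, 1)), c(0, 1, 0, 1))
  expect_equal(dew_point_from_precipitable_water(ug(exp(1.8084)))$values[1, 1, 1], 0)
  expect_equal(dew_point_from_precipitable_water(ug(12))$values[1, 1, 1],
               9.2042, tolerance = 1e-4)
  # round trip Td -> U -> Td
  td <- seq(-20, 25, by = 2.5)
  u <- exp(1.8084 + 0.0735 * td)
  back <- dew_point_from_precipitable_water(
    grid_stack(array(u, c(1, 1, length(u))), c(0, 1, 0, 1)))
  expect_equal(as.numeric(back$values[1, 1, ]), td)
  expect_warning(out <- dew_point_from_precipitable_water(ug(-1)), "U <= 0")
  expect_true(is.na(out$values[1, 1, 1]))
})

test_that("vapor pressure deficit follows the saturation formula and floor rule", {
  kg <- function(x) grid_stack(array(x, c(1, 1, 1)), c(0, 1, 0, 1))
  expect_equal(vapor_pressure_deficit(kg(290), kg(290))$values[1, 1, 1], 0)
  expect_equal(vapor_pressure_deficit(kg(285), kg(290))$values[1, 1, 1], 0)
  expect_equal(vapor_pressure_deficit(kg(293), kg(283))$values[1, 1, 1],
               1.113, tolerance = 1e-3)
  expect_warning(out <- vapor_pressure_deficit(kg(30), kg(290)), "36")
  expect_true(is.na(out$values[1, 1, 1]))
})

test_that("moisture scalar: We(0)=1, monotone non-increasing, clamped at 0", {
  dg <- function(x) grid_stack(array(x, c(1, 1, length(x))), c(0, 1, 0, 1))
  expect_equal(water_stress(dg(0))$values[1, 1, 1], 1.0)
  expect_equal(water_stress(dg(1))$values[1, 1, 1], 0.6456, tolerance = 1e-4)
  expect_warning(w20 <- water_stress(dg(20))$values[1, 1, 1], "clamped")
  expect_equal(w20, 0)
  dd <- seq(0, 25, by = 0.05)
  suppressWarnings(we <- as.numeric(water_stress(dg(dd))$values[1, 1, ]))
  expect_true(all(diff(we) <= 0))
  expect_true(all(we >= 0 & we <= 1))
  expect_error(water_stress(dg(-0.5)), "negative")
})

test_that("LUE is the stress product times eps_max; NPP is APAR x LUE", {
  one <- grid_stack(matrix(1, 1, 1), c(0, 1, 0, 1))
  s1 <- grid_stack(array(1, c(1, 1, 1)), c(0, 1, 0, 1))
  expect_equal(compute_lue(one, s1, s1)$values[1, 1, 1], 0.604)
  g <- function(x) grid_stack(array(x, c(1, 1, 1)), c(0, 1, 0, 1))
  expect_equal(compute_lue(g(0.9), g(0.8), g(0.7))$values[1, 1, 1],
               0.9 * 0.8 * 0.7 * 0.604)
  expect_equal(compute_lue(g(0), s1, s1)$values[1, 1, 1], 0)
  expect_equal(compute_npp(g(100), g(0.25))$values[1, 1, 1], 25)
  expect_equal(compute_npp(g(0), g(0.4))$values[1, 1, 1], 0)
})

test_that("NPP is bilinear in SOL and LUE is independent of SOL and FPAR", {
  scene <- generate_scene(scene_config(grid_shape = c(8, 8), seed = 11))
  base <- run_casa(scene$inputs)
  scaled <- scene$inputs
  scaled$sol <- grid_like(scaled$sol, scaled$sol$values * 3)
  out <- run_casa(scaled)
  expect_equal(out$apar$values, base$apar$values * 3)
  expect_equal(out$npp$values, base$npp$values * 3)
  expect_equal(out$lue$values, base$lue$values)
})

test_that("every grid operation matches the scalar-loop oracle on small grids", {
  set.seed(7)
  for (rep in 1:4) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    fpar <- rand_stack(nr, nc, 12, na_frac = 0.05)
    temp <- rand_stack(nr, nc, 12, lo = -15, hi = 25, na_frac = 0.05)
    sol <- rand_stack(nr, nc, 12, lo = 100, hi = 700)
    lst <- rand_stack(nr, nc, 12, lo = 260, hi = 305)
    u <- rand_stack(nr, nc, 12, lo = 1, hi = 30)
    tol <- 1e-12
    apar <- compute_apar(sol, fpar)
    expect_equal(apar$values,
                 o_elementwise(sol$values, fpar$values, function(a, b) a * b * 0.5),
                 tolerance = tol)
    topt <- compute_topt(temp, fpar)
    expect_equal(topt$values[, , 1], o_topt(temp$values, fpar$values),
                 tolerance = tol)
    expect_equal(temperature_stress_1(topt)$values[, , 1],
                 o_te1(topt$values[, , 1]), tolerance = tol)
    te2 <- temperature_stress_2(topt, temp)
    expect_equal(te2$values, o_te2(topt$values[, , 1], temp$values),
                 tolerance = tol)
    td_k <- grid_like(u, (log(u$values) - 1.8084) / 0.0735 + 273, units = "K")
    d <- vapor_pressure_deficit(lst, td_k)
    expect_equal(d$values, o_vpd(lst$values, td_k$values), tolerance = tol)
    suppressWarnings(we <- water_stress(d))
    expect_equal(we$values, o_we(d$values), tolerance = tol)
    lue <- compute_lue(temperature_stress_1(topt), te2, we)
    npp <- compute_npp(apar, lue)
    expect_equal(npp$values,
                 o_elementwise(apar$values, lue$values, function(a, b) a * b),
                 tolerance = tol)
  }
})

test_that("run_casa validates its input bundle and propagates masks", {
  scene <- generate_scene(scene_config(grid_shape = c(6, 6), seed = 2))
  inp <- scene$inputs
  expect_error(run_casa(inp[-1]), "missing input.*sol")
  bad <- inp; bad$lst <- grid_layer(bad$lst, 1)
  expect_error(run_casa(bad), "lst")
  allna <- inp
  allna$fpar <- grid_like(allna$fpar, array(NA_real_, dim(allna$fpar$values)))
  out <- run_casa(allna)
  expect_true(all(is.na(out$npp$values)))
  expect_true(all(is.na(out$npp_annual$values)))
})

test_that("annual layer conserves the monthly sum on unmasked cells", {
  scene <- generate_scene(scene_config(grid_shape = c(8, 8), seed = 5))
  out <- run_casa(scene$inputs)
  manual <- apply(out$npp$values, c(1, 2), sum)
  expect_equal(out$npp_annual$values[, , 1], manual, tolerance = 1e-12)
})
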