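test_that("serpentine schedule has the documented geometry and timing", {
  g <- scan_grid(25, 25, n_per_line = 3, n_lines = 2, rate = 1)
  ev <- build_serpentine_scan(g)
  expect_equal(nrow(ev), 6)
  expect_equal(ev$t, 0:5)
  expect_equal(ev$x[1:3], c(0, 25, 50))       # first line +fast
  expect_equal(ev$x[4:6], c(50, 25, 0))       # second line reversed
  expect_equal(ev$y, rep(c(0, 25), each = 3))

  # fast axis can be y
  gy <- scan_grid(10, 30, 2, 2, rate = 2, fast_axis = "y")
  evy <- build_serpentine_scan(gy)
  expect_equal(evy$y[1:2], c(0, 10))
  expect_equal(evy$x, rep(c(0, 30), each = 2))

  expect_error(scan_grid(0, 25, 3, 2, 1), "steps")
  expect_error(scan_grid(25, 25, 0, 2, 1), "counts")
})

test_that("in-line and adjacent-line time separations match closed forms", {
  # exhaustive pair scan as oracle, against 1/rate and (2N-1)/rate
  for (case in list(c(231.25, 5, 4), c(100, 100, 3), c(231.25, 7, 3))) {
    rate <- case[1]; npl <- case[2]; nl <- case[3]
    ev <- build_serpentine_scan(scan_grid(25, 25, npl, nl, rate))
    seps <- neighbor_separations(ev)
    in_line <- seps[abs(seps$distance - 25) < 1e-9, ]
    expect_equal(min(in_line$dt), 1 / rate)
    # extreme lag among spatial nearest neighbours
    expect_equal(max(in_line$dt), (2 * npl - 1) / rate)
  }
  # 231.25 Hz in-line spacing ~ 4.324 ms
  ev <- build_serpentine_scan(scan_grid(25, 25, 5, 2, 231.25))
  expect_equal(ev$t[2] - ev$t[1], 1 / 231.25)
  expect_equal(round(1000 * (ev$t[2] - ev$t[1]), 3), 4.324)
  # n_per_line = 100 at 100 Hz: extreme adjacent-line lag 1.99 s
  ev2 <- build_serpentine_scan(scan_grid(25, 25, 100, 2, 100))
  s2 <- neighbor_separations(ev2)
  expect_equal(max(s2$dt[abs(s2$distance - 25) < 1e-9]), 1.99)
})

test_that("neighbor_separations identifies the documented extreme pairs", {
  ev <- build_serpentine_scan(scan_grid(25, 25, 3, 2, rate = 1))
  seps <- neighbor_separations(ev)
  nn <- seps[abs(seps$distance - 25) < 1e-9, ]
  # min lag is an in-line adjacent pair
  best <- nn[which.min(nn$dt), ]
  expect_equal(best$dt, 1)
  # max lag among nearest neighbours: first exposure of line 1 (index 0)
  # with last exposure of line 2 (index 5); exhaustive enumeration
  worst <- nn[which.max(nn$dt), ]
  expect_equal(sort(c(worst$i, worst$j)), c(0, 5))
  expect_equal(worst$dt, 5)
  # square grid: nearest-neighbour distance equals the step
  expect_equal(min(seps$distance), 25)
  # single event: empty table
  expect_equal(nrow(neighbor_separations(ev[1, ])), 0)
  # summary covers distance classes
  sm <- separation_summary(seps)
  expect_true(all(sm$min_dt <= sm$max_dt))
})

test_that("spread_radius follows the constant-speed and diffusive forms", {
  cs <- spread_model("constant_speed", speed = 1000)  # 1 um/ms
  expect_equal(spread_radius(cs, 0.010), 10)
  expect_equal(spread_radius(cs, 0), 0)
  dm <- spread_model("diffusive", diffusivity = 1000)
  expect_equal(spread_radius(dm, 0.25), sqrt(4 * 1000 * 0.25))
  expect_equal(spread_radius(dm, 0), 0)
  t <- seq(0, 2, by = 0.1)
  expect_true(all(diff(spread_radius(dm, t)) >= 0))
  expect_error(spread_radius(dm, -1), "negative")
  expect_error(spread_model("constant_speed", speed = 1, diffusivity = 1),
               "exactly one")
})

test_that("affected_fraction matches an exhaustive oracle and is monotone", {
  ev <- build_serpentine_scan(scan_grid(30, 30, 10, 3, rate = 1))
  expect_equal(affected_fraction(ev, spread_model("constant_speed", speed = 0)), 0)
  huge <- spread_model("constant_speed", speed = 1e9)
  expect_equal(affected_fraction(ev, huge), (nrow(ev) - 1) / nrow(ev))
  # regime of the schematic: spread covers step/10 per inter-exposure period
  v <- (30 / 10) / 1     # um per second at 1 Hz
  m <- spread_model("constant_speed", speed = v)
  expect_equal(affected_fraction(ev, m),
               oracle_affected_fraction(ev, function(dt) v * dt))
  # monotone non-decreasing in speed
  fr <- vapply(c(1, 5, 20, 100, 1000), function(sp)
    affected_fraction(ev, spread_model("constant_speed", speed = sp)), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("multi_hit_fraction behaves geometrically and under the seed", {
  sizes <- crystal_size_model(20, 0)
  # step well above diameter, point beam: no multiple hits
  g_wide <- scan_grid(100, 100, 8, 8, rate = 100)
  expect_lt(multi_hit_fraction(g_wide, sizes, n_sim = 3000, seed = 2), 0.01)
  # step 5 um, diameter 20 um: on the infinite lattice every disc covers
  # >= 2 grid points (geometric oracle over all center offsets)
  offs <- expand.grid(ox = seq(0, 5, length.out = 41),
                      oy = seq(0, 5, length.out = 41))
  lattice <- expand.grid(x = seq(-25, 25, by = 5), y = seq(-25, 25, by = 5))
  min_cover <- min(vapply(seq_len(nrow(offs)), function(i)
    sum((lattice$x - offs$ox[i])^2 + (lattice$y - offs$oy[i])^2 <= 10^2),
    0L))
  expect_gte(min_cover, 2)
  # the Monte-Carlo estimate approaches 1, short of it only through crystals
  # clipping the finite chip edge
  g_fine <- scan_grid(5, 5, 30, 30, rate = 100)
  expect_gt(multi_hit_fraction(g_fine, sizes, n_sim = 2000, seed = 2), 0.95)
  # monotone non-increasing in step at matched seeds
  fr <- vapply(c(5, 10, 20, 40, 80), function(s)
    multi_hit_fraction(scan_grid(s, s, 20, 20, 100),
                       crystal_size_model(20, 5), n_sim = 2000, seed = 7), 0)
  expect_true(all(diff(fr) <= 0))
  # deterministic under fixed seed
  expect_identical(
    multi_hit_fraction(g_fine, crystal_size_model(20, 8), 500, seed = 11),
    multi_hit_fraction(g_fine, crystal_size_model(20, 8), 500, seed = 11))
})

test_that("multi_hit estimator standard error scales as 1/sqrt(n_sim)", {
  g <- scan_grid(15, 15, 15, 15, rate = 100)
  sizes <- crystal_size_model(20, 6)
  est <- function(n, seeds) vapply(seeds, function(s)
    multi_hit_fraction(g, sizes, n_sim = n, seed = s), 0)
  sd_small <- sd(est(150, 1:24))
  sd_large <- sd(est(600, 101:124))
  expect_gt(sd_small / sd_large, 1.3)
  expect_lt(sd_small / sd_large, 3.1)
})

test_that("thermal_increment kernel conserves deposited energy", {
  med <- list(density = 1000, heat_capacity = 4184, diffusivity = 1.43e-7)
  E <- 1e-4
  # far field -> ~0
  expect_lt(thermal_increment(E, 1e5, 0.005, med), 1e-12)
  # t = 0 handling
  expect_equal(thermal_increment(E, 10, 0, med), 0)
  expect_error(thermal_increment(E, 0, 0, med), "singular")
  # 3-D: integral of rho c dT over space = E (quadrature oracle), at two times
  for (t in c(1e-3, 1e-2)) {
    f <- function(r_um) {
      dT <- vapply(r_um, function(r) thermal_increment(E, r, t, med), 0)
      med$density * med$heat_capacity * dT * 4 * pi * (r_um * 1e-6)^2 * 1e-6
    }
    got <- stats::integrate(f, 0, 5e4, rel.tol = 1e-8)$value
    expect_equal(got, E, tolerance = 0.01)
  }
  # 2-D sheet kernel conserves E within its sheet
  h <- 10
  f2 <- function(r_um) {
    dT <- vapply(r_um, function(r)
      thermal_increment(E, r, 1e-3, med, kernel = "sheet2d", sheet_thickness = h), 0)
    med$density * med$heat_capacity * dT * 2 * pi * (r_um * 1e-6) * 1e-6 * (h * 1e-6)
  }
  expect_equal(stats::integrate(f2, 0, 5e4, rel.tol = 1e-8)$value, E,
               tolerance = 0.01)
  # order of magnitude: ~4.9e10 photons of 11.56 keV (~9e-5 J) deposited,
  # neighbour at 25 um, one in-line period later: a degrees-scale increase,
  # not thousands of kelvin, not microkelvin (qualitative check only)
  E_pulse <- 4.90e10 * 11.56 * 1.602176634e-16
  dT <- thermal_increment(E_pulse, 25, 1 / 231.25, med)
  expect_gt(dT, 0.1); expect_lt(dT, 100)
})
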