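test_that("reaction-free dynamics conserve mass to integrator tolerance", {
  p0 <- cc_params(1300, 0, 0, 4965, 5435)
  sr <- small_radial()
  sim <- simulate_model(p0, lin2, sr$ic, sr$grid, c(0, 23, 46))
  m <- vapply(1:3, function(i) total_mass(sim, i), numeric(1))
  expect_lt(max(abs(m / m[1] - 1)), 1e-8)
  sb <- small_block()
  sim2 <- simulate_model(p0, lin2, sb$ic, sb$grid, c(0, 23, 46))
  m2 <- vapply(1:3, function(i) total_mass(sim2, i), numeric(1))
  expect_lt(max(abs(m2 / m2[1] - 1)), 1e-8)
})

test_that("densities stay nonnegative and mass is nondecreasing under growth", {
  for (build in list(small_radial(), small_block())) {
    sim <- simulate_model(modes, lin2, build$ic, build$grid, seq(0, 40, 8))
    expect_true(all(sim$rho1 >= 0) && all(sim$rho2 >= 0))
    m <- vapply(seq_along(sim$times), function(i) total_mass(sim, i),
                numeric(1))
    expect_true(all(diff(m) >= 0))
  }
})

test_that("a uniform field follows the two-compartment ODE (matrix exponential oracle)", {
  p <- cc_params(800, 0.612, 0.457, 1, 1)
  g <- cc_grid("cartesian1d", 1000, 50)
  ic <- cc_initial_condition(g, 1000, 400)
  sim <- simulate_model(p, const2, ic, g, c(0, 5, 10))
  A <- matrix(c(-p$k1, p$k1, 2 * p$k2, -p$k2), 2)
  for (i in 2:3) {
    ref <- as.numeric(Matrix::expm(A * sim$times[i]) %*% c(1000, 400))
    expect_equal(sim$rho1[i, ], rep(ref[1], g$N), tolerance = 1e-6)
    expect_equal(sim$rho2[i, ], rep(ref[2], g$N), tolerance = 1e-6)
  }
  # uniform field with linear crowding against a tight ODE integration
  pl <- cc_params(800, 0.612, 0.457, 4965, 5435)
  sim_l <- simulate_model(pl, lin2, ic, g, c(0, 10))
  ode_ref <- deSolve::ode(c(1000, 400), c(0, 10), function(t, y, parms) {
    rho <- sum(y)
    a <- pl$k1 * max(1 - rho / pl$K1, 0)
    b <- pl$k2 * max(1 - rho / pl$K2, 0)
    list(c(-a * y[1] + 2 * b * y[2], a * y[1] - b * y[2]))
  }, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(sim_l$rho1[2, g$N / 2], ode_ref[2, 2], tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("compiled and reference right-hand sides produce the same solution", {
  sr <- small_radial(N = 60)
  a <- simulate_model(modes, lin2, sr$ic, sr$grid, c(0, 10, 20))
  b <- simulate_model(modes, lin2, sr$ic, sr$grid, c(0, 10, 20),
                      solver_settings(compiled = FALSE))
  expect_equal(a$rho1, b$rho1, tolerance = 1e-5)
  expect_equal(a$rho2, b$rho2, tolerance = 1e-5)
})

test_that("spatial discretisation converges at second order", {
  run_at <- function(N) {
    g <- cc_grid("cartesian1d", 2000, N)
    ic <- cc_initial_condition(g, 2000 * exp(-((g$x - 800) / 300)^2),
                               1000 * exp(-((g$x - 1100) / 250)^2))
    sim <- simulate_model(modes, lin2, ic, g, c(0, 10),
                          solver_settings(rtol = 1e-10, atol = 1e-12))
    stats::approx(g$x, sim$rho1[2, ], xout = seq(100, 1900, 100))$y
  }
  coarse <- run_at(100)
  finer <- run_at(200)
  ref <- run_at(800)
  ratio <- max(abs(coarse - ref)) / max(abs(finer - ref))
  expect_gt(ratio, 3)   # ~4 for a second-order scheme
  expect_lt(ratio, 5.5)
})

test_that("radial and Cartesian fronts far from the origin move at the same speed", {
  ic_band <- function(g) cc_initial_condition(
    g, ifelse(g$x > 2500 & g$x < 3500, 500, 0), 0)
  speeds <- sapply(c("radial", "cartesian1d"), function(geom) {
    g <- cc_grid(geom, 6000, 480)
    sim <- simulate_model(modes, lin2, ic_band(g), g, seq(0, 40, 5),
                          fast_solver)
    expansion_speed(sim, 50, window = c(20, 40))
  })
  expect_lt(abs(speeds[1] / speeds[2] - 1), 0.02)
})

test_that("total mass matches area formulas and is grid-converged", {
  # uniform disc: rho0 * pi * R^2 (with the um^2 -> mm^2 conversion)
  g <- cc_grid("radial", 2000, 100)
  sim <- structure(list(grid = g, times = 0,
                        rho1 = matrix(1500, 1, g$N),
                        rho2 = matrix(500, 1, g$N)), class = "cc_sim")
  expect_equal(total_mass(sim, 1), 2000 * pi * 2000^2 / 1e6)
  # uniform interval: c * L per mm width
  g2 <- cc_grid("cartesian1d", 3000, 120)
  sim2 <- structure(list(grid = g2, times = 0,
                         rho1 = matrix(4800, 1, g2$N),
                         rho2 = matrix(0, 1, g2$N)), class = "cc_sim")
  expect_equal(total_mass(sim2, 1), 4800 * 3000 / 1e3)
  expect_error(total_mass(sim2, 5), "out of range")
  # refinement changes a smooth profile's mass by well under 0.5%
  mass_at <- function(N) {
    g <- cc_grid("radial", 3000, N)
    s <- structure(list(grid = g, times = 0,
                        rho1 = matrix(3000 * exp(-(g$x / 1200)^2), 1, g$N),
                        rho2 = matrix(0, 1, g$N)), class = "cc_sim")
    total_mass(s, 1)
  }
  expect_lt(abs(mass_at(400) / mass_at(200) - 1), 0.005)
})

test_that("edge detection interpolates the outermost threshold crossing", {
  g <- cc_grid("cartesian1d", 1000, 100)
  step <- ifelse(g$x < 500, 5000, 0)
  expect_equal(edge_position(step, g$x, 50), 500, tolerance = g$dx)
  ramp <- 5000 * (1 - g$x / 1000)
  expect_equal(edge_position(ramp, g$x, 2500), 500, tolerance = 1e-9)
  expect_true(is.na(edge_position(rep(10, 100), g$x, 50)))
  expect_error(edge_position(step, g$x, -1), "threshold")
})

test_that("expansion speed is the least-squares slope of the edge trajectory", {
  g <- cc_grid("cartesian1d", 4000, 200)
  times <- seq(0, 50, 10)
  moving <- t(sapply(times, function(t) ifelse(g$x < 500 + 30 * t, 4000, 0)))
  sim <- structure(list(grid = g, times = times, rho1 = moving,
                        rho2 = 0 * moving), class = "cc_sim")
  expect_equal(expansion_speed(sim, 50), 30, tolerance = 0.02)
  still <- t(sapply(times, function(t) ifelse(g$x < 800, 4000, 0)))
  sim0 <- structure(list(grid = g, times = times, rho1 = still,
                         rho2 = 0 * still), class = "cc_sim")
  expect_equal(expansion_speed(sim0, 50), 0, tolerance = 1e-9)
  expect_error(expansion_speed(sim0, 1e6), "edge")
})

test_that("invalid grids, initial conditions and time vectors are rejected", {
  expect_error(cc_grid("radial", -5, 10), "L")
  expect_error(cc_grid("radial", 100, 2), "N")
  g <- cc_grid("radial", 100, 10)
  expect_error(cc_initial_condition(g, -1, 0), "nonnegative")
  expect_error(cc_initial_condition(g, NaN, 0), "finite|nonnegative")
  ic <- cc_initial_condition(g, 100, 0)
  expect_error(simulate_model(modes, lin2, ic, g, c(5, 2)), "times")
})
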