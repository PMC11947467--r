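test_that("observation and simulation CSVs round-trip losslessly", {
  obs <- scratch_scenario(L = 1600, N = 40, times = c(0, 16),
                          replicates = 3, noise = 20, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_observations(obs, f)
  back <- read_observations(f, "cartesian1d")
  expect_equal(plain_df(back), plain_df(obs), tolerance = 1e-12)
  favg <- tempfile(fileext = ".csv")
  write_observations(replicate_average(obs), favg)
  bavg <- read_observations(favg, "cartesian1d")
  expect_true(isTRUE(attr(bavg, "averaged")))
  expect_equal(bavg$sd1, replicate_average(obs)$sd1, tolerance = 1e-12)

  sim <- attr(obs, "sim")
  fs <- tempfile(fileext = ".csv")
  write_simulation(sim, fs)
  back_sim <- read_simulation(fs, "cartesian1d")
  expect_equal(back_sim$rho1, sim$rho1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back_sim$grid$x, sim$grid$x)
  # malformed input is reported by column name
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_simulation(bad), "time_h")
})

test_that("config validation names the missing keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 1", "simulate:", "  grid: {geometry: radial, L: 100, 'N': 10}"), f)
  expect_error(run_simulate(f), "simulate.params")
  writeLines(c("seed: 1", "wave:", "  params: {D: 10, k1: 1}"), f)
  expect_error(run_wave(f), "wave.params.k2")
  writeLines("seed: 1", f)
  expect_error(run_fit(f), "fit")
})

test_that("a reaction-free simulation run reports negligible mass drift", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 1",
    "simulate:",
    "  params: {D: 1300, k1: 0, k2: 0, K1: 4965, K2: 5435}",
    "  grid: {geometry: radial, L: 3000, 'N': 150}",
    "  initial: {rho1: 2500, rho2: 1000, step_at: 1200, smoothing: 200}",
    "  times: {from: 0, to: 46, by: 23}"), f)
  out <- run_simulate(f, tempfile("cons"))
  expect_lt(out$report$mass_rel_drift, 1e-8)
  expect_true(file.exists(out$csv) && file.exists(out$json))
})

test_that("the shipped colonization example runs end-to-end", {
  cfg <- system.file("extdata", "colonization.yaml", package = "crowdcycle")
  expect_true(nzchar(cfg))
  od <- tempfile("colo")
  out <- run_simulate(cfg, od)
  expect_true(file.exists(file.path(od, "simulation.csv")))
  sim <- read_simulation(file.path(od, "simulation.csv"), "cartesian1d")
  expect_equal(max(sim$times), 24)
  # wave block of the same config
  w <- run_wave(cfg, od)
  expect_equal(w$report$cmin, min_wave_speed(mdck_modes()))
})

test_that("synthetic data written to disk matches an equivalent simulation run", {
  od <- tempfile("zn")
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 4",
    "synth:",
    "  scenario: colonization",
    "  noise: 0",
    "  replicates: 1",
    "  times: [0, 6, 12]"), f)
  syn <- run_synth(f, od)
  # provenance records the seed
  prov <- yaml::read_yaml(syn$yaml)
  expect_equal(prov$seed, 4)
  expect_equal(prov$scenario, "colonization")
  f2 <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 4",
    "simulate:",
    "  params: {D: 1300, k1: 0.612, k2: 0.457, K1: 4965, K2: 5435}",
    "  grid: {geometry: cartesian1d, L: 3000, 'N': 300}",
    "  initial: {rho1: 4800, rho2: 0, step_at: 850}",
    "  times: [0, 6, 12]"), f2)
  simr <- run_simulate(f2, od)
  obs <- read_observations(syn$csv, "cartesian1d")
  sim <- read_simulation(file.path(od, "simulation.csv"), "cartesian1d")
  expect_equal(matrix(obs$rho1, nrow = 3, byrow = TRUE), sim$rho1,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(matrix(obs$rho2, nrow = 3, byrow = TRUE), sim$rho2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fit runs from config are deterministic and shaped as configured", {
  od <- tempfile("fit")
  obs <- scratch_scenario(L = 1600, N = 40, times = c(0, 24, 48),
                          replicates = 4, noise = 20, seed = 1)
  data_csv <- file.path(tempdir(), "obs_fit.csv")
  write_observations(obs, data_csv)
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 21",
    "fit:",
    paste0("  data: ", data_csv),
    "  geometry: cartesian1d",
    "  model: exponential",
    "  mcmc: {walkers: 10, steps: 40, burnin: 0.5, init_draws: 8, refine_maxit: 40}"),
    f)
  r1 <- run_fit(f, file.path(od, "a"))
  r2 <- run_fit(f, file.path(od, "b"))
  # identical seeds give bit-identical posterior draws and summaries
  expect_identical(readLines(r1$posterior_csv), readLines(r2$posterior_csv))
  s1 <- jsonlite::read_json(r1$json)
  s2 <- jsonlite::read_json(r2$json)
  s1$config_path <- s2$config_path <- NULL
  expect_identical(s1, s2)
  # row count = walkers x (steps - burn-in)
  post <- utils::read.csv(r1$posterior_csv)
  expect_equal(nrow(post), 10 * 20)
  # exponential-model flag restricts the sampled parameters
  expect_identical(names(post), c("D", "k1", "k2", "sigma"))
  expect_equal(s1$seed, 21)
})

test_that("wave analytics exported as machine-readable report", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 1",
    "wave:",
    "  params: {D: 1300, k1: 0.612, k2: 0.457, K1: 4965, K2: 5435}"), f)
  out <- run_wave(f, tempfile("wave"))
  j <- jsonlite::read_json(out$json)
  expect_equal(j$cmin, 33.62367, tolerance = 1e-5)
  expect_equal(j$fkpp_cmin, 26.08144, tolerance = 1e-5)
  expect_equal(round(j$regime, 2), 0.98)
  expect_equal(j$edge_minus_bulk, 470)
  expect_match(j$config_hash, "^[0-9a-f]{32}$")
  # degenerate and subcritical parameter sets
  writeLines(c("wave:", "  params: {D: 0, k1: 0.5, k2: 0.5, K1: 100, K2: 5000}"), f)
  out2 <- run_wave(f, tempfile("wave"))
  expect_equal(out2$report$cmin, 0)
  expect_equal(out2$report$branch, "subcritical")
  expect_equal(out2$report$rho2_bulk, 0)
})

test_that("the command-line wrapper drives the pipeline and signals failure", {
  cli <- system.file("cli", "crowdcycle.R", package = "crowdcycle")
  cfg <- system.file("extdata", "colonization.yaml", package = "crowdcycle")
  expect_true(nzchar(cli) && nzchar(cfg))
  od <- tempfile("cliout")
  status <- system2("Rscript", c(cli, "wave", "--config", cfg,
                                 "--out-dir", od, "--quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  expect_true(file.exists(file.path(od, "wave.json")))
  status2 <- system2("Rscript", c(cli, "wave", "--config", "/no/such.yaml"),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 1)
})
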