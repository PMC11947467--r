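test_that("Gaussian likelihood: zero residuals, monotonicity, brute-force oracle", {
  obs <- tiny_obs()
  sim <- attr(obs, "sim")
  n_res <- 2 * 2 * 40   # two populations, two post-initial times, 40 nodes
  # observations equal to the simulation: only the normalising constant
  ll0 <- log_likelihood(attr(obs, "truth"), 1, obs, const2)
  expect_equal(ll0, -(n_res / 2) * log(2 * pi), tolerance = 1e-9)
  # perturbing any observation strictly decreases the likelihood
  pert <- obs
  pert$rho1[100] <- pert$rho1[100] + 25
  expect_lt(log_likelihood(attr(obs, "truth"), 1, pert, const2), ll0)
  # independent per-point re-summation at other parameter values
  p2 <- cc_params(500, 0.05, 0.06, 1, 1)
  sigma <- 35
  ll <- log_likelihood(p2, sigma, obs, const2)
  prep <- crowdcycle:::prepare_observations(obs)
  sim2 <- simulate_model(p2, const2, prep$ic, prep$grid, prep$times)
  acc <- 0
  for (i in 2:3) for (j in 1:40) {
    acc <- acc + dnorm(prep$rho1[i, j] - sim2$rho1[i, j], 0, sigma, log = TRUE)
    acc <- acc + dnorm(prep$rho2[i, j] - sim2$rho2[i, j], 0, sigma, log = TRUE)
  }
  expect_equal(ll, acc, tolerance = 1e-10)
  expect_error(log_likelihood(p2, -1, obs), "sigma")
})

test_that("likelihood is invariant to observation-row ordering", {
  obs <- tiny_obs()
  p <- cc_params(600, 0.05, 0.08, 1, 1)
  shuffled <- as.data.frame(obs)[sample(nrow(obs)), ]
  obs2 <- observation_set(shuffled, "cartesian1d")
  expect_equal(log_likelihood(p, 20, obs, const2),
               log_likelihood(p, 20, obs2, const2))
})

test_that("log-posterior: support, uniform-prior offset, bound-shift invariance", {
  obs <- tiny_obs()
  pri <- cc_priors("exponential")
  thA <- c(700, 0.04, 0.07, 15)
  thB <- c(500, 0.06, 0.05, 30)
  expect_identical(log_posterior(c(-5, 0.04, 0.07, 15), obs, pri,
                                 const2), -Inf)
  expect_identical(log_posterior(c(700, 0.04, 0.07, 5000), obs, pri,
                                 const2), -Inf)
  # inside the support the prior contributes a constant
  ll_diff <- log_likelihood(cc_params(thA[1], thA[2], thA[3], 1, 1), thA[4],
                            obs, const2) -
             log_likelihood(cc_params(thB[1], thB[2], thB[3], 1, 1), thB[4],
                            obs, const2)
  expect_equal(log_posterior(thA, obs, pri, const2) -
                 log_posterior(thB, obs, pri, const2), ll_diff)
  # shifting the (uniform) prior box leaves log-posterior differences —
  # and hence the MAP location — unchanged
  pri2 <- cc_priors("exponential", lower = c(D = 100), upper = c(D = 4000))
  expect_equal(log_posterior(thA, obs, pri2, const2) -
                 log_posterior(thB, obs, pri2, const2), ll_diff)
})

test_that("ensemble sampling is exactly reproducible given the seed", {
  obs <- tiny_obs(times = c(0, 24))
  pri <- cc_priors("exponential")
  st <- mcmc_settings(walkers = 10, steps = 16, seed = 99, init_draws = 8,
                      refine = FALSE)
  a <- suppressWarnings(sample_posterior(obs, pri, st))
  b <- suppressWarnings(sample_posterior(obs, pri, st))
  expect_identical(a$draws, b$draws)
  expect_true(all(is.finite(a$draws)))
  # draws confined to the prior box
  for (j in seq_len(nrow(pri)))
    expect_true(all(a$draws[, j] > pri$lower[j] & a$draws[, j] < pri$upper[j]))
  st2 <- mcmc_settings(walkers = 10, steps = 16, seed = 100, init_draws = 8,
                       refine = FALSE)
  c <- suppressWarnings(sample_posterior(obs, pri, st2))
  expect_false(identical(a$draws, c$draws))
})

test_that("an uninformative likelihood returns the prior (posterior = prior limit)", {
  # short horizon bounds the worst-case simulated density (~1e7 at the
  # k = 3 prior corner), and the noise scale is pinned far above it, so
  # the log-likelihood is constant over the box to ~0.03 nats
  obs <- tiny_obs(times = c(0, 8))
  pri <- cc_priors("exponential",
                   lower = c(sigma = 1e9 - 1), upper = c(sigma = 1e9 + 1))
  st <- mcmc_settings(walkers = 16, steps = 500, seed = 3, init_draws = 8,
                      refine = FALSE, init_spread = 0.5)
  post <- suppressWarnings(sample_posterior(obs, pri, st))
  for (par in c("D", "k1", "k2")) {
    j <- which(pri$param == par)
    expect_lt(abs(mean(post$draws[, par]) -
                    mean(c(pri$lower[j], pri$upper[j]))) /
                (pri$upper[j] - pri$lower[j]), 0.15)
    expect_gt(sd(post$draws[, par]) / crowdcycle:::prior_sd(pri)[par], 0.6)
  }
})

test_that("posterior summaries: degenerate, unimodal and bimodal marginals", {
  flat <- matrix(5, 400, 1, dimnames = list(NULL, "D"))
  s <- posterior_summary(flat)
  expect_equal(s$mode, 5)
  expect_equal(s$sd, 0)
  expect_false(s$multimodal)
  set.seed(1)
  g <- matrix(rnorm(5000, 10, 1), ncol = 1, dimnames = list(NULL, "k1"))
  sg <- posterior_summary(g)
  expect_lt(abs(sg$mode - mean(g)), 0.15)
  expect_false(sg$multimodal)
  expect_lt(sg$q2.5, sg$q97.5)
  bi <- matrix(c(rnorm(2500, -3, 0.3), rnorm(2500, 3, 0.3)), ncol = 1,
               dimnames = list(NULL, "K1"))
  sb <- posterior_summary(bi)
  expect_true(sb$multimodal)
  expect_lt(min(abs(sb$mode - c(-3, 3))), 0.3)
})

test_that("identifiability verdicts follow the posterior/prior sd ratio", {
  pri <- cc_priors("exponential")
  set.seed(2)
  # posterior == prior: ratio ~ 1, non-identifiable
  draws <- sapply(seq_len(nrow(pri)), function(j)
    runif(3000, pri$lower[j], pri$upper[j]))
  colnames(draws) <- pri$param
  rep1 <- identifiability_report(draws, pri)
  expect_true(all(abs(rep1$ratio - 1) < 0.1))
  expect_true(all(rep1$verdict == "non-identifiable"))
  # a point-mass posterior: ratio 0, identifiable
  point <- draws
  point[] <- rep(colMeans(draws), each = 3000)
  rep2 <- identifiability_report(point, pri)
  expect_true(all(rep2$ratio == 0))
  expect_true(all(rep2$verdict == "identifiable"))
})

test_that("credible intervals cover the truth across repeated experiments", {
  # Five independent shallow-wound datasets (densities well above zero, so
  # the Gaussian likelihood is exactly specified), density-independent
  # submodel, well-mixed chains: the 95% intervals for (D, k1, k2) should
  # cover the generating values in at least 80% of parameter-dataset
  # pairs. The forward solver settings are shared between generator and
  # likelihood so that the check isolates the inference machinery.
  truth <- scratch_truth()
  g <- cc_grid("cartesian1d", 1600, 40)
  prof <- ifelse(g$x < 600 | g$x > 1000, 400, 220)
  ic <- cc_initial_condition(g, 0.6 * prof, 0.4 * prof)
  times <- c(0, 16, 32, 48)
  sim <- simulate_model(truth, const2, ic, g, times, fast_solver)
  hits <- 0; total <- 0
  for (seed in 1:5) {
    set.seed(seed)
    reps <- lapply(1:8, function(r) {
      tt <- rep(times, each = g$N)
      e1 <- rnorm(4 * g$N, 0, 20)
      e2 <- rnorm(4 * g$N, 0, 20)
      e1[tt == 0] <- 0  # the seeded geometry is recorded exactly
      e2[tt == 0] <- 0
      data.frame(replicate = r, time_h = tt,
                 position_um = rep(g$x, 4),
                 rho1 = as.vector(t(sim$rho1)) + e1,
                 rho2 = as.vector(t(sim$rho2)) + e2)
    })
    obs <- observation_set(do.call(rbind, reps), "cartesian1d")
    st <- mcmc_settings(walkers = 16, steps = 2000, seed = 100 + seed,
                        init_draws = 32, refine_maxit = 400,
                        solver = fast_solver)
    fit <- suppressWarnings(fit_cellcycle(obs, model = "exponential",
                                          settings = st))
    want <- c(D = truth$D, k1 = truth$k1, k2 = truth$k2)
    for (par in names(want)) {
      row <- fit$summary[fit$summary$param == par, ]
      total <- total + 1
      if (want[par] >= row$q2.5 && want[par] <= row$q97.5) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.8)
})
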