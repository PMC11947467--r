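# Shared fixtures: small, fast problem sizes for unit tests. The
# acceptance suite uses the study-scale problem sizes instead.

modes <- mdck_modes()
lin2 <- crowding_spec("linear", "linear")
const2 <- crowding_spec("constant", "constant")

# quick solver settings for tests that only need qualitative accuracy
fast_solver <- solver_settings(rtol = 1e-4, atol = 1e-6)

# a small smooth radial tissue
small_radial <- function(N = 80, L = 4000) {
  g <- cc_grid("radial", L, N)
  prof <- 3500 / (1 + exp((g$x - 1500) / 100))
  list(grid = g, ic = cc_initial_condition(g, 0.7 * prof, 0.3 * prof))
}

# a small cartesian block
small_block <- function(N = 80, L = 2000, edge = 700, rho1 = 2000, rho2 = 500) {
  g <- cc_grid("cartesian1d", L, N)
  list(grid = g,
       ic = cc_initial_condition(g, ifelse(g$x < edge, rho1, 0),
                                 ifelse(g$x < edge, rho2, 0)))
}

# tiny zero-noise observation set (fast likelihood evaluations)
tiny_obs <- function(times = c(0, 16, 32), N = 40, L = 1600) {
  scratch_scenario(L = L, N = N, gap = c(600, 1000), times = times,
                   replicates = 1, noise = 0)
}

# drop generator/provenance attributes, keeping plain data.frame content
plain_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}
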