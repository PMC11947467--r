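## Shared machinery: forward-simulate a scenario and sample noisy replicates.
## Noise is additive Gaussian with constant scale, censored at zero (cell
## counts cannot be negative), and is applied only where the underlying
## density exceeds `noise_floor`: counting noise arises where cells are
## present, while empty regions of a segmented image count exactly zero.
sample_replicates <- function(sim, times, replicates, noise, seed,
                              noise_floor = 1, ic_noise = noise) {
  set.seed(seed)
  idx <- match(times, sim$times)
  if (any(is.na(idx)))
    stop("observation time beyond the simulated horizon", call. = FALSE)
  n <- sim$grid$N
  scale_t <- c(ic_noise, rep(noise, length(times) - 1))
  reps <- lapply(seq_len(replicates), function(r) {
    m1 <- sim$rho1[idx, , drop = FALSE]
    m2 <- sim$rho2[idx, , drop = FALSE]
    if (any(scale_t > 0)) {
      sd_m <- matrix(scale_t, nrow = length(times), ncol = n)
      e1 <- stats::rnorm(length(m1), 0, 1) * sd_m
      e2 <- stats::rnorm(length(m2), 0, 1) * sd_m
      e1[m1 <= noise_floor] <- 0
      e2[m2 <= noise_floor] <- 0
      m1 <- pmax(m1 + e1, 0)
      m2 <- pmax(m2 + e2, 0)
    }
    data.frame(replicate = r,
               time_h = rep(times, each = n),
               position_um = rep(sim$grid$x, length(times)),
               rho1 = as.vector(t(m1)), rho2 = as.vector(t(m2)))
  })
  geometry <- if (sim$grid$geometry == "radial") "radial" else "cartesian1d"
  obs <- observation_set(do.call(rbind, reps), geometry)
  attr(obs, "seed") <- seed
  obs
}

## Half-cosine edge ramp: density `plateau` up to (edge - width), 0 beyond
## `edge`, smooth in between. width = 0 gives a sharp step at `edge`.
ramp_profile <- function(x, edge, plateau, width) {
  if (width <= 0) return(ifelse(x < edge, plateau, 0))
  inner <- edge - width
  v <- ifelse(x <= inner, plateau,
              ifelse(x >= edge, 0,
                     plateau * 0.5 * (1 + cos(pi * (x - inner) / width))))
  v
}

#' Synthetic circular tissue-expansion experiment
#'
#' Emulates FUCCI tissue-expansion assays: a circular tissue (default
#' initial radius 1700 um, i.e. diameter ~3.4 mm) at plateau density
#' ~3500 cells/mm^2 expands freely and is imaged at regular intervals; 11
#' noisy replicates share the same underlying tissue. The observation
#' clock starts at the first profile retained for analysis (discarding the
#' stencil-removal transient), so observation time 0 is the initial
#' condition handed to the model.
#'
#' @param params true model parameters (default: MDCK posterior modes).
#' @param spec crowding functions of the generating model.
#' @param radius initial tissue radius, um.
#' @param total_density initial plateau total density, cells/mm^2.
#' @param split fraction of the initial density in G1/post-M (the rest is
#'   S/G2/M).
#' @param smoothing half-cosine edge ramp width, um.
#' @param times observation times, h (first is the initial condition).
#' @param replicates number of noisy replicates.
#' @param noise additive Gaussian noise scale per replicate, cells/mm^2
#'   (censored at zero).
#' @param noise_floor noise is only applied where the noiseless density
#'   exceeds this level, cells/mm^2: counting noise arises where cells are
#'   present, while empty regions count exactly zero.
#' @param ic_noise noise scale applied to the first observation time,
#'   cells/mm^2. For expansions the first retained frame is itself a
#'   measurement and defaults to the common noise scale; for scratch
#'   assays the initial state is the seeded geometry, set by the protocol,
#'   and defaults to being recorded exactly.
#' @param seed integer seed for the noise.
#' @param grid radial \code{\link{cc_grid}} to simulate on.
#' @param solver \code{\link{solver_settings}}.
#' @return A \code{"cc_obs"} observation set carrying attributes
#'   \code{truth} (the generating parameters), \code{sim} (the noiseless
#'   simulation) and \code{seed}.
#' @examples
#' obs <- expansion_scenario(replicates = 2, grid = cc_grid("radial", 4000, 80))
#' @export
expansion_scenario <- function(params = mdck_modes(),
                               spec = crowding_spec(),
                               radius = 1700, total_density = 3500,
                               split = 0.7, smoothing = 100,
                               times = seq(0, 36, by = 6),
                               replicates = 11, noise = 150, seed = 1,
                               noise_floor = 1, ic_noise = noise,
                               grid = cc_grid("radial", 5000, 500),
                               solver = solver_settings()) {
  stopifnot(grid$geometry == "radial", replicates >= 1, noise >= 0)
  prof <- ramp_profile(grid$x, radius, total_density, smoothing)
  ic <- cc_initial_condition(grid, split * prof, (1 - split) * prof)
  sim <- simulate_model(params, spec, ic, grid, times, solver)
  obs <- sample_replicates(sim, times, replicates, noise, seed, noise_floor,
                           ic_noise)
  attr(obs, "truth") <- params
  attr(obs, "sim") <- sim
  obs
}

#' Synthetic barrier-release colonization experiment
#'
#' Emulates colonization of free space after removal of a confining
#' barrier: a high-density block of G0/G1-arrested cells
#' (\code{rho1 = 4800} cells/mm^2 for \code{x < 850} um, zero S/G2/M) on a
#' 1-D domain of length 3000 um with no-flux boundaries. Cells behind the
#' retreating high-density edge re-enter the cycle, producing a transient
#' S/G2/M pulse. The low-density two-population variant
#' (\code{rho1 = rho2 = 500} cells/mm^2 behind the step) that develops
#' into a traveling wave is obtained by overriding the plateau arguments.
#'
#' @inheritParams expansion_scenario
#' @param L domain length, um.
#' @param N number of grid cells.
#' @param step_at position of the initial density step, um.
#' @param rho1_plateau,rho2_plateau initial densities behind the step,
#'   cells/mm^2.
#' @param smoothing edge ramp width, um (default 0: the sharp step is
#'   applied as given on the grid).
#' @return A list with elements \code{ic} (the initial condition),
#'   \code{sim} (noiseless simulation) and \code{obs} (observation set,
#'   with the same attributes as \code{\link{expansion_scenario}}).
#' @export
colonization_scenario <- function(params = mdck_modes(),
                                  spec = crowding_spec(),
                                  L = 3000, N = 300, step_at = 850,
                                  rho1_plateau = 4800, rho2_plateau = 0,
                                  smoothing = 0,
                                  times = seq(0, 24, by = 6),
                                  replicates = 1, noise = 0, seed = 1,
                                  noise_floor = 1,
                                  solver = solver_settings()) {
  grid <- cc_grid("cartesian1d", L, N)
  ic <- cc_initial_condition(grid,
                             ramp_profile(grid$x, step_at, rho1_plateau,
                                          smoothing),
                             ramp_profile(grid$x, step_at, rho2_plateau,
                                          smoothing))
  sim <- simulate_model(params, spec, ic, grid, times, solver)
  obs <- sample_replicates(sim, times, replicates, noise, seed, noise_floor)
  attr(obs, "truth") <- params
  attr(obs, "sim") <- sim
  list(ic = ic, sim = sim, obs = obs)
}

#' Default generating parameters for the scratch-assay scenario
#'
#' Mesenchymal-like truth parameters for the low-density scratch scenario:
#' slower cycling than epithelial MDCK (one to two divisions over two
#' days) with moderate motility. The crowding thresholds are carried along
#' but inert, as the generating model is density-independent.
#'
#' @return A \code{\link{cc_params}} object.
#' @export
scratch_truth <- function() {
  cc_params(D = 700, k1 = 0.04, k2 = 0.07, K1 = 4965, K2 = 5435)
}

#' Synthetic low-density scratch-assay experiment
#'
#' Emulates a wound-healing scratch assay in the low-density regime: two
#' blocks of cells at ~400 cells/mm^2 (about 5 percent of a typical
#' epithelial packing density) separated by a central cell-free gap, on a
#' 1-D domain, observed every 16 h over 2 days. The generating model is
#' density-independent (constant crowding functions) by default, so these
#' data carry essentially no information about crowding thresholds —
#' the scenario used to demonstrate practical non-identifiability of K1
#' and K2.
#'
#' @inheritParams expansion_scenario
#' @param L domain length, um.
#' @param N number of grid cells.
#' @param plateau seeded density in the two blocks, cells/mm^2.
#' @param gap numeric length-2: the cell-free interval, um.
#' @param split fraction of the seeded density in G1/post-M.
#' @return A \code{"cc_obs"} observation set (attributes as in
#'   \code{\link{expansion_scenario}}).
#' @export
scratch_scenario <- function(params = scratch_truth(),
                             spec = crowding_spec("constant", "constant"),
                             L = 2000, N = 200, plateau = 400,
                             gap = c(700, 1300), split = 0.6,
                             times = c(0, 16, 32, 48),
                             replicates = 3, noise = 150, seed = 1,
                             noise_floor = 1, ic_noise = 0,
                             solver = solver_settings()) {
  grid <- cc_grid("cartesian1d", L, N)
  block <- ifelse(grid$x < gap[1] | grid$x > gap[2], plateau, 0)
  ic <- cc_initial_condition(grid, split * block, (1 - split) * block)
  sim <- simulate_model(params, spec, ic, grid, times, solver)
  obs <- sample_replicates(sim, times, replicates, noise, seed, noise_floor,
                           ic_noise)
  attr(obs, "truth") <- params
  attr(obs, "sim") <- sim
  obs
}
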