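#' Finite-volume spatial grid
#'
#' A uniform cell-centred grid on \[0, L\], either a 1-D Cartesian interval
#' or the radial coordinate of a radially symmetric disc. Node positions are
#' the cell centres \code{(i - 1/2) * dx}; the innermost radial volume
#' element touches r = 0, so the symmetry condition at the origin is the
#' zero-flux condition through a face of zero radius.
#'
#' @param geometry \code{"cartesian1d"} or \code{"radial"}.
#' @param L domain length / maximum radius, um.
#' @param N number of volume elements (\code{N >= 3}).
#' @return An object of class \code{"cc_grid"} with elements
#'   \code{geometry}, \code{L}, \code{N}, \code{dx} and node positions
#'   \code{x} (um).
#' @examples
#' cc_grid("radial", L = 5000, N = 500)
#' @export
cc_grid <- function(geometry = c("cartesian1d", "radial"), L, N) {
  geometry <- match.arg(geometry)
  if (!is.finite(L) || L <= 0) stop("'L' must be positive", call. = FALSE)
  N <- as.integer(N)
  if (N < 3) stop("'N' must be at least 3", call. = FALSE)
  dx <- L / N
  structure(list(geometry = geometry, L = L, N = N, dx = dx,
                 x = (seq_len(N) - 0.5) * dx),
            class = "cc_grid")
}

#' @export
print.cc_grid <- function(x, ...) {
  cat(sprintf("%s grid: L = %g um, N = %d cells, dx = %g um\n",
              x$geometry, x$L, x$N, x$dx))
  invisible(x)
}

## Reconstruct a cc_grid from a vector of (cell-centre) observation
## positions. Radial grids must be anchored so the first centre is dx/2.
grid_from_positions <- function(positions, geometry = "radial") {
  p <- sort(unique(positions))
  n <- length(p)
  if (n < 3) stop("need at least 3 positions to reconstruct a grid", call. = FALSE)
  dx <- diff(p)
  if (diff(range(dx)) > 1e-6 * mean(dx))
    stop("observation positions are not on a uniform grid", call. = FALSE)
  dx <- mean(dx)
  if (geometry == "radial" && abs(p[1] - dx / 2) > 1e-6 * dx)
    stop("radial observation grid must start at dx/2 (anchored at r = 0)",
         call. = FALSE)
  cc_grid(geometry, L = p[n] + dx / 2, N = n)
}

#' Initial condition on a grid
#'
#' @param grid a \code{\link{cc_grid}}.
#' @param rho1,rho2 density profiles for the G1/post-M and S/G2/M
#'   populations, cells/mm^2: either scalars (uniform) or vectors of
#'   length \code{grid$N}. Must be finite and nonnegative.
#' @return An object of class \code{"cc_ic"}.
#' @export
cc_initial_condition <- function(grid, rho1, rho2) {
  r1 <- rep_len(rho1, grid$N)
  r2 <- rep_len(rho2, grid$N)
  if (any(!is.finite(r1)) || any(!is.finite(r2)) || any(r1 < 0) || any(r2 < 0))
    stop("initial densities must be finite and nonnegative", call. = FALSE)
  structure(list(rho1 = r1, rho2 = r2), class = "cc_ic")
}

#' Solver settings
#'
#' Time integration is method-of-lines. The default is adaptive
#' (\code{deSolve::ode}, \code{lsoda}) with relative/absolute tolerances;
#' a fixed-step classical Runge-Kutta fallback with a diffusive CFL bound
#' \code{dt <= safety * dx^2 / (2 D)} is available (and is the default for
#' Heaviside crowding, whose discontinuous reaction terms defeat adaptive
#' error control). Tolerance-level negative undershoots (more negative than
#' \code{-negativity_tol}) abort the run; smaller ones are clamped to zero.
#'
#' @param method \code{"adaptive"} or \code{"fixed"}.
#' @param rtol,atol tolerances for the adaptive integrator.
#' @param dt fixed step, h (\code{NULL}: derived from the CFL bound).
#' @param cfl_safety safety factor multiplying the CFL step bound.
#' @param negativity_tol clamp threshold for negative undershoots,
#'   cells/mm^2.
#' @param compiled use the compiled right-hand side (default). The pure-R
#'   right-hand side computes the identical discretisation and serves as a
#'   reference implementation.
#' @return An object of class \code{"cc_solver_settings"}.
#' @export
solver_settings <- function(method = c("adaptive", "fixed"),
                            rtol = 1e-6, atol = 1e-9,
                            dt = NULL, cfl_safety = 0.9,
                            negativity_tol = 1e-6, compiled = TRUE) {
  method <- match.arg(method)
  structure(list(method = method, rtol = rtol, atol = atol, dt = dt,
                 cfl_safety = cfl_safety, negativity_tol = negativity_tol,
                 compiled = isTRUE(compiled)),
            class = "cc_solver_settings")
}

## Right-hand side of the method-of-lines system. The state interleaves the
## two populations (rho1_1, rho2_1, rho1_2, rho2_2, ...) so that the
## Jacobian is banded with bandwidth 2, which lets the implicit integrator
## use a cheap banded numerical Jacobian. Diffusion is discretised in
## conservative flux form; for the radial geometry the face areas are the
## face radii and the exact finite-volume cell "area"
## (r_{i+1/2}^2 - r_{i-1/2}^2)/2 equals r_i * dx on this grid, so mass
## 2*pi*sum(rho_i r_i dx) is conserved to integrator tolerance.
cc_rhs <- function(t, y, parms) {
  rho1 <- y[parms$i1]
  rho2 <- y[parms$i2]
  rho <- rho1 + rho2

  lap <- function(u) {
    d <- diff(u) * parms$inv_dx          # interior face gradients
    fl <- parms$face_w * d               # face areas (1 for cartesian)
    (c(fl, 0) - c(0, fl)) * parms$inv_vol
  }

  f <- crowding_value(parms$kind_f, pmax(rho, 0), parms$K1)
  g <- crowding_value(parms$kind_g, pmax(rho, 0), parms$K2)
  trans <- parms$k1 * f * rho1
  divi  <- parms$k2 * g * rho2

  dy <- numeric(2 * parms$N)
  dy[parms$i1] <- parms$D * lap(rho1) - trans + 2 * divi
  dy[parms$i2] <- parms$D * lap(rho2) + trans - divi
  list(dy)
}

#' Simulate the two-population cell-cycle model
#'
#' Solves the coupled reaction-diffusion system
#' \deqn{\partial_t \rho_1 = D \Delta \rho_1 - k_1 \rho_1 f(\rho) + 2 k_2 \rho_2 g(\rho)}
#' \deqn{\partial_t \rho_2 = D \Delta \rho_2 + k_1 \rho_1 f(\rho) - k_2 \rho_2 g(\rho)}
#' with zero-flux boundaries on the given grid, by the method of lines with
#' a conservative second-order finite-volume Laplacian.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param spec a \code{\link{crowding_spec}} object.
#' @param ic a \code{\link{cc_initial_condition}} on \code{grid}.
#' @param grid a \code{\link{cc_grid}}.
#' @param times output times, h; strictly increasing, first \code{>= 0}.
#'   The first output time is the time of the initial condition.
#' @param settings a \code{\link{solver_settings}} object.
#' @return An object of class \code{"cc_sim"}: list with \code{grid},
#'   \code{times}, and matrices \code{rho1}, \code{rho2} indexed
#'   \[time, position\] in cells/mm^2.
#' @examples
#' g <- cc_grid("cartesian1d", 1000, 50)
#' ic <- cc_initial_condition(g, rho1 = ifelse(g$x < 300, 2000, 0), rho2 = 0)
#' sim <- simulate_model(mdck_modes(), crowding_spec(), ic, g, times = c(0, 12, 24))
#' @export
simulate_model <- function(params, spec, ic, grid, times,
                           settings = solver_settings()) {
  stopifnot(inherits(params, "cc_params"), inherits(spec, "crowding_spec"),
            inherits(ic, "cc_ic"), inherits(grid, "cc_grid"))
  if (length(times) < 1 || any(diff(times) <= 0) || times[1] < 0)
    stop("'times' must be nondecreasing with first time >= 0", call. = FALSE)

  N <- grid$N
  dx <- grid$dx
  if (grid$geometry == "radial") {
    face_w <- seq_len(N - 1) * dx        # interior face radii
    inv_vol <- 1 / (grid$x * dx)         # 1 / (r_i dx)
  } else {
    face_w <- rep(1, N - 1)
    inv_vol <- rep(1 / dx, N)
  }
  i1 <- seq(1, 2 * N, by = 2)
  i2 <- i1 + 1
  kind_code <- c(linear = 0, heaviside = 1, constant = 2)
  if (isTRUE(settings$compiled)) {
    rhs_args <- list(func = "cc_derivs", dllname = "crowdcycle",
                     initfunc = "cc_initmod",
                     parms = c(params$D, params$k1, params$k2,
                               params$K1, params$K2,
                               kind_code[[spec$kind_f]],
                               kind_code[[spec$kind_g]],
                               dx, as.numeric(grid$geometry == "radial")))
  } else {
    rhs_args <- list(func = cc_rhs,
                     parms = list(N = N, i1 = i1, i2 = i2,
                                  inv_dx = 1 / dx, face_w = face_w,
                                  inv_vol = inv_vol,
                                  D = params$D, k1 = params$k1,
                                  k2 = params$k2,
                                  K1 = params$K1, K2 = params$K2,
                                  kind_f = spec$kind_f,
                                  kind_g = spec$kind_g))
  }
  y0 <- numeric(2 * N)
  y0[i1] <- ic$rho1
  y0[i2] <- ic$rho2

  # integrate on an internal clock starting at 0
  t_int <- times - times[1]
  if (settings$method == "adaptive") {
    out <- do.call(deSolve::ode,
                   c(list(y = y0,
                          times = if (length(t_int) == 1) c(0, 0) else t_int,
                          method = "lsoda",
                          jactype = "bandint", bandup = 2, banddown = 2,
                          rtol = settings$rtol, atol = settings$atol),
                     rhs_args))
    if (length(t_int) == 1) out <- out[1, , drop = FALSE]
  } else {
    dt <- settings$dt
    if (is.null(dt)) {
      dt <- if (params$D > 0) settings$cfl_safety * dx^2 / (2 * params$D)
            else 0.1 / max(params$k1, params$k2)
    }
    tmax <- max(t_int)
    tfine <- sort(unique(c(seq(0, tmax, by = dt), t_int)))
    out <- do.call(deSolve::ode,
                   c(list(y = y0, times = tfine, method = "rk4"), rhs_args))
    out <- out[match(signif(t_int, 12), signif(tfine, 12)), , drop = FALSE]
  }
  state <- out[, -1, drop = FALSE]
  dimnames(state) <- NULL
  if (any(!is.finite(state))) {
    bad <- which(!apply(is.finite(state), 1, all))[1]
    stop(sprintf("integration failed: non-finite state at t = %g h",
                 times[bad]), call. = FALSE)
  }
  mn <- min(state)
  if (mn < -settings$negativity_tol)
    stop(sprintf("integration failed: negative density %.3g cells/mm^2", mn),
         call. = FALSE)
  state[state < 0] <- 0

  structure(list(grid = grid, times = times,
                 rho1 = state[, i1, drop = FALSE],
                 rho2 = state[, i2, drop = FALSE]),
            class = "cc_sim")
}

#' @export
print.cc_sim <- function(x, ...) {
  cat(sprintf("cc_sim: %s grid (L = %g um, N = %d), %d output times in [%g, %g] h\n",
              x$grid$geometry, x$grid$L, x$grid$N, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @describeIn simulate_model Long-format view: one row per (time, position)
#'   with columns \code{time_h, position_um, rho1, rho2}.
#' @param x,row.names,optional,... standard \code{as.data.frame} arguments.
#' @export
as.data.frame.cc_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_h = rep(x$times, each = x$grid$N),
             position_um = rep(x$grid$x, length(x$times)),
             rho1 = as.vector(t(x$rho1)),
             rho2 = as.vector(t(x$rho2)))
}

#' Total cell number in a simulation snapshot
#'
#' Midpoint (finite-volume) quadrature of the total density. For a radial
#' grid this is the cell count on the disc, \code{2*pi*sum(rho r dr)}; for
#' a Cartesian grid, the count per mm of transverse width,
#' \code{integral of rho dx}. Densities are cells/mm^2 and positions um, so
#' the um -> mm conversion is applied internally.
#'
#' @param result a \code{"cc_sim"} object.
#' @param time_index index into \code{result$times}.
#' @return Cells (radial) or cells per mm transverse width (cartesian1d).
#' @export
total_mass <- function(result, time_index = length(result$times)) {
  if (time_index < 1 || time_index > length(result$times))
    stop("'time_index' out of range", call. = FALSE)
  rho <- result$rho1[time_index, ] + result$rho2[time_index, ]
  g <- result$grid
  if (g$geometry == "radial") {
    2 * pi * sum(rho * g$x * g$dx) / 1e6   # um^2 -> mm^2
  } else {
    sum(rho * g$dx) / 1e3                  # um -> mm
  }
}

#' Position of the tissue edge
#'
#' The outermost position at which a density profile crosses a threshold,
#' located by linear interpolation between the bracketing grid nodes.
#'
#' @param profile density values on the grid nodes, cells/mm^2.
#' @param positions node positions, um (same length, increasing).
#' @param threshold crossing level, cells/mm^2 (\code{> 0}).
#' @return Edge position in um, or \code{NA_real_} when the profile never
#'   reaches the threshold.
#' @export
edge_position <- function(profile, positions, threshold) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be positive", call. = FALSE)
  above <- which(profile >= threshold)
  if (length(above) == 0) return(NA_real_)
  i <- max(above)
  if (i == length(profile)) return(positions[i])
  # interpolate between node i (>= threshold) and node i+1 (< threshold)
  p1 <- profile[i]; p2 <- profile[i + 1]
  positions[i] + (p1 - threshold) / (p1 - p2) * (positions[i + 1] - positions[i])
}

#' Tissue expansion speed
#'
#' Least-squares slope of the edge trajectory over a time window.
#'
#' @param result a \code{"cc_sim"} object.
#' @param threshold edge-detection threshold, cells/mm^2.
#' @param window numeric length-2 time interval, h (default: the full
#'   simulated range).
#' @return Speed, um/h.
#' @export
expansion_speed <- function(result, threshold, window = range(result$times)) {
  sel <- result$times >= window[1] & result$times <= window[2]
  tt <- result$times[sel]
  edges <- vapply(which(sel), function(i)
    edge_position(result$rho1[i, ] + result$rho2[i, ], result$grid$x, threshold),
    numeric(1))
  ok <- is.finite(edges)
  if (sum(ok) < 3)
    stop("need at least 3 output times with a detected edge in the window",
         call. = FALSE)
  unname(stats::coef(stats::lm(edges[ok] ~ tt[ok]))[2])
}

#' Edge trajectory of a simulation
#'
#' @inheritParams expansion_speed
#' @return data.frame with columns \code{time_h}, \code{edge_um}.
#' @export
edge_trajectory <- function(result, threshold) {
  data.frame(time_h = result$times,
             edge_um = vapply(seq_along(result$times), function(i)
               edge_position(result$rho1[i, ] + result$rho2[i, ],
                             result$grid$x, threshold), numeric(1)))
}

#' Plot density profiles of a simulation
#'
#' @param x a \code{"cc_sim"} object.
#' @param which \code{"total"}, \code{"rho1"}, \code{"rho2"} or \code{"both"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.cc_sim <- function(x, which = c("both", "total", "rho1", "rho2"), ...) {
  which <- match.arg(which)
  xl <- if (x$grid$geometry == "radial") "r (um)" else "x (um)"
  if (which == "both") {
    graphics::matplot(x$grid$x, t(x$rho1), type = "l", lty = 1,
                      col = grDevices::hcl.colors(length(x$times), "Reds 3"),
                      xlab = xl, ylab = "density (cells/mm^2)",
                      ylim = c(0, max(x$rho1, x$rho2)), ...)
    graphics::matlines(x$grid$x, t(x$rho2), lty = 2,
                       col = grDevices::hcl.colors(length(x$times), "Greens 3"))
    graphics::legend("topright", c("G1/post-M", "S/G2/M"), lty = c(1, 2),
                     bty = "n")
  } else {
    z <- switch(which, total = x$rho1 + x$rho2, rho1 = x$rho1, rho2 = x$rho2)
    graphics::matplot(x$grid$x, t(z), type = "l", lty = 1,
                      xlab = xl, ylab = "density (cells/mm^2)", ...)
  }
  invisible(x)
}
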