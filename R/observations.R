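#' Replicated density-profile observations
#'
#' The calibration target: long-format tables of cell densities for the two
#' model populations, observed on a shared position grid at a common set of
#' times across one or more replicates. Column layout:
#' \code{replicate, time_h, position_um, rho1, rho2}; a replicate-averaged
#' set carries \code{sd1, sd2} columns instead of \code{replicate}.
#'
#' @param data a data.frame with columns \code{replicate} (integer),
#'   \code{time_h}, \code{position_um}, \code{rho1}, \code{rho2}.
#' @param geometry \code{"radial"} or \code{"cartesian1d"}: the geometry of
#'   the position coordinate.
#' @return An object of class \code{"cc_obs"} (a data.frame).
#' @export
observation_set <- function(data, geometry = c("radial", "cartesian1d")) {
  geometry <- match.arg(geometry)
  need <- c("replicate", "time_h", "position_um", "rho1", "rho2")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("observation data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(data$rho1 < 0, na.rm = TRUE) || any(data$rho2 < 0, na.rm = TRUE))
    stop("observed densities must be nonnegative", call. = FALSE)
  # every (replicate, time) must share the position grid
  pos <- sort(unique(data$position_um))
  sp <- split(data$position_um, interaction(data$replicate, data$time_h,
                                            drop = TRUE))
  same <- vapply(sp, function(p) identical(sort(p), pos), logical(1))
  if (!all(same))
    stop("every (replicate, time) must share the same position grid",
         call. = FALSE)
  data <- data[order(data$replicate, data$time_h, data$position_um), ,
               drop = FALSE]
  rownames(data) <- NULL
  structure(as.data.frame(data), class = c("cc_obs", "data.frame"),
            geometry = geometry, averaged = FALSE)
}

#' @export
print.cc_obs <- function(x, ...) {
  avg <- isTRUE(attr(x, "averaged"))
  cat(sprintf("cc_obs (%s): %s%d time(s) x %d position(s)\n",
              attr(x, "geometry"),
              if (avg) "replicate-averaged, "
              else sprintf("%d replicate(s), ", length(unique(x$replicate))),
              length(unique(x$time_h)), length(unique(x$position_um))))
  NextMethod()
}

#' Replicate-averaged view of an observation set
#'
#' Pointwise mean and sample standard deviation of both population
#' densities across replicates (sd is 0 for a single replicate). The
#' result is invariant to replicate relabelling.
#'
#' @param obs a \code{\link{observation_set}} object.
#' @return A \code{"cc_obs"} data.frame with columns
#'   \code{time_h, position_um, rho1, rho2, sd1, sd2} and attribute
#'   \code{averaged = TRUE}.
#' @export
replicate_average <- function(obs) {
  if (isTRUE(attr(obs, "averaged"))) return(obs)
  key <- interaction(obs$time_h, obs$position_um, drop = TRUE)
  one <- length(unique(obs$replicate)) == 1
  agg <- data.frame(
    time_h = tapply(obs$time_h, key, `[`, 1),
    position_um = tapply(obs$position_um, key, `[`, 1),
    rho1 = tapply(obs$rho1, key, mean),
    rho2 = tapply(obs$rho2, key, mean),
    sd1 = if (one) 0 else tapply(obs$rho1, key, stats::sd),
    sd2 = if (one) 0 else tapply(obs$rho2, key, stats::sd))
  agg <- agg[order(agg$time_h, agg$position_um), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("cc_obs", "data.frame"),
            geometry = attr(obs, "geometry"), averaged = TRUE,
            n_replicates = if (one) 1L else length(unique(obs$replicate)))
}

## Internal: reshape an averaged observation set into matrices
## [time x position] plus the reconstructed grid, ready for the likelihood.
prepare_observations <- function(obs) {
  avg <- replicate_average(obs)
  geometry <- attr(avg, "geometry")
  times <- sort(unique(avg$time_h))
  pos <- sort(unique(avg$position_um))
  grid <- grid_from_positions(pos, geometry)
  o <- order(avg$time_h, avg$position_um)
  m1 <- matrix(avg$rho1[o], nrow = length(times), byrow = TRUE)
  m2 <- matrix(avg$rho2[o], nrow = length(times), byrow = TRUE)
  list(geometry = geometry, times = times, grid = grid,
       rho1 = m1, rho2 = m2,
       ic = cc_initial_condition(grid, m1[1, ], m2[1, ]))
}
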