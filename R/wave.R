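#' Minimum traveling-wave (invasion front) speed
#'
#' Fronts invading the zero-density state are pulled: their speed is set by
#' the linearisation about \code{rho = 0}, giving the minimum speed
#' \deqn{c_{min} = 2 \sqrt{D \lambda(0)}, \quad
#'   \lambda(0) = \tfrac{1}{2}\left(-k_1 - k_2 +
#'   \sqrt{k_1^2 + k_2^2 + 6 k_1 k_2}\right).}
#' The speed depends only on the diffusivity and the intrinsic rates; it is
#' independent of the crowding thresholds \code{K1}, \code{K2} and of the
#' crowding-function shapes.
#'
#' @param params a \code{\link{cc_params}} object.
#' @return Speed, um/h.
#' @examples
#' min_wave_speed(mdck_modes())   # ~33.6 um/h
#' @export
min_wave_speed <- function(params) {
  lam0 <- growth_eigenvalue(params, crowding_spec("constant", "constant"), 0)
  2 * sqrt(params$D * lam0)
}

#' Fisher-KPP-style approximation to the front speed
#'
#' The single-population low-rate approximation \code{sqrt(2 D r)} with
#' \code{r = k1 k2 / (k1 + k2)}, valid when \code{4 r / (k1 + k2) << 1}
#' (well-separated compartment timescales). The regime diagnostic
#' \code{4 r / (k1 + k2)} is returned by \code{\link{wave_report}}.
#'
#' @inheritParams min_wave_speed
#' @return Speed, um/h.
#' @examples
#' fkpp_wave_speed(mdck_modes())  # ~26.1 um/h
#' @export
fkpp_wave_speed <- function(params) {
  sqrt(2 * params$D * intrinsic_rate(params))
}

#' Critical threshold ratio of the reduced Heaviside-crowding model
#'
#' In the reduced model with step crowding functions the S/G2/M bulk
#' density behind the front is positive precisely when
#' \code{K1/K2 > alpha_kappa(kappa)}, where \code{kappa = k1/k2} and
#' \deqn{\alpha_\kappa = \frac{2}{\sqrt{\kappa^2 + 6\kappa + 1} - \kappa + 1}.}
#' The function is decreasing on \code{(0, Inf)} with values in
#' \code{(1/2, 1)} and limit 1/2 as \code{kappa -> Inf}.
#'
#' @param kappa ratio of intrinsic rates \code{k1/k2} (vectorised,
#'   \code{> 0}).
#' @return Dimensionless threshold ratio(s).
#' @export
alpha_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("'kappa' must be positive and finite", call. = FALSE)
  2 / (sqrt(kappa^2 + 6 * kappa + 1) - kappa + 1)
}

#' Reduced-model prediction of bulk and edge S/G2/M densities
#'
#' Replacing the linear crowding ramps by Heaviside steps
#' (\code{f = H(K1 - rho)}, \code{g = H(K2 - rho)}) yields closed-form
#' traveling-wave predictions for the S/G2/M density far behind the front
#' (the bulk) and at its peak near the edge. On the supercritical branch
#' (\code{K1/K2 > alpha_kappa}):
#' \code{rho2_bulk/K2 = (K1/K2)/alpha_kappa - 1},
#' \code{rho2_edge/K2 = (K1/K2) (1 - alpha_kappa)/alpha_kappa}, so the
#' edge-bulk difference reduces to \code{K2 - K1}. On the subcritical
#' branch the bulk S/G2/M density vanishes.
#'
#' @inheritParams min_wave_speed
#' @return A list of class \code{"cc_bulk_edge"}: \code{kappa},
#'   \code{alpha_kappa}, \code{branch} (\code{"supercritical"} or
#'   \code{"subcritical"}), \code{rho2_bulk}, \code{rho2_edge},
#'   \code{edge_minus_bulk} (cells/mm^2).
#' @examples
#' reduced_bulk_edge(mdck_modes())  # rho2_bulk/K2 ~ 0.35, difference 470
#' @export
reduced_bulk_edge <- function(params) {
  kappa <- params$k1 / params$k2
  ak <- alpha_kappa(kappa)
  ratio <- params$K1 / params$K2
  if (ratio > ak) {
    bulk <- params$K2 * (ratio / ak - 1)
    edge <- params$K2 * ratio * (1 - ak) / ak
    branch <- "supercritical"
  } else {
    bulk <- 0
    edge <- params$K2 * ratio * (1 - ak) / ak
    branch <- "subcritical"
  }
  structure(list(kappa = kappa, alpha_kappa = ak, branch = branch,
                 rho2_bulk = bulk, rho2_edge = edge,
                 edge_minus_bulk = edge - bulk),
            class = "cc_bulk_edge")
}

#' @export
print.cc_bulk_edge <- function(x, ...) {
  cat("Reduced Heaviside-crowding traveling-wave prediction\n")
  cat(sprintf("  kappa = k1/k2 = %.4f, alpha_kappa = %.4f (%s branch)\n",
              x$kappa, x$alpha_kappa, x$branch))
  cat(sprintf("  rho2 bulk = %.1f, edge = %.1f, edge - bulk = %.1f cells/mm^2\n",
              x$rho2_bulk, x$rho2_edge, x$edge_minus_bulk))
  invisible(x)
}

#' Measure the front speed and plateau composition of a simulation
#'
#' Delegates the speed to \code{\link{expansion_speed}} and additionally
#' reports the S/G2/M composition of the invaded plateau (mean of rho2 over
#' the trailing 20 percent of the region behind the front at the final
#' output time), for comparison with \code{\link{reduced_bulk_edge}}.
#'
#' @param result a 1-D Cartesian \code{"cc_sim"} with an established front.
#' @param threshold edge threshold, cells/mm^2 (default 1 percent of the
#'   final maximum total density).
#' @param window time window for the speed fit, h (default: final half of
#'   the output times).
#' @return List with \code{speed} (um/h), \code{rho2_bulk_sim}
#'   (cells/mm^2), \code{threshold}, \code{window}.
#' @export
measure_wave_speed <- function(result, threshold = NULL, window = NULL) {
  if (result$grid$geometry != "cartesian1d")
    stop("front-speed measurement expects a 1-D Cartesian simulation",
         call. = FALSE)
  nt <- length(result$times)
  tot_final <- result$rho1[nt, ] + result$rho2[nt, ]
  if (is.null(threshold)) threshold <- 0.01 * max(tot_final)
  if (is.null(window)) {
    tr <- range(result$times)
    window <- c(mean(tr), tr[2])
  }
  speed <- expansion_speed(result, threshold, window)
  edge <- edge_position(tot_final, result$grid$x, threshold)
  if (!is.finite(edge))
    stop("no front detected at the final output time", call. = FALSE)
  trailing <- result$grid$x <= 0.2 * edge
  list(speed = speed,
       rho2_bulk_sim = mean(result$rho2[nt, trailing]),
       threshold = threshold, window = window)
}

#' Traveling-wave analytics report
#'
#' Collects the closed-form wave quantities for a parameter set: the
#' minimum front speed, its Fisher-KPP approximation, the equivalent
#' single-population rate r and the regime diagnostic \code{4r/(k1+k2)},
#' and the reduced-model bulk/edge predictions.
#'
#' @inheritParams min_wave_speed
#' @return A named list (class \code{"cc_wave_report"}).
#' @examples
#' wave_report(mdck_modes())
#' @export
wave_report <- function(params) {
  be <- reduced_bulk_edge(params)
  r <- intrinsic_rate(params)
  structure(list(cmin = min_wave_speed(params),
                 fkpp_cmin = fkpp_wave_speed(params),
                 r = r,
                 regime = 4 * r / (params$k1 + params$k2),
                 kappa = be$kappa,
                 alpha_kappa = be$alpha_kappa,
                 branch = be$branch,
                 rho2_bulk = be$rho2_bulk,
                 rho2_edge = be$rho2_edge,
                 edge_minus_bulk = be$edge_minus_bulk),
            class = "cc_wave_report")
}

#' @export
print.cc_wave_report <- function(x, ...) {
  cat("Traveling-wave analytics\n")
  cat(sprintf("  minimum front speed c_min      = %.2f um/h\n", x$cmin))
  cat(sprintf("  Fisher-KPP approximation       = %.2f um/h\n", x$fkpp_cmin))
  cat(sprintf("  r = k1 k2/(k1+k2)              = %.4f 1/h\n", x$r))
  cat(sprintf("  regime diagnostic 4r/(k1+k2)   = %.2f\n", x$regime))
  cat(sprintf("  reduced model (%s): rho2 bulk = %.0f, edge - bulk = %.0f cells/mm^2\n",
              x$branch, x$rho2_bulk, x$edge_minus_bulk))
  invisible(x)
}
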