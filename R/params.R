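#' Model parameters for the two-population cell-cycle model
#'
#' Bundles the five parameters of the reaction-diffusion model: a common
#' diffusivity and, for each of the two cell-cycle transitions, an intrinsic
#' rate and a crowding threshold. Densities and thresholds share the unit
#' cells/mm^2; they only ever enter the model through the ratio
#' \code{rho / K}, so any common rescaling of densities and thresholds leaves
#' the dynamics unchanged.
#'
#' @param D diffusivity, um^2/h (\code{D >= 0}).
#' @param k1 intrinsic G1 -> S transition rate, 1/h (\code{k1 >= 0};
#'   zero switches the transition off, e.g. for conservation checks).
#' @param k2 intrinsic division (S/G2/M -> G1) rate, 1/h (\code{k2 >= 0}).
#' @param K1 crowding threshold for the G1 -> S transition, cells/mm^2.
#' @param K2 crowding threshold for division, cells/mm^2. \code{K1 < K2} is
#'   a typical finding for epithelia, not an enforced constraint.
#' @return An object of class \code{"cc_params"}: a named list with elements
#'   \code{D, k1, k2, K1, K2}.
#' @examples
#' cc_params(D = 1300, k1 = 0.612, k2 = 0.457, K1 = 4965, K2 = 5435)
#' @export
cc_params <- function(D, k1, k2, K1, K2) {
  stopifnot(length(D) == 1, length(k1) == 1, length(k2) == 1,
            length(K1) == 1, length(K2) == 1)
  vals <- c(D = D, k1 = k1, k2 = k2, K1 = K1, K2 = K2)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite", call. = FALSE)
  if (D < 0) stop("'D' must be nonnegative", call. = FALSE)
  if (k1 < 0) stop("'k1' must be nonnegative", call. = FALSE)
  if (k2 < 0) stop("'k2' must be nonnegative", call. = FALSE)
  if (K1 <= 0) stop("'K1' must be positive", call. = FALSE)
  if (K2 <= 0) stop("'K2' must be positive", call. = FALSE)
  structure(list(D = D, k1 = k1, k2 = k2, K1 = K1, K2 = K2),
            class = "cc_params")
}

#' @export
print.cc_params <- function(x, ...) {
  cat("Cell-cycle model parameters:\n")
  cat(sprintf("  D  = %g um^2/h (diffusivity)\n", x$D))
  cat(sprintf("  k1 = %g 1/h (G1 -> S intrinsic rate)\n", x$k1))
  cat(sprintf("  k2 = %g 1/h (division intrinsic rate)\n", x$k2))
  cat(sprintf("  K1 = %g cells/mm^2 (G1 -> S crowding threshold)\n", x$K1))
  cat(sprintf("  K2 = %g cells/mm^2 (division crowding threshold)\n", x$K2))
  invisible(x)
}

#' Posterior-mode parameter set for MDCK tissue expansions
#'
#' Convenience constructor returning the calibrated posterior-mode estimates
#' for MDCK FUCCI tissue-expansion experiments:
#' \code{(D, k1, k2, K1, K2) = (1300, 0.612, 0.457, 4965, 5435)}.
#' Used throughout examples, the synthetic-data generator defaults and the
#' traveling-wave analytics.
#'
#' @return A \code{\link{cc_params}} object.
#' @export
mdck_modes <- function() {
  cc_params(D = 1300, k1 = 0.612, k2 = 0.457, K1 = 4965, K2 = 5435)
}

#' Crowding-function specification
#'
#' Declares the functional form of the two crowding functions f (modulating
#' the G1 -> S transition, threshold \code{K1}) and g (modulating division,
#' threshold \code{K2}). Each is a nonincreasing function of the total
#' density with values in \[0, 1\] and value 1 at zero density:
#' \itemize{
#'   \item \code{"linear"}: \code{max(1 - rho/K, 0)} — a linear ramp hitting
#'     zero at the threshold;
#'   \item \code{"heaviside"}: 1 below the threshold, 0 at and above it
#'     (the threshold density itself is absorbing, matching the linear
#'     variant's value at \code{rho = K});
#'   \item \code{"constant"}: identically 1 (no density dependence;
#'     \code{f = g = "constant"} is the exponential-growth model).
#' }
#'
#' @param f,g one of \code{"linear"}, \code{"heaviside"}, \code{"constant"}.
#' @return An object of class \code{"crowding_spec"}.
#' @examples
#' crowding_spec()                         # linear/linear (default model)
#' crowding_spec("constant", "constant")   # exponential growth
#' @export
crowding_spec <- function(f = c("linear", "heaviside", "constant"),
                          g = c("linear", "heaviside", "constant")) {
  f <- match.arg(f)
  g <- match.arg(g)
  structure(list(kind_f = f, kind_g = g), class = "crowding_spec")
}

#' @export
print.crowding_spec <- function(x, ...) {
  cat(sprintf("Crowding functions: f = %s (threshold K1), g = %s (threshold K2)\n",
              x$kind_f, x$kind_g))
  invisible(x)
}

#' Evaluate a single crowding function
#'
#' @param kind one of \code{"linear"}, \code{"heaviside"}, \code{"constant"}.
#' @param rho total cell density, cells/mm^2 (vectorised, \code{rho >= 0}).
#' @param K crowding threshold, cells/mm^2 (\code{K > 0}; ignored for
#'   \code{kind = "constant"}).
#' @return Dimensionless values in \[0, 1\], nonincreasing in \code{rho},
#'   equal to 1 at \code{rho = 0}.
#' @examples
#' crowding_value("linear", c(0, 2482.5, 4965, 6000), K = 4965)
#' @export
crowding_value <- function(kind, rho, K = NULL) {
  kind <- match.arg(kind, c("linear", "heaviside", "constant"))
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("'rho' must be finite and nonnegative", call. = FALSE)
  if (kind == "constant") return(rep(1, length(rho)))
  if (is.null(K) || !is.finite(K) || K <= 0)
    stop("'K' must be a positive finite threshold", call. = FALSE)
  switch(kind,
         linear = pmax(1 - rho / K, 0),
         heaviside = as.numeric(rho < K))
}

## Internal: evaluate f and g on a density vector given params + spec.
crowding_fg <- function(params, spec, rho) {
  list(f = crowding_value(spec$kind_f, rho, params$K1),
       g = crowding_value(spec$kind_g, rho, params$K2))
}

#' Local growth matrix of the two-compartment kinetics
#'
#' At a fixed total density the reaction part of the model is linear in
#' \code{(rho1, rho2)} with matrix
#' \deqn{A(\rho) = \begin{pmatrix} -k_1 f(\rho) & 2 k_2 g(\rho) \\
#'   k_1 f(\rho) & -k_2 g(\rho) \end{pmatrix},}
#' the factor 2 encoding division into two daughters. Column sums are 0 and
#' \code{k2 g(rho)}: total density grows only through division.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param spec a \code{\link{crowding_spec}} object.
#' @param rho total density, cells/mm^2 (scalar).
#' @return A 2x2 numeric matrix, units 1/h.
#' @export
growth_matrix <- function(params, spec, rho) {
  fg <- crowding_fg(params, spec, rho)
  a <- params$k1 * fg$f
  b <- params$k2 * fg$g
  matrix(c(-a, a, 2 * b, -b), nrow = 2)
}

#' Dominant eigenvalue of the growth matrix
#'
#' The local net population growth rate: the larger eigenvalue
#' \eqn{\lambda(\rho) = (-(a+b) + \sqrt{(a+b)^2 + 4ab})/2} of the growth
#' matrix, with \eqn{a = k_1 f(\rho)}, \eqn{b = k_2 g(\rho)}. At zero
#' density (where f = g = 1) this reduces to
#' \eqn{\lambda(0) = (-k_1 - k_2 + \sqrt{k_1^2 + k_2^2 + 6 k_1 k_2})/2}.
#' Always real; positive iff both crowding factors are positive, and exactly
#' zero when either factor vanishes.
#'
#' @inheritParams growth_matrix
#' @param rho total density, cells/mm^2 (vectorised).
#' @return Growth rate(s), 1/h.
#' @examples
#' growth_eigenvalue(mdck_modes(), crowding_spec(), 0)   # ~0.2174 /h
#' @export
growth_eigenvalue <- function(params, spec, rho) {
  fg <- crowding_fg(params, spec, rho)
  a <- params$k1 * fg$f
  b <- params$k2 * fg$g
  (-(a + b) + sqrt((a + b)^2 + 4 * a * b)) / 2
}

#' Density-dependent cell-cycle phase durations
#'
#' Under linear crowding the average residence time in G1 (plus the
#' postmitotic pause) at a fixed density is \code{1 / (k1 * (1 - rho/K1)+)}
#' and in S/G2/M it is \code{1 / (k2 * (1 - rho/K2)+)}. Where a crowding
#' factor is zero the corresponding duration is reported as \code{Inf}
#' (the phase is arrested).
#'
#' @param params a \code{\link{cc_params}} object.
#' @param rho total density, cells/mm^2 (vectorised).
#' @return A data.frame with columns \code{rho}, \code{T_G1_postM},
#'   \code{T_SG2M}, \code{T_total} (hours).
#' @examples
#' phase_durations(mdck_modes(), c(0, 4000))
#' @export
phase_durations <- function(params, rho) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("'rho' must be finite and nonnegative", call. = FALSE)
  f <- crowding_value("linear", rho, params$K1)
  g <- crowding_value("linear", rho, params$K2)
  t1 <- ifelse(f > 0, 1 / (params$k1 * f), Inf)
  t2 <- ifelse(g > 0, 1 / (params$k2 * g), Inf)
  data.frame(rho = rho, T_G1_postM = t1, T_SG2M = t2, T_total = t1 + t2)
}

#' Population doubling time
#'
#' Defined as \code{log(2) / lambda(rho)} where \code{lambda} is the dominant
#' growth-matrix eigenvalue: the doubling time of the exponentially growing
#' dominant mode at fixed density. \code{Inf} where growth is arrested.
#'
#' @inheritParams growth_eigenvalue
#' @return Doubling time(s), hours.
#' @export
doubling_time <- function(params, spec, rho) {
  lam <- growth_eigenvalue(params, spec, rho)
  ifelse(lam > 0, log(2) / lam, Inf)
}

#' Intrinsic growth rate of the equivalent single-population model
#'
#' The single-population rate r whose inverse is the summed mean passage
#' time through the two compartments: \code{1/r = 1/k1 + 1/k2}, i.e.
#' \code{r = k1 k2 / (k1 + k2)}.
#'
#' @param params a \code{\link{cc_params}} object.
#' @return Rate, 1/h.
#' @export
intrinsic_rate <- function(params) {
  if (params$k1 + params$k2 == 0) return(0)
  params$k1 * params$k2 / (params$k1 + params$k2)
}
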