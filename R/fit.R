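#' Fit the cell-cycle reaction-diffusion model to density profiles
#'
#' Calibrates the two-population model to replicated density-profile
#' observations by Bayesian ensemble MCMC. The replicate-averaged profile
#' at the earliest observed time is consumed as the initial condition; all
#' later times enter an independent-Gaussian likelihood with an inferred
#' noise scale \code{sigma}. Returns a fitted-model object supporting the
#' usual methods: \code{print}, \code{summary}, \code{coef} (marginal
#' posterior modes), \code{predict} (forward simulation at the modes),
#' \code{residuals}, \code{plot}, \code{simulate} (posterior-predictive
#' observation sets) and \code{as.matrix} (posterior draws).
#'
#' @param obs an \code{\link{observation_set}}.
#' @param model \code{"crowding"}: the full model with linear crowding
#'   functions (parameters D, k1, k2, K1, K2, sigma); or
#'   \code{"exponential"}: the density-independent submodel f = g = 1
#'   (parameters D, k1, k2, sigma), appropriate in the low-density regime.
#' @param priors a \code{\link{cc_priors}} object (default: the standard
#'   boxes for the chosen model).
#' @param settings a \code{\link{mcmc_settings}} object.
#' @param per_replicate if \code{TRUE}, fit the stacked per-replicate
#'   profiles rather than the replicate-averaged view (not the default;
#'   the averaged profile is the standard calibration target).
#' @return An object of class \code{"ccfit"}.
#' @examples
#' \donttest{
#' obs <- expansion_scenario(replicates = 3, noise = 100,
#'                           grid = cc_grid("radial", 4000, 80),
#'                           times = seq(0, 24, 12))
#' fit <- fit_cellcycle(obs, settings = mcmc_settings(steps = 50, seed = 1))
#' coef(fit)
#' }
#' @export
fit_cellcycle <- function(obs, model = c("crowding", "exponential"),
                          priors = NULL, settings = mcmc_settings(),
                          per_replicate = FALSE) {
  model <- match.arg(model)
  if (is.null(priors)) priors <- cc_priors(model)
  if (attr(priors, "model") != model)
    stop("'priors' were built for the ", attr(priors, "model"), " model",
         call. = FALSE)
  target <- if (per_replicate) obs else replicate_average(obs)
  samples <- sample_posterior(target, priors, settings)
  summ <- posterior_summary(samples)
  ident <- identifiability_report(samples)
  structure(list(model = model, samples = samples, summary = summ,
                 identifiability = ident, obs = target, priors = priors,
                 settings = settings, seed = settings$seed),
            class = "ccfit")
}

#' @export
print.ccfit <- function(x, ...) {
  cat(sprintf("Cell-cycle reaction-diffusion model fit (%s model)\n", x$model))
  cat(sprintf("  %d posterior draws (%d walkers x %d sweeps, burn-in %g%%), seed %d\n",
              nrow(x$samples$draws), x$samples$settings$walkers,
              x$samples$settings$steps, 100 * x$samples$settings$burnin,
              x$seed))
  cat("  marginal posterior modes:\n")
  co <- coef(x)
  cat("   ", paste(sprintf("%s = %.4g", names(co), co), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ccfit <- function(object, ...) {
  stats::setNames(object$summary$mode, object$summary$param)
}

#' @export
as.matrix.ccfit <- function(x, ...) x$samples$draws

#' @export
summary.ccfit <- function(object, ...) {
  structure(list(model = object$model, summary = object$summary,
                 identifiability = object$identifiability,
                 acceptance = object$samples$acceptance,
                 rhat = object$samples$rhat, seed = object$seed),
            class = "summary.ccfit")
}

#' @export
print.summary.ccfit <- function(x, ...) {
  cat(sprintf("Posterior summary (%s model), acceptance %.2f\n",
              x$model, x$acceptance))
  print(x$summary, digits = 4)
  cat("\nPractical identifiability (posterior sd / prior sd):\n")
  print(x$identifiability, digits = 3)
  invisible(x)
}

## Parameters at the marginal posterior modes, as cc_params + sigma + spec.
ccfit_point <- function(object) {
  co <- coef(object)
  if (object$model == "exponential") {
    list(params = cc_params(co[["D"]], co[["k1"]], co[["k2"]], 1, 1),
         sigma = co[["sigma"]],
         spec = crowding_spec("constant", "constant"))
  } else {
    list(params = cc_params(co[["D"]], co[["k1"]], co[["k2"]],
                            co[["K1"]], co[["K2"]]),
         sigma = co[["sigma"]],
         spec = crowding_spec("linear", "linear"))
  }
}

#' Forward simulation at the posterior modes
#'
#' @param object a \code{"ccfit"} object.
#' @param times output times, h (default: the observation times).
#' @param settings solver settings (default: the tighter defaults, not the
#'   loosened likelihood tolerances).
#' @param ... unused.
#' @return A \code{"cc_sim"} object on the observation grid, started from
#'   the earliest observed profile.
#' @export
predict.ccfit <- function(object, times = NULL,
                          settings = solver_settings(), ...) {
  prep <- prepare_observations(object$obs)
  if (is.null(times)) times <- prep$times
  pt <- ccfit_point(object)
  simulate_model(pt$params, pt$spec, prep$ic, prep$grid, times, settings)
}

#' @export
residuals.ccfit <- function(object, ...) {
  prep <- prepare_observations(object$obs)
  sim <- predict(object)
  later <- seq_along(prep$times)[-1]
  data.frame(time_h = rep(prep$times[later], each = prep$grid$N),
             position_um = rep(prep$grid$x, length(later)),
             res1 = as.vector(t(prep$rho1[later, , drop = FALSE] -
                                  sim$rho1[later, , drop = FALSE])),
             res2 = as.vector(t(prep$rho2[later, , drop = FALSE] -
                                  sim$rho2[later, , drop = FALSE])))
}

#' Posterior-predictive observation sets
#'
#' Draws parameter vectors from the posterior, forward-simulates each on
#' the observation grid and adds Gaussian observation noise at the drawn
#' \code{sigma} (censored at zero).
#'
#' @param object a \code{"ccfit"} object.
#' @param nsim number of predictive datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of \code{"cc_obs"} observation sets.
#' @export
simulate.ccfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_observations(object$obs)
  priors <- object$priors
  idx <- sample.int(nrow(object$samples$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    tp <- theta_to_params(object$samples$draws[i, ], priors)
    spec <- object$samples$spec
    sim <- simulate_model(tp$params, spec, prep$ic, prep$grid, prep$times,
                          object$settings$solver)
    df <- data.frame(replicate = 1L,
                     time_h = rep(prep$times, each = prep$grid$N),
                     position_um = rep(prep$grid$x, length(prep$times)),
                     rho1 = pmax(as.vector(t(sim$rho1)) +
                                   stats::rnorm(length(sim$rho1), 0, tp$sigma), 0),
                     rho2 = pmax(as.vector(t(sim$rho2)) +
                                   stats::rnorm(length(sim$rho2), 0, tp$sigma), 0))
    observation_set(df, prep$geometry)
  })
}

#' Plot a fitted model
#'
#' \code{type = "posterior"}: kernel-density estimates of the marginal
#' posteriors with the mode marked. \code{type = "fit"}: observed
#' replicate-averaged profiles (points) against the model prediction at
#' the posterior modes (lines), per observation time.
#'
#' @param x a \code{"ccfit"} object.
#' @param type \code{"posterior"} or \code{"fit"}.
#' @param ... unused.
#' @export
plot.ccfit <- function(x, type = c("posterior", "fit"), ...) {
  type <- match.arg(type)
  if (type == "posterior") {
    draws <- x$samples$draws
    np <- ncol(draws)
    old <- graphics::par(mfrow = grDevices::n2mfrow(np), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(old))
    for (j in seq_len(np)) {
      den <- stats::density(draws[, j])
      plot(den, main = "", xlab = colnames(draws)[j])
      graphics::abline(v = x$summary$mode[j], lty = 2)
    }
  } else {
    prep <- prepare_observations(x$obs)
    sim <- predict(x)
    nt <- length(prep$times)
    old <- graphics::par(mfrow = grDevices::n2mfrow(nt), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (i in seq_len(nt)) {
      ylim <- c(0, max(prep$rho1, prep$rho2, sim$rho1, sim$rho2))
      plot(prep$grid$x, prep$rho1[i, ], col = "firebrick", pch = 20,
           cex = 0.5, ylim = ylim, xlab = "position (um)",
           ylab = "density (cells/mm^2)",
           main = sprintf("t = %g h", prep$times[i]))
      graphics::points(prep$grid$x, prep$rho2[i, ], col = "forestgreen",
                       pch = 20, cex = 0.5)
      graphics::lines(sim$grid$x, sim$rho1[i, ], col = "firebrick")
      graphics::lines(sim$grid$x, sim$rho2[i, ], col = "forestgreen")
    }
  }
  invisible(x)
}
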