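## ---- CSV round-tripping ----------------------------------------------

#' Write / read an observation set as long-format CSV
#'
#' Columns \code{replicate, time_h, position_um, rho1, rho2}; a
#' replicate-averaged set is written with \code{sd1, sd2} instead of
#' \code{replicate}. Values round-trip losslessly (full double precision).
#'
#' @param obs a \code{"cc_obs"} object.
#' @param path file path.
#' @return \code{write_observations}: the path, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(format(as.data.frame(obs), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @param geometry geometry of the position coordinate (not stored in the
#'   CSV itself; recorded in the provenance YAML by the pipeline).
#' @return \code{read_observations}: a \code{"cc_obs"} object.
#' @export
read_observations <- function(path, geometry = c("radial", "cartesian1d")) {
  geometry <- match.arg(geometry)
  df <- utils::read.csv(path)
  if ("sd1" %in% names(df)) {
    obs <- structure(df[order(df$time_h, df$position_um), , drop = FALSE],
                     class = c("cc_obs", "data.frame"),
                     geometry = geometry, averaged = TRUE)
    rownames(obs) <- NULL
    obs
  } else {
    observation_set(df, geometry)
  }
}

#' Write / read a simulation result as long-format CSV
#'
#' Columns \code{time_h, position_um, rho1, rho2}.
#'
#' @param sim a \code{"cc_sim"} object.
#' @param path file path.
#' @return \code{write_simulation}: the path, invisibly.
#' @export
write_simulation <- function(sim, path) {
  utils::write.csv(format(as.data.frame(sim), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_simulation
#' @param geometry grid geometry of the stored result.
#' @return \code{read_simulation}: a \code{"cc_sim"} object.
#' @export
read_simulation <- function(path, geometry = c("radial", "cartesian1d")) {
  geometry <- match.arg(geometry)
  df <- utils::read.csv(path)
  need <- c("time_h", "position_um", "rho1", "rho2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("simulation CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  times <- sort(unique(df$time_h))
  grid <- grid_from_positions(sort(unique(df$position_um)), geometry)
  df <- df[order(df$time_h, df$position_um), ]
  structure(list(grid = grid, times = times,
                 rho1 = matrix(df$rho1, nrow = length(times), byrow = TRUE),
                 rho2 = matrix(df$rho2, nrow = length(times), byrow = TRUE)),
            class = "cc_sim")
}

## ---- run configuration ------------------------------------------------

## Fetch required keys from a config block; missing keys are reported by
## their full dotted path.
need_keys <- function(block, keys, where) {
  miss <- setdiff(keys, names(block))
  if (length(miss) > 0)
    stop("config validation: missing key(s) ",
         paste(paste0(where, ".", miss), collapse = ", "), call. = FALSE)
  block
}

config_params <- function(pb, where = "params") {
  need_keys(pb, c("D", "k1", "k2", "K1", "K2"), where)
  cc_params(pb$D, pb$k1, pb$k2, pb$K1, pb$K2)
}

config_spec <- function(cb) {
  if (is.null(cb)) return(crowding_spec())
  crowding_spec(if (is.null(cb$f)) "linear" else cb$f,
                if (is.null(cb$g)) "linear" else cb$g)
}

config_solver <- function(sb) {
  if (is.null(sb)) return(solver_settings())
  do.call(solver_settings, sb)
}

#' Read a YAML run configuration
#'
#' A run configuration carries a top-level \code{seed} and
#' \code{out_dir}, plus one block per pipeline stage (\code{simulate},
#' \code{synth}, \code{fit}, \code{wave}); each stage validates its own
#' block before computing and names any missing keys.
#'
#' @param path YAML file path.
#' @return A named list of class \code{"cc_config"} with attribute
#'   \code{hash} (md5 of the file) and \code{path}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "cc_config",
            hash = unname(tools::md5sum(path)), path = path)
}

## Common provenance fields embedded in every artifact.
provenance <- function(config, seed) {
  list(seed = seed, config_hash = attr(config, "hash"),
       config_path = attr(config, "path"))
}

stage_log <- function(quiet, stage, t0, ...) {
  if (quiet) return(invisible())
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(proc.time()[3] - t0), paste(..., collapse = " ")))
}

## ---- pipeline stages --------------------------------------------------

#' Run the simulation stage of a configuration
#'
#' Validates the \code{simulate} block, forward-simulates the model and
#' writes \code{simulation.csv} (long format) plus \code{report.json}
#' containing the mass trajectory and relative drift, the edge trajectory
#' and the fitted expansion speed.
#'
#' @param config a \code{"cc_config"} or a path to one.
#' @param out_dir output directory (default: the config's \code{out_dir},
#'   or a temporary directory).
#' @param quiet suppress the one-line stage log.
#' @return Invisibly, a list with \code{sim}, \code{report} and the output
#'   paths.
#' @export
run_simulate <- function(config, out_dir = NULL, quiet = TRUE) {
  t0 <- proc.time()[3]
  if (is.character(config)) config <- read_run_config(config)
  sb <- need_keys(config, "simulate", "(top level)")$simulate
  need_keys(sb, c("params", "grid", "initial", "times"), "simulate")
  params <- config_params(sb$params, "simulate.params")
  spec <- config_spec(sb$crowding)
  gb <- need_keys(sb$grid, c("geometry", "L", "N"), "simulate.grid")
  grid <- cc_grid(gb$geometry, gb$L, gb$N)
  ib <- sb$initial
  ic <- if (!is.null(ib$profile_csv)) {
    s <- read_simulation(ib$profile_csv, grid$geometry)
    cc_initial_condition(grid, s$rho1[1, ], s$rho2[1, ])
  } else {
    need_keys(ib, c("rho1", "rho2", "step_at"), "simulate.initial")
    w <- if (is.null(ib$smoothing)) 0 else ib$smoothing
    cc_initial_condition(grid,
                         ramp_profile(grid$x, ib$step_at, ib$rho1, w),
                         ramp_profile(grid$x, ib$step_at, ib$rho2, w))
  }
  times <- if (is.list(sb$times))
    seq(sb$times$from, sb$times$to, by = sb$times$by)
  else as.numeric(sb$times)
  sim <- simulate_model(params, spec, ic, grid, times, config_solver(sb$solver))

  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("ccrun")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "simulation.csv")
  write_simulation(sim, csv)

  mass <- vapply(seq_along(times), function(i) total_mass(sim, i), numeric(1))
  thr <- if (!is.null(sb$report$threshold)) sb$report$threshold
         else 0.01 * max(sim$rho1[1, ] + sim$rho2[1, ])
  edges <- edge_trajectory(sim, thr)
  speed <- tryCatch(expansion_speed(sim, thr), error = function(e) NA_real_)
  report <- c(provenance(config, config$seed), list(
    times_h = times, total_mass = mass,
    mass_rel_drift = max(abs(mass - mass[1])) / mass[1],
    edge_threshold = thr, edge_um = edges$edge_um,
    expansion_speed_um_h = speed))
  json <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA)
  stage_log(quiet, "simulate", t0,
            sprintf("mass drift %.2e, speed %.3g um/h",
                    report$mass_rel_drift, speed))
  invisible(list(sim = sim, report = report, csv = csv, json = json))
}

#' Run the synthetic-data stage of a configuration
#'
#' Validates the \code{synth} block, generates the requested scenario and
#' writes \code{observations.csv}, \code{observations_avg.csv} and a
#' provenance YAML recording the scenario arguments, seed and config hash.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with \code{obs} and the output paths.
#' @export
run_synth <- function(config, out_dir = NULL, quiet = TRUE) {
  t0 <- proc.time()[3]
  if (is.character(config)) config <- read_run_config(config)
  sb <- need_keys(config, "synth", "(top level)")$synth
  need_keys(sb, "scenario", "synth")
  seed <- if (!is.null(sb$seed)) sb$seed
          else if (!is.null(config$seed)) config$seed else 1L
  args <- sb[setdiff(names(sb), c("scenario", "params", "crowding", "grid"))]
  args$seed <- seed
  if (!is.null(sb$params)) args$params <- config_params(sb$params, "synth.params")
  if (!is.null(sb$crowding)) args$spec <- config_spec(sb$crowding)
  if (!is.null(sb$grid))
    args$grid <- cc_grid(sb$grid$geometry, sb$grid$L, sb$grid$N)
  res <- switch(sb$scenario,
                expansion = do.call(expansion_scenario, args),
                colonization = do.call(colonization_scenario, args),
                scratch = do.call(scratch_scenario, args),
                stop("config validation: synth.scenario must be one of ",
                     "expansion, colonization, scratch", call. = FALSE))
  obs <- if (sb$scenario == "colonization") res$obs else res

  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("ccrun")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "observations.csv")
  write_observations(obs, csv)
  avg_csv <- file.path(out_dir, "observations_avg.csv")
  write_observations(replicate_average(obs), avg_csv)
  prov <- file.path(out_dir, "observations.yaml")
  plain <- args[!vapply(args, is.object, logical(1))]
  plain$seed <- NULL   # recorded once, in the provenance block
  yaml::write_yaml(c(list(scenario = sb$scenario,
                          geometry = attr(obs, "geometry")),
                     plain, provenance(config, seed)), prov)
  stage_log(quiet, "synth", t0, sb$scenario,
            sprintf("%d rows, seed %d", nrow(obs), seed))
  invisible(list(obs = obs, csv = csv, avg_csv = avg_csv, yaml = prov))
}

#' Run the calibration stage of a configuration
#'
#' Validates the \code{fit} block, reads the observation CSV, fits the
#' requested model and writes \code{posterior.csv} (one column per
#' parameter, one row per post-burn-in draw) and \code{summary.json}
#' (modes, sds, credible intervals, convergence diagnostics,
#' identifiability verdicts, acceptance, seed). Convergence warnings are
#' reported in the summary, not raised as errors.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with the \code{ccfit} object and the output
#'   paths.
#' @export
run_fit <- function(config, out_dir = NULL, quiet = TRUE) {
  t0 <- proc.time()[3]
  if (is.character(config)) config <- read_run_config(config)
  fb <- need_keys(config, "fit", "(top level)")$fit
  need_keys(fb, c("data", "geometry"), "fit")
  obs <- read_observations(fb$data, fb$geometry)
  model <- if (is.null(fb$model)) "crowding" else fb$model
  margs <- if (is.null(fb$mcmc)) list() else fb$mcmc
  if (!is.null(config$seed) && is.null(margs$seed)) margs$seed <- config$seed
  settings <- do.call(mcmc_settings, margs)
  fit <- suppressWarnings(fit_cellcycle(obs, model = model,
                                        settings = settings))

  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("ccrun")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  post_csv <- file.path(out_dir, "posterior.csv")
  utils::write.csv(as.data.frame(as.matrix(fit)), post_csv,
                   row.names = FALSE, quote = FALSE)
  summ <- c(provenance(config, settings$seed), list(
    model = model,
    summary = fit$summary,
    identifiability = fit$identifiability,
    acceptance = fit$samples$acceptance,
    rhat = as.list(fit$samples$rhat),
    convergence_warning = any(fit$samples$rhat > 1.05, na.rm = TRUE)))
  json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  stage_log(quiet, "fit", t0, model,
            sprintf("%d draws, acceptance %.2f", nrow(as.matrix(fit)),
                    fit$samples$acceptance))
  invisible(list(fit = fit, posterior_csv = post_csv, json = json))
}

#' Run the traveling-wave analytics stage of a configuration
#'
#' Validates the \code{wave} block and writes \code{wave.json} with the
#' closed-form front-speed and reduced-model quantities of
#' \code{\link{wave_report}}.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with the report and the output path.
#' @export
run_wave <- function(config, out_dir = NULL, quiet = TRUE) {
  t0 <- proc.time()[3]
  if (is.character(config)) config <- read_run_config(config)
  wb <- need_keys(config, "wave", "(top level)")$wave
  params <- config_params(need_keys(wb, "params", "wave")$params,
                          "wave.params")
  rep <- wave_report(params)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("ccrun")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- file.path(out_dir, "wave.json")
  jsonlite::write_json(c(provenance(config, config$seed), unclass(rep)),
                       json, auto_unbox = TRUE, digits = NA)
  stage_log(quiet, "wave", t0, sprintf("cmin %.3g um/h", rep$cmin))
  invisible(list(report = rep, json = json))
}
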