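#' Full experiment configuration
#'
#' Bundles geometry, grid, mechanics, plasticity, remodeling and
#' dynamical-system parameters with the follow-up settings into one
#' validated, serialisable configuration; a run is reproducible from its
#' configuration plus a seed.
#'
#' @param r_lumen,r_iel,r_outer Initial radii (mm).
#' @param h Grid step (mm).
#' @param smc_fraction Initial SMC wall-area fraction.
#' @param r_smc,r_ecm SMC and ECM element radii (mm).
#' @param stiffness Membrane stiffnesses (lumen wall, IEL, external wall).
#' @param porosity_threshold IEL stress opening SMC passage.
#' @param shear_drop Imposed initial fractional drop of wall shear below the
#'   baseline (0 = basic solution; 0.5 = the hyperplasia stimulus).
#' @param horizon_h Follow-up duration (h).
#' @param n_runs Ensemble size.
#' @param stop_occlusion Occlusion fraction at which a run arrests
#'   (default 0.5).
#' @param mechanics,plasticity,remodeling,ds Parameter objects; defaults are
#'   built consistently with the radii above.
#' @param log_events Keep the per-step event log in the run object.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(r_lumen = 0.24, r_iel = 0.28, r_outer = 0.3,
                              h = 0.01, smc_fraction = 0.25,
                              r_smc = 0.005, r_ecm = 0.004,
                              stiffness = c(1, 2, 50),
                              porosity_threshold = 0,
                              shear_drop = 0, horizon_h = 240, n_runs = 10,
                              stop_occlusion = 0.5,
                              mechanics = mechanics_params(r_smc = r_smc),
                              plasticity = plasticity_params(),
                              remodeling = remodeling_params(r_smc = r_smc,
                                                             r_ecm = r_ecm),
                              ds = NULL, log_events = FALSE) {
  stopifnot(0 < r_lumen, r_lumen < r_iel, r_iel < r_outer,
            smc_fraction >= 0, smc_fraction < 1,
            shear_drop >= 0, shear_drop < 1, horizon_h >= 0,
            stop_occlusion > 0, stop_occlusion <= 1, n_runs >= 1)
  if (is.null(ds))
    ds <- ds_params(shear_drop = shear_drop,
                    turnover = plasticity$alpha1 * smc_fraction /
                      plasticity$mitotic_cycle,
                    activity = function(t) macrophage_activity(t, plasticity))
  structure(list(r_lumen = r_lumen, r_iel = r_iel, r_outer = r_outer,
                 h = h, smc_fraction = smc_fraction, r_smc = r_smc,
                 r_ecm = r_ecm, stiffness = stiffness,
                 porosity_threshold = porosity_threshold,
                 shear_drop = shear_drop, horizon_h = horizon_h,
                 n_runs = n_runs, stop_occlusion = stop_occlusion,
                 mechanics = mechanics, plasticity = plasticity,
                 remodeling = remodeling, ds = ds, log_events = log_events),
            class = "experiment_config")
}

#' The study presets
#'
#' * `basic_solution`: the stationary healthy vein at implantation (25%
#'   SMCs, no shear perturbation, 240 h).
#' * `early_hyperplasia`: 1 day of adaptation under a 50% shear drop, with
#'   motility variants `"b"` (random motion only), `"c"` (plus cell-cell
#'   repulsion) and `"d"` (plus matrix invasion with `n_e = 3`).
#' * `late_hyperplasia`: 1 month (720 h) follow-up.
#' * `cross_validation`: 4 months (2880 h), N = 10, radii
#'   0.3 / 0.28 / 0.24 mm and a 50% shear drop, for calibration of the
#'   reduced dynamical system.
#'
#' Months are 30 days throughout.
#'
#' @param name Preset name.
#' @param variant For `early_hyperplasia`: `"b"`, `"c"` or `"d"`.
#' @return An `experiment_config`.
#' @export
preset_experiments <- function(name = c("basic_solution",
                                        "early_hyperplasia",
                                        "late_hyperplasia",
                                        "cross_validation"),
                               variant = "d") {
  name <- match.arg(name)
  switch(name,
    basic_solution = experiment_config(shear_drop = 0, horizon_h = 240,
                                       n_runs = 10),
    early_hyperplasia = {
      toggles <- switch(variant,
        b = c(random = TRUE, repulsion = FALSE, invasion = FALSE,
              chemotaxis = FALSE),
        c = c(random = TRUE, repulsion = TRUE, invasion = FALSE,
              chemotaxis = FALSE),
        d = c(random = TRUE, repulsion = TRUE, invasion = TRUE,
              chemotaxis = FALSE),
        stop("unknown early-hyperplasia variant: ", variant, call. = FALSE))
      experiment_config(shear_drop = 0.5, horizon_h = 24, n_runs = 10,
                        remodeling = remodeling_params(forces = toggles,
                                                       n_e = 3))
    },
    late_hyperplasia = experiment_config(shear_drop = 0.5, horizon_h = 720,
                                         n_runs = 10),
    cross_validation = experiment_config(shear_drop = 0.5,
                                         horizon_h = 2880, n_runs = 10,
                                         remodeling = remodeling_params(
                                           dt_ibm = 1 / 10))
  )
}

#' Run one seeded hybrid simulation
#'
#' The hourly time-split driver: the mechanical fields are recomputed
#' whenever the lumen has moved more than the tolerance since the last
#' update; the stochastic plasticity step is interrogated every hour; the
#' resulting event batch drives the immersed-boundary tissue relaxation with
#' the inward/outward adjustment. The run halts at the horizon or at the
#' first hour the occlusion fraction reaches `stop_occlusion`.
#'
#' @param config An `experiment_config`.
#' @param seed Integer seed; all stochastic components derive named
#'   sub-streams from it.
#' @return An object of class `veinsim_run`: `trajectory` (hourly tibble),
#'   `state` (final `section`, `agents`, `ecm`), `events` (if logged),
#'   `config`, `seed`, `status`.
#' @export
run_simulation <- function(config, seed = 1) {
  rng <- make_run_rng(seed)
  section <- build_basic_geometry(config$r_lumen, config$r_iel,
                                  config$r_outer, h = config$h,
                                  stiffness = config$stiffness,
                                  porosity_threshold =
                                    config$porosity_threshold,
                                  r_smc = config$r_smc)
  seeded <- seed_cells(section, config$smc_fraction, rng$seeding,
                       r_smc = config$r_smc, r_ecm = config$r_ecm,
                       mitotic_cycle = config$plasticity$mitotic_cycle,
                       ecm_cycle = config$plasticity$ecm_cycle)
  agents <- seeded$agents; ecm <- seeded$ecm
  mech <- config$mechanics
  rem <- config$remodeling
  ws <- ibm_workspace(section$grid, rem)

  # baseline mechanics: tau_bar such that the initial state sits shear_drop
  # below baseline (shear_drop = 0 reproduces the basic-solution balance)
  flow0 <- solve_lumen_flow(section, mech)
  if (is.null(mech$tau_bar))
    mech$tau_bar <- mean(flow0$tau_wall) / (1 - config$shear_drop)
  a0 <- sqrt(polygon_area(section$lumen_wall$points) / pi)
  b0 <- sqrt(polygon_area(section$external_wall$points) / pi)
  sigma_profile <- function(sec) {
    cc <- grid_centres(sec$grid)
    rho <- sqrt(outer(cc$x^2, cc$y^2, "+"))
    strain_energy_density(rho, a0, b0, mech)
  }
  sigma0 <- sigma_profile(section)
  wall0 <- section$region == REGION_INTIMA | section$region == REGION_MEDIA
  sigma_bar <- mean(sigma0[wall0])

  fields <- compute_fields(section, mech)
  dsig_rel <- (fields$sigma - sigma0) / sigma_bar
  dsig_rel[section$region == REGION_LUMEN |
             section$region == REGION_EXTERNAL] <- 0

  initial_lumen <- polygon_area(section$lumen_wall$points)
  traj <- vector("list", config$horizon_h + 1)
  traj[[1]] <- trajectory_row(0, section, agents, initial_lumen, 0, 0, NA)
  events <- if (config$log_events) list() else NULL
  status <- "horizon"
  t_end <- 0
  if (config$horizon_h >= 1) for (t in seq_len(config$horizon_h)) {
    if (should_update_mechanics(fields$lumen_snapshot, section$lumen_wall,
                                mech)) {
      fields <- compute_fields(section, mech)
      dsig_rel <- (fields$sigma - sigma0) / sigma_bar
      dsig_rel[section$region == REGION_LUMEN |
                 section$region == REGION_EXTERNAL] <- 0
    }
    sp <- step_plasticity(agents, section, fields, dsig_rel, t,
                          rng$plasticity, config$plasticity)
    agents <- sp$agents
    rx <- relax_tissue(section, agents, ecm, sp$batch, fields, mech, rem,
                       rng, ws)
    section <- rx$section; agents <- rx$agents; ecm <- rx$ecm
    if (config$log_events && nrow(sp$batch) > 0)
      events[[length(events) + 1]] <- dplyr::mutate(sp$batch, t_h = t,
                                                    .before = 1)
    traj[[t + 1]] <- trajectory_row(t, section, agents, initial_lumen,
                                    rx$diagnostics$net_source_area,
                                    rx$diagnostics$adjust_term,
                                    rx$diagnostics$membrane_energy)
    t_end <- t
    if (traj[[t + 1]]$occlusion >= config$stop_occlusion) {
      status <- "arrested"
      break
    }
  }
  structure(list(
    trajectory = dplyr::bind_rows(traj[!vapply(traj, is.null, logical(1))]),
    state = list(section = section, agents = agents, ecm = ecm),
    events = if (config$log_events) dplyr::bind_rows(events),
    config = config, seed = seed, status = status, t_end = t_end,
    tau_bar = mech$tau_bar), class = "veinsim_run")
}

trajectory_row <- function(t, section, agents, initial_lumen, net_src, adj,
                           energy) {
  a <- section_areas(section)
  live <- agents$alive
  tibble::tibble(
    t_h = t, lumen_area = a[["lumen"]], intimal_area = a[["intima"]],
    medial_area = a[["media"]],
    occlusion = occlusion_fraction(section, initial_lumen),
    smc_intima = sum(live & agents$layer == "intima"),
    smc_media = sum(live & agents$layer == "media"),
    net_source_area = net_src, adjust_term = adj,
    membrane_energy = energy)
}

#' @export
print.veinsim_run <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf(paste0("<veinsim_run> seed %d, %s at t = %d h; occlusion ",
                     "%.1f%%, SMC %d intima / %d media\n"),
              x$seed, x$status, x$t_end, 100 * last$occlusion,
              last$smc_intima, last$smc_media))
  invisible(x)
}

#' Hourly trajectory of a run as a tibble
#' @param x A `veinsim_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.veinsim_run <- function(x, ...) x$trajectory

#' Run an ensemble of independent seeded simulations
#'
#' @param config An `experiment_config`.
#' @param N Number of runs (defaults to `config$n_runs`).
#' @param base_seed Base seed; run `i` uses `base_seed + i - 1`.
#' @return An object of class `veinsim_ensemble`: `mean` (per-hour tibble of
#'   mean and SD of the lumen/intimal/medial areas, each normalised to its
#'   initial value), `runs` (list of `veinsim_run`), `failed` (seeds of any
#'   failed runs).
#' @export
run_ensemble <- function(config, N = config$n_runs, base_seed = 1) {
  stopifnot(N >= 1)
  runs <- vector("list", N)
  failed <- integer(0)
  for (i in seq_len(N)) {
    seed_i <- base_seed + i - 1
    runs[[i]] <- tryCatch(run_simulation(config, seed_i), error = function(e) {
      warning("run with seed ", seed_i, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(runs[[i]])) failed <- c(failed, seed_i)
  }
  done <- runs[!vapply(runs, is.null, logical(1))]
  if (length(done) == 0) stop("all ensemble runs failed", call. = FALSE)
  norm_traj <- lapply(seq_along(done), function(i) {
    tr <- done[[i]]$trajectory
    dplyr::transmute(tr, run = i, t_h = .data$t_h,
                     lumen = .data$lumen_area / .data$lumen_area[1],
                     intima = .data$intimal_area / .data$intimal_area[1],
                     media = .data$medial_area / .data$medial_area[1])
  })
  mean_tr <- dplyr::bind_rows(norm_traj) |>
    dplyr::group_by(.data$t_h) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     lumen_mean = mean(.data$lumen),
                     lumen_sd = stats::sd(.data$lumen),
                     intima_mean = mean(.data$intima),
                     intima_sd = stats::sd(.data$intima),
                     media_mean = mean(.data$media),
                     media_sd = stats::sd(.data$media),
                     .groups = "drop")
  structure(list(mean = mean_tr, runs = done, failed = failed,
                 config = config, base_seed = base_seed),
            class = "veinsim_ensemble")
}

#' @export
print.veinsim_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<veinsim_ensemble> %d runs (base seed %d), %d h; ",
                     "final mean normalised lumen area %.3f\n"),
              length(x$runs), x$base_seed, max(x$mean$t_h),
              x$mean$lumen_mean[nrow(x$mean)]))
  invisible(x)
}

#' Mean normalised trajectory of an ensemble
#' @param x A `veinsim_ensemble`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.veinsim_ensemble <- function(x, ...) x$mean

#' Daily calibration target from an ensemble
#'
#' Downsamples the ensemble's hourly mean normalised trajectory to daily
#' samples in the format [calibrate_gamma()] expects.
#'
#' @param ensemble A `veinsim_ensemble`.
#' @return Tibble with `day`, `lumen_norm`, `intimal_norm`.
#' @export
ensemble_daily_target <- function(ensemble) {
  m <- ensemble$mean
  keep <- m$t_h %% 24 == 0
  tibble::tibble(day = m$t_h[keep] / 24,
                 lumen_norm = m$lumen_mean[keep],
                 intimal_norm = m$intima_mean[keep])
}

#' Coefficient of variation of nearest-neighbour distances
#'
#' The quantitative stand-in for the visual uniformity of the intimal SMC
#' distribution across the motility variants: lower CV means a more uniform
#' (histology-like) distribution.
#'
#' @param agents Agent tibble.
#' @param layer Layer to evaluate (default `"intima"`).
#' @return CV (sd/mean) of nearest-neighbour distances, or `NA` with fewer
#'   than 3 cells.
#' @export
nn_distance_cv <- function(agents, layer = "intima") {
  sel <- agents$alive & agents$layer == layer
  x <- agents$x[sel]; y <- agents$y[sel]
  n <- length(x)
  if (n < 3) return(NA_real_)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  stats::sd(nn) / mean(nn)
}

#' Write the hourly trajectory of a run to CSV
#' @param run A `veinsim_run`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  readr::write_csv(run$trajectory, path)
  invisible(path)
}

#' Save a state snapshot as a single JSON container
#'
#' One hierarchical text container per saved time: the agent table, the
#' gridded ECM density and region mask, and the three membrane point lists.
#'
#' @param state List with `section`, `agents`, `ecm` (as in
#'   `veinsim_run$state`).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(state, path) {
  rlang::check_installed("jsonlite")
  sec <- state$section
  obj <- list(
    grid = list(nx = sec$grid$nx, ny = sec$grid$ny, h = sec$grid$h,
                origin = sec$grid$origin),
    agents = state$agents[, c("id", "x", "y", "layer")],
    ecm_density = state$ecm$density,
    region = sec$region,
    membranes = list(lumen_wall = sec$lumen_wall$points,
                     iel = sec$iel$points,
                     external_wall = sec$external_wall$points))
  jsonlite::write_json(obj, path, digits = 10, matrix = "columnmajor")
  invisible(path)
}

#' @importFrom rlang .data
NULL
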