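#' Reduced dynamical-system parameters
#'
#' The zero-dimensional counterpart of the hybrid model: intimal area grows
#' at a rate proportional to the relative wall-shear deficit under constant
#' flow, with gain `gamma` (the counterpart of the intimal division gain
#' `alpha5`), and the lumen loses the same area (inward growth against a
#' fixed IEL).
#'
#' @param gamma Intimal-growth gain (dimensionless).
#' @param shear_drop Initial fractional shear-stress drop from baseline
#'   (0.5 for the cross-validation setup).
#' @param turnover Baseline intimal area-turnover rate (per hour): the
#'   fraction of intimal area cycling through SMC mitosis per hour in the
#'   basic solution. Defaults to `alpha1 * smc_fraction / mitotic_cycle`
#'   evaluated at the package defaults.
#' @param activity Inflammation envelope `A(t)` as a function of time in
#'   hours; defaults to the constant 1 (no envelope).
#' @return An object of class `ds_params`.
#' @export
ds_params <- function(gamma = 4.6, shear_drop = 0.5,
                      turnover = 0.05 * 0.25 / 12,
                      activity = function(t) rep(1, length(t))) {
  stopifnot(gamma >= 0, shear_drop >= 0, shear_drop < 1, turnover > 0)
  structure(list(gamma = gamma, shear_drop = shear_drop,
                 turnover = turnover, activity = activity),
            class = "ds_params")
}

#' Simulate the reduced dynamical system
#'
#' Explicit time stepping of `dA_I/dt = turnover * gamma * A(t) *
#' (dtau/tau_bar) * A_I`, where the relative shear deficit is recomputed at
#' every step from the Poiseuille shear at the current lumen radius under
#' constant flow (`tau ~ 1/r^3`), starting from a drop of `shear_drop`.
#' The lumen loses the area the intima gains (inward growth, IEL fixed);
#' the medial area is constant. Output is sampled daily.
#'
#' @param initial Named list or vector with radii `R_outer`, `re_iel`,
#'   `r_lumen` (mm), strictly ordered.
#' @param params A `ds_params`.
#' @param horizon Follow-up duration (days).
#' @param substeps_per_day Internal explicit substeps per day (default 24,
#'   i.e. hourly, matching the hybrid model's biology step).
#' @return A tibble: `day`, `t_h`, `lumen_area`, `intimal_area`,
#'   `medial_area` (mm^2), `lumen_norm`, `intimal_norm`, `medial_norm`
#'   (normalised on day 0), `collapsed` flag.
#' @export
ds_simulate <- function(initial, params, horizon, substeps_per_day = 24) {
  stopifnot(horizon > 0)
  R <- initial[["R_outer"]]; re <- initial[["re_iel"]]
  r0 <- initial[["r_lumen"]]
  stopifnot(0 < r0, r0 < re, re < R)
  A_L <- pi * r0^2
  A_I <- pi * (re^2 - r0^2)
  A_M <- pi * (R^2 - re^2)
  tau_rel0 <- 1 - params$shear_drop   # tau(r0) / tau_bar
  dt_h <- 24 / substeps_per_day
  days <- 0:horizon
  out_L <- out_I <- numeric(horizon + 1)
  out_L[1] <- A_L; out_I[1] <- A_I
  collapsed <- FALSE
  # inflammation envelope evaluated once for all substep times
  act <- params$activity((seq_len(horizon * substeps_per_day) - 1) * dt_h)
  act <- rep_len(act, horizon * substeps_per_day)
  gain <- params$turnover * params$gamma * dt_h
  r0_3 <- r0^3
  for (d in seq_len(horizon)) {
    if (!collapsed) {
      base <- (d - 1) * substeps_per_day
      for (k in seq_len(substeps_per_day)) {
        deficit <- 1 - tau_rel0 * r0_3 / sqrt(A_L / pi)^3
        if (deficit < 0) deficit <- 0
        dA <- gain * act[base + k] * deficit * A_I
        A_I <- A_I + dA
        A_L <- A_L - dA
        if (A_L <= 0) { A_L <- 0; collapsed <- TRUE; break }
      }
    }
    out_L[d + 1] <- A_L; out_I[d + 1] <- A_I
  }
  tibble::tibble(day = days, t_h = days * 24,
                 lumen_area = out_L, intimal_area = out_I,
                 medial_area = A_M,
                 lumen_norm = out_L / out_L[1],
                 intimal_norm = out_I / out_I[1],
                 medial_norm = 1,
                 collapsed = collapsed)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param bounds Search interval for `gamma`.
#' @param mutation_sd Gaussian mutation standard deviation (in units of the
#'   search interval width).
#' @param crossover_rate Blend-crossover probability.
#' @param tournament Tournament size for selection.
#' @param patience Generations without improvement before an early stop.
#' @param seed RNG seed for the GA stream.
#' @export
ga_config <- function(pop_size = 40, generations = 100, bounds = c(0, 20),
                      mutation_sd = 0.08, crossover_rate = 0.7,
                      tournament = 3, patience = 25, seed = 1) {
  stopifnot(pop_size >= 4, generations >= 1, bounds[1] < bounds[2])
  list(pop_size = pop_size, generations = generations, bounds = bounds,
       mutation_sd = mutation_sd, crossover_rate = crossover_rate,
       tournament = tournament, patience = patience, seed = seed)
}

#' Calibrate the dynamical-system gain against a target trajectory
#'
#' Minimises, by a seeded genetic algorithm, the L2 distance between the
#' dynamical system's normalised daily lumen-area (or intimal-area)
#' trajectory and a target trajectory — typically the hybrid model
#' ensemble's mean — and reports the optimal `gamma` together with the
#' maximum pointwise percent relative error of the calibrated fit.
#'
#' @param ds_initial Radii list for [ds_simulate()].
#' @param target Tibble with columns `day` and `lumen_norm` (or
#'   `intimal_norm` when `mode = "intima"`): the trajectory to match,
#'   normalised on its first sample.
#' @param ga A [ga_config()].
#' @param params A `ds_params`; its `gamma` is ignored (calibrated).
#' @param mode `"lumen"` (default) or `"intima"`: which normalised area the
#'   distance is computed on.
#' @return An object of class `veinsim_calibration`: `gamma`,
#'   `relative_error` (max pointwise percent error), `objective`, `trace`
#'   (per-generation tibble), `fit` (the calibrated DS trajectory).
#' @export
calibrate_gamma <- function(ds_initial, target, ga = ga_config(),
                            params = ds_params(), mode = c("lumen",
                                                           "intima")) {
  mode <- match.arg(mode)
  col <- if (mode == "lumen") "lumen_norm" else "intimal_norm"
  stopifnot(all(c("day", col) %in% names(target)))
  horizon <- max(target$day)
  y <- target[[col]][match(0:horizon, target$day)]
  stopifnot(!anyNA(y))
  simulate_norm <- function(gamma) {
    p <- params; p$gamma <- gamma
    ds_simulate(ds_initial, p, horizon)[[col]]
  }
  objective <- function(gamma) sqrt(mean((simulate_norm(gamma) - y)^2))
  rng <- rng_substream(ga$seed, "ga")
  lo <- ga$bounds[1]; hi <- ga$bounds[2]; width <- hi - lo
  pop <- rng(function() stats::runif(ga$pop_size, lo, hi))
  fit <- vapply(pop, objective, numeric(1))
  best <- which.min(fit)
  trace <- vector("list", ga$generations + 1)
  trace[[1]] <- tibble::tibble(generation = 0L, best_gamma = pop[best],
                               objective = fit[best])
  stagnant <- 0L; gen_done <- 0L
  for (gen in seq_len(ga$generations)) {
    prev_best <- fit[best]
    draws <- rng(function() list(
      t1 = matrix(sample.int(ga$pop_size, 2 * ga$pop_size * ga$tournament,
                             replace = TRUE), ncol = ga$tournament),
      u_x = stats::runif(ga$pop_size), bl = stats::runif(ga$pop_size),
      mut = stats::rnorm(ga$pop_size, 0, ga$mutation_sd * width)))
    pick <- function(rows) {
      apply(rows, 1, function(idx) idx[which.min(fit[idx])])
    }
    p1 <- pick(draws$t1[seq_len(ga$pop_size), , drop = FALSE])
    p2 <- pick(draws$t1[ga$pop_size + seq_len(ga$pop_size), , drop = FALSE])
    child <- ifelse(draws$u_x < ga$crossover_rate,
                    draws$bl * pop[p1] + (1 - draws$bl) * pop[p2], pop[p1])
    child <- pmin(pmax(child + draws$mut, lo), hi)
    child[1] <- pop[best]                       # elitism
    cfit <- vapply(child, objective, numeric(1))
    pop <- child; fit <- cfit
    best <- which.min(fit)
    trace[[gen + 1]] <- tibble::tibble(generation = gen,
                                       best_gamma = pop[best],
                                       objective = fit[best])
    gen_done <- gen
    stagnant <- if (fit[best] < prev_best * (1 - 1e-10)) 0L else stagnant + 1L
    if (stagnant >= ga$patience) {
      warning("GA made no improvement over ", ga$patience,
              " generations; returning best-so-far", call. = FALSE)
      break
    }
  }
  gamma_star <- pop[best]
  ds_fit <- local({p <- params; p$gamma <- gamma_star
    ds_simulate(ds_initial, p, horizon)})
  rel <- 100 * max(abs(ds_fit[[col]] - y) / pmax(abs(y), 1e-12))
  structure(list(gamma = gamma_star, relative_error = rel,
                 objective = fit[best], mode = mode,
                 generations_run = gen_done,
                 trace = dplyr::bind_rows(trace[!vapply(trace, is.null,
                                                        logical(1))]),
                 fit = ds_fit, target = y),
            class = "veinsim_calibration")
}

#' @export
print.veinsim_calibration <- function(x, ...) {
  cat(sprintf(paste0("<veinsim_calibration> gamma* = %.4g, max pointwise ",
                     "relative error = %.3g%% (%s area, %d generations)\n"),
              x$gamma, x$relative_error, x$mode, x$generations_run))
  invisible(x)
}

#' Tidy the per-generation trace of a calibration
#' @param x A `veinsim_calibration`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.veinsim_calibration <- function(x, ...) x$trace

#' One-row summary of a calibration
#' @param x A `veinsim_calibration`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.veinsim_calibration <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, relative_error = x$relative_error,
                 objective = x$objective, mode = x$mode,
                 generations_run = x$generations_run)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
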