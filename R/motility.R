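#' Cell-cell repulsion velocity
#'
#' Repulsive interaction between SMCs of the same layer. The default law
#' decays linearly from `k_S` at contact to zero at distance
#' `2 n_s R_SMC` (no interaction beyond); a Lennard-Jones-like alternative
#' with equilibrium at one cell diameter is available via
#' `repulsion_kind = "lennard_jones"`.
#'
#' @param agents Agent tibble (live agents).
#' @param params A `remodeling_params`.
#' @param rng RNG stream, used only to break coincident-centre ties.
#' @return n x 2 matrix of velocity components (mm per relaxation unit).
#' @export
v_repulsion <- function(agents, params, rng = NULL) {
  n <- nrow(agents)
  if (n < 2) return(matrix(0, n, 2))
  cutoff <- 2 * params$n_s * params$r_smc
  lay <- as.integer(factor(agents$layer, levels = c("intima", "media")))
  res <- cpp_repulsion(agents$x, agents$y, lay, params$k_S, cutoff,
                       2 * params$r_smc,
                       params$repulsion_kind == "lennard_jones")
  out <- res$v
  coin <- res$coincident   # indices of agents with a coincident partner
  if (length(coin) > 0) {
    # coincident centres: random unit direction at full magnitude
    warning("coincident SMC centres; repulsion direction randomised",
            call. = FALSE)
    th <- if (is.null(rng)) stats::runif(length(coin), 0, 2 * pi)
    else rng(function() stats::runif(length(coin), 0, 2 * pi))
    out[coin, 1] <- out[coin, 1] + params$k_S * cos(th)
    out[coin, 2] <- out[coin, 2] + params$k_S * sin(th)
  }
  out
}

#' Matrix-invasion velocity
#'
#' Attraction of an SMC toward surrounding ECM-occupied, cell-free grid
#' cells: each such cell within range `2 n_e R_SMC` contributes a pull of
#' magnitude `k_E (1 - d / (2 n_e R_SMC))`, weighted by its ECM density.
#' This is the mechanical-homeostasis drive by which SMCs infiltrate
#' cell-free matrix pockets.
#'
#' @param agents Live agent tibble.
#' @param ecm An `ecm_field`.
#' @param grid A `sim_grid`.
#' @param params A `remodeling_params`.
#' @return n x 2 velocity matrix.
#' @export
v_matrix_invasion <- function(agents, ecm, grid, params) {
  n <- nrow(agents)
  out <- matrix(0, n, 2)
  if (n == 0) return(out)
  cutoff <- 2 * params$n_e * params$r_smc
  rcell <- ceiling(cutoff / grid$h)
  offs <- expand.grid(di = -rcell:rcell, dj = -rcell:rcell)
  # occupancy: cells holding an SMC centre are not cell-free
  occ <- matrix(FALSE, grid$nx, grid$ny)
  ia <- pmin(pmax(ceiling((agents$x - grid$origin[1]) / grid$h), 1), grid$nx)
  ja <- pmin(pmax(ceiling((agents$y - grid$origin[2]) / grid$h), 1), grid$ny)
  occ[cbind(ia, ja)] <- TRUE
  dens <- ecm$density * !occ
  cc <- grid_centres(grid)
  for (k in seq_len(nrow(offs))) {
    i <- ia + offs$di[k]; j <- ja + offs$dj[k]
    ok <- i >= 1 & i <= grid$nx & j >= 1 & j <= grid$ny
    if (!any(ok)) next
    i <- pmin(pmax(i, 1), grid$nx); j <- pmin(pmax(j, 1), grid$ny)
    w <- dens[cbind(i, j)] * ok
    ddx <- cc$x[i] - agents$x; ddy <- cc$y[j] - agents$y
    d <- sqrt(ddx^2 + ddy^2)
    in_range <- w > 0 & d > 1e-12 & d < cutoff
    if (!any(in_range)) next
    mag <- params$k_E * (1 - d / cutoff) * w * in_range
    out[, 1] <- out[, 1] + ifelse(in_range, mag * ddx / d, 0)
    out[, 2] <- out[, 2] + ifelse(in_range, mag * ddy / d, 0)
  }
  out
}

#' Chemotaxis velocity
#'
#' Proportional to the local growth-factor gradient: `k_G grad(G)`
#' interpolated at the agent position.
#'
#' @param agents Live agent tibble.
#' @param G nx x ny growth-factor field.
#' @param grid A `sim_grid`.
#' @param params A `remodeling_params`.
#' @return n x 2 velocity matrix.
#' @export
v_chemotaxis <- function(agents, G, grid, params) {
  n <- nrow(agents)
  if (n == 0) return(matrix(0, 0, 2))
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (G[3:nx, ] - G[1:(nx - 2), ]) / (2 * h)
  gy[, 2:(ny - 1)] <- (G[, 3:ny] - G[, 1:(ny - 2)]) / (2 * h)
  params$k_G * cbind(interp_field(gx, grid, agents$x, agents$y),
                     interp_field(gy, grid, agents$x, agents$y))
}

#' Random motility velocity
#'
#' Uniform random direction with magnitude uniform in `[0, R_SMC/delta_t]`,
#' so a cell's random displacement over one relaxation period never exceeds
#' one cell radius.
#'
#' @param n Number of agents.
#' @param rng RNG stream from [rng_substream()].
#' @param params A `remodeling_params`.
#' @return n x 2 velocity matrix.
#' @export
v_random <- function(n, rng, params) {
  if (n == 0) return(matrix(0, 0, 2))
  u <- rng(function() cbind(stats::runif(n, 0, 2 * pi),
                            stats::runif(n, 0, 1)))
  vmax <- params$r_smc / params$delta_t
  cbind(cos(u[, 1]), sin(u[, 1])) * (u[, 2] * vmax)
}

#' Total active SMC velocity (multi-potential motility)
#'
#' Sum of the enabled components: cell-cell repulsion, matrix invasion,
#' chemotaxis and random motility. The passive transport by the relaxing
#' medium is added separately during the IBM substeps.
#'
#' @param agents Live agent tibble.
#' @param ecm An `ecm_field`.
#' @param G Growth-factor field.
#' @param grid A `sim_grid`.
#' @param rng RNG stream.
#' @param params A `remodeling_params` (component toggles in
#'   `params$forces`).
#' @return n x 2 velocity matrix (mm per relaxation unit).
#' @export
smc_velocity <- function(agents, ecm, G, grid, rng, params) {
  n <- nrow(agents)
  v <- matrix(0, n, 2)
  if (n == 0) return(v)
  if (params$forces[["repulsion"]])
    v <- v + v_repulsion(agents, params, rng)
  if (params$forces[["invasion"]])
    v <- v + v_matrix_invasion(agents, ecm, grid, params)
  if (params$forces[["chemotaxis"]])
    v <- v + v_chemotaxis(agents, G, grid, params)
  if (params$forces[["random"]])
    v <- v + v_random(n, rng, params)
  v
}
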