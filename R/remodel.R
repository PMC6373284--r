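#' Assemble the mass-source density field from an event batch
#'
#' Each mitosis or ECM-production event deposits one element area (SMC disc
#' `pi R_SMC^2`, ECM element `pi R_ECM^2`) into its containing grid cell over
#' the relaxation period `delta_t`; apoptosis and ECM degradation deposit the
#' negative. Migration carries no mass.
#'
#' @param batch Event tibble (`kind`, `x`, `y`, `agent_id`), optionally with
#'   an `area` column of signed effective areas (used for ECM events whose
#'   deposit was limited by the cell's occupancy).
#' @param grid A `sim_grid`.
#' @param params A `remodeling_params`.
#' @return nx x ny source-density field (1/time): integral of the field
#'   times `h^2 delta_t` equals the net element area added.
#' @export
assemble_mass_sources <- function(batch, grid, params) {
  s <- matrix(0, grid$nx, grid$ny)
  if (nrow(batch) == 0) return(s)
  area <- if ("area" %in% names(batch)) batch$area
  else c(mitosis = pi * params$r_smc^2,
         apoptosis = -pi * params$r_smc^2,
         ecm_production = pi * params$r_ecm^2,
         ecm_degradation = -pi * params$r_ecm^2,
         migration = 0)[batch$kind]
  i <- pmin(pmax(ceiling((batch$x - grid$origin[1]) / grid$h), 1), grid$nx)
  j <- pmin(pmax(ceiling((batch$y - grid$origin[2]) / grid$h), 1), grid$ny)
  rate <- area / (grid$h^2 * params$delta_t)
  for (k in seq_along(rate)) s[i[k], j[k]] <- s[i[k], j[k]] + rate[k]
  s
}

# Analytic wall strain energy for an equivalent annulus (a, b), integrating
# the Lame plane-strain energy density over the cross section.
annulus_energy <- function(a, b, params) {
  stats::integrate(function(rho)
    strain_energy_density(rho, a, b, params) * 2 * pi * rho,
    lower = a, upper = b, rel.tol = 1e-8)$value
}

#' Energy-minimising inward/outward remodeling term
#'
#' Because the medium filling the lumen is incompressible, wall mass sources
#' alone can only remodel the graft outward; inward remodeling requires a
#' lumen-side term in the mass balance. This operation evaluates the
#' analytic wall potential energy for a trial inward perturbation (lumen
#' loses `magnitude` of area, wall thickens inward) and a trial outward one
#' (lumen gains `magnitude`), and returns the signed lumen-side mass term
#' for whichever trial strictly lowers the energy: `-magnitude` (a sink
#' draining the lumen) for inward remodeling, `+magnitude` for outward,
#' `0` when neither lowers the energy or on an exact tie.
#'
#' @param section A `vein_section`.
#' @param mech A `mechanics_params`.
#' @param magnitude Trial area perturbation (mm^2) per cycle.
#' @return Signed lumen-side area term (mm^2 per cycle).
#' @export
inward_outward_adjust <- function(section, mech, magnitude) {
  if (magnitude <= 0) return(0)
  a <- sqrt(polygon_area(section$lumen_wall$points) / pi)
  b <- sqrt(polygon_area(section$external_wall$points) / pi)
  dA <- magnitude
  a_in <- sqrt(max(a^2 - dA / pi, 1e-12))
  a_out <- sqrt(a^2 + dA / pi)
  if (a_out >= b) return(0)
  e0 <- annulus_energy(a, b, mech)
  e_in <- annulus_energy(a_in, b, mech)
  e_out <- annulus_energy(a_out, b, mech)
  if (e_in < e0 && e_in < e_out) return(-dA)
  if (e_out < e0 && e_out < e_in) return(dA)
  0
}

# Lumen cells in a band 2-4 grid cells inside the lumen membrane: the ring
# receiving the inward/outward lumen-side mass term. The band sits outside
# the support of the regularised delta kernel, so the velocity field at the
# membrane is smooth and the enclosed-volume change matches the injected
# term.
lumen_ring_cells <- function(section) {
  g <- section$grid
  reg <- section$region
  lum <- which(reg == REGION_LUMEN)
  cc <- grid_centres(g)
  px <- rep(cc$x, times = g$ny)[lum]
  py <- rep(cc$y, each = g$nx)[lum]
  pts <- section$lumen_wall$points
  d2 <- outer(px, pts[, 1], "-")^2 + outer(py, pts[, 2], "-")^2
  d <- sqrt(apply(d2, 1, min))
  band <- lum[d > 2 * g$h & d <= 4 * g$h]
  if (length(band) == 0) band <- lum[d <= 4 * g$h]
  band
}

# Move event mass-deposit locations to the radial mid-band of their layer.
# A source within the regularised-delta support of a membrane leaks part of
# its volume across the interface (the membrane velocity is interpolated
# from the smeared field), so deposits are shifted along their ray to the
# middle of the bounding membranes; the mass still enters the correct layer
# at the correct angle.
displace_sources <- function(batch, section) {
  if (nrow(batch) == 0) return(batch)
  mass <- batch$kind != "migration"
  if (!any(mass)) return(batch)
  x <- batch$x[mass]; y <- batch$y[mass]
  r <- sqrt(x^2 + y^2)
  rad_at <- function(mem) {
    idx <- nearest_point_index(x, y, mem$points)
    sqrt(rowSums(mem$points[idx, , drop = FALSE]^2))
  }
  rl <- rad_at(section$lumen_wall)
  ri <- rad_at(section$iel)
  re <- rad_at(section$external_wall)
  intimal <- r <= ri
  r_new <- ifelse(intimal, (rl + ri) / 2, (ri + re) / 2)
  scale <- ifelse(r > 1e-12, r_new / r, 1)
  batch$x[mass] <- x * scale
  batch$y[mass] <- y * scale
  batch
}

# Total elastic energy of the membranes (diagnostic; also the quantity that
# relaxes as delta_t grows).
membrane_elastic_energy <- function(membranes) {
  sum(vapply(membranes, function(m) {
    len <- segment_lengths(m$points)
    sum(0.5 * m$stiffness * (len - m$rest_lengths)^2 / m$rest_lengths)
  }, numeric(1)))
}

# Resample a membrane by arc length when its discretisation coarsens beyond
# the 2h kernel bound.
resample_membrane <- function(mem, spacing) {
  p <- mem$points
  len <- segment_lengths(p)
  if (max(len) <= 2 * spacing) return(mem)
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  n_new <- max(16L, as.integer(ceiling(total / spacing)))
  s <- seq(0, total, length.out = n_new + 1)[-(n_new + 1)]
  pc <- rbind(p, p[1, ])
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[seg]) / len[seg]
  mem$points <- pc[seg, , drop = FALSE] +
    (pc[seg + 1, , drop = FALSE] - pc[seg, , drop = FALSE]) * frac
  mem$rest_lengths <- segment_lengths(mem$points)
  mem
}

# Place daughters, remove apoptotic agents, execute migrations, update ECM
# density. Returns updated agents/ecm plus the effective batch carrying the
# signed mass area of each event; ECM occupancy is bounded in [0, 1], so a
# production into a nearly full cell (or a degradation of a nearly empty
# one) exchanges only the area the cell can accommodate.
apply_events <- function(batch, agents, ecm, section, params, rng) {
  g <- section$grid
  area <- c(mitosis = pi * params$r_smc^2,
            apoptosis = -pi * params$r_smc^2,
            ecm_production = pi * params$r_ecm^2,
            ecm_degradation = -pi * params$r_ecm^2,
            migration = 0)[batch$kind]
  if (nrow(batch) > 0) {
    for (k in seq_len(nrow(batch))) {
      kind <- batch$kind[k]
      if (kind == "apoptosis") {
        agents$alive[agents$id == batch$agent_id[k]] <- FALSE
      } else if (kind == "mitosis") {
        parent <- which(agents$id == batch$agent_id[k])
        pos <- daughter_position(agents$x[parent], agents$y[parent],
                                 agents$layer[parent], section,
                                 2 * params$r_smc, rng)
        agents <- tibble::add_row(agents, id = max(agents$id) + 1L,
                                  x = pos[1], y = pos[2],
                                  radius = params$r_smc,
                                  layer = agents$layer[parent],
                                  mitosis_clock = 0, ecm_clock = 0,
                                  alive = TRUE)
      } else if (kind == "migration") {
        idx <- which(agents$id == batch$agent_id[k])
        ni <- nearest_point_index(agents$x[idx], agents$y[idx],
                                  section$iel$points)
        p <- section$iel$points[ni, ]
        nin <- -p / sqrt(sum(p^2))   # toward the vessel centre
        agents$x[idx] <- p[1] + 2 * params$r_smc * nin[1]
        agents$y[idx] <- p[2] + 2 * params$r_smc * nin[2]
        agents$layer[idx] <- "intima"
      } else if (kind %in% c("ecm_production", "ecm_degradation")) {
        i <- pmin(pmax(ceiling((batch$x[k] - g$origin[1]) / g$h), 1), g$nx)
        j <- pmin(pmax(ceiling((batch$y[k] - g$origin[2]) / g$h), 1), g$ny)
        # one ECM element is spread over the 3x3 neighbourhood (an element
        # is not confined to one cell, and per-cell occupancy is bounded in
        # [0, 1]); the effective exchanged area honours those bounds
        ii <- pmin(pmax(i + rep(-1:1, 3), 1), g$nx)
        jj <- pmin(pmax(j + rep(-1:1, each = 3), 1), g$ny)
        idx <- unique(cbind(ii, jj))
        wall_ok <- section$region[idx] == REGION_INTIMA |
          section$region[idx] == REGION_MEDIA
        idx <- idx[wall_ok, , drop = FALSE]
        if (nrow(idx) > 0) {
          dq <- pi * params$r_ecm^2 / g$h^2 / nrow(idx)
          d0 <- ecm$density[idx]
          delta <- if (kind == "ecm_production") pmin(dq, 1 - d0)
          else -pmin(dq, d0)
          ecm$density[idx] <- d0 + delta
          area[k] <- sum(delta) * g$h^2
        } else {
          area[k] <- 0
        }
      }
    }
  }
  batch$area <- unname(area)
  list(agents = agents, ecm = ecm, batch = batch)
}

# Daughter placement: one cell diameter from the parent in a uniformly
# random direction that stays in the parent's layer; after 20 failed
# directions, radially inward.
daughter_position <- function(x, y, layer, section, dist, rng) {
  want <- if (layer == "intima") REGION_INTIMA else REGION_MEDIA
  th <- rng(function() stats::runif(20, 0, 2 * pi))
  for (t in th) {
    cand <- c(x + dist * cos(t), y + dist * sin(t))
    if (region_at(section, cand[1], cand[2]) == want) return(cand)
  }
  r <- sqrt(x^2 + y^2)
  c(x, y) * (r - dist) / r
}

# Clamp agents back between their layer's bounding membranes (radial
# projection at the agent's angle; membranes stay star-shaped in practice).
clamp_agents <- function(agents, section, r_smc) {
  live <- which(agents$alive)
  if (length(live) == 0) return(agents)
  x <- agents$x[live]; y <- agents$y[live]
  r <- sqrt(x^2 + y^2)
  rad_at <- function(mem) {
    idx <- nearest_point_index(x, y, mem$points)
    sqrt(rowSums(mem$points[idx, , drop = FALSE]^2))
  }
  rl <- rad_at(section$lumen_wall)
  ri <- rad_at(section$iel)
  re <- rad_at(section$external_wall)
  intima <- agents$layer[live] == "intima"
  lo <- ifelse(intima, rl + r_smc, ri + r_smc)
  hi <- ifelse(intima, ri - r_smc, re - r_smc)
  mid <- (lo + hi) / 2
  lo2 <- pmin(lo, mid); hi2 <- pmax(hi, mid)
  rn <- pmin(pmax(r, lo2), hi2)
  scale <- ifelse(r > 1e-12, rn / r, 1)
  agents$x[live] <- x * scale
  agents$y[live] <- y * scale
  agents
}

#' Relax the tissue for one hourly cycle
#'
#' The core of tissue remodeling: applies the cycle's cellular events
#' (daughter insertion, apoptotic removal, IEL crossing, ECM density
#' updates), assembles the mass sources plus the energy-minimising
#' inward/outward lumen-side term, and runs `ceil(delta_t / dt_ibm)`
#' immersed-boundary substeps of membrane-force spreading, source-modified
#' projection, membrane advection and agent transport (passive medium motion
#' plus active multi-potential motility). Membrane rest lengths then relax
#' plastically by `rest_plasticity`, agents are clamped back into their
#' layers, and the region labelling is refreshed when membranes have moved
#' by more than half a cell.
#'
#' A net source is incompatible with the sealed no-slip box; it is balanced
#' by a uniform compensation restricted to the external-tissue region (the
#' far tissue acts as the volume reservoir), so the divergence identity
#' `div V = s` holds exactly over the vessel wall.
#'
#' @param section A `vein_section`.
#' @param agents Agent tibble.
#' @param ecm An `ecm_field`.
#' @param batch Event tibble from [step_plasticity()].
#' @param fields A `field_set` (for chemotaxis).
#' @param mech A `mechanics_params`.
#' @param params A `remodeling_params`.
#' @param rng List of RNG streams (`motility`, `placement`).
#' @param ws IBM workspace from [ibm_workspace()]; rebuilt when `NULL`.
#' @return List: updated `section`, `agents`, `ecm`, and `diagnostics`
#'   (net source area, adjustment term, membrane elastic energy before
#'   plastic relaxation).
#' @export
relax_tissue <- function(section, agents, ecm, batch, fields, mech, params,
                         rng, ws = NULL) {
  g <- section$grid
  upd <- apply_events(batch, agents, ecm, section, params, rng$placement)
  agents <- upd$agents; ecm <- upd$ecm
  source <- assemble_mass_sources(displace_sources(upd$batch, section),
                                  g, params)
  net_area <- sum(source) * g$h^2 * params$delta_t

  # The adjustment redistributes a fraction of the cycle's *signed* net mass
  # change toward the energy-minimising side: added wall volume drains the
  # lumen when inward remodeling lowers the energy, lost volume refills it.
  # Balanced turnover (net ~ 0 on average) therefore produces no systematic
  # lumen drift.
  adj <- 0
  if (params$adjust_gain > 0 && abs(net_area) > 0) {
    adj <- inward_outward_adjust(section, mech,
                                 params$adjust_gain * abs(net_area))
    adj <- adj * sign(net_area)
    if (adj != 0) {
      ring <- lumen_ring_cells(section)
      source[ring] <- source[ring] +
        adj / (length(ring) * g$h^2 * params$delta_t)
    }
  }

  live <- which(agents$alive)
  v_active <- matrix(0, nrow(agents), 2)
  v_active[live, ] <- smc_velocity(agents[live, ], ecm, fields$G, g,
                                   rng$motility, params)

  membranes <- list(section$lumen_wall, section$iel, section$external_wall)
  energy <- NA_real_
  if (any(source != 0) || params$rest_plasticity < 1) {
    # balance the net source in the external region only
    ext <- section$region == REGION_EXTERNAL
    src_eff <- source
    imb <- sum(source)
    if (abs(imb) > 0) src_eff[ext] <- src_eff[ext] - imb / sum(ext)
    n_sub <- ceiling(params$delta_t / params$dt_ibm)
    state <- NULL
    for (k in seq_len(n_sub)) {
      forces <- spread_membrane_forces(membranes, g)
      state <- ibm_substep(state, forces, src_eff, ws)
      membranes <- advect_membranes(membranes, state, g, params$dt_ibm)
      if (length(live) > 0) {
        um <- interp_points(state$u, cbind(agents$x[live], agents$y[live]),
                            g, "u")
        vm <- interp_points(state$v, cbind(agents$x[live], agents$y[live]),
                            g, "v")
        agents$x[live] <- agents$x[live] +
          params$dt_ibm * (um + v_active[live, 1])
        agents$y[live] <- agents$y[live] +
          params$dt_ibm * (vm + v_active[live, 2])
      }
    }
    energy <- membrane_elastic_energy(membranes)
    for (k in 1:3) {
      len <- segment_lengths(membranes[[k]]$points)
      membranes[[k]]$rest_lengths <- membranes[[k]]$rest_lengths +
        params$rest_plasticity * (len - membranes[[k]]$rest_lengths)
      membranes[[k]] <- resample_membrane(membranes[[k]], g$h)
    }
    section$lumen_wall <- membranes[[1]]
    section$iel <- membranes[[2]]
    section$external_wall <- membranes[[3]]
    if (!all(vapply(membranes, function(m) curve_is_simple(m$points),
                    logical(1))))
      stop("membrane self-intersection after relaxation", call. = FALSE)
    section <- refresh_regions(section)
  } else if (length(live) > 0) {
    # quiescent medium: agents move by active motility alone
    agents$x[live] <- agents$x[live] + params$delta_t * v_active[live, 1]
    agents$y[live] <- agents$y[live] + params$delta_t * v_active[live, 2]
    energy <- membrane_elastic_energy(membranes)
  }

  agents <- clamp_agents(agents, section, params$r_smc)
  agents <- agents[agents$alive, , drop = FALSE]
  list(section = section, agents = agents, ecm = ecm,
       diagnostics = list(net_source_area = net_area, adjust_term = adj,
                          membrane_energy = energy))
}

# Relabel the region mask only when membranes have moved materially since
# the stored labelling snapshot (mask resolution is h anyway).
refresh_regions <- function(section, force = FALSE) {
  snap <- section$label_snapshot
  cur <- rbind(section$lumen_wall$points, section$iel$points,
               section$external_wall$points)
  if (!force && !is.null(snap) && nrow(snap) == nrow(cur)) {
    if (max(abs(cur - snap)) < 0.5 * section$grid$h) return(section)
  }
  section$region <- label_regions(section)
  section$label_snapshot <- cur
  section
}
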