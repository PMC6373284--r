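#' Tissue-remodeling (immersed boundary) parameters
#'
#' The wall relaxes as a highly viscous incompressible medium for a period
#' `delta_t` (the tissue relaxation time, in dimensionless relaxation units)
#' every hourly biology cycle. Mass sources and sinks from the cellular
#' events enter the pressure-correction Poisson problem; membranes exert
#' spring forces spread onto the staggered grid through a regularised Peskin
#' delta kernel and move with the interpolated medium velocity.
#'
#' @param delta_t Relaxation duration per hourly cycle (relaxation units).
#'   An unknown of the model: the larger `delta_t`, the more the membranes
#'   relax toward circularity each cycle.
#' @param dt_ibm IBM substep; default `delta_t / 25`.
#' @param rho Medium density (relaxation units).
#' @param mu_tissue Medium viscosity; high, so the flow is a quasi-static
#'   Stokes relaxation.
#' @param n_s Cell-cell repulsion range in cell diameters (interaction zero
#'   beyond `2 n_s R_SMC`).
#' @param n_e Matrix-invasion range in cell diameters (zero beyond
#'   `2 n_e R_SMC`).
#' @param k_S,k_E,k_G Motility force gains (mm per relaxation unit).
#' @param adjust_gain Inward/outward mass-term amplitude, as a dimensionless
#'   gain on the magnitude of the current cycle's net event source area
#'   (0 disables the adjustment).
#' @param forces Named logical toggles for the active-motility components:
#'   `random`, `repulsion`, `invasion`, `chemotaxis`.
#' @param repulsion_kind `"linear"` (default, used for all results) or
#'   `"lennard_jones"` (the initial-guess alternative).
#' @param rest_plasticity Fraction of membrane stretch converted into new
#'   rest length at the end of each hourly cycle (1 = fully plastic between
#'   cycles: membranes resist deformation during a relaxation but carry no
#'   elastic memory across cycles).
#' @param r_smc,r_ecm SMC and ECM element radii (mm).
#' @return An object of class `remodeling_params`.
#' @export
remodeling_params <- function(delta_t = 1, dt_ibm = delta_t / 25, rho = 1,
                              mu_tissue = 10, n_s = 2, n_e = 3,
                              k_S = 0.004, k_E = 0.002, k_G = 0.01,
                              adjust_gain = 0.5,
                              forces = c(random = TRUE, repulsion = TRUE,
                                         invasion = TRUE, chemotaxis = TRUE),
                              repulsion_kind = "linear",
                              rest_plasticity = 1,
                              r_smc = 0.005, r_ecm = 0.004) {
  stopifnot(delta_t > 0, dt_ibm > 0, dt_ibm <= delta_t, rho > 0,
            mu_tissue > 0, n_s >= 1, n_e >= 1,
            rest_plasticity >= 0, rest_plasticity <= 1)
  f <- c(random = TRUE, repulsion = TRUE, invasion = TRUE, chemotaxis = TRUE)
  f[names(forces)] <- forces
  structure(list(delta_t = delta_t, dt_ibm = dt_ibm, rho = rho,
                 mu_tissue = mu_tissue, n_s = n_s, n_e = n_e,
                 k_S = k_S, k_E = k_E, k_G = k_G, adjust_gain = adjust_gain,
                 forces = f, repulsion_kind = repulsion_kind,
                 rest_plasticity = rest_plasticity,
                 r_smc = r_smc, r_ecm = r_ecm),
            class = "remodeling_params")
}

#' Four-point cosine Peskin kernel
#'
#' Regularised one-dimensional delta kernel `phi(r) = (1 + cos(pi r / 2))/4`
#' for `|r| < 2`, zero outside; satisfies the discrete partition of unity,
#' so spreading conserves total force exactly.
#'
#' @param r Distance in grid-cell units.
#' @export
peskin_phi <- function(r) ifelse(abs(r) < 2, (1 + cos(pi * r / 2)) / 4, 0)

# Staggered-grid coordinates.
# u lives on vertical faces: (nx+1) x ny; v on horizontal faces: nx x (ny+1).
stag_coords <- function(grid, stag) {
  if (stag == "u")
    list(x = grid$origin[1] + (0:grid$nx) * grid$h,
         y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$h)
  else
    list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$h,
         y = grid$origin[2] + (0:grid$ny) * grid$h)
}

# Spread per-point force components onto a staggered component grid:
# f_grid = sum_l F_l phi((x - X_l)/h) phi((y - Y_l)/h) / h^2.
spread_points <- function(X, F, grid, stag) {
  co <- stag_coords(grid, stag)
  cpp_spread(X, F, co$x[1], co$y[1], grid$h, length(co$x), length(co$y))
}

# Interpolate a staggered component field at Lagrangian points (adjoint of
# spread_points up to the h^2 quadrature weight).
interp_points <- function(fld, X, grid, stag) {
  co <- stag_coords(grid, stag)
  as.numeric(cpp_interp(fld, X, co$x[1], co$y[1], grid$h))
}

#' Elastic tension forces at the Lagrangian points of a membrane
#'
#' Linear springs along each segment against its rest length; a stretched
#' segment pulls its endpoints together, a compressed one pushes them apart.
#'
#' @param mem A `membrane`.
#' @return n x 2 matrix of force components.
#' @export
membrane_forces <- function(mem) {
  p <- mem$points
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  d <- nxt - p
  len <- sqrt(rowSums(d^2))
  tension <- mem$stiffness * (len - mem$rest_lengths) / mem$rest_lengths
  fseg <- d / len * tension        # force on start point of each segment
  fseg - rbind(fseg[nrow(fseg), , drop = FALSE],
               fseg[-nrow(fseg), , drop = FALSE])
}

#' Spread the elastic forces of a set of membranes onto the staggered grid
#'
#' @param membranes List of `membrane` objects.
#' @param grid A `sim_grid`.
#' @return List `fx` ((nx+1) x ny) and `fy` (nx x (ny+1)) body-force
#'   components on the u and v face grids.
#' @export
spread_membrane_forces <- function(membranes, grid) {
  X <- do.call(rbind, lapply(membranes, `[[`, "points"))
  F <- do.call(rbind, lapply(membranes, membrane_forces))
  list(fx = spread_points(X, F[, 1], grid, "u"),
       fy = spread_points(X, F[, 2], grid, "v"))
}

# ---- fast constant-coefficient solvers (tensor eigendecomposition) --------

# 1D second-difference operator (1/h^2 scaling), as a dense symmetric matrix.
# bc = "dirichlet": nodes strictly inside, value 0 at both outer nodes.
# bc = "half": node centres half a cell from a Dirichlet wall (diag -3 ends).
# bc = "neumann": cell-centred, dropped links (diag -1 ends).
second_diff_1d <- function(n, h, bc) {
  d <- rep(-2, n)
  if (bc == "half") d[c(1, n)] <- -3
  if (bc == "neumann") d[c(1, n)] <- -1
  M <- diag(d)
  idx <- seq_len(n - 1)
  M[cbind(idx, idx + 1)] <- 1
  M[cbind(idx + 1, idx)] <- 1
  M / h^2
}

eig_op <- function(n, h, bc) {
  e <- eigen(second_diff_1d(n, h, bc), symmetric = TRUE)
  list(Q = e$vectors, lambda = e$values)
}

#' Precomputed workspace for the IBM solves on a fixed grid
#'
#' Eigendecompositions of the 1D operators behind the implicit momentum
#' diffusion (Dirichlet box) and the pressure-correction Poisson problem
#' (homogeneous Neumann), so each substep reduces to dense matrix products.
#'
#' @param grid A `sim_grid`.
#' @param params A `remodeling_params`.
#' @return An opaque workspace list; pass to [ibm_substep()].
#' @export
ibm_workspace <- function(grid, params) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  nu <- params$mu_tissue / params$rho
  dt <- params$dt_ibm
  ux <- eig_op(nx - 1, h, "dirichlet"); uy <- eig_op(ny, h, "half")
  vx <- eig_op(nx, h, "half");          vy <- eig_op(ny - 1, h, "dirichlet")
  px <- eig_op(nx, h, "neumann");       py <- eig_op(ny, h, "neumann")
  lam_p <- outer(px$lambda, py$lambda, "+")
  izero <- which(abs(lam_p) == min(abs(lam_p)))[1]
  lam_p[izero] <- 1  # constant mode, coefficient forced to zero in the solve
  list(grid = grid, dt = dt, nu = nu, rho = params$rho,
       ux = ux, uy = uy, vx = vx, vy = vy, px = px, py = py,
       du = 1 - dt * nu * outer(ux$lambda, uy$lambda, "+"),
       dv = 1 - dt * nu * outer(vx$lambda, vy$lambda, "+"),
       lam_p = lam_p, izero = izero)
}

#' One substep of the projection scheme with mass sources
#'
#' Semi-implicit first-order step of the viscous relaxation flow: the
#' predictor treats diffusion implicitly and convection by the method of
#' characteristics (semi-Lagrangian), with the spread membrane forces as an
#' explicit body force; the corrector solves the source-modified pressure
#' Poisson problem `Lap(Pi) = (rho/dt) (div V* - s)` with homogeneous
#' Neumann conditions and projects, so the corrected velocity satisfies
#' `div V = s` discretely. No-slip holds on the outer computational box. A
#' source field whose integral is nonzero is incompatible with the closed
#' box; it is balanced by subtracting its mean (optionally with a message).
#'
#' @param state List with staggered components `u` ((nx+1) x ny) and `v`
#'   (nx x (ny+1)); pass `NULL` for a quiescent start.
#' @param forces List `fx`, `fy` from [spread_membrane_forces()].
#' @param source nx x ny mass-source density field (1/time).
#' @param ws Workspace from [ibm_workspace()].
#' @param quiet Suppress the imbalance message (default `TRUE`).
#' @return Updated `state` with the pressure correction `Pi` attached.
#' @export
ibm_substep <- function(state, forces, source, ws, quiet = TRUE) {
  g <- ws$grid; nx <- g$nx; ny <- g$ny
  if (is.null(state))
    state <- list(u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1))
  if (!quiet) {
    imb <- mean(source)
    if (abs(imb) > 1e-8 * (max(abs(source)) + 1e-300))
      message("mass-source imbalance ", signif(imb, 3),
              " balanced by mean subtraction")
  }
  res <- cpp_ibm_substep(state$u, state$v, forces$fx, forces$fy, source,
                         ws$ux$Q, ws$uy$Q, ws$du, ws$vx$Q, ws$vy$Q, ws$dv,
                         ws$px$Q, ws$py$Q, ws$lam_p, ws$izero,
                         g$h, ws$dt, ws$rho)
  list(u = res$u, v = res$v, Pi = res$Pi)
}

# Discrete divergence of a staggered state at cell centres.
state_divergence <- function(state, grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  (state$u[-1, ] - state$u[-(nx + 1), ]) / h +
    (state$v[, -1] - state$v[, -(ny + 1)]) / h
}

#' Advect membranes with the interpolated medium velocity
#'
#' Each Lagrangian point moves by the velocity interpolated through the same
#' Peskin kernel used for force spreading (so spreading and interpolation
#' stay adjoint), times `dt`. Optionally re-checks curve simplicity and rolls
#' the step back with a halved `dt` (at most 5 halvings).
#'
#' @param membranes List of `membrane` objects.
#' @param state Staggered velocity state.
#' @param grid A `sim_grid`.
#' @param dt Substep length.
#' @param check Re-check simplicity and roll back on self-intersection.
#' @return The advected list of membranes.
#' @export
advect_membranes <- function(membranes, state, grid, dt, check = FALSE) {
  move <- function(mem, dtk) {
    up <- interp_points(state$u, mem$points, grid, "u")
    vp <- interp_points(state$v, mem$points, grid, "v")
    mem$points <- mem$points + dtk * cbind(up, vp, deparse.level = 0)
    mem
  }
  out <- lapply(membranes, move, dtk = dt)
  if (check) {
    for (k in seq_along(out)) {
      dtk <- dt; tries <- 0
      while (!curve_is_simple(out[[k]]$points)) {
        tries <- tries + 1
        if (tries > 5) stop("membrane self-intersection persists after 5 ",
                            "halvings of the substep", call. = FALSE)
        dtk <- dtk / 2
        out[[k]] <- move(membranes[[k]], dtk)
      }
    }
  }
  out
}
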