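#' Mechanical-model parameters
#'
#' Parameters of the steady mechanical model: lumen blood flow, wall shear
#' stress, thick-cylinder strain energy, and growth-factor (GF) diffusion.
#'
#' @param mu Blood dynamic viscosity (Pa s). Default 3.5e-3 (whole blood).
#' @param Q_target Prescribed volumetric flow rate (mm^3/s). The vascular
#'   system holds flow constant, so the pressure gradient is rescaled to keep
#'   this rate as the lumen narrows.
#' @param c_gf GF diffusion coefficient (mm^2/h); only the steady profile
#'   enters the hourly biology.
#' @param tol Lumen-displacement tolerance (mm) that triggers a mechanics
#'   recomputation; of the order of an SMC diameter.
#' @param p_internal,p_external Internal (blood) and external (support
#'   tissue) pressures (Pa).
#' @param E,nu Elastic modulus (Pa) and Poisson ratio of the venous wall used
#'   in the plane-strain thick-cylinder energy.
#' @param tau_bar Baseline wall shear stress (Pa) of the basic solution; the
#'   GF boundary value is the relative shear deficit against this baseline.
#' @param eta Penalty parameter imposing boundary conditions on the Cartesian
#'   grid (Angot-style volume penalisation).
#' @param r_smc SMC radius (mm) used for the default `tol` (one diameter).
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(mu = 3.5e-3, Q_target = 3.1, c_gf = 0.1,
                             tol = NULL, p_internal = 13300,
                             p_external = 2000, E = 3e5, nu = 0.45,
                             tau_bar = NULL, eta = 1e-8, r_smc = 0.005) {
  if (is.null(tol)) tol <- 2 * r_smc
  stopifnot(mu > 0, Q_target >= 0, c_gf > 0, tol > 0, eta > 0)
  structure(list(mu = mu, Q_target = Q_target, c_gf = c_gf, tol = tol,
                 p_internal = p_internal, p_external = p_external,
                 E = E, nu = nu, tau_bar = tau_bar, eta = eta),
            class = "mechanics_params")
}

# 5-point Laplacian (1/h^2 scaling) with homogeneous Neumann box boundary
# (dropped links), as a sparse matrix over cell-centred unknowns.
grid_laplacian <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; h2 <- grid$h^2
  idx <- function(i, j) i + (j - 1L) * nx
  ii <- jj <- integer(0)
  # horizontal links
  i <- rep(seq_len(nx - 1), ny); j <- rep(seq_len(ny), each = nx - 1)
  ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i + 1L, j))
  # vertical links
  i <- rep(seq_len(nx), ny - 1); j <- rep(seq_len(ny - 1), each = nx)
  ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i, j + 1L))
  L <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                            x = 1 / h2, dims = c(nx * ny, nx * ny))
  Matrix::Diagonal(nx * ny, -Matrix::rowSums(L)) + L
}

#' Solve the steady fully developed lumen flow and wall shear stress
#'
#' The axial velocity solves a Poisson problem on the lumen cross section with
#' a no-slip wall imposed by volume penalisation outside the lumen; the
#' pressure-gradient constant is rescaled so the discharge matches
#' `Q_target` exactly (constant-flow control). Wall shear stress is evaluated
#' at every lumen-membrane point by a one-sided second-order difference along
#' the inward normal.
#'
#' @param section A `vein_section`.
#' @param params A `mechanics_params`.
#' @return List: `w` (nx x ny axial-velocity matrix, mm/s), `tau_wall`
#'   (Pa, one value per lumen-membrane point), `Q` (achieved flow rate).
#' @export
solve_lumen_flow <- function(section, params) {
  g <- section$grid
  lum <- as.vector(section$region == REGION_LUMEN)
  if (!any(lum)) stop("occlusion error: lumen region is empty", call. = FALSE)
  if (params$Q_target == 0) {
    w <- matrix(0, g$nx, g$ny)
    return(list(w = w, tau_wall = rep(0, nrow(section$lumen_wall$points)),
                Q = 0))
  }
  L <- grid_laplacian(g)
  A <- -params$mu * L + Matrix::Diagonal(g$nx * g$ny, (!lum) / params$eta)
  w1 <- as.numeric(Matrix::solve(A, as.numeric(lum)))  # unit pressure gradient
  Q1 <- sum(w1[lum]) * g$h^2
  w <- matrix(w1 * params$Q_target / Q1, g$nx, g$ny)
  list(w = w, tau_wall = wall_shear(w, section, params), Q = params$Q_target)
}

# One-sided normal derivative of w at each lumen-membrane point: quadratic
# extrapolation from three interior samples along the inward normal. The
# samples start 1.5 cells inside so the penalty-smeared wall layer is skipped;
# extrapolating to the membrane avoids the O(h/2) rasterisation offset of the
# penalised wall.
wall_shear <- function(w, section, params) {
  pts <- section$lumen_wall$points
  g <- section$grid
  centroid <- colMeans(pts)
  nin <- cbind(centroid[1] - pts[, 1], centroid[2] - pts[, 2])
  nin <- nin / sqrt(rowSums(nin^2))
  d <- g$h * c(1.5, 2.5, 3.5)
  f <- lapply(d, function(dk)
    interp_field(w, g, pts[, 1] + dk * nin[, 1], pts[, 2] + dk * nin[, 2]))
  # derivative at 0 of the quadratic through (d1,f1),(d2,f2),(d3,f3)
  l1 <- (-d[2] - d[3]) / ((d[1] - d[2]) * (d[1] - d[3]))
  l2 <- (-d[1] - d[3]) / ((d[2] - d[1]) * (d[2] - d[3]))
  l3 <- (-d[1] - d[2]) / ((d[3] - d[1]) * (d[3] - d[2]))
  tau <- params$mu * abs(l1 * f[[1]] + l2 * f[[2]] + l3 * f[[3]])
  # smooth along the membrane over the rasterisation scale: the point-wise
  # extraction carries cell-scale mask noise, which would otherwise rectify
  # through the clipped shear-deficit F(tau) into a spurious growth-factor
  # level at exact balance
  circular_smooth(tau, k = 3)
}

# Circular moving average over +/- k neighbours of a closed-curve signal.
circular_smooth <- function(x, k) {
  n <- length(x)
  if (n <= 2 * k + 1) return(rep(mean(x), n))
  acc <- x
  for (s in seq_len(k)) {
    acc <- acc + x[c((s + 1):n, 1:s)] + x[c((n - s + 1):n, 1:(n - s))]
  }
  acc / (2 * k + 1)
}

#' Bilinear interpolation of a cell-centred field
#'
#' @param field nx x ny matrix sampled at cell centres.
#' @param grid A `sim_grid`.
#' @param x,y Query coordinates (mm), vectorised.
#' @return Interpolated values (constant extrapolation at the domain edge).
#' @export
interp_field <- function(field, grid, x, y) {
  gx <- (x - grid$origin[1]) / grid$h - 0.5
  gy <- (y - grid$origin[2]) / grid$h - 0.5
  i0 <- pmin(pmax(floor(gx) + 1, 1), grid$nx - 1)
  j0 <- pmin(pmax(floor(gy) + 1, 1), grid$ny - 1)
  fx <- pmin(pmax(gx - (i0 - 1), 0), 1)
  fy <- pmin(pmax(gy - (j0 - 1), 0), 1)
  f00 <- field[cbind(i0, j0)]; f10 <- field[cbind(i0 + 1, j0)]
  f01 <- field[cbind(i0, j0 + 1)]; f11 <- field[cbind(i0 + 1, j0 + 1)]
  f00 * (1 - fx) * (1 - fy) + f10 * fx * (1 - fy) +
    f01 * (1 - fx) * fy + f11 * fx * fy
}

#' Lamé thick-cylinder stresses
#'
#' Radial and hoop stresses of a pressurised thick-walled cylinder with inner
#' radius `a`, outer radius `b`, internal pressure `p_i` and external
#' pressure `p_e`, at radii `rho` (clamped to `[a, b]`).
#'
#' @param rho Radii (mm) at which to evaluate.
#' @param a,b Inner and outer radii (mm), `a < b`.
#' @param p_i,p_e Pressures (Pa).
#' @return List with components `sr` (radial) and `st` (hoop), in Pa.
#' @export
lame_stress <- function(rho, a, b, p_i, p_e) {
  if (a >= b) stop("geometry error: inner radius must be below outer radius",
                   call. = FALSE)
  rho <- pmin(pmax(rho, a), b)
  A <- (p_i * a^2 - p_e * b^2) / (b^2 - a^2)
  B <- (p_i - p_e) * a^2 * b^2 / (b^2 - a^2)
  list(sr = A - B / rho^2, st = A + B / rho^2)
}

#' Strain energy density across the wall (thick-cylinder approximation)
#'
#' The wall is treated as a plane-strain thick cylinder with area-equivalent
#' inner and outer radii; the elastic strain energy density of the Lamé
#' stress state is evaluated at each wall grid cell by its radius.
#'
#' @inheritParams solve_lumen_flow
#' @return nx x ny matrix of strain energy density (Pa); zero outside the
#'   wall.
#' @export
compute_strain_energy <- function(section, params) {
  g <- section$grid
  a <- sqrt(polygon_area(section$lumen_wall$points) / pi)
  b <- sqrt(polygon_area(section$external_wall$points) / pi)
  cc <- grid_centres(g)
  rho <- sqrt(outer(cc$x^2, cc$y^2, "+"))
  u <- strain_energy_density(rho, a, b, params)
  wall <- section$region == REGION_INTIMA | section$region == REGION_MEDIA
  u[!wall] <- 0
  u
}

strain_energy_density <- function(rho, a, b, params) {
  s <- lame_stress(rho, a, b, params$p_internal, params$p_external)
  nu <- params$nu; E <- params$E
  sz <- nu * (s$sr + s$st)                      # plane strain
  er <- ((1 + nu) / E) * ((1 - nu) * s$sr - nu * s$st)
  et <- ((1 + nu) / E) * ((1 - nu) * s$st - nu * s$sr)
  0.5 * (s$sr * er + s$st * et)
}

#' Growth-factor boundary value from the wall shear deficit
#'
#' Low shear activates growth factors: the GF concentration imposed at the
#' lumen boundary is the relative shear deficit `max(0, (tau_bar - tau) /
#' tau_bar)`, so the basic solution (tau = tau_bar) carries no GF and a 50%
#' shear drop imposes a boundary value of 0.5.
#'
#' @param tau Wall shear stress (Pa), vectorised.
#' @param params A `mechanics_params` (uses `tau_bar`).
#' @return Dimensionless GF boundary values in `[0, 1]`.
#' @export
gf_boundary_value <- function(tau, params) {
  if (is.null(params$tau_bar)) stop("tau_bar not set; compute the basic ",
                                    "solution baseline first", call. = FALSE)
  pmax(0, (params$tau_bar - tau) / params$tau_bar)
}

#' Steady growth-factor diffusion across the wall
#'
#' Solves the steady isotropic diffusion problem with a Dirichlet value
#' `F(tau_wall)` on the lumen boundary (imposed by penalisation over the
#' lumen region) and zero flux on the outer computational boundary.
#'
#' @inheritParams solve_lumen_flow
#' @param tau_wall Shear stress at each lumen-membrane point (Pa).
#' @return nx x ny matrix of dimensionless GF concentration.
#' @export
solve_gf_diffusion <- function(section, tau_wall, params) {
  g <- section$grid
  lum <- as.vector(section$region == REGION_LUMEN)
  gvals <- gf_boundary_value(tau_wall, params)
  if (all(gvals == 0)) return(matrix(0, g$nx, g$ny))
  # Dirichlet data carried by each lumen cell: value of the nearest membrane pt
  cc <- grid_centres(g)
  px <- rep(cc$x, times = g$ny)[lum]
  py <- rep(cc$y, each = g$nx)[lum]
  pts <- section$lumen_wall$points
  nearest <- nearest_point_index(px, py, pts)
  g0 <- numeric(g$nx * g$ny)
  g0[lum] <- gvals[nearest]
  L <- grid_laplacian(g)
  A <- -params$c_gf * L + Matrix::Diagonal(g$nx * g$ny, lum / params$eta)
  G <- as.numeric(Matrix::solve(A, g0 / params$eta * lum))
  matrix(pmax(G, 0), g$nx, g$ny)
}

nearest_point_index <- function(px, py, pts) {
  d2 <- outer(px, pts[, 1], "-")^2 + outer(py, pts[, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Should the mechanical fields be recomputed?
#'
#' The mechanical model is updated only when the lumen boundary has moved by
#' more than `tol` (strictly) since the last update; otherwise the cached
#' fields are reused.
#'
#' @param old_lumen,new_lumen `membrane` objects (or point matrices).
#' @param params A `mechanics_params`.
#' @export
should_update_mechanics <- function(old_lumen, new_lumen, params) {
  boundary_displacement(old_lumen, new_lumen) > params$tol
}

#' Mechanical potential energy of the wall
#'
#' @param section A `vein_section`.
#' @param sigma Strain energy density field (from [compute_strain_energy()]).
#' @return Integral of sigma over the wall region (Pa mm^2, i.e. energy per
#'   unit vessel length up to unit conversion).
#' @export
wall_potential_energy <- function(section, sigma) {
  wall <- section$region == REGION_INTIMA | section$region == REGION_MEDIA
  sum(sigma[wall]) * section$grid$h^2
}

#' Compute the full mechanical field set for a cross section
#'
#' Runs the flow solve, strain-energy evaluation and steady GF diffusion and
#' returns them as one `field_set`.
#'
#' @inheritParams solve_lumen_flow
#' @return A `field_set`: `w`, `tau_wall`, `sigma`, `G`, plus the lumen
#'   membrane snapshot the fields were computed for.
#' @export
compute_fields <- function(section, params) {
  flow <- solve_lumen_flow(section, params)
  sigma <- compute_strain_energy(section, params)
  G <- if (is.null(params$tau_bar)) matrix(0, section$grid$nx,
                                           section$grid$ny)
  else solve_gf_diffusion(section, flow$tau_wall, params)
  structure(list(w = flow$w, tau_wall = flow$tau_wall, sigma = sigma, G = G,
                 lumen_snapshot = section$lumen_wall$points),
            class = "field_set")
}
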