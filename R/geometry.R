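# Region codes used throughout the package. The cross section is partitioned
# into lumen / tunica intima / tunica media / external support tissue.
REGION_LUMEN <- 0L
REGION_INTIMA <- 1L
REGION_MEDIA <- 2L
REGION_EXTERNAL <- 3L

#' Construct a regular Cartesian simulation grid
#'
#' The grid carries every scalar field of the model (axial velocity, strain
#' energy, growth factor, ECM occupancy) with cell-centred sampling. The step
#' `h` must not exceed one SMC diameter so that a single cell agent spans at
#' least one grid cell.
#'
#' @param nx,ny Number of cells in x and y.
#' @param h Grid step (mm).
#' @param origin Coordinates (mm) of the lower-left corner of the domain.
#'   Defaults to centring the domain on the origin.
#' @param r_smc SMC radius (mm) used to validate `h`.
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(nx, ny, h, origin = c(-nx * h / 2, -ny * h / 2),
                     r_smc = 0.005) {
  stopifnot(nx >= 4, ny >= 4, h > 0)
  if (h > 2 * r_smc + 1e-12) {
    stop("grid step h = ", h, " exceeds one SMC diameter (", 2 * r_smc, " mm)",
         call. = FALSE)
  }
  g <- list(nx = as.integer(nx), ny = as.integer(ny), h = h,
            origin = as.numeric(origin))
  class(g) <- "sim_grid"
  g
}

#' Grid large enough to enclose a vessel of given outer radius
#'
#' Builds a square, origin-centred grid whose half-width exceeds `r_outer` by
#' at least `margin` grid cells on every side.
#'
#' @inheritParams sim_grid
#' @param r_outer Outer vessel radius (mm).
#' @param margin Number of clear cells between the outer membrane and the
#'   domain edge (default 4).
#' @export
grid_for_vessel <- function(r_outer, h, margin = 4, r_smc = 0.005) {
  n <- 2L * as.integer(ceiling(r_outer / h + margin))
  sim_grid(n, n, h, r_smc = r_smc)
}

# Cell-centre coordinates of a grid, as vectors.
grid_centres <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$h,
       y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$h)
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d cells, h = %g mm, origin (%g, %g) mm\n",
              x$nx, x$ny, x$h, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Create a closed elastic membrane curve
#'
#' Membranes bound each layer of the graft (lumen wall, internal elastic
#' lamina, external wall). They are closed polylines of Lagrangian points tied
#' by linear springs at their rest lengths, and are porous to SMC passage
#' where local membrane stress exceeds `porosity_threshold`.
#'
#' @param points n x 2 matrix of ordered coordinates (mm); the curve closes
#'   from the last point back to the first.
#' @param stiffness Spring stiffness (force per unit relative stretch).
#' @param porosity_threshold Segment stress level above which an SMC may pass.
#' @param rest_lengths Per-segment rest lengths (mm); defaults to the current
#'   segment lengths so a freshly built membrane carries no tension.
#' @return An object of class `membrane`.
#' @export
membrane <- function(points, stiffness = 1, porosity_threshold = Inf,
                     rest_lengths = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 16)
  if (is.null(rest_lengths)) rest_lengths <- segment_lengths(points)
  stopifnot(length(rest_lengths) == nrow(points))
  m <- list(points = points, rest_lengths = as.numeric(rest_lengths),
            stiffness = stiffness, porosity_threshold = porosity_threshold)
  class(m) <- "membrane"
  m
}

#' Circular membrane discretised at a target spacing
#'
#' @param r Radius (mm).
#' @param spacing Target adjacent-point spacing (mm); points are placed at
#'   most this far apart (the interpolation stencils of the immersed-boundary
#'   kernel require spacing below two grid cells).
#' @inheritParams membrane
#' @export
membrane_circle <- function(r, spacing, stiffness = 1,
                            porosity_threshold = Inf) {
  n <- max(16L, as.integer(ceiling(2 * pi * r / spacing)))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  membrane(cbind(r * cos(th), r * sin(th)), stiffness, porosity_threshold)
}

segment_lengths <- function(points) {
  nxt <- rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE])
  sqrt(rowSums((nxt - points)^2))
}

#' Signed and absolute polygon area (shoelace formula)
#' @param points n x 2 matrix of polygon vertices (closed implicitly).
#' @return Area in mm^2 (absolute value).
#' @export
polygon_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Even-odd point-in-polygon test, vectorised over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE if the closed polyline has no self-intersection (non-adjacent
# segment-pair crossing check).
curve_is_simple <- function(points) cpp_curve_simple(points)

#' Symmetric point-set (Hausdorff) distance between two closed curves
#'
#' The lumen-geometry variation that triggers a mechanics update is measured
#' as the symmetric max-min Euclidean distance over the discretised membrane
#' points of the old and new curves.
#'
#' @param old,new `membrane` objects (or n x 2 point matrices).
#' @return Distance in mm.
#' @export
boundary_displacement <- function(old, new) {
  a <- if (inherits(old, "membrane")) old$points else as.matrix(old)
  b <- if (inherits(new, "membrane")) new$points else as.matrix(new)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

#' Build the basic concentric vessel cross section
#'
#' Three concentric circular membranes (lumen wall, internal elastic lamina,
#' external wall) on a Cartesian grid, with every grid cell labelled as
#' lumen, intima, media or external tissue by point-in-polygon tests.
#'
#' @param r_lumen,r_iel,r_outer Radii (mm), strictly increasing.
#' @param grid A `sim_grid`; built automatically from `h` when omitted.
#' @param h Grid step (mm), used when `grid` is missing.
#' @param stiffness Length-3 vector of membrane stiffnesses
#'   (lumen wall, IEL, external wall). The external support is stiffest so
#'   that wall growth encroaches on the lumen rather than the surroundings.
#' @param porosity_threshold IEL stress level above which medial SMCs may
#'   cross into the intima.
#' @param r_smc SMC radius (mm), kept with the section for grid validation.
#' @return An object of class `vein_section` with elements `grid`,
#'   `lumen_wall`, `iel`, `external_wall`, `region` (integer matrix) and the
#'   initial areas.
#' @export
build_basic_geometry <- function(r_lumen, r_iel, r_outer, grid = NULL,
                                 h = 0.005,
                                 stiffness = c(1, 2, 50),
                                 porosity_threshold = 0,
                                 r_smc = 0.005) {
  if (!(r_lumen > 0 && r_lumen < r_iel && r_iel < r_outer)) {
    stop("invalid geometry: radii must satisfy 0 < r_lumen < r_iel < r_outer",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- grid_for_vessel(r_outer, h, r_smc = r_smc)
  half_w <- min(grid$nx, grid$ny) * grid$h / 2
  if (half_w < r_outer + 4 * grid$h) {
    stop("invalid geometry: grid does not enclose the outer membrane with a ",
         "4-cell margin", call. = FALSE)
  }
  sp <- grid$h  # point spacing h: half the 2h bound, so stencils never skip
  section <- structure(list(
    grid = grid,
    lumen_wall = membrane_circle(r_lumen, sp, stiffness[1]),
    iel = membrane_circle(r_iel, sp, stiffness[2], porosity_threshold),
    external_wall = membrane_circle(r_outer, sp, stiffness[3]),
    r_smc = r_smc
  ), class = "vein_section")
  section$region <- label_regions(section)
  section$initial_areas <- section_areas(section)
  section
}

#' Label grid cells by vessel sub-domain
#'
#' @param section A `vein_section`.
#' @return Integer nx x ny matrix with codes 0 = lumen, 1 = intima,
#'   2 = media, 3 = external.
#' @export
label_regions <- function(section) {
  g <- section$grid
  cc <- grid_centres(g)
  px <- rep(cc$x, times = g$ny)
  py <- rep(cc$y, each = g$nx)
  in_l <- points_in_polygon(px, py, section$lumen_wall$points)
  in_i <- points_in_polygon(px, py, section$iel$points)
  in_e <- points_in_polygon(px, py, section$external_wall$points)
  reg <- rep(REGION_EXTERNAL, length(px))
  reg[in_e] <- REGION_MEDIA
  reg[in_i] <- REGION_INTIMA
  reg[in_l] <- REGION_LUMEN
  matrix(as.integer(reg), g$nx, g$ny)
}

#' Sub-domain areas of a cross section
#'
#' Areas are computed from the membrane polygons (not the rasterised mask),
#' so they are exact for the discretised curves.
#'
#' @param section A `vein_section`.
#' @return Named vector: `lumen`, `intima`, `media`, `wall` (mm^2).
#' @export
section_areas <- function(section) {
  al <- polygon_area(section$lumen_wall$points)
  ai <- polygon_area(section$iel$points)
  ae <- polygon_area(section$external_wall$points)
  c(lumen = al, intima = ai - al, media = ae - ai, wall = ae - al)
}

#' Fraction of the initial lumen lost to stenosis
#'
#' @param section A `vein_section`.
#' @param initial_lumen_area Reference lumen area (mm^2) at the start of the
#'   follow-up.
#' @return Occlusion fraction in `[0, 1]`.
#' @export
occlusion_fraction <- function(section, initial_lumen_area) {
  stopifnot(initial_lumen_area > 0)
  occ <- 1 - polygon_area(section$lumen_wall$points) / initial_lumen_area
  min(max(occ, 0), 1)
}

#' Seed SMC agents and uniform ECM into the wall
#'
#' Disc-shaped SMC agents are placed by rejection sampling so that their total
#' disc area is the requested fraction of the wall area; the remaining wall is
#' uniform ECM. Cell clocks start at uniformly random phases so divisions are
#' desynchronised from the first step.
#'
#' @param section A `vein_section`.
#' @param smc_fraction Target SMC wall-area fraction (the basic solution uses
#'   0.25, i.e. 25% SMCs, 75% ECM).
#' @param rng A seeded RNG stream from [rng_substream()], or an integer seed.
#' @param r_smc SMC disc radius (mm).
#' @param r_ecm ECM element radius (mm).
#' @param mitotic_cycle,ecm_cycle Clock cycle lengths (h).
#' @return List with `agents` (a tibble: id, x, y, radius, layer,
#'   mitosis_clock, ecm_clock, alive) and `ecm` (an `ecm_field`).
#' @export
seed_cells <- function(section, smc_fraction, rng = 1L, r_smc = section$r_smc,
                       r_ecm = 0.004, mitotic_cycle = 12, ecm_cycle = 2) {
  stopifnot(smc_fraction >= 0, smc_fraction < 1)
  if (!is.function(rng)) rng <- rng_substream(rng, "seeding")
  areas <- section_areas(section)
  disc <- pi * r_smc^2
  n_target <- round(smc_fraction * areas[["wall"]] / disc)
  g <- section$grid
  r_out <- max(sqrt(rowSums(section$external_wall$points^2)))
  r_in <- min(sqrt(rowSums(section$lumen_wall$points^2)))
  xs <- ys <- numeric(0)
  rejections <- 0L
  while (length(xs) < n_target) {
    # uniform in the bounding annulus, thinned to the wall region
    u <- rng(function() stats::runif(2))
    rr <- sqrt(r_in^2 + u[1] * (r_out^2 - r_in^2))
    th <- 2 * pi * u[2]
    x <- rr * cos(th); y <- rr * sin(th)
    reg <- region_at(section, x, y)
    ok <- reg %in% c(REGION_INTIMA, REGION_MEDIA)
    if (ok && length(xs) > 0) {
      # discs may overlap by at most 10% of a radius
      ok <- min((xs - x)^2 + (ys - y)^2) >= (1.9 * r_smc)^2
    }
    if (ok) {
      xs <- c(xs, x); ys <- c(ys, y); rejections <- 0L
    } else {
      rejections <- rejections + 1L
      if (rejections > 1e5) {
        stop("packing error: SMC fraction ", smc_fraction,
             " infeasible for this geometry", call. = FALSE)
      }
    }
  }
  n <- length(xs)
  layer <- ifelse(points_in_polygon(xs, ys, section$iel$points),
                  "intima", "media")
  clocks <- if (n > 0) rng(function()
    cbind(stats::runif(n, 0, mitotic_cycle), stats::runif(n, 0, ecm_cycle)))
  else matrix(0, 0, 2)
  agents <- tibble::tibble(
    id = seq_len(n), x = xs, y = ys, radius = r_smc, layer = layer,
    mitosis_clock = clocks[, 1] %% mitotic_cycle,
    ecm_clock = clocks[, 2] %% ecm_cycle, alive = rep(TRUE, n))
  wall <- section$region == REGION_INTIMA | section$region == REGION_MEDIA
  density <- matrix(0, g$nx, g$ny)
  density[wall] <- 1 - smc_fraction
  ecm <- structure(list(density = density, element_radius = r_ecm),
                   class = "ecm_field")
  list(agents = agents, ecm = ecm)
}

# Region code at arbitrary points, via the rasterised mask (cheap) — vectorised.
region_at <- function(section, x, y) {
  g <- section$grid
  i <- pmin(pmax(ceiling((x - g$origin[1]) / g$h), 1L), g$nx)
  j <- pmin(pmax(ceiling((y - g$origin[2]) / g$h), 1L), g$ny)
  section$region[cbind(i, j)]
}

#' @export
print.vein_section <- function(x, ...) {
  a <- section_areas(x)
  cat(sprintf(paste0("<vein_section> lumen %.4f mm^2, intima %.4f mm^2, ",
                     "media %.4f mm^2 on a %d x %d grid (h = %g mm)\n"),
              a["lumen"], a["intima"], a["media"],
              x$grid$nx, x$grid$ny, x$grid$h))
  invisible(x)
}
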