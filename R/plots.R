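#' Plot a vessel cross section with its SMC agents
#'
#' Draws the three membranes (lumen wall, IEL, external wall) and the SMC
#' disc centres, the package's analogue of the histology-style cross-section
#' figures.
#'
#' @param section A `vein_section`.
#' @param agents Optional agent tibble.
#' @param ecm Optional `ecm_field`, shown as a density raster.
#' @return A ggplot object.
#' @export
plot_cross_section <- function(section, agents = NULL, ecm = NULL) {
  ring <- function(mem, label) {
    p <- mem$points
    tibble::tibble(x = c(p[, 1], p[1, 1]), y = c(p[, 2], p[1, 2]),
                   membrane = label)
  }
  rings <- dplyr::bind_rows(ring(section$lumen_wall, "lumen wall"),
                            ring(section$iel, "IEL"),
                            ring(section$external_wall, "external wall"))
  pl <- ggplot2::ggplot()
  if (!is.null(ecm)) {
    cc <- grid_centres(section$grid)
    df <- tibble::tibble(x = rep(cc$x, times = section$grid$ny),
                         y = rep(cc$y, each = section$grid$nx),
                         density = as.vector(ecm$density))
    pl <- pl + ggplot2::geom_raster(
      data = dplyr::filter(df, .data$density > 0),
      ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
      ggplot2::scale_fill_gradient(low = "grey95", high = "grey55")
  }
  pl <- pl +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(.data$x, .data$y,
                                    colour = .data$membrane))
  if (!is.null(agents) && nrow(agents) > 0) {
    pl <- pl + ggplot2::geom_point(
      data = agents[agents$alive, ],
      ggplot2::aes(.data$x, .data$y), colour = "firebrick", size = 0.8)
  }
  pl + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL,
                  fill = "ECM") +
    ggplot2::theme_minimal()
}

#' Plot the area trajectories of a run
#'
#' Lumen, intimal and medial areas over the follow-up, each normalised to
#' its initial value.
#'
#' @param object A `veinsim_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.veinsim_run <- function(object, ...) {
  tr <- object$trajectory
  df <- tibble::tibble(
    t_h = rep(tr$t_h, 3),
    compartment = rep(c("lumen", "intima", "media"), each = nrow(tr)),
    norm = c(tr$lumen_area / tr$lumen_area[1],
             tr$intimal_area / tr$intimal_area[1],
             tr$medial_area / tr$medial_area[1]))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_h / 24, .data$norm,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "follow-up (days)", y = "area / initial area",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble's mean normalised trajectories with spread
#'
#' @param object A `veinsim_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.veinsim_ensemble <- function(object, ...) {
  m <- object$mean
  df <- tibble::tibble(
    t_h = rep(m$t_h, 3),
    compartment = rep(c("lumen", "intima", "media"), each = nrow(m)),
    mean = c(m$lumen_mean, m$intima_mean, m$media_mean),
    sd = c(m$lumen_sd, m$intima_sd, m$media_sd))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_h / 24, .data$mean,
                                   colour = .data$compartment,
                                   fill = .data$compartment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "follow-up (days)", y = "area / initial area",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibrated dynamical-system fit against its target
#'
#' @param object A `veinsim_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.veinsim_calibration <- function(object, ...) {
  col <- if (object$mode == "lumen") "lumen_norm" else "intimal_norm"
  df <- tibble::tibble(day = object$fit$day,
                       ds = object$fit[[col]],
                       target = object$target)
  ggplot2::ggplot(df, ggplot2::aes(.data$day)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$target,
                                    colour = "hybrid ensemble mean")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ds,
                                    colour = "calibrated dynamical system"),
                       linetype = 2) +
    ggplot2::labs(x = "follow-up (days)",
                  y = paste(object$mode, "area / initial"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
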