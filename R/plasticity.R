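#' Tissue-plasticity (stochastic ABM) parameters
#'
#' Rate coefficients of the hourly stochastic rules for SMC division,
#' apoptosis and migration and for ECM production and degradation. In the
#' basic solution division and apoptosis balance at rate `alpha1` and ECM
#' production and degradation balance at `alpha2`; all probabilities are
#' scaled by the macrophage-activity envelope `A(t)` with peak time
#' `T = alpha3` and relaxation time `deltaT = alpha4`. The shear-driven
#' growth-factor gain on intimal division is `alpha5`, the strain-energy gain
#' on ECM production `alpha6`, and `alpha7`/`alpha8` govern medial SMC
#' migration across the IEL.
#'
#' The coefficient values are not universal constants; the defaults here are
#' chosen so that the basic solution is stationary and a 50% shear drop
#' produces intimal hyperplasia on a weeks time scale, and every run records
#' them in its manifest.
#'
#' @param alpha1 Baseline division/apoptosis probability per completed
#'   mitotic cycle (must be in `[0, 0.5]` so the division/apoptosis
#'   trichotomy stays a probability under unit gains).
#' @param alpha2 Baseline ECM production/degradation probability per
#'   completed ECM cycle.
#' @param alpha3 `T`, time of maximum macrophage activity (h).
#' @param alpha4 `deltaT`, macrophage relaxation time (h).
#' @param alpha5,alpha6,alpha7,alpha8 Gain coefficients (dimensionless).
#' @param mitotic_cycle,ecm_cycle Cycle lengths (h); the hourly step must
#'   divide both.
#' @param step ABM interrogation step (h).
#' @param allow_pre_peak_growth If `TRUE`, use the literal exponential
#'   `A(t) = exp(-(t - T)/deltaT)` also for `t < T`, where it exceeds 1.
#'   Default `FALSE` clamps `A(t) <= 1` so activity peaks at `T`.
#' @param division_layers Layers in which SMC division/apoptosis runs
#'   (default intima only; medial proliferation is off by default).
#' @param enable_apoptosis Set `FALSE` to switch apoptosis off entirely
#'   (degenerate forced-growth experiments).
#' @param ecm_layers Layers in which ECM production/degradation runs.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha1 = 0.05, alpha2 = 0.05, alpha3 = 24,
                              alpha4 = 168, alpha5 = 4.6, alpha6 = 1,
                              alpha7 = 0.02, alpha8 = 1,
                              mitotic_cycle = 12, ecm_cycle = 2, step = 1,
                              allow_pre_peak_growth = FALSE,
                              division_layers = "intima",
                              ecm_layers = c("intima", "media"),
                              enable_apoptosis = TRUE) {
  stopifnot(alpha1 >= 0, alpha1 <= 1, alpha2 >= 0, alpha2 <= 1,
            alpha4 > 0, step > 0,
            mitotic_cycle %% step == 0, ecm_cycle %% step == 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 alpha4 = alpha4, alpha5 = alpha5, alpha6 = alpha6,
                 alpha7 = alpha7, alpha8 = alpha8,
                 mitotic_cycle = mitotic_cycle, ecm_cycle = ecm_cycle,
                 step = step,
                 allow_pre_peak_growth = allow_pre_peak_growth,
                 division_layers = division_layers, ecm_layers = ecm_layers,
                 enable_apoptosis = enable_apoptosis),
            class = "plasticity_params")
}

#' Macrophage activity envelope A(t)
#'
#' `A(t) = exp(-(t - T)/deltaT)` with `T = alpha3` (time of maximum
#' macrophage activity) and `deltaT = alpha4` (relaxation time). Because the
#' literal exponential exceeds 1 before the peak, `A` is clamped to at most 1
#' for `t < T` unless `allow_pre_peak_growth` is set.
#'
#' @param t Time (h), vectorised.
#' @param params A `plasticity_params`.
#' @export
macrophage_activity <- function(t, params) {
  A <- exp(-(t - params$alpha3) / params$alpha4)
  if (!params$allow_pre_peak_growth) A <- pmin(A, 1)
  A
}

#' Per-event probabilities for an agent or site
#'
#' Evaluates the stochastic rule set: intimal division gains with the local
#' growth-factor level (shear deficit driven), ECM production gains with the
#' strain-energy excess in the media, apoptosis and ECM degradation stay at
#' their baselines, and medial migration gains with the growth factor. Every
#' probability is scaled by `A(t)` and clipped to `[0, 1]`.
#'
#' @param G Dimensionless growth-factor level at the agent position.
#' @param dsig_rel Relative strain-energy excess `(sigma - sigma_bar) /
#'   sigma_bar` at the site.
#' @param layer `"intima"` or `"media"`, vectorised with `G`.
#' @param t Time (h).
#' @param params A `plasticity_params`.
#' @return A tibble with columns `division`, `apoptosis`, `production`,
#'   `degradation`, `migration`.
#' @export
event_probabilities <- function(G, dsig_rel, layer, t, params) {
  A <- macrophage_activity(t, params)
  n <- max(length(G), length(layer))
  G <- rep_len(G, n); dsig_rel <- rep_len(dsig_rel, n)
  layer <- rep_len(layer, n)
  clip <- function(p) pmin(pmax(p, 0), 1)
  div_on <- layer %in% params$division_layers
  ecm_on <- layer %in% params$ecm_layers
  p_div <- clip(params$alpha1 * A *
                  ifelse(layer == "intima", 1 + params$alpha5 * G, 1)) * div_on
  p_apo <- clip(params$alpha1 * A) * div_on *
    isTRUE(params$enable_apoptosis)
  p_pro <- clip(params$alpha2 * A *
                  ifelse(layer == "media", 1 + params$alpha6 * dsig_rel, 1)) *
    ecm_on
  p_deg <- clip(params$alpha2 * A) * ecm_on
  p_mig <- clip(params$alpha7 * A * (1 + params$alpha8 * G)) *
    (layer == "media")
  if (any(p_div + p_apo > 1 + 1e-12))
    stop("configuration error: p_division + p_apoptosis exceeds 1; ",
         "reduce alpha1 or alpha5", call. = FALSE)
  if (any(p_pro + p_deg > 1 + 1e-12))
    stop("configuration error: p_production + p_degradation exceeds 1; ",
         "reduce alpha2 or alpha6", call. = FALSE)
  tibble::tibble(division = p_div, apoptosis = p_apo, production = p_pro,
                 degradation = p_deg, migration = p_mig)
}

#' One hourly interrogation of the agent-based model
#'
#' Advances every live agent's mitotic and ECM clocks by one step. Agents
#' whose mitotic clock completes draw division / apoptosis / nothing as a
#' mutually exclusive trichotomy; agents whose ECM clock completes draw
#' production / degradation / nothing at their site; medial agents adjacent
#' to the IEL (within one SMC diameter) draw migration hourly, executed only
#' where the local IEL segment stress exceeds the membrane's porosity
#' threshold. An agent contributes at most one event per step (mitotic fate
#' takes precedence over ECM turnover, which takes precedence over
#' migration). The batch is returned in randomised agent order.
#'
#' @param agents Agent tibble (see [seed_cells()]).
#' @param section A `vein_section`.
#' @param fields A `field_set` from [compute_fields()].
#' @param dsig_rel nx x ny matrix of relative strain-energy excess (0 in the
#'   basic solution).
#' @param t Time (h).
#' @param rng A seeded stream from [rng_substream()].
#' @param params A `plasticity_params`.
#' @return List: `batch` (tibble `kind`, `x`, `y`, `agent_id`), `agents`
#'   (clock-advanced tibble).
#' @export
step_plasticity <- function(agents, section, fields, dsig_rel, t, rng,
                            params) {
  live <- which(agents$alive)
  n <- length(live)
  empty <- tibble::tibble(kind = character(0), x = numeric(0),
                          y = numeric(0), agent_id = integer(0))
  if (n == 0) return(list(batch = empty, agents = agents))
  g <- section$grid
  Gv <- interp_field(fields$G, g, agents$x[live], agents$y[live])
  dsv <- interp_field(dsig_rel, g, agents$x[live], agents$y[live])
  probs <- event_probabilities(Gv, dsv, agents$layer[live], t, params)

  mit_done <- (agents$mitosis_clock[live] + params$step) >=
    params$mitotic_cycle
  ecm_done <- (agents$ecm_clock[live] + params$step) >= params$ecm_cycle
  agents$mitosis_clock[live] <- (agents$mitosis_clock[live] + params$step) %%
    params$mitotic_cycle
  agents$ecm_clock[live] <- (agents$ecm_clock[live] + params$step) %%
    params$ecm_cycle

  near_iel <- abs(distance_to_membrane(agents$x[live], agents$y[live],
                                       section$iel)) <= 2 * agents$radius[live]
  draws <- rng(function() list(u_mit = stats::runif(n),
                               u_ecm = stats::runif(n),
                               u_mig = stats::runif(n),
                               ord = sample.int(n)))

  kind <- rep(NA_character_, n)
  mit <- mit_done & draws$u_mit < probs$division
  apo <- mit_done & !mit & draws$u_mit < probs$division + probs$apoptosis
  kind[mit] <- "mitosis"; kind[apo] <- "apoptosis"
  pro <- is.na(kind) & ecm_done & draws$u_ecm < probs$production
  deg <- is.na(kind) & ecm_done & !pro &
    draws$u_ecm < probs$production + probs$degradation
  kind[pro] <- "ecm_production"; kind[deg] <- "ecm_degradation"
  mig <- is.na(kind) & near_iel & draws$u_mig < probs$migration
  if (any(mig)) {
    stress <- iel_stress_at(section, agents$x[live][mig], agents$y[live][mig])
    mig[mig] <- stress > section$iel$porosity_threshold
  }
  kind[mig] <- "migration"

  sel <- draws$ord[!is.na(kind[draws$ord])]
  batch <- tibble::tibble(kind = kind[sel],
                          x = agents$x[live][sel],
                          y = agents$y[live][sel],
                          agent_id = agents$id[live][sel])
  list(batch = batch, agents = agents)
}

# Unsigned distance from points to the closest membrane vertex.
distance_to_membrane <- function(x, y, mem) {
  pts <- mem$points
  d2 <- outer(x, pts[, 1], "-")^2 + outer(y, pts[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

# Tensile stress (stiffness x |relative stretch|) of the IEL segment nearest
# to each query point; governs membrane porosity to migrating SMCs.
iel_stress_at <- function(section, x, y) {
  mem <- section$iel
  len <- segment_lengths(mem$points)
  stress <- mem$stiffness * abs(len - mem$rest_lengths) / mem$rest_lengths
  idx <- nearest_point_index(x, y, mem$points)
  stress[idx]
}
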