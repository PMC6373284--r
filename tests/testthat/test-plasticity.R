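test_that("macrophage activity peaks at T and relaxes exponentially", {
  p <- plasticity_params(alpha3 = 24, alpha4 = 168)
  expect_equal(macrophage_activity(24, p), 1)
  expect_equal(macrophage_activity(24 + 168, p), exp(-1))
  # clamped before the peak by default; literal formula behind the flag
  expect_equal(macrophage_activity(0, p), 1)
  p_lit <- plasticity_params(alpha3 = 24, alpha4 = 168,
                             allow_pre_peak_growth = TRUE)
  expect_equal(macrophage_activity(0, p_lit), exp(24 / 168))
  # monotone decay after the peak
  a <- macrophage_activity(seq(24, 1000, by = 8), p)
  expect_true(all(diff(a) < 0))
  expect_lt(macrophage_activity(24 + 10 * 168, p), 1e-4)
})

test_that("basic-solution balance: equal division/apoptosis and ECM rates", {
  p <- plasticity_params(alpha1 = 0.05, alpha2 = 0.05, alpha3 = 24)
  pr <- event_probabilities(G = 0, dsig_rel = 0, layer = "intima", t = 24, p)
  expect_equal(pr$division, 0.05)
  expect_equal(pr$apoptosis, 0.05)
  expect_equal(pr$production, 0.05)
  expect_equal(pr$degradation, 0.05)
})

test_that("growth-factor and strain gains raise the stimulated rates", {
  p <- plasticity_params(alpha1 = 0.1, alpha5 = 2, alpha6 = 1, alpha3 = 24)
  # alpha5 * G = 1 doubles intimal division at the activity peak
  pr <- event_probabilities(G = 0.5, dsig_rel = 0, layer = "intima", 24, p)
  expect_equal(pr$division, 0.2)
  expect_equal(pr$apoptosis, 0.1)
  # strain-energy excess raises medial ECM production only
  pr2 <- event_probabilities(G = 0, dsig_rel = 0.5, layer = "media", 24, p)
  expect_equal(pr2$production, p$alpha2 * 1.5)
  expect_equal(pr2$degradation, p$alpha2)
  # zero coefficients give zero probabilities
  p0 <- plasticity_params(alpha1 = 0, alpha2 = 0, alpha7 = 0)
  pr0 <- event_probabilities(G = 1, dsig_rel = 1, layer = "intima", 24, p0)
  expect_true(all(as.matrix(pr0) == 0))
})

test_that("probabilities are clipped to [0, 1] for any field values", {
  p <- plasticity_params(alpha1 = 0.4, alpha5 = 50, alpha7 = 1, alpha8 = 100)
  for (G in c(-5, 0, 0.5, 3, 100)) {
    pr <- event_probabilities(G, dsig_rel = -10, layer = "media", 24, p)
    expect_true(all(as.matrix(pr) >= 0 & as.matrix(pr) <= 1))
  }
})

test_that("raising G never decreases the division probability", {
  p <- plasticity_params(alpha5 = 4.6)
  g <- seq(0, 2, by = 0.05)
  pd <- event_probabilities(g, 0, "intima", 24, p)$division
  expect_true(all(diff(pd) >= 0))
})

test_that("overloaded division rates raise a configuration error", {
  p <- plasticity_params(alpha1 = 0.9, alpha5 = 10)
  expect_error(event_probabilities(1, 0, "intima", 24, p),
               "configuration error")
})

# A minimal deterministic environment for stepping the ABM.
plasticity_env <- function(G_level = 0) {
  sec <- std_section()
  fields <- list(G = matrix(G_level, sec$grid$nx, sec$grid$ny),
                 sigma = matrix(0, sec$grid$nx, sec$grid$ny))
  dsig <- matrix(0, sec$grid$nx, sec$grid$ny)
  list(sec = sec, fields = fields, dsig = dsig)
}

test_that("forced division: every completing agent divides", {
  env <- plasticity_env()
  p <- plasticity_params(alpha1 = 1, alpha2 = 0, alpha5 = 0, alpha7 = 0,
                         enable_apoptosis = FALSE)
  ag <- seed_cells(env$sec, 0.2, rng = 3)$agents
  ag$mitosis_clock <- p$mitotic_cycle - 0.5   # all complete this hour
  ag$ecm_clock <- 0
  rng <- rng_substream(1, "plasticity")
  # alpha1 = 1 means p_division = 1 and apoptosis can never be drawn
  out <- step_plasticity(ag, env$sec, env$fields, env$dsig, t = 24, rng, p)
  intimal <- sum(ag$layer == "intima")
  expect_equal(sum(out$batch$kind == "mitosis"), intimal)
  expect_equal(sum(out$batch$kind == "apoptosis"), 0)
})

test_that("division counts follow the binomial law", {
  env <- plasticity_env()
  p <- plasticity_params(alpha1 = 0.3, alpha2 = 0, alpha7 = 0, alpha3 = 24)
  ag <- seed_cells(env$sec, 0.25, rng = 5)$agents
  ag <- ag[ag$layer == "intima", ]
  ag$mitosis_clock <- p$mitotic_cycle - 0.5
  M <- nrow(ag)
  counts <- vapply(1:20, function(s) {
    rng <- rng_substream(s, "plasticity")
    out <- step_plasticity(ag, env$sec, env$fields, env$dsig, 24, rng, p)
    sum(out$batch$kind == "mitosis")
  }, numeric(1))
  expect_lt(abs(mean(counts) - M * 0.3),
            3 * sqrt(M * 0.3 * 0.7 / 20))
})

test_that("division and apoptosis are exchangeable in the basic solution", {
  # over ~10^3 completing agent-cycles the net drift stays within 4 binomial
  # standard deviations
  env <- plasticity_env()
  p <- plasticity_params(alpha1 = 0.2, alpha2 = 0, alpha7 = 0, alpha3 = 24)
  ag <- seed_cells(env$sec, 0.25, rng = 11)$agents
  ag <- ag[ag$layer == "intima", ]
  ag$mitosis_clock <- p$mitotic_cycle - 0.5
  ndiv <- napo <- 0
  for (s in 1:10) {
    rng <- rng_substream(100 + s, "plasticity")
    out <- step_plasticity(ag, env$sec, env$fields, env$dsig, 24, rng, p)
    ndiv <- ndiv + sum(out$batch$kind == "mitosis")
    napo <- napo + sum(out$batch$kind == "apoptosis")
  }
  M <- nrow(ag) * 10
  expect_lt(abs(ndiv - napo), 4 * sqrt(2 * M * 0.2 * 0.8))
})

test_that("clocks advance, reset on completion, and events are exclusive", {
  env <- plasticity_env()
  p <- plasticity_params(alpha1 = 0.5, alpha2 = 0.5, alpha3 = 24)
  ag <- seed_cells(env$sec, 0.2, rng = 2)$agents
  rng <- rng_substream(3, "plasticity")
  out <- step_plasticity(ag, env$sec, env$fields, env$dsig, 24, rng, p)
  expect_equal(out$agents$mitosis_clock,
               (ag$mitosis_clock + 1) %% p$mitotic_cycle)
  expect_equal(out$agents$ecm_clock, (ag$ecm_clock + 1) %% p$ecm_cycle)
  # at most one event per agent per step
  expect_false(any(duplicated(out$batch$agent_id)))
  # all event locations inside the wall
  reg <- veinsim:::region_at(env$sec, out$batch$x, out$batch$y)
  expect_true(all(reg %in% c(1L, 2L)))
})

test_that("the seeded stream makes the event sequence reproducible", {
  env <- plasticity_env(G_level = 0.5)
  p <- plasticity_params()
  ag <- seed_cells(env$sec, 0.25, rng = 4)$agents
  b1 <- step_plasticity(ag, env$sec, env$fields, env$dsig, 24,
                        rng_substream(9, "plasticity"), p)$batch
  b2 <- step_plasticity(ag, env$sec, env$fields, env$dsig, 24,
                        rng_substream(9, "plasticity"), p)$batch
  expect_identical(b1, b2)
})

test_that("migration requires IEL porosity to be exceeded", {
  env <- plasticity_env(G_level = 1)
  # place a medial agent right on the IEL; migration probability forced to 1
  p <- plasticity_params(alpha1 = 0, alpha2 = 0, alpha7 = 1, alpha8 = 0,
                         alpha3 = 24)
  ag <- agents_at(0.281, 0, layer = "media")
  rng <- rng_substream(1, "plasticity")
  # membranes at rest: stress 0, not above the threshold -> no migration
  out <- step_plasticity(ag, env$sec, env$fields, env$dsig, 24, rng, p)
  expect_equal(nrow(out$batch), 0)
  # stretch the IEL so its stress exceeds the (zero) porosity threshold
  sec2 <- env$sec
  sec2$iel$rest_lengths <- sec2$iel$rest_lengths * 0.9
  out2 <- step_plasticity(ag, sec2, env$fields, env$dsig, 24,
                          rng_substream(1, "plasticity"), p)
  expect_equal(out2$batch$kind, "migration")
})
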