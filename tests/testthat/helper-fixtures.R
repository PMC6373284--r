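# Shared small fixtures: a coarse standard vessel section and parameter sets
# sized so unit tests run in seconds.

std_section <- function(h = 0.01, r_smc = 0.005) {
  build_basic_geometry(0.24, 0.28, 0.3, h = h, r_smc = r_smc)
}

std_mech <- function(...) mechanics_params(r_smc = 0.005, ...)

std_rem <- function(...) remodeling_params(r_smc = 0.005, ...)

# Agent tibble at explicit positions, all other fields defaulted.
agents_at <- function(x, y, layer = "intima", radius = 0.005) {
  n <- length(x)
  tibble::tibble(id = seq_len(n), x = x, y = y, radius = radius,
                 layer = rep_len(layer, n), mitosis_clock = 0,
                 ecm_clock = 0, alive = TRUE)
}

# Uniform ECM field over the wall of a section.
uniform_ecm <- function(section, density = 0.75, r_ecm = 0.004) {
  d <- matrix(0, section$grid$nx, section$grid$ny)
  d[section$region == 1L | section$region == 2L] <- density
  structure(list(density = d, element_radius = r_ecm), class = "ecm_field")
}
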