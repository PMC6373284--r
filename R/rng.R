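#' Named, reproducible RNG sub-streams
#'
#' Each simulation run draws from independent named sub-streams (seeding,
#' plasticity, motility, calibration, ...) derived from one base seed, so that
#' switching one stochastic component on or off does not shift the draws of
#' any other. A sub-stream is a closure: call it with a thunk that performs
#' base-R random draws and it evaluates the thunk under the stream's saved
#' `.Random.seed`, then puts the global RNG state back.
#'
#' @param seed Integer base seed.
#' @param name Stream name; the pair (seed, name) determines the stream.
#' @return A function `f(thunk)` evaluating `thunk()` on the stream.
#' @examples
#' r <- rng_substream(1, "motility")
#' r(function() runif(2))
#' @export
rng_substream <- function(seed, name = "default") {
  # fold the name into the seed with a small string hash (31-based, mod 2^31-1)
  hv <- 0
  for (ch in utf8ToInt(name)) hv <- (hv * 31 + ch) %% 2147483647
  sub_seed <- as.integer((as.numeric(seed) * 7919 + hv) %% 2147483647)
  state_env <- new.env(parent = emptyenv())
  local({
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(sub_seed, kind = "Mersenne-Twister")
    state_env$state <- .Random.seed
  })
  function(thunk) {
    old <- get_rng_state()
    assign(".Random.seed", state_env$state, envir = globalenv())
    res <- thunk()
    state_env$state <- .Random.seed
    set_rng_state(old)
    res
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Bundle of the sub-streams a run needs.
make_run_rng <- function(seed) {
  list(
    seeding = rng_substream(seed, "seeding"),
    plasticity = rng_substream(seed, "plasticity"),
    motility = rng_substream(seed, "motility"),
    placement = rng_substream(seed, "placement")
  )
}
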