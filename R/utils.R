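#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 31-bit seed derivation: one root seed per run is split into
## independent substreams (population vs allocation) per replicate, so that
## changing the allocation rule or learner never perturbs the simulated
## patient population.  The multiplier is kept below 2^22 so every product
## stays exactly representable in a double.
MOD31 <- 2147483629  # largest prime < 2^31

derive_seed <- function(seed, replicate, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  state <- (abs(seed) %% MOD31)
  for (v in c(replicate, stream, 17L)) {
    state <- (state * 69069 + v * 2971 + 1) %% MOD31
    state <- (state * 69069 + 101) %% MOD31
  }
  as.integer(state %% 2147483647) + 1L
}

#' Derive the reproducible random streams of one replicate
#'
#' Every replicate of a simulated trial uses two independent random streams:
#' a *population* stream (biomarkers, counterfactual latent outcomes,
#' arrival gaps, dropout) and an *allocation* stream (burn-in permutation,
#' randomized assignment, tie-breaks, learner-internal randomness). Keeping
#' them separate means two designs run with the same root seed see the same
#' patients, which sharpens design comparisons.
#'
#' @param seed integer root seed.
#' @param replicate replicate index (1-based).
#' @return named list with integer elements `population` and `allocation`.
#' @export
replicate_seeds <- function(seed, replicate = 1L) {
  list(population = derive_seed(seed, replicate, 1L),
       allocation = derive_seed(seed, replicate, 2L))
}
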