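## Shared fixtures and independent oracles for the test suite.

## Brute-force logrank tabulation: walk the distinct event times, count the
## risk sets by hand, and accumulate observed-minus-expected deaths in group 1
## with the hypergeometric variance (multi-death correction included).  Kept
## deliberately naive and separate from the package implementation.
brute_force_logrank <- function(time, event, arm) {
  stopifnot(length(unique(arm)) == 2L)
  groups <- sort(unique(arm))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == groups[1L])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & arm == groups[1L])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chisq = 0, O = O, E = E, V = V))
  list(chisq = (O - E)^2 / V, O = O, E = E, V = V)
}

## Minimal hand-built trial object for evaluation-function unit tests.
fake_trial <- function(scenario, x, arm, latent, L = 1L,
                       time = NULL, event = NULL) {
  K <- scenario$K
  n <- length(arm)
  p <- data.frame(n = seq_len(n), arrival_day = seq_len(n) - 1L)
  if (is_survival_scenario(scenario)) {
    p$x1 <- x[, 1L]; p$x2 <- x[, 2L]
  } else {
    p$x1 <- x
  }
  p$arm <- arm
  p$latent_outcome <- latent[cbind(seq_len(n), arm)]
  p$observed_time <- time %||% NA_integer_
  p$event <- event %||% NA
  p$best_arm <- p$latent_outcome >= apply(latent, 1L, max) - 1e-12
  p$pi_n <- NA_real_
  ## built directly (not via trial_config) so tiny hand-made trials are not
  ## rejected by the L*K < N validation
  cfg <- structure(list(N = n, K = K, L = L, pi_start = 1 / K, pi_end = 0.1,
                        learner = "fixed", burn_in = "balanced",
                        alpha_one_sided = 0.025, alpha_two_sided = 0.05,
                        alpha_one_sided_subgroup = 0.0125,
                        alpha_two_sided_subgroup = 0.025,
                        learner_opts = list()),
                   class = "cara_config")
  structure(list(patients = p, latent = latent, scenario = scenario,
                 config = cfg, seed = 0L, replicate = 1L),
            class = "cara_trial")
}

is_survival_scenario <- function(s) identical(s$setting, "survival")

`%||%` <- function(a, b) if (is.null(a)) b else a

## 3-sigma Monte-Carlo band for a binomial proportion at nominal p.
mc_band <- function(p, n) 3 * sqrt(p * (1 - p) / n)
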