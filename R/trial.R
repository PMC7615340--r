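## Trial engine ---------------------------------------------------------------
##
## Sequential CARA design: an equal-probability burn-in of L patients per arm,
## then, for each incoming patient, every arm's learner is refit on the data
## available at that patient's arrival, the arm with the best predicted
## outcome is identified, and the patient is randomized with probability
## 1 - (K - 1) * pi_n to that arm and pi_n to each other arm, where pi_n
## decays linearly from pi_start (at the last burn-in patient) to pi_end (at
## patient N).

#' Build a trial configuration
#'
#' @param N total sample size.
#' @param learner learner family (see [learner_families()]), or `"fixed"` for
#'   equal fixed randomization throughout, or `"oracle"` for an allocator that
#'   knows the true mean-outcome functions.
#' @param K number of arms (the shipped scenarios use 2).
#' @param L burn-in patients per arm (default 5).
#' @param pi_start,pi_end endpoints of the linearly decaying randomization
#'   sequence; defaults `1/K` and 0.1. Must satisfy
#'   `0 <= pi_end <= pi_start <= 1/K`.
#' @param burn_in `"balanced"` (exactly `L` patients per arm, order
#'   randomized; the default, which guarantees every arm `L` observations
#'   before the first model fit) or `"bernoulli"` (independent equal-probability
#'   draws).
#' @param alpha_one_sided,alpha_two_sided nominal overall test levels
#'   (defaults 0.025 / 0.05).
#' @param alpha_one_sided_subgroup,alpha_two_sided_subgroup nominal levels for
#'   biomarker-subgroup tests (defaults 0.0125 / 0.025).
#' @param learner_opts list of learner hyperparameters: `degree`
#'   (polynomial), `k_neighbors`, `n_trees`, `gp_refresh` (re-run the GP
#'   hyperparameter search every this many new patients per arm; default 5).
#' @return object of class `cara_config`.
#' @export
trial_config <- function(N, learner,
                         K = 2L, L = 5L,
                         pi_start = 1 / K, pi_end = 0.1,
                         burn_in = c("balanced", "bernoulli"),
                         alpha_one_sided = 0.025, alpha_two_sided = 0.05,
                         alpha_one_sided_subgroup = 0.0125,
                         alpha_two_sided_subgroup = 0.025,
                         learner_opts = list()) {
  burn_in <- match.arg(burn_in)
  N <- as.integer(N); K <- as.integer(K); L <- as.integer(L)
  stopifnot(K >= 2L, L >= 1L, L * K < N,
            pi_end >= 0, pi_end <= pi_start, pi_start <= 1 / K + 1e-12)
  alphas <- c(alpha_one_sided, alpha_two_sided,
              alpha_one_sided_subgroup, alpha_two_sided_subgroup)
  stopifnot(all(alphas > 0 & alphas < 1))
  structure(list(N = N, K = K, L = L,
                 pi_start = pi_start, pi_end = pi_end,
                 learner = learner, burn_in = burn_in,
                 alpha_one_sided = alpha_one_sided,
                 alpha_two_sided = alpha_two_sided,
                 alpha_one_sided_subgroup = alpha_one_sided_subgroup,
                 alpha_two_sided_subgroup = alpha_two_sided_subgroup,
                 learner_opts = learner_opts),
            class = "cara_config")
}

#' @export
print.cara_config <- function(x, ...) {
  cat(sprintf("<cara_config> N=%d K=%d L=%d pi: %.3g -> %.3g learner=%s (%s burn-in)\n",
              x$N, x$K, x$L, x$pi_start, x$pi_end, x$learner, x$burn_in))
  invisible(x)
}

#' Randomization sequence pi_n
#'
#' Linear decay anchored at the last burn-in patient: `pi_n = pi_start` at
#' `n = L*K`, `pi_n = pi_end` at `n = N`, affine in between.
#'
#' @param n enrollment index (or vector), must lie in `[L*K, N]`.
#' @param config a [trial_config()].
#' @return non-best-arm assignment probability.
#' @export
pi_sequence <- function(n, config) {
  n0 <- config$L * config$K
  if (any(n < n0 | n > config$N)) {
    stop(sprintf("enrollment index must lie in [%d, %d]", n0, config$N))
  }
  config$pi_start + (config$pi_end - config$pi_start) * (n - n0) / (config$N - n0)
}

#' Per-arm assignment probabilities given the estimated best arm
#'
#' The estimated best arm receives `1 - (K - 1) * pi_n`; every other arm
#' receives `pi_n`.
#'
#' @param best_arm index of the estimated best arm.
#' @param pi_n non-best-arm probability, in `[0, 1/K]`.
#' @param K number of arms.
#' @return probability vector of length `K` summing to one.
#' @export
assignment_probabilities <- function(best_arm, pi_n, K) {
  stopifnot(best_arm %in% seq_len(K))
  if (pi_n < 0 || pi_n > 1 / K + 1e-12) {
    stop("pi_n must lie in [0, 1/K]: the best arm's probability may not fall below the others'")
  }
  p <- rep(pi_n, K)
  p[best_arm] <- 1 - (K - 1) * pi_n
  p
}

#' Burn-in arm assignments
#'
#' `"balanced"` draws a random permutation of exactly `L` copies of each arm;
#' `"bernoulli"` draws each arm independently with equal probability.
#'
#' @param config a [trial_config()].
#' @return integer vector of length `L*K`.
#' @export
burn_in_assign <- function(config) {
  if (config$burn_in == "balanced") {
    sample(rep(seq_len(config$K), config$L))
  } else {
    sample.int(config$K, config$L * config$K, replace = TRUE)
  }
}

#' Allocate the next patient from per-arm predictions
#'
#' Identifies the arm with the best predicted outcome (ties broken uniformly
#' at random) and samples the assignment from [assignment_probabilities()].
#'
#' @param predictions numeric vector of per-arm predicted outcomes at the
#'   incoming patient's biomarker value.
#' @param pi_n current value of the randomization sequence.
#' @return list with `arm` (assigned), `best` (estimated best arm) and
#'   `probs`.
#' @export
allocate_next <- function(predictions, pi_n) {
  K <- length(predictions)
  if (any(!is.finite(predictions))) stop("non-finite learner prediction")
  top <- which(predictions == max(predictions))
  best <- if (length(top) > 1L) top[sample.int(length(top), 1L)] else top
  probs <- assignment_probabilities(best, pi_n, K)
  arm <- sample.int(K, 1L, prob = probs)
  list(arm = arm, best = best, probs = probs)
}

## Population draw (population stream): everything about the patients that
## does not depend on the allocation rule, including counterfactual latent
## outcomes under every arm.
draw_population <- function(scenario, N) {
  K <- scenario$K
  if (is_survival(scenario)) {
    x <- draw_biomarker(scenario, N)
    arrivals <- draw_arrivals(N, scenario$arrival_mean)
    u_out <- matrix(stats::runif(N * K), N, K)
    latent <- vapply(seq_len(K), function(k) {
      draw_survival_outcome(scenario, k, x, u = u_out[, k])
    }, integer(N))
    list(x = x, arrival = arrivals, latent = latent,
         u_dropout = stats::runif(N), u_ctime = stats::runif(N))
  } else {
    x <- draw_biomarker(scenario, N)
    z <- stats::rnorm(N)     # one shared noise deviate per patient
    latent <- vapply(seq_len(K), function(k) {
      draw_continuous_outcome(scenario, k, x, z = z)
    }, numeric(N))
    list(x = x, arrival = seq_len(N) - 1L, latent = latent)
  }
}

arm_dataset <- function(scenario, pop, arms, upto, current_day,
                        final_time, final_event, arm) {
  prev <- seq_len(upto)
  mine <- prev[arms[prev] == arm]
  if (is_survival(scenario)) {
    if (length(mine) == 0L) return(NULL)
    iv <- interim_view(pop$arrival, final_time, final_event,
                       current_day, keep = mine)
    if (nrow(iv) == 0L) return(NULL)
    list(x = pop$x[iv$idx, , drop = FALSE], time = iv$time, event = iv$event)
  } else {
    if (length(mine) == 0L) return(NULL)
    list(x = pop$x[mine], y = pop$latent[cbind(mine, arms[mine])])
  }
}

#' Simulate one trial
#'
#' Runs the full sequential design on a freshly drawn patient population:
#' burn-in, per-patient learner refits on the data available at each arrival
#' (continuous outcomes are known immediately; survival outcomes enter
#' through the interim-censored view), probabilistic allocation, outcome
#' generation, and administrative censoring at six months after the last
#' arrival (survival setting).
#'
#' @param scenario a [cara_scenario()].
#' @param config a [trial_config()]; its learner must match the scenario
#'   setting (`"fixed"` and `"oracle"` work in both).
#' @param seed root seed.
#' @param replicate replicate index; `(seed, replicate)` determine the
#'   independent population and allocation streams (see [replicate_seeds()]).
#' @return object of class `cara_trial`: a per-patient data frame plus the
#'   counterfactual latent-outcome matrix and run metadata. Identical
#'   arguments give bit-identical results.
#' @export
run_trial <- function(scenario, config, seed, replicate = 1L) {
  stopifnot(inherits(scenario, "cara_scenario"), inherits(config, "cara_config"),
            scenario$K == config$K)
  surv <- is_survival(scenario)
  fam <- config$learner
  if (!fam %in% c("fixed", "oracle")) {
    ok <- fam %in% learner_families(if (surv) "survival" else "continuous")
    if (!ok) stop(sprintf("learner '%s' is not available for %s outcomes",
                          fam, scenario$setting))
  }
  N <- config$N; K <- config$K; n0 <- config$L * config$K
  seeds <- replicate_seeds(seed, replicate)

  set.seed(seeds$population)
  pop <- draw_population(scenario, N)

  set.seed(seeds$allocation)
  arms <- integer(N)
  pis <- rep(NA_real_, N)
  best_est <- rep(NA_integer_, N)
  final_time <- integer(N); final_event <- logical(N)

  arms[seq_len(n0)] <- burn_in_assign(config)
  record_outcome <- function(n) {
    if (surv) {
      ## inline apply_dropout(): called once per patient in the hot loop
      latent <- pop$latent[n, arms[n]]
      drop_n <- pop$u_dropout[n] < scenario$dropout[arms[n]]
      final_time[n] <<- if (drop_n) as.integer(ceiling(pop$u_ctime[n] * latent)) else latent
      final_event[n] <<- !drop_n
    }
  }
  for (n in seq_len(n0)) record_outcome(n)

  gp_state <- vector("list", K)   # cached GP hyperparameters per arm
  gp_refresh <- config$learner_opts$gp_refresh %||% 5L

  for (n in (n0 + 1L):N) {
    pi_n <- pi_sequence(n, config)
    pis[n] <- pi_n
    if (fam == "fixed") {
      pis[n] <- 1 / K
      arms[n] <- sample.int(K, 1L)
    } else {
      xn <- if (surv) pop$x[n, , drop = FALSE] else pop$x[n]
      preds <- numeric(K)
      for (k in seq_len(K)) {
        if (fam == "oracle") {
          preds[k] <- mean_outcome(scenario, k, xn)
        } else {
          dat <- arm_dataset(scenario, pop, arms, n - 1L, pop$arrival[n],
                             final_time, final_event, k)
          if (is.null(dat)) {
            stop("arm ", k, " has no usable observations at patient ", n,
                 "; increase the burn-in")
          }
          hyp <- NULL
          if (fam == "gp") {
            st <- gp_state[[k]]
            n_arm <- length(dat$y)
            if (!is.null(st) && n_arm - st$n_at_fit < gp_refresh) hyp <- st$hyp
          }
          fitted <- fit_arm_learner(fam, dat, config$learner_opts, hyp = hyp)
          if (fam == "gp" && is.null(hyp)) {
            gp_state[[k]] <- list(hyp = fitted$state$hyp, n_at_fit = length(dat$y))
          }
          preds[k] <- predict_cara(fitted, xn)
        }
      }
      alloc <- allocate_next(preds, pi_n)
      arms[n] <- alloc$arm
      best_est[n] <- alloc$best
    }
    record_outcome(n)
  }

  if (surv) {
    final_day <- pop$arrival[N] + scenario$followup_days
    adm <- administrative_censor(pop$arrival, final_time, final_event, final_day)
    final_time <- adm$time; final_event <- adm$event
  }

  assigned_latent <- pop$latent[cbind(seq_len(N), arms)]
  best_ind <- assigned_latent >= apply(pop$latent, 1L, max) - 1e-12

  patients <- data.frame(n = seq_len(N), arrival_day = pop$arrival)
  if (surv) {
    patients$x1 <- pop$x[, 1L]; patients$x2 <- pop$x[, 2L]
  } else {
    patients$x1 <- pop$x
  }
  patients$arm <- arms
  patients$latent_outcome <- assigned_latent
  patients$observed_time <- if (surv) final_time else NA_integer_
  patients$event <- if (surv) final_event else NA
  patients$best_arm <- best_ind
  patients$pi_n <- pis

  structure(list(patients = patients, latent = pop$latent,
                 scenario = scenario, config = config,
                 seed = seed, replicate = replicate,
                 best_estimated = best_est,
                 final_day = if (surv) final_day else NA_integer_),
            class = "cara_trial")
}

#' @export
print.cara_trial <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<cara_trial> %s / %s, N=%d, seed=%s rep=%d\n",
              x$scenario$id, x$config$learner, nrow(p),
              format(x$seed), x$replicate))
  cat("  arm allocation:", paste(tabulate(p$arm, x$config$K), collapse = " / "),
      sprintf("| proportion on best arm: %.3f\n", mean(p$best_arm)))
  invisible(x)
}

#' @export
as.data.frame.cara_trial <- function(x, ...) x$patients

#' Write / read the per-patient trial record
#'
#' One row per patient with columns
#' `n, arrival_day, x1[, x2], arm, latent_outcome, observed_time, event,
#' best_arm, pi_n`; the continuous setting leaves the survival columns empty.
#'
#' @param trial a `cara_trial`.
#' @param path CSV file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the patient data frame.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial$patients, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  utils::read.csv(path)
}
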