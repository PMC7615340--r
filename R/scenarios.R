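## Scenario catalogue ---------------------------------------------------------
##
## Two families of synthetic trial scenarios:
##   s1..s6  : continuous outcome, one continuous biomarker x ~ U[-100, 100],
##             Y_{n,k} = f_k(x_n) + eps_n with heteroscedastic noise
##             sd_k(x) = c * |f_k(x)| (flat arms inherit the noise size of the
##             other arm at the crossing point).
##   cs1..cs4: right-censored overall-survival outcome, two independent binary
##             biomarkers coded on {1, 2}, exponential survival with per-cell
##             means, Poisson(5) arrival gaps, per-arm dropout, and
##             administrative censoring six months after the last arrival.

#' Convert an exponential median to its mean
#'
#' For an exponential distribution the median is mean * log(2); a reported
#' median overall survival therefore implies mean = median / log(2).
#'
#' @param median_days positive median survival in days.
#' @return mean survival in days (not rounded).
#' @export
#' @examples
#' median_to_mean_exponential(68)  # ~98 days
median_to_mean_exponential <- function(median_days) {
  stopifnot(is.numeric(median_days), all(median_days > 0))
  median_days / log(2)
}

#' Convert a hazard ratio to an experimental-arm exponential mean
#'
#' Exponential hazards are reciprocal means, so a hazard ratio `hr` relative
#' to a control arm with mean `control_mean` implies an experimental mean of
#' `control_mean / hr`.
#'
#' @param control_mean control-arm mean survival (days, > 0).
#' @param hazard_ratio hazard ratio experimental vs control (> 0).
#' @return experimental-arm mean survival in days (not rounded; round only
#'   for display).
#' @export
#' @examples
#' hr_to_mean(98, 0.695)  # ~141 days
#' hr_to_mean(98, 0.518)  # ~189 days
hr_to_mean <- function(control_mean, hazard_ratio) {
  stopifnot(is.numeric(control_mean), all(control_mean > 0),
            is.numeric(hazard_ratio), all(hazard_ratio > 0))
  control_mean / hazard_ratio
}

## Continuous mean functions.  The qualitative structure (which marker is
## prognostic/predictive, crossing points at -8 / -11, step shape of s6) is
## fixed; the exact curves are package defaults and can be overridden through
## `mean_funs`.
.continuous_catalogue <- function() {
  list(
    s1 = list(f = list(function(x) rep(10, length(x)),
                       function(x) rep(10, length(x))),
              crossing = NULL, flat = c(TRUE, TRUE),
              label = "null: identical flat arms"),
    s2 = list(f = list(function(x) 10 + 0.05 * x,
                       function(x) 13 + 0.05 * x),
              crossing = NULL, flat = c(FALSE, FALSE),
              label = "prognostic marker, arm 2 uniformly better"),
    s3 = list(f = list(function(x) rep(10, length(x)),
                       function(x) 10 - 0.25 * (x + 8)),
              crossing = -8, flat = c(TRUE, FALSE),
              label = "predictive marker, arm 2 better iff x < -8"),
    s4 = list(f = list(function(x) 10 + 0.06 * x,
                       function(x) 10.11 + 0.07 * x),
              crossing = -11, flat = c(FALSE, FALSE),
              label = "predictive + prognostic, small gap, cross at -11"),
    s5 = list(f = list(function(x) rep(10, length(x)),
                       function(x) 10 + 0.06 * (x + 8)),
              crossing = -8, flat = c(TRUE, FALSE),
              label = "predictive marker, arm 2 better iff x > -8"),
    s6 = list(f = list(function(x) rep(10, length(x)),
                       function(x) ifelse(x < -8, 16, 9)),
              crossing = -8, flat = c(TRUE, FALSE),
              label = "step-function predictive marker")
  )
}

## Survival cell means (days), cells indexed by (x1, x2) in {1,2}^2.
## Control mean 98 = 68 / log 2; experimental means from the reported hazard
## ratios, rounded to whole days as quoted.
.survival_catalogue <- function() {
  flat98 <- matrix(98, 2, 2)
  list(
    cs1 = list(means = list(flat98, flat98), dropout = c(0.20, 0.20),
               label = "null, equal dropout"),
    cs2 = list(means = list(flat98, flat98), dropout = c(0.20, 0.08),
               label = "null, differential dropout"),
    cs3 = list(means = list(flat98,
                            matrix(c(141, 141, 189, 189), 2, 2,
                                   dimnames = list(x2 = 1:2, x1 = 1:2),
                                   byrow = FALSE)),
               dropout = c(0.20, 0.08),
               label = "RLC predictive, experimental better everywhere"),
    cs4 = list(means = list(flat98,
                            matrix(c(90, 160, 170, 200), 2, 2,
                                   dimnames = list(x2 = 1:2, x1 = 1:2),
                                   byrow = FALSE)),
               dropout = c(0.20, 0.08),
               label = "RLC and KI predictive, one unfavourable cell")
  )
}
## cs3/cs4 mean matrices: rows = x2 level (KI), cols = x1 level (RLC);
## cs3 column means (141, 189) depend on RLC only; cs4 cells are
## (x1=1,x2=1)=90, (x1=1,x2=2)=160, (x1=2,x2=1)=170, (x1=2,x2=2)=200.

#' Build a scenario specification
#'
#' Scenarios `s1`–`s6` are continuous-outcome designs with one continuous
#' biomarker; `cs1`–`cs4` are the catumaxomab-style survival designs with two
#' binary biomarkers (relative lymphocyte count and Karnofsky index, coded
#' 1/2), staggered arrivals, dropout and administrative censoring.
#'
#' @param id scenario id, one of `"s1"`..`"s6"`, `"cs1"`..`"cs4"`.
#' @param noise_c continuous scenarios only: noise scale `c` in
#'   `sd = c * |f_k(x)|` (default 0.1).
#' @param followup_days survival scenarios only: administrative follow-up
#'   after the last arrival (default 180, i.e. six months).
#' @param arrival_mean survival scenarios only: mean Poisson arrival gap in
#'   days (default 5).
#' @param mean_funs continuous scenarios only: optional list of two functions
#'   overriding the per-arm mean curves.
#' @param prevalence survival scenarios only: success probabilities
#'   `P(x1 = 2)`, `P(x2 = 2)` (defaults 0.6824 and 0.8584).
#' @return object of class `cara_scenario`.
#' @export
cara_scenario <- function(id,
                          noise_c = 0.1,
                          followup_days = 180L,
                          arrival_mean = 5,
                          mean_funs = NULL,
                          prevalence = c(0.6824, 0.8584)) {
  id <- match.arg(id, c(paste0("s", 1:6), paste0("cs", 1:4)))
  if (grepl("^s", id) && !grepl("^cs", id)) {
    cat0 <- .continuous_catalogue()[[id]]
    f <- mean_funs %||% cat0$f
    stopifnot(length(f) == 2L, all(vapply(f, is.function, TRUE)))
    spec <- list(id = id, setting = "continuous", K = 2L, f = f,
                 flat = cat0$flat, crossing = cat0$crossing,
                 noise_c = noise_c, support = c(-100, 100),
                 label = cat0$label)
  } else {
    cat0 <- .survival_catalogue()[[id]]
    stopifnot(length(prevalence) == 2L, all(prevalence > 0 & prevalence < 1))
    spec <- list(id = id, setting = "survival", K = 2L,
                 cell_means = cat0$means, dropout = cat0$dropout,
                 prevalence = prevalence, crossing = NULL,
                 followup_days = as.integer(followup_days),
                 arrival_mean = arrival_mean, label = cat0$label)
  }
  class(spec) <- "cara_scenario"
  spec
}

#' @export
print.cara_scenario <- function(x, ...) {
  cat(sprintf("<cara_scenario %s> %s outcome: %s\n", x$id, x$setting, x$label))
  invisible(x)
}

is_survival <- function(scenario) identical(scenario$setting, "survival")

#' True mean outcome of an arm at a biomarker value
#'
#' @param scenario a [cara_scenario()].
#' @param arm arm index (1 = control, 2 = experimental).
#' @param x continuous setting: numeric vector of biomarker values; survival
#'   setting: a length-2 vector `c(x1, x2)` or a 2-column matrix of codes in
#'   `{1, 2}`.
#' @return numeric vector of mean outcomes (continuous response or mean
#'   survival in days).
#' @export
mean_outcome <- function(scenario, arm, x) {
  stopifnot(inherits(scenario, "cara_scenario"), arm %in% seq_len(scenario$K))
  if (is_survival(scenario)) {
    xm <- if (is.matrix(x)) x else matrix(x, ncol = 2L, byrow = TRUE)
    stopifnot(all(xm %in% c(1, 2)))
    m <- scenario$cell_means[[arm]]
    m[cbind(xm[, 2L], xm[, 1L])]
  } else {
    scenario$f[[arm]](x)
  }
}

#' Heteroscedastic noise standard deviation of a continuous scenario
#'
#' `sd_k(x) = c * |f_k(x)|` for arms whose mean depends on the biomarker; an
#' arm with a flat mean inherits the noise size of the non-flat arm evaluated
#' at the crossing point (at the flat level when there is no crossing), so
#' that the two arms are equally noisy where their mean curves meet.
#'
#' @inheritParams mean_outcome
#' @return numeric vector of noise standard deviations.
#' @export
noise_sd <- function(scenario, arm, x) {
  stopifnot(!is_survival(scenario))
  cc <- scenario$noise_c
  if (!scenario$flat[arm]) return(cc * abs(scenario$f[[arm]](x)))
  other <- if (arm == 1L) 2L else 1L
  anchor <- if (!is.null(scenario$crossing) && !scenario$flat[other]) {
    ## at the crossing the curves meet at the flat level; use it directly so
    ## the rule is well defined even for the discontinuous step arm (s6)
    abs(scenario$f[[arm]](scenario$crossing))
  } else {
    abs(scenario$f[[arm]](0))
  }
  rep(cc * anchor, length(x))
}

#' Draw baseline biomarkers
#'
#' Continuous scenarios draw `x ~ Uniform(-100, 100)`; survival scenarios draw
#' two independent binary codes with `P(x1 = 2) = 0.6824` and
#' `P(x2 = 2) = 0.8584` (defaults).
#'
#' @param scenario a [cara_scenario()].
#' @param n number of patients.
#' @return continuous: numeric vector length `n`; survival: `n x 2` integer
#'   matrix of codes in `{1, 2}`.
#' @export
draw_biomarker <- function(scenario, n = 1L) {
  if (is_survival(scenario)) {
    p <- scenario$prevalence
    cbind(x1 = 1L + (stats::runif(n) < p[1L]),
          x2 = 1L + (stats::runif(n) < p[2L]))
  } else {
    stats::runif(n, scenario$support[1L], scenario$support[2L])
  }
}

#' Draw continuous outcomes
#'
#' `Y = f_k(x) + sd_k(x) * z`; when `z` is supplied it is the patient's shared
#' standard-normal deviate, so counterfactual outcomes across arms use common
#' random numbers.
#'
#' @inheritParams mean_outcome
#' @param z optional standard-normal deviates (length of `x`).
#' @return numeric vector of outcomes.
#' @export
draw_continuous_outcome <- function(scenario, arm, x, z = NULL) {
  mu <- mean_outcome(scenario, arm, x)
  if (any(!is.finite(mu))) stop("non-finite mean outcome")
  z <- z %||% stats::rnorm(length(x))
  mu + noise_sd(scenario, arm, x) * z
}

#' Draw integer-day survival outcomes
#'
#' Exponential draw with the biomarker cell's mean, rounded up to a whole
#' day (so every survival time is >= 1). When `u` is supplied the draw is the
#' inverse-CDF transform of that uniform, which lets callers hold a patient's
#' draw fixed across designs.
#'
#' @inheritParams mean_outcome
#' @param u optional uniforms in (0, 1), one per patient.
#' @return integer vector of latent survival days (>= 1).
#' @export
draw_survival_outcome <- function(scenario, arm, x, u = NULL) {
  mu <- mean_outcome(scenario, arm, x)
  u <- u %||% stats::runif(length(mu))
  as.integer(ceiling(-mu * log1p(-u)))
}

#' Draw staggered arrival days
#'
#' First patient arrives on day 0; successive inter-arrival gaps are i.i.d.
#' Poisson with the given mean (same-day arrivals keep enrollment order).
#'
#' @param n number of patients.
#' @param mean_gap mean arrival gap in days (default 5).
#' @return non-decreasing integer vector of length `n`.
#' @export
draw_arrivals <- function(n, mean_gap = 5) {
  stopifnot(n >= 1)
  cumsum(c(0L, stats::rpois(n - 1L, mean_gap)))
}

#' Draw per-patient dropout indicators
#'
#' Bernoulli with the scenario's per-arm dropout probability (cs1: 20%/20%;
#' cs2–cs4: 20% control / 8% experimental).
#'
#' @param scenario a survival [cara_scenario()].
#' @param arm arm index per patient (vector).
#' @param u optional uniforms (common random numbers across arms).
#' @return logical vector.
#' @export
dropout_indicator <- function(scenario, arm, u = NULL) {
  stopifnot(is_survival(scenario))
  u <- u %||% stats::runif(length(arm))
  u < scenario$dropout[arm]
}

#' Apply dropout censoring to a latent survival time
#'
#' A dropout's censored time is discrete-uniform on `1..latent` days (event
#' flag `FALSE`); otherwise the latent death time is observed (`TRUE`),
#' subject to later administrative censoring.
#'
#' @param latent integer latent survival days (>= 1).
#' @param is_dropout logical vector.
#' @param u optional uniforms in (0, 1).
#' @return data.frame with columns `time` (integer) and `event` (logical).
#' @export
apply_dropout <- function(latent, is_dropout, u = NULL) {
  stopifnot(all(latent >= 1))
  u <- u %||% stats::runif(length(latent))
  time <- as.integer(ifelse(is_dropout, ceiling(u * latent), latent))
  data.frame(time = time, event = !is_dropout)
}

#' Administrative censoring at the end of follow-up
#'
#' Every patient is followed until `final_day` (the last arrival plus the
#' follow-up window); any observation extending beyond it is censored at
#' `final_day - arrival_day`.
#'
#' @param arrival integer arrival days.
#' @param time observed days so far.
#' @param event logical event flags.
#' @param final_day calendar day of database lock.
#' @return data.frame with columns `time`, `event` after censoring.
#' @export
administrative_censor <- function(arrival, time, event, final_day) {
  over <- arrival + time > final_day
  data.frame(time = as.integer(ifelse(over, final_day - arrival, time)),
             event = event & !over)
}

#' Interim view of the accumulated survival data
#'
#' What the learners are allowed to see when a new patient arrives on
#' `current_day`: a previous patient whose (dropout-censored) endpoint has
#' already occurred contributes it; anyone else is censored at their current
#' follow-up `current_day - arrival`. Patients with zero follow-up carry no
#' information and are dropped.
#'
#' @param arrival,time,event enrollment history (final times *before*
#'   administrative censoring).
#' @param current_day calendar day of the incoming patient's arrival.
#' @param keep optional logical/index subset of patients.
#' @return data.frame `idx`, `time`, `event` restricted to patients with
#'   positive follow-up.
#' @export
interim_view <- function(arrival, time, event, current_day, keep = NULL) {
  idx <- seq_along(arrival)
  if (!is.null(keep)) idx <- idx[keep]
  stopifnot(all(current_day >= arrival[idx]))
  fup <- current_day - arrival[idx]
  done <- time[idx] <= fup
  t_obs <- as.integer(ifelse(done, time[idx], fup))
  keep_pos <- t_obs >= 1L
  ## built without data.frame() for speed: this runs twice per allocation
  structure(list(idx = idx[keep_pos], time = t_obs[keep_pos],
                 event = (event[idx] & done)[keep_pos]),
            class = "data.frame", row.names = seq_len(sum(keep_pos)))
}
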