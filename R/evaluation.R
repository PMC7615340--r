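## Operating characteristics --------------------------------------------------
##
## Per-trial metrics (proportion of patients on their individually best
## treatment, allocation performance ratio R(A), hypothesis tests overall and
## in biomarker subgroups) and their replicate aggregation with Monte-Carlo
## standard errors.

#' Proportion of patients allocated to their best treatment
#'
#' `type = "latent"` (default) calls a patient's best arm the one with the
#' highest counterfactual latent outcome for that individual — under
#' heteroscedastic noise or exponential survival this can differ from the
#' mean-best arm, so even a perfect allocator scores below one.
#' `type = "mean"` compares true mean outcomes instead, the benchmark under
#' which an oracle allocator with a fully decayed randomization sequence
#' scores exactly one after burn-in. Ties count as best.
#'
#' @param trial a `cara_trial`.
#' @param type `"latent"` or `"mean"`.
#' @param post_burn_in restrict to patients after the burn-in?
#' @return proportion in `[0, 1]`.
#' @export
proportion_best <- function(trial, type = c("latent", "mean"),
                            post_burn_in = FALSE) {
  type <- match.arg(type)
  p <- trial$patients
  idx <- if (post_burn_in) {
    seq(trial$config$L * trial$config$K + 1L, nrow(p))
  } else {
    seq_len(nrow(p))
  }
  if (type == "latent") return(mean(p$best_arm[idx]))
  sc <- trial$scenario
  x <- if (is_survival(sc)) as.matrix(p[, c("x1", "x2")]) else p$x1
  mu <- vapply(seq_len(sc$K), function(k) mean_outcome(sc, k, x),
               numeric(nrow(p)))
  assigned <- mu[cbind(seq_len(nrow(p)), p$arm)]
  mean((assigned >= apply(mu, 1L, max) - 1e-9)[idx])
}

#' Allocation performance ratio R(A)
#'
#' Ratio of the total achieved true mean outcome to the total under the
#' oracle rule that gives every patient their mean-best arm:
#' `R(A) = sum_j f_{I_j}(x_j) / sum_j f_{k*(x_j)}(x_j)`. Equals 1 for the
#' optimal policy, and is at most 1 whenever all mean outcomes are positive.
#'
#' @param trial a `cara_trial`.
#' @return the performance ratio.
#' @export
performance_ratio <- function(trial) {
  p <- trial$patients
  sc <- trial$scenario
  x <- if (is_survival(sc)) as.matrix(p[, c("x1", "x2")]) else p$x1
  mu <- vapply(seq_len(sc$K), function(k) mean_outcome(sc, k, x),
               numeric(nrow(p)))
  denom <- sum(apply(mu, 1L, max))
  if (denom == 0) stop("performance ratio undefined: zero optimal total outcome")
  sum(mu[cbind(seq_len(nrow(p)), p$arm)]) / denom
}

#' Hypothesis-test specifications for a scenario
#'
#' Overall one-sided (level `alpha_one_sided`) and two-sided
#' (`alpha_two_sided`) comparisons; in the continuous setting additionally
#' the biomarker subgroups `x >= 0`, `x < 0` and — when the scenario declares
#' a true crossing point X — `x >= X`, `x < X`, at the subgroup levels.
#'
#' @param scenario a [cara_scenario()].
#' @param config a [trial_config()] (supplies the nominal levels).
#' @return data.frame with columns `name`, `sidedness`, `subgroup`, `level`.
#' @export
default_test_specs <- function(scenario, config) {
  specs <- data.frame(name = c("one_sided", "two_sided"),
                      sidedness = c("one", "two"),
                      subgroup = "all",
                      level = c(config$alpha_one_sided, config$alpha_two_sided))
  if (!is_survival(scenario)) {
    sub <- c("x_ge_0", "x_lt_0")
    if (!is.null(scenario$crossing)) sub <- c(sub, "x_ge_X", "x_lt_X")
    for (s in sub) {
      specs <- rbind(specs,
        data.frame(name = paste0(c("one_sided_", "two_sided_"), s),
                   sidedness = c("one", "two"), subgroup = s,
                   level = c(config$alpha_one_sided_subgroup,
                             config$alpha_two_sided_subgroup)))
    }
  }
  specs
}

subgroup_filter <- function(trial, subgroup) {
  p <- trial$patients
  X <- trial$scenario$crossing
  switch(subgroup,
         all = rep(TRUE, nrow(p)),
         x_ge_0 = p$x1 >= 0,
         x_lt_0 = p$x1 < 0,
         x_ge_X = p$x1 >= X,
         x_lt_X = p$x1 < X,
         stop("unknown subgroup rule: ", subgroup))
}

#' Welch comparison of continuous outcomes between the two arms
#'
#' Unequal-variance two-sample comparison of observed outcomes, restricted to
#' a biomarker subgroup; the one-sided alternative is that the experimental
#' arm (arm 2) has the greater mean. A subgroup leaving either arm with
#' fewer than two patients (or zero variance) is counted as a non-rejection.
#'
#' @param trial a continuous-outcome `cara_trial`.
#' @param sidedness `"one"` or `"two"`.
#' @param subgroup one of `"all"`, `"x_ge_0"`, `"x_lt_0"`, `"x_ge_X"`,
#'   `"x_lt_X"`.
#' @param level nominal test level.
#' @return list with `reject`, `p_value`, `degenerate`.
#' @export
continuous_endpoint_test <- function(trial, sidedness = c("two", "one"),
                                     subgroup = "all", level = 0.05) {
  sidedness <- match.arg(sidedness)
  stopifnot(!is_survival(trial$scenario))
  p <- trial$patients[subgroup_filter(trial, subgroup), ]
  y1 <- p$latent_outcome[p$arm == 1L]
  y2 <- p$latent_outcome[p$arm == 2L]
  if (length(y1) < 2L || length(y2) < 2L) {
    return(list(reject = FALSE, p_value = NA_real_, degenerate = TRUE))
  }
  tt <- tryCatch(
    stats::t.test(y2, y1,
                  alternative = if (sidedness == "one") "greater" else "two.sided"),
    error = function(e) NULL)
  if (is.null(tt)) {
    return(list(reject = FALSE, p_value = NA_real_, degenerate = TRUE))
  }
  list(reject = tt$p.value < level, p_value = tt$p.value, degenerate = FALSE)
}

#' Logrank comparison of two survival curves
#'
#' Standard logrank statistic (observed minus expected events over the
#' hypergeometric variance across risk sets, with the usual correction for
#' tied death times), computed via [survival::survdiff()]. The two-sided
#' p-value comes from the chi-square distribution with 1 df; the one-sided
#' alternative is that the experimental arm (arm 2) has the lower hazard.
#'
#' @param time observed times.
#' @param event logical / 0-1 event indicators.
#' @param arm arm labels (1 = control, 2 = experimental).
#' @param sidedness `"two"` (default) or `"one"`.
#' @param level nominal test level.
#' @return list with `reject`, `p_value`, `chisq`, `degenerate`.
#' @export
logrank_test <- function(time, event, arm, sidedness = c("two", "one"),
                         level = 0.05) {
  sidedness <- match.arg(sidedness)
  if (sum(event) == 0) {
    warning("no events observed: logrank test degenerate")
    return(list(reject = FALSE, p_value = NA_real_, chisq = NA_real_,
                degenerate = TRUE))
  }
  if (length(unique(arm)) < 2L) {
    return(list(reject = FALSE, p_value = NA_real_, chisq = NA_real_,
                degenerate = TRUE))
  }
  sd <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ arm),
                 error = function(e) NULL)
  if (is.null(sd)) {
    ## zero hypergeometric variance (every risk set exhausted by deaths or of
    ## size one) forces observed = expected, so the statistic is zero
    return(list(reject = FALSE, p_value = 1, chisq = 0, degenerate = TRUE))
  }
  chisq <- sd$chisq
  if (sidedness == "two") {
    pv <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  } else {
    ## experimental better <=> fewer observed than expected events on arm 2
    z <- (sd$obs[2L] - sd$exp[2L]) / sqrt(sd$var[2L, 2L])
    pv <- stats::pnorm(z)
  }
  list(reject = pv < level, p_value = pv, chisq = chisq, degenerate = FALSE)
}

## Evaluate every configured test on one finished trial.
trial_rejections <- function(trial, specs) {
  surv <- is_survival(trial$scenario)
  vapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    res <- if (surv) {
      p <- trial$patients
      logrank_test(p$observed_time, p$event, p$arm,
                   sidedness = s$sidedness, level = s$level)
    } else {
      continuous_endpoint_test(trial, sidedness = s$sidedness,
                               subgroup = s$subgroup, level = s$level)
    }
    res$reject
  }, logical(1))
}

#' Simulate replicates and aggregate operating characteristics
#'
#' Runs `replicates` independent trials of a scenario under one design and
#' aggregates the ethical and inferential metrics: mean proportion of
#' patients on their individually best arm (and on the mean-best arm), per-arm
#' allocation proportions, mean performance ratio, and the empirical
#' rejection rate of every test specification with its Monte-Carlo standard
#' error `sqrt(p(1-p)/replicates)`. Under a null scenario the rejection rates
#' are type I errors, otherwise powers.
#'
#' @param scenario a [cara_scenario()] or scenario id.
#' @param config a [trial_config()], or `NULL` to build one from `N` and
#'   `learner`.
#' @param replicates number of simulated trials.
#' @param seed root seed (replicate `r` uses streams derived from
#'   `(seed, r)`).
#' @param N,learner used only when `config` is `NULL`.
#' @param specs optional test-spec data frame (default
#'   [default_test_specs()]).
#' @return object of class `cara_oc`.
#' @export
operating_characteristics <- function(scenario, config = NULL,
                                      replicates = 100L, seed = 1L,
                                      N = NULL, learner = NULL,
                                      specs = NULL) {
  if (is.character(scenario)) scenario <- cara_scenario(scenario)
  if (is.null(config)) config <- trial_config(N = N, learner = learner)
  specs <- specs %||% default_test_specs(scenario, config)
  K <- config$K
  pb <- pbm <- pr <- numeric(replicates)
  arm_prop <- matrix(0, replicates, K)
  rej <- matrix(FALSE, replicates, nrow(specs))
  for (r in seq_len(replicates)) {
    tr <- run_trial(scenario, config, seed = seed, replicate = r)
    pb[r] <- proportion_best(tr, "latent")
    pbm[r] <- proportion_best(tr, "mean")
    pr[r] <- performance_ratio(tr)
    arm_prop[r, ] <- tabulate(tr$patients$arm, K) / config$N
    rej[r, ] <- trial_rejections(tr, specs)
  }
  rates <- colMeans(rej)
  structure(list(
    scenario = scenario$id, setting = scenario$setting,
    learner = config$learner, N = config$N, replicates = replicates,
    seed = seed,
    proportion_best = mean(pb),
    proportion_best_se = stats::sd(pb) / sqrt(replicates),
    proportion_best_mean_def = mean(pbm),
    proportion_on_arm = colMeans(arm_prop),
    performance_ratio = mean(pr),
    rejection = data.frame(specs,
                           rate = rates,
                           mc_se = sqrt(rates * (1 - rates) / replicates)),
    config = config),
    class = "cara_oc")
}

#' @export
print.cara_oc <- function(x, ...) {
  cat(sprintf("<cara_oc> %s / %s, N=%d, %d replicates (seed %s)\n",
              x$scenario, x$learner, x$N, x$replicates, format(x$seed)))
  cat(sprintf("  proportion best (individual): %.4f (MC se %.4f); mean-best: %.4f\n",
              x$proportion_best, x$proportion_best_se, x$proportion_best_mean_def))
  cat(sprintf("  allocation: %s | performance ratio R(A): %.4f\n",
              paste(sprintf("%.3f", x$proportion_on_arm), collapse = " / "),
              x$performance_ratio))
  cat("  rejection rates:\n")
  r <- x$rejection
  for (i in seq_len(nrow(r))) {
    cat(sprintf("    %-22s level %-6.4g rate %.4f (MC se %.4f)\n",
                r$name[i], r$level[i], r$rate[i], r$mc_se[i]))
  }
  invisible(x)
}

#' Tidy one-row-per-metric view of operating characteristics
#' @param x a `cara_oc`.
#' @param ... unused.
#' @return data.frame with columns `scenario, learner, N, replicates, metric,
#'   test, level, value, mc_se`.
#' @export
as.data.frame.cara_oc <- function(x, ...) {
  base <- data.frame(scenario = x$scenario, learner = x$learner,
                     N = x$N, replicates = x$replicates)
  rows <- rbind(
    cbind(base, metric = "proportion_best", test = NA, level = NA,
          value = x$proportion_best, mc_se = x$proportion_best_se),
    cbind(base, metric = "proportion_best_mean_def", test = NA, level = NA,
          value = x$proportion_best_mean_def, mc_se = NA),
    cbind(base, metric = "performance_ratio", test = NA, level = NA,
          value = x$performance_ratio, mc_se = NA))
  for (k in seq_along(x$proportion_on_arm)) {
    rows <- rbind(rows, cbind(base, metric = paste0("proportion_on_arm_", k),
                              test = NA, level = NA,
                              value = x$proportion_on_arm[k], mc_se = NA))
  }
  r <- x$rejection
  rbind(rows, cbind(base[rep(1L, nrow(r)), ], metric = "rejection_rate",
                    test = r$name, level = r$level, value = r$rate,
                    mc_se = r$mc_se, row.names = NULL))
}
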