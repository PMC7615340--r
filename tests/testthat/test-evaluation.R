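test_that("logrank statistic matches the hand-tabulated risk-set value on the toy example", {
  ## group A times (1, 2), group B times (3, 4), all events: O_A = 2,
  ## E_A = 1/2 + 1/3, V = 1/4 + 2/9, chi-square = 2.882353 (hand-computed)
  res <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(res$chisq, 2.882353, tolerance = 1e-6)
  oracle <- brute_force_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-10)
})

test_that("logrank matches brute-force tabulation on exhaustive and random small instances", {
  ## exhaustive: all 4-patient 2v2 instances with times in {1,2} and any
  ## event pattern with at least one event and both groups at risk
  arm <- c(1, 1, 2, 2)
  for (tcode in 0:15) {
    for (ecode in 1:15) {
      time <- 1 + as.integer(intToBits(tcode))[1:4]
      event <- as.integer(intToBits(ecode))[1:4]
      res <- logrank_test(time, event, arm)
      oracle <- brute_force_logrank(time, event, arm)
      if (oracle$V > 0) {
        expect_equal(res$chisq, oracle$chisq, tolerance = 1e-8)
      }
    }
  }
  ## random instances up to 6 patients
  set.seed(61)
  checked <- 0
  while (checked < 150) {
    n <- sample(3:6, 1)
    arm <- c(1, 2, sample(1:2, n - 2, TRUE))
    time <- sample(1:4, n, TRUE)
    event <- as.integer(runif(n) < 0.7)
    if (sum(event) == 0) next
    oracle <- brute_force_logrank(time, event, arm)
    if (oracle$V == 0) next
    expect_equal(logrank_test(time, event, arm)$chisq, oracle$chisq,
                 tolerance = 1e-8)
    checked <- checked + 1
  }
})

test_that("logrank degenerates gracefully and respects sidedness", {
  expect_warning(res <- logrank_test(c(5, 6), c(0, 0), c(1, 2)), "no events")
  expect_false(res$reject)
  ## two identical single-event groups: no separation
  sym <- logrank_test(c(3, 3), c(1, 1), c(1, 2))
  expect_equal(sym$chisq, 0)
  expect_equal(sym$p_value, 1)
  ## one-sided direction: experimental (arm 2) surviving longer gives small p
  longer <- logrank_test(c(1, 2, 3, 10, 11, 12), rep(1, 6), c(1, 1, 1, 2, 2, 2),
                         sidedness = "one")
  shorter <- logrank_test(c(10, 11, 12, 1, 2, 3), rep(1, 6), c(1, 1, 1, 2, 2, 2),
                          sidedness = "one")
  expect_lt(longer$p_value, 0.5)
  expect_gt(shorter$p_value, 0.5)
})

test_that("performance ratio is the achieved-over-optimal total mean outcome", {
  ## two flat arms at 5 and 10: assigning one patient to each arm scores
  ## (5 + 10) / (10 + 10)
  sc <- cara_scenario("s2", mean_funs = list(function(x) rep(5, length(x)),
                                             function(x) rep(10, length(x))))
  tr <- fake_trial(sc, x = c(-10, 10), arm = c(1L, 2L),
                   latent = cbind(c(5, 5), c(10, 10)))
  expect_equal(performance_ratio(tr), 0.75)
  ## an allocation that is optimal for every patient scores exactly 1
  s3 <- cara_scenario("s3")
  cfg <- trial_config(N = 40, learner = "oracle", pi_start = 0, pi_end = 0)
  opt <- run_trial(s3, cfg, seed = 3)
  mu <- cbind(mean_outcome(s3, 1, opt$patients$x1),
              mean_outcome(s3, 2, opt$patients$x1))
  forced <- opt
  forced$patients$arm <- max.col(mu)                # hand the best arm to everyone
  expect_equal(performance_ratio(forced), 1)
  post <- opt$patients$n > 10
  expect_equal(sum(mu[cbind(which(post), opt$patients$arm[post])]),
               sum(apply(mu[post, ], 1, max)))     # exact optimality after burn-in
  ## the engine's ratio agrees with a first-principles tabulation and an
  ## adaptive rule always sits between the oracle and total misallocation
  expect_equal(performance_ratio(opt),
               sum(mu[cbind(1:40, opt$patients$arm)]) / sum(apply(mu, 1, max)))
  for (r in 1:5) {
    any_tr <- run_trial(s3, trial_config(N = 40, learner = "nearest"),
                        seed = 19, replicate = r)
    expect_lte(performance_ratio(any_tr), 1)
  }
})

test_that("proportion-best distinguishes individual-draw and mean-outcome definitions", {
  sc <- cara_scenario("cs3")
  ## both patients receive the mean-best arm (catumaxomab, mean 141 vs 98 in
  ## cell (1,1)), but patient 1's individual control draw happened to win
  x <- rbind(c(1, 1), c(1, 1))
  latent <- cbind(c(200L, 100L), c(150L, 180L))
  tr <- fake_trial(sc, x = x, arm = c(2L, 2L), latent = latent)
  expect_equal(proportion_best(tr, "latent"), 0.5)
  expect_equal(proportion_best(tr, "mean"), 1)
})

test_that("evaluation metrics are invariant to patient reordering", {
  sc <- cara_scenario("s5")
  tr <- run_trial(sc, trial_config(N = 40, learner = "polynomial"), seed = 21)
  shuffled <- tr
  perm <- sample(40)
  shuffled$patients <- tr$patients[perm, ]
  shuffled$latent <- tr$latent[perm, ]
  expect_equal(proportion_best(shuffled), proportion_best(tr))
  expect_equal(performance_ratio(shuffled), performance_ratio(tr))
})

test_that("Welch endpoint test is directional and degrades to non-rejection in thin subgroups", {
  sc <- cara_scenario("s2")
  set.seed(71)
  x <- runif(60, -100, 100)
  ## arm 2 three pooled SDs above arm 1
  latent <- cbind(rnorm(60, 0, 1), rnorm(60, 3, 1))
  arm <- rep(c(1L, 2L), 30)
  tr <- fake_trial(sc, x, arm, latent)
  strong <- continuous_endpoint_test(tr, "one", "all", 0.025)
  expect_true(strong$reject)
  ## inferior experimental arm: the one-sided test must not fire
  trd <- fake_trial(sc, x, arm, latent[, 2:1])
  expect_false(continuous_endpoint_test(trd, "one", "all", 0.025)$reject)
  ## subgroup leaving arm 2 empty counts as a non-rejection
  arm_split <- ifelse(x >= 0, 1L, 2L)
  trs <- fake_trial(sc, x, arm_split, latent)
  thin <- continuous_endpoint_test(trs, "two", "x_ge_0", 0.025)
  expect_false(thin$reject)
  expect_true(thin$degenerate)
})

test_that("replicate aggregation reports binomial Monte-Carlo errors and flags arm proportions", {
  sc <- cara_scenario("s1")
  cfg <- trial_config(N = 40, learner = "fixed")
  oc <- operating_characteristics(sc, cfg, replicates = 30, seed = 31)
  expect_equal(oc$rejection$mc_se,
               sqrt(oc$rejection$rate * (1 - oc$rejection$rate) / 30))
  expect_equal(sum(oc$proportion_on_arm), 1)
  expect_equal(nrow(oc$rejection), 6)   # overall + x>=0/x<0 pairs, no crossing
  tidy <- as.data.frame(oc)
  expect_true(all(c("metric", "value", "mc_se") %in% names(tidy)))
  expect_equal(tidy$value[tidy$metric == "proportion_best"],
               oc$proportion_best)
})

test_that("an oracle allocator with decayed sequence aggregates to proportion-best one (mean definition)", {
  sc <- cara_scenario("s3")
  cfg <- trial_config(N = 30, learner = "oracle", pi_start = 0, pi_end = 0)
  pb <- vapply(1:10, function(r) {
    proportion_best(run_trial(sc, cfg, seed = 77, replicate = r),
                    "mean", post_burn_in = TRUE)
  }, numeric(1))
  expect_equal(pb, rep(1, 10))
})
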