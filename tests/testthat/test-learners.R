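test_that("polynomial learner interpolates low-degree truths and degrades gracefully", {
  x <- seq(-50, 50, length.out = 12)
  fit <- fit_polynomial(x, 2 * x + 1, degree = 3)
  expect_equal(predict(fit, c(-80, 0, 33)), 2 * c(-80, 0, 33) + 1,
               tolerance = 1e-8)
  fit2 <- fit_polynomial(c(-1, 0, 1), c(1, 0, 1), degree = 2)
  expect_equal(predict(fit2, 2), 4, tolerance = 1e-8)   # exact fit of y = x^2
  fit0 <- fit_polynomial(rep(3, 5), c(1, 2, 3, 4, 5), degree = 3)
  expect_equal(predict(fit0, c(-10, 3, 10)), rep(3, 3))  # degree drops to 0
  expect_error(fit_polynomial(numeric(0), numeric(0)))
})

test_that("nearest-neighbour learner averages the k closest points with tie inclusion", {
  fit1 <- fit_nearest_neighbor(c(0, 10), c(5, 7), k_neighbors = 1)
  expect_equal(predict(fit1, 1), 5)
  fit2 <- fit_nearest_neighbor(c(0, 10), c(5, 7), k_neighbors = 2)
  expect_equal(predict(fit2, 1), 6)
  fit3 <- fit_nearest_neighbor(c(0, 10), c(5, 7), k_neighbors = 3)
  expect_equal(predict(fit3, 1), 6)                     # k capped at n
  ## distance ties: both points at distance 5 are averaged even with k = 1
  ftie <- fit_nearest_neighbor(c(-5, 5), c(0, 10), k_neighbors = 1)
  expect_equal(predict(ftie, 0), 5)
  fdef <- fit_nearest_neighbor(1:30, rep(2, 30))
  expect_equal(fdef$state$k, 6L)                        # max(3, ceiling(sqrt(30)))
})

test_that("Gaussian-process learner interpolates, reverts to the prior mean, and recovers smooth signals", {
  x <- c(-80, -40, 0, 40, 80)
  y <- c(1, 3, 2, 5, 4)
  fit <- fit_gaussian_process(x, y, hyp = list(ell = 20, g = 1e-10))
  expect_equal(predict(fit, x), y, tolerance = 1e-6)    # noise-free limit
  expect_equal(predict(fit, 1e4), mean(y), tolerance = 1e-6)  # stationary kernel limit
  ## posterior mean cross-checked against a direct linear solve
  hyp <- list(ell = 30, g = 0.05)
  fit2 <- fit_gaussian_process(x, y, hyp = hyp)
  C <- exp(-outer(x, x, `-`)^2 / (2 * hyp$ell^2)) + diag(hyp$g, 5)
  kst <- exp(-(17 - x)^2 / (2 * hyp$ell^2))
  expect_equal(predict(fit2, 17),
               mean(y) + drop(kst %*% solve(C, y - mean(y))),
               tolerance = 1e-9)
  set.seed(41)
  xs <- seq(-100, 100, length.out = 20)
  ys <- sin(xs / 20) + rnorm(20, sd = 0.1)
  gfit <- fit_gaussian_process(xs, ys)
  grid <- seq(-90, 90, length.out = 41)
  rmse <- sqrt(mean((predict(gfit, grid) - sin(grid / 20))^2))
  expect_lt(rmse, 0.1)
})

test_that("smoothing-spline learner reproduces a noise-free cubic and falls back when data are too thin", {
  x <- seq(-100, 100, length.out = 30)
  y <- 1e-4 * x^3 - 0.02 * x + 3
  fit <- fit_spline(x, y)
  interior <- seq(-80, 80, length.out = 33)
  truth <- 1e-4 * interior^3 - 0.02 * interior + 3
  expect_lt(sqrt(mean((predict(fit, interior) - truth)^2)),
            1e-3 * diff(range(y)))
  ## three distinct biomarker values: quietly a polynomial fit
  fb <- fit_spline(c(0, 1, 2, 2), c(0, 1, 4, 4))
  expect_s3_class(fb, "cara_polynomial")
  expect_equal(predict(fb, 3), 9, tolerance = 1e-8)
})

test_that("random-forest learner fits constants, recovers step plateaus, and is seed-reproducible", {
  const <- fit_random_forest(1:10, rep(4, 10))
  expect_equal(predict(const, c(0, 5, 20)), rep(4, 3))
  set.seed(17)
  x <- runif(60, -100, 100)
  y <- ifelse(x < -8, 16, 9) + rnorm(60, sd = 1)
  rf <- fit_random_forest(x, y)
  expect_equal(mean(predict(rf, seq(-90, -30, by = 5))), 16, tolerance = 1)
  expect_equal(mean(predict(rf, seq(10, 90, by = 5))), 9, tolerance = 1)
  set.seed(99); p1 <- predict(fit_random_forest(x, y), c(-50, 50))
  set.seed(99); p2 <- predict(fit_random_forest(x, y), c(-50, 50))
  expect_identical(p1, p2)
})

test_that("per-cell exponential estimator matches the censored MLE closed form", {
  x <- matrix(c(1, 1, 1, 1, 1, 1), ncol = 2)        # one cell
  f1 <- fit_survival_cellwise(x, c(10, 20, 30), c(TRUE, TRUE, TRUE))
  expect_equal(predict(f1, c(1, 1)), 20)
  f2 <- fit_survival_cellwise(x, c(10, 20, 30), c(TRUE, FALSE, TRUE))
  expect_equal(predict(f2, c(1, 1)), 30)            # 60 days at risk / 2 events
  ## random censored datasets: every populated, event-bearing cell is sum(t)/sum(d)
  set.seed(23)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    xx <- cbind(sample(1:2, n, TRUE), sample(1:2, n, TRUE))
    tt <- sample(1:200, n, TRUE)
    dd <- runif(n) < 0.7
    fit <- fit_survival_cellwise(xx, tt, dd)
    for (x1 in 1:2) for (x2 in 1:2) {
      sel <- xx[, 1] == x1 & xx[, 2] == x2
      if (sum(dd[sel]) > 0) {
        expect_equal(predict(fit, c(x1, x2)), sum(tt[sel]) / sum(dd[sel]))
      }
    }
  }
})

test_that("zero-event cells shrink to the arm-pooled mean, zero-event arms to total exposure", {
  x <- rbind(c(1, 1), c(1, 1), c(2, 2))
  fit <- fit_survival_cellwise(x, c(10, 30, 50), c(TRUE, TRUE, FALSE))
  expect_equal(predict(fit, c(1, 1)), 20)
  expect_equal(predict(fit, c(2, 2)), 90 / 2)       # pooled-arm fallback
  expect_equal(predict(fit, c(2, 1)), 90 / 2)       # empty cell, same fallback
  none <- fit_survival_cellwise(x, c(10, 30, 50), rep(FALSE, 3))
  expect_equal(predict(none, c(1, 2)), 90)          # conservative total exposure
})

test_that("saturated exponential regression equals the per-cell MLE on fully observed data", {
  set.seed(31)
  n <- 80
  x <- cbind(sample(1:2, n, TRUE), sample(1:2, n, TRUE))
  tt <- sample(1:300, n, TRUE)
  dd <- rep(TRUE, n)
  sat <- fit_survival_parametric(x, tt, dd, "saturated")
  cw <- fit_survival_cellwise(x, tt, dd)
  grid <- as.matrix(expand.grid(1:2, 1:2))
  expect_equal(predict(sat, grid), predict(cw, grid), tolerance = 1e-8)
})

test_that("main-effects exponential regression finds a null effect and recovers cs3-pattern means", {
  ## equal cell means with one varying covariate: fitted slope ~ 0
  set.seed(37)
  n <- 400
  x <- cbind(sample(1:2, n, TRUE), rep(1L, n))
  tt <- as.integer(ceiling(rexp(n, 1 / 100)))
  fit <- fit_survival_parametric(x, tt, rep(TRUE, n), "main")
  expect_equal(predict(fit, c(1, 1)), predict(fit, c(2, 1)), tolerance = 0.15)
  ## parameter recovery from the RLC-predictive survival scenario: with all
  ## events observed the cell means are recovered closely at 400/arm
  sc <- cara_scenario("cs3")
  grid <- as.matrix(expand.grid(1:2, 1:2))
  for (arm in 1:2) {
    set.seed(100 + arm)
    xx <- draw_biomarker(sc, 400)
    lat <- draw_survival_outcome(sc, arm, xx)
    fit <- fit_survival_parametric(xx, lat, rep(TRUE, 400), "main")
    truth <- mean_outcome(sc, arm, grid)
    expect_equal(predict(fit, grid), truth, tolerance = 0.15)
  }
  ## under the scenario's own dropout the uniform-on-[1, OS] censoring is
  ## informative and inflates the exponential MLE, but the between-arm
  ## ordering that drives allocation is preserved in every cell
  set.seed(103)
  fits <- lapply(1:2, function(arm) {
    xx <- draw_biomarker(sc, 400)
    lat <- draw_survival_outcome(sc, arm, xx)
    oc <- apply_dropout(lat, dropout_indicator(sc, rep(arm, 400)))
    fit_survival_parametric(xx, oc$time, oc$event, "main")
  })
  expect_true(all(predict(fits[[2]], grid) > predict(fits[[1]], grid)))
})

test_that("every learner family recovers a flat truth", {
  x <- seq(-100, 100, length.out = 25)
  y <- rep(7, 25)
  for (fam in c("polynomial", "nearest", "gp", "spline", "rf")) {
    set.seed(1)
    fit <- switch(fam,
                  polynomial = fit_polynomial(x, y),
                  nearest = fit_nearest_neighbor(x, y),
                  gp = fit_gaussian_process(x, y),
                  spline = fit_spline(x, y),
                  rf = fit_random_forest(x, y))
    expect_equal(predict(fit, c(-60, 0, 60)), rep(7, 3), tolerance = 1e-6)
  }
  xs <- cbind(sample(1:2, 30, TRUE), sample(1:2, 30, TRUE))
  ts <- rep(50L, 30)
  for (fam in c("cellwise", "main", "saturated")) {
    fit <- if (fam == "cellwise") fit_survival_cellwise(xs, ts, rep(TRUE, 30))
           else fit_survival_parametric(xs, ts, rep(TRUE, 30), fam)
    expect_equal(predict(fit, as.matrix(expand.grid(1:2, 1:2))), rep(50, 4),
                 tolerance = 1e-6)
  }
})

test_that("survival estimators are invariant to patient order and biomarker relabeling", {
  set.seed(53)
  n <- 50
  x <- cbind(sample(1:2, n, TRUE), sample(1:2, n, TRUE))
  tt <- sample(1:150, n, TRUE)
  dd <- runif(n) < 0.6
  grid <- as.matrix(expand.grid(1:2, 1:2))
  perm <- sample(n)
  for (fam in c("cellwise", "main", "saturated")) {
    fit_fun <- function(xx, t2, d2) {
      if (fam == "cellwise") fit_survival_cellwise(xx, t2, d2)
      else fit_survival_parametric(xx, t2, d2, fam)
    }
    base <- predict(fit_fun(x, tt, dd), grid)
    expect_equal(predict(fit_fun(x[perm, ], tt[perm], dd[perm]), grid), base,
                 tolerance = 1e-10)
    swapped <- predict(fit_fun(x[, 2:1], tt, dd), grid[, 2:1])
    expect_equal(swapped, base, tolerance = 1e-10)
  }
})
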