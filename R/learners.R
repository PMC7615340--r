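## Regression learners --------------------------------------------------------
##
## Each arm keeps its own predictor f_hat_k(x), refit on that arm's accumulated
## data before every allocation.  Continuous-outcome families: polynomial,
## nearest neighbour, Gaussian process, smoothing spline, random forest.
## Survival families (right-censored, two binary biomarkers): per-cell
## exponential MLE and exponential regression with log-link (main effects or
## saturated).  All fitted objects share the `cara_predictor` class and a
## `predict()` method mapping biomarker values to a predicted outcome
## (continuous mean response, or mean survival days).

new_predictor <- function(family, state) {
  structure(list(family = family, state = state),
            class = c(paste0("cara_", family), "cara_predictor"))
}

#' @export
print.cara_predictor <- function(x, ...) {
  cat(sprintf("<cara_predictor: %s>\n", x$family)); invisible(x)
}

#' Predict outcomes from a fitted arm learner
#'
#' @param object a fitted `cara_predictor`.
#' @param x continuous families: numeric vector of biomarker values; survival
#'   families: 2-column matrix (or length-2 vector) of codes in `{1, 2}`.
#' @param ... unused.
#' @return numeric vector of predicted outcomes.
#' @export
predict.cara_predictor <- function(object, x, ...) {
  predict_cara(object, x)
}

predict_cara <- function(object, x) UseMethod("predict_cara")

n_distinct_x <- function(x) length(unique(x))

## --- polynomial --------------------------------------------------------------

#' Fit a polynomial regression learner
#'
#' Least-squares polynomial in the (scaled) biomarker. The degree is reduced
#' automatically when the data contain fewer distinct biomarker values than
#' `degree + 1`, down to a constant (the arm mean) in the degenerate case.
#'
#' @param x,y numeric training data (one arm's patients).
#' @param degree requested polynomial degree (default 3).
#' @return a `cara_predictor`.
#' @export
fit_polynomial <- function(x, y, degree = 3L) {
  stopifnot(length(x) == length(y), length(y) >= 1L)
  degree <- min(degree, n_distinct_x(x) - 1L)
  degree <- max(degree, 0L)
  scale <- max(abs(x), 1)         # guards conditioning of the Vandermonde
  X <- outer(x / scale, 0:degree, `^`)
  fit <- .lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  new_predictor("polynomial",
                list(beta = beta, degree = degree, scale = scale))
}

#' @export
predict_cara.cara_polynomial <- function(object, x) {
  s <- object$state
  drop(outer(x / s$scale, 0:s$degree, `^`) %*% s$beta)
}

## --- nearest neighbour -------------------------------------------------------

#' Fit a k-nearest-neighbour learner
#'
#' `predict(x)` averages the outcomes of the `k` nearest training biomarkers
#' (Euclidean distance; distance ties are all included; `k` is capped at the
#' dataset size). Default `k = max(3, ceiling(sqrt(n)))`.
#'
#' @param x,y numeric training data.
#' @param k_neighbors neighbourhood size; `NULL` for the default rule.
#' @return a `cara_predictor`.
#' @export
fit_nearest_neighbor <- function(x, y, k_neighbors = NULL) {
  stopifnot(length(x) == length(y), length(y) >= 1L)
  k <- k_neighbors %||% max(3L, ceiling(sqrt(length(y))))
  new_predictor("nearest", list(x = x, y = y, k = min(k, length(y))))
}

#' @export
predict_cara.cara_nearest <- function(object, x) {
  s <- object$state
  vapply(x, function(x0) {
    d <- abs(s$x - x0)
    kth <- sort(d, partial = s$k)[s$k]
    mean(s$y[d <= kth])
  }, numeric(1))
}

## --- Gaussian process --------------------------------------------------------

## Log marginal likelihood of a centred GP with kernel
## s2f * [exp(-(dx)^2 / (2 l^2)) + g * I]; the signal variance s2f is profiled
## out in closed form, leaving a bounded 2-d search over (l, g).
gp_loglik <- function(D2, yc, ell, g) {
  n <- length(yc)
  C <- exp(-D2 / (2 * ell^2)) + diag(g, n)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  a <- backsolve(ch, forwardsolve(t(ch), yc))
  s2f <- sum(yc * a) / n
  if (s2f <= 0) s2f <- .Machine$double.eps
  ll <- -0.5 * (n * log(s2f) + 2 * sum(log(diag(ch))) + n)
  ## posterior mean = s2f k(x*,x)' (s2f C)^{-1} yc = k(x*,x)' C^{-1} yc,
  ## so the profiled signal variance cancels from the predictor
  list(ll = ll, alpha = a)
}

#' Fit a Gaussian-process regression learner
#'
#' Posterior-mean predictor of a GP with a squared-exponential kernel plus an
#' observation-noise term, centred on the arm mean. Hyperparameters
#' (lengthscale and noise-to-signal ratio) are chosen by maximizing the log
#' marginal likelihood over a bounded grid; the signal variance is profiled
#' out analytically. Fixed hyperparameters can be supplied to skip the search
#' (used by the trial engine to refresh the search only every few patients).
#'
#' @param x,y numeric training data.
#' @param hyp optional list `list(ell =, g =)` of fixed hyperparameters.
#' @param ell_grid,g_grid candidate lengthscales (absolute units) and
#'   noise-to-signal variance ratios; defaults span 5%–80% of the data range
#'   and 1e-4–1.
#' @return a `cara_predictor` whose state records the selected
#'   hyperparameters (`$state$hyp`).
#' @export
fit_gaussian_process <- function(x, y, hyp = NULL,
                                 ell_grid = NULL, g_grid = NULL) {
  stopifnot(length(x) == length(y), length(y) >= 1L)
  m <- mean(y)
  yc <- y - m
  xr <- diff(range(x))
  if (xr == 0 || length(y) < 2L || stats::var(y) == 0) {
    return(new_predictor("gp", list(degenerate = TRUE, m = m,
                                    hyp = list(ell = 1, g = 1))))
  }
  D2 <- outer(x, x, `-`)^2
  if (is.null(hyp)) {
    ell_grid <- ell_grid %||% (xr * c(0.05, 0.1, 0.2, 0.4, 0.8))
    g_grid <- g_grid %||% c(1e-4, 1e-3, 1e-2, 1e-1, 0.5, 1)
    best <- list(ll = -Inf)
    hyp <- list(ell = ell_grid[1L], g = g_grid[1L])
    for (ell in ell_grid) for (g in g_grid) {
      cand <- gp_loglik(D2, yc, ell, g)
      if (cand$ll > best$ll) { best <- cand; hyp <- list(ell = ell, g = g) }
    }
    if (!is.finite(best$ll)) {
      warning("GP marginal-likelihood search failed; using fallback hyperparameters")
      hyp <- list(ell = 0.2 * xr, g = 0.1)
    }
  }
  fit <- gp_loglik(D2, yc, hyp$ell, hyp$g)
  if (!is.finite(fit$ll)) {            # pathological kernel: revert to mean
    return(new_predictor("gp", list(degenerate = TRUE, m = m, hyp = hyp)))
  }
  new_predictor("gp", list(degenerate = FALSE, x = x, alpha = fit$alpha,
                           m = m, hyp = hyp))
}

#' @export
predict_cara.cara_gp <- function(object, x) {
  s <- object$state
  if (isTRUE(s$degenerate)) return(rep(s$m, length(x)))
  Kst <- exp(-outer(x, s$x, `-`)^2 / (2 * s$hyp$ell^2))
  s$m + drop(Kst %*% s$alpha)
}

## --- smoothing spline --------------------------------------------------------

#' Fit a cubic smoothing-spline learner
#'
#' `stats::smooth.spline` with the smoothing parameter chosen by generalized
#' cross-validation. With fewer than four distinct biomarker values (or a
#' failed spline fit) the learner falls back to a reduced-degree polynomial.
#'
#' @param x,y numeric training data.
#' @return a `cara_predictor`.
#' @export
fit_spline <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 1L)
  if (n_distinct_x(x) < 4L) return(fit_polynomial(x, y))
  ss <- tryCatch(
    suppressWarnings(stats::smooth.spline(x, y, cv = FALSE, keep.data = FALSE)),
    error = function(e) NULL)
  if (is.null(ss)) return(fit_polynomial(x, y))
  new_predictor("spline", list(fit = ss))
}

#' @export
predict_cara.cara_spline <- function(object, x) {
  stats::predict(object$state$fit, x)$y
}

## --- random forest -----------------------------------------------------------

#' Fit a random-forest learner (continuous outcomes only)
#'
#' Ensemble-of-trees regression via \pkg{randomForest}; predictions are the
#' tree average. Not available in the survival setting, where two binary
#' biomarkers leave too little structure for trees.
#'
#' @param x,y numeric training data.
#' @param n_trees number of trees (default 100).
#' @return a `cara_predictor`.
#' @export
fit_random_forest <- function(x, y, n_trees = 100L) {
  stopifnot(length(x) == length(y), length(y) >= 1L)
  if (length(y) < 2L || stats::var(y) == 0) {
    return(fit_polynomial(x, y, degree = 0L))
  }
  ## randomForest warns whenever an arm holds <= 5 outcomes, which is routine
  ## just after burn-in
  rf <- suppressWarnings(
    randomForest::randomForest(x = matrix(x, ncol = 1L), y = y,
                               ntree = n_trees))
  new_predictor("rf", list(fit = rf))
}

#' @export
predict_cara.cara_rf <- function(object, x) {
  unname(stats::predict(object$state$fit, matrix(x, ncol = 1L)))
}

## --- survival learners -------------------------------------------------------

cell_index <- function(x) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 2L, byrow = TRUE)
  (xm[, 1L] - 1L) * 2L + xm[, 2L]   # cells 1..4 = (1,1),(1,2),(2,1),(2,2)
}

cell_totals <- function(x, time, event) {
  idx <- cell_index(x)
  tt <- ee <- numeric(4L)
  for (c in 1:4) {
    sel <- idx == c
    tt[c] <- sum(time[sel]); ee[c] <- sum(event[sel])
  }
  list(time = tt, events = ee, n = tabulate(idx, 4L))
}

POISSON_FAMILY <- stats::poisson()

## Shrinkage fallback for unidentified cells: arm-pooled exponential mean; if
## the whole arm has zero events, its total observed time (a conservative
## lower bound on the mean).
arm_fallback_mean <- function(tot) {
  if (sum(tot$events) > 0) sum(tot$time) / sum(tot$events) else max(sum(tot$time), 1)
}

#' Fit the per-cell exponential survival learner
#'
#' For each of the four biomarker cells, the exponential maximum-likelihood
#' mean = total observed time in the cell / number of events in the cell.
#' Cells with no events (or no patients) shrink to the arm-pooled exponential
#' mean, so a prediction is defined as soon as the arm has one observation.
#'
#' @param x 2-column matrix of biomarker codes in `{1, 2}`.
#' @param time observed days (>= 1).
#' @param event logical event flags (`FALSE` = censored).
#' @return a `cara_predictor` predicting mean survival days per cell.
#' @export
fit_survival_cellwise <- function(x, time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(time >= 1))
  tot <- cell_totals(x, time, event)
  fallback <- arm_fallback_mean(tot)
  means <- ifelse(tot$events > 0, tot$time / tot$events, fallback)
  new_predictor("cellwise", list(means = means, fallback = fallback))
}

#' @export
predict_cara.cara_cellwise <- function(object, x) {
  object$state$means[cell_index(x)]
}

#' Fit an exponential survival regression learner
#'
#' Exponential survival regression with log-link on the binary biomarker
#' codes, fitted by maximum likelihood through the Poisson equivalence
#' (events ~ Poisson with offset log(exposure)) on per-cell aggregates.
#' `family = "main"` uses linear main effects of the two biomarkers;
#' `family = "saturated"` adds their interaction, whose MLE coincides with
#' the per-cell estimator on fully identified cells. Cells the model cannot
#' identify (zero events) and non-convergent fits fall back to the
#' shrinkage per-cell estimator.
#'
#' @inheritParams fit_survival_cellwise
#' @param family `"main"` or `"saturated"`.
#' @return a `cara_predictor` predicting mean survival days per cell.
#' @export
fit_survival_parametric <- function(x, time, event, family = c("main", "saturated")) {
  family <- match.arg(family)
  stopifnot(length(time) == length(event), length(time) >= 1L, all(time >= 1))
  tot <- cell_totals(x, time, event)
  cells <- fit_survival_cellwise(x, time, event)
  grid <- cbind(1, z1 = c(0, 0, 1, 1), z2 = c(0, 1, 0, 1))
  if (family == "saturated") grid <- cbind(grid, z12 = grid[, 2L] * grid[, 3L])
  use <- tot$time > 0 & tot$n > 0
  means <- NULL
  if (family == "saturated" && all(use) && all(tot$events > 0)) {
    ## fully identified saturated model: the MLE is the per-cell estimator
    return(cells)
  }
  if (sum(use) >= ncol(grid) && sum(tot$events[use]) > 0) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(grid[use, , drop = FALSE],
                                      tot$events[use],
                                      offset = log(tot$time[use]),
                                      family = POISSON_FAMILY)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && !anyNA(fit$coefficients)) {
      eta <- drop(grid %*% fit$coefficients)   # log hazard per cell
      means <- exp(-eta)                       # exponential mean = 1 / hazard
    }
  }
  if (is.null(means)) return(cells)            # cellwise fallback
  ## keep unidentified (zero-event) cells on the shrinkage estimate for the
  ## saturated model, where the MLE would diverge
  if (family == "saturated") {
    bad <- tot$events == 0
    means[bad] <- cells$state$means[bad]
  }
  means[!is.finite(means)] <- cells$state$means[!is.finite(means)]
  new_predictor("cellwise", list(means = means, fallback = cells$state$fallback,
                                 model = family))
}

## --- dispatcher --------------------------------------------------------------

continuous_families <- c("polynomial", "nearest", "gp", "spline", "rf")
survival_families <- c("cellwise", "exp_main", "exp_saturated")

#' List the learner families available in each outcome setting
#' @param setting `"continuous"` or `"survival"`.
#' @return character vector of family names.
#' @export
learner_families <- function(setting = c("continuous", "survival")) {
  switch(match.arg(setting),
         continuous = continuous_families,
         survival = survival_families)
}

## Fit the configured family on one arm's dataset. `data` is a list with
## elements x, y (continuous) or x, time, event (survival); `opts` carries the
## hyperparameters from the trial config; `hyp` optionally reuses cached GP
## hyperparameters.
fit_arm_learner <- function(family, data, opts = list(), hyp = NULL) {
  switch(family,
    polynomial = fit_polynomial(data$x, data$y, degree = opts$degree %||% 3L),
    nearest = fit_nearest_neighbor(data$x, data$y,
                                   k_neighbors = opts$k_neighbors),
    gp = fit_gaussian_process(data$x, data$y, hyp = hyp),
    spline = fit_spline(data$x, data$y),
    rf = fit_random_forest(data$x, data$y, n_trees = opts$n_trees %||% 100L),
    cellwise = fit_survival_cellwise(data$x, data$time, data$event),
    exp_main = fit_survival_parametric(data$x, data$time, data$event, "main"),
    exp_saturated = fit_survival_parametric(data$x, data$time, data$event,
                                            "saturated"),
    stop("unknown learner family: ", family)
  )
}
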