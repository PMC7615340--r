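---
title: "A biomarker-guided response-adaptive randomization design: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biomarker-guided response-adaptive randomization design: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caratrial)
```

## The design

`caratrial` simulates a covariate-adjusted response-adaptive (CARA) trial
with $K \ge 2$ arms and $N$ sequentially arriving patients. Each patient $n$
presents a baseline biomarker $x_n$; arm $k$'s outcome is modelled as
$Y_{n,k} = f_k(x_n)$ plus noise, with no assumption on the form of $f_k$.
The design has three phases per patient:

1. **Burn-in.** The first $L \times K$ patients (default $L = 5$ per arm) are
   randomized with equal probability across arms, so each arm starts with
   $L$ observations before any model is trusted.
2. **Prediction.** At each later arrival, every arm's regression learner
   $\hat f_k$ is refit on the outcomes of that arm's previous patients, and
   the incoming patient's predicted outcome $\hat f_k(x_n)$ is computed for
   each arm. The arm with the largest prediction is the *estimated best*
   (ties broken uniformly at random).
3. **Allocation.** The estimated best arm is assigned with probability
   $1 - (K-1)\pi_n$, every other arm with probability $\pi_n$. The sequence
   $\pi_n$ decays linearly from $\pi_{LK} = 1/K$ at the last burn-in patient
   to $\pi_N = 0.1$, so early allocations stay close to equal randomization
   while late patients receive the estimated best arm with probability up to
   0.9 — but a lesser arm always keeps at least probability 0.1, protecting
   against model error and preserving information about all arms.

Ethical performance is summarized by the proportion of patients allocated to
their *individually* best treatment and by the performance ratio
$R(A) = \sum_j f_{I_j}(x_j) \big/ \sum_j f_{k^*(x_j)}(x_j)$, the achieved
total mean outcome relative to an oracle that assigns every patient their
mean-best arm. Inferential performance is the type I error and power of
end-of-trial two-arm comparisons, overall and within biomarker subgroups.

## Outcome settings

**Continuous outcomes, one continuous biomarker.** Scenarios `s1`–`s6` draw
$x \sim \mathrm{Uniform}(-100, 100)$ and $Y_{n,k} = f_k(x_n) + \varepsilon_n$
with heteroscedastic noise $\mathrm{sd}_k(x) = c\,|f_k(x)|$ (default
$c = 0.1$): larger outcomes are noisier. An arm whose mean is flat in $x$
inherits the noise size of the other arm at the crossing point, so the arms
are equally noisy where their curves meet; for the discontinuous step arm of
`s6` we anchor this at the flat arm's own level, which coincides with the
crossing level in all shipped scenarios. Outcomes are known immediately, so
each refit sees all previous outcomes. The six mean-function pairs cover: no
effect (`s1`); a purely prognostic marker with a uniformly better arm
(`s2`); predictive markers whose better arm switches at $X = -8$ (`s3`,
`s5`, and the step function `s6`); and a weakly separated
predictive-plus-prognostic pair crossing at $X = -11$ (`s4`). The exact
curves are package defaults chosen to satisfy those qualitative
descriptions — flat level 10, slopes of 0.05–0.25, a 3-unit prognostic
offset, a 16/9 step — and every one is overridable through
`cara_scenario(..., mean_funs = )`. Quantities that depend on the exact
curves (for example the numeric value of power in `s5`) are therefore
design-specific; only their ordinal relationships are treated as
reproducible.

**Survival outcomes, two binary biomarkers.** Scenarios `cs1`–`cs4` emulate
a completed catumaxomab trial in malignant ascites: overall survival in
integer days, a control arm (paracentesis alone) versus catumaxomab, and two
binary biomarkers — relative lymphocyte count (RLC, coded 2 when
$> 13\%$, prevalence 0.6824) and Karnofsky index (KI, coded 2 when
$\ge 70\%$, prevalence 0.8584), drawn independently. Survival is exponential
per biomarker cell: the control mean is $68 / \log 2 \approx 98$ days (from
the reported median), and experimental means derive from reported hazard
ratios as $98/\mathrm{HR}$ — 141 and 189 days by RLC level in `cs3`, and 90
/ 160 / 170 / 200 days across the four cells in `cs4`; the published cell
table repeats one "KI ≥ 70" label, which we resolve by placing the 200-day
mean in the doubly favourable cell and 170 in (RLC > 13%, KI < 70%). `cs1`
and `cs2` are nulls (both arms at 98 days) differing only in dropout.
Patients arrive with i.i.d. Poisson(mean 5) day gaps; dropout (20% control /
8% experimental; 20%/20% in `cs1`) censors a patient uniformly on
$[1, \mathrm{OS}]$ days; after the last arrival everyone is followed six
more months (180 days) and still-unobserved deaths are administratively
censored. Because outcomes are survival times, a learner refit at patient
$n$'s arrival sees only the *interim view*: deaths and dropouts that have
already occurred, and everyone else censored at their current follow-up.
Draws are rounded up to whole days, so every time is at least one day.

Two modelling consequences of this generative design are worth knowing.
First, the dropout mechanism is *informative* (the censoring time depends on
the latent death time), which inflates exponential mean estimates by roughly
$10\%$ at a 20% dropout rate; the inflation is similar across arms and cells,
so the between-arm ordering that drives allocation is essentially preserved,
but absolute cell means are not unbiased — the differential dropout of `cs2`
(a null scenario) is in fact enough to tilt allocation a few points away
from one half. Second, because individual survival draws are exponential,
the arm with the better *mean* frequently loses the comparison of the two
individual draws: with means 98 versus 189 the mean-better arm wins only
about 66% of the time. The proportion on the individually best treatment is
therefore bounded well below the allocation proportion even for a perfect
allocator — this is why the case-study proportion-best tops out near 0.55
while two thirds of patients sit on the experimental arm.

## Counterfactual outcomes and random streams

Each replicate derives two independent random streams from
`(seed, replicate)`: a *population* stream (biomarkers, arrivals, latent
outcomes under **every** arm, dropout) and an *allocation* stream (burn-in
permutation, randomized assignment, tie-breaks, learner-internal
randomness). Designs compared under the same seed therefore see identical
patients — common random numbers across designs — and any single replicate
can be regenerated in isolation. Within a patient, the continuous setting
uses one shared standard-normal deviate scaled by each arm's noise sd
(mirroring a single additive error term per patient), while the survival
setting draws the arms' latent times independently: with comonotone
exponential draws the mean-better arm would win every individual comparison,
contradicting the behaviour described above. "Individually best" is judged
against these counterfactual latent outcomes; a mean-outcome variant
(`proportion_best(type = "mean")`) is the benchmark under which an oracle
allocator with $\pi_n \equiv 0$ scores exactly 1 after burn-in.

## Learners

All continuous learners are refit from scratch before every allocation.
Their hyperparameters are package defaults, exposed in
`trial_config(learner_opts = )`:

- **Polynomial** (`polynomial`): least-squares cubic by default, on a
  max-abs-scaled biomarker; the degree auto-reduces when there are fewer
  distinct biomarker values than coefficients, down to the arm mean.
- **Nearest neighbour** (`nearest`): mean outcome of the
  $k = \max(3, \lceil\sqrt{n}\rceil)$ closest biomarkers, with distance ties
  all included.
- **Gaussian process** (`gp`): posterior mean under a squared-exponential
  kernel plus observation noise, centred on the arm mean. The lengthscale
  and noise-to-signal ratio maximize the log marginal likelihood over a
  bounded grid (5 lengthscales spanning 5–80% of the data range × 6 noise
  ratios from $10^{-4}$ to 1), with the signal variance profiled out in
  closed form. A grid search rather than numeric optimization keeps every
  refit deterministic and cheap inside the per-patient loop; within the
  per-arm sample sizes of these trials the marginal-likelihood surface is
  flat enough that finer tuning does not change allocations. The search is
  re-run only every 5 new observations per arm (`gp_refresh`), with the
  posterior itself updated at every refit.
- **Smoothing spline** (`spline`): `stats::smooth.spline` with
  generalized-cross-validated smoothing; below four distinct biomarker
  values it falls back to the reduced-degree polynomial.
- **Random forest** (`rf`): 100 trees via `randomForest`; continuous setting
  only — two binary biomarkers offer too little splitting structure, so the
  family is rejected with an error in the survival setting.

Survival learners predict *mean survival days* per biomarker cell, so the
argmax over arms maximizes predicted mean OS (under exponential models the
mean and median orderings agree):

- **Per-cell exponential MLE** (`cellwise`): mean = total observed days /
  events in the cell. A cell with no events shrinks to the arm-pooled
  exponential mean; an arm with no events at all uses its total observed
  time, a conservative lower bound that keeps predictions defined under
  heavy interim censoring.
- **Exponential regression** (`exp_main`, `exp_saturated`): log-link
  exponential survival regression on the biomarker codes, fitted through the
  Poisson-likelihood equivalence on per-cell aggregates. The main-effects
  variant borrows strength across cells; the saturated variant (main effects
  + interaction) coincides with the per-cell MLE wherever cells are
  identified and keeps the shrinkage estimate in zero-event cells.
  Non-convergent or rank-deficient fits fall back to the per-cell estimator.

Every family sits on a fallback ladder (requested family → reduced-degree
polynomial → arm mean), so the engine always produces a prediction after
burn-in.

## Inference

The continuous endpoint is compared with Welch's unequal-variance two-sample
test — matching the heteroscedastic generative model; a pooled-variance
test would be mis-specified by construction. Overall tests use levels 0.025
(one-sided, experimental greater) and 0.05 (two-sided); biomarker subgroups
($x \ge 0$, $x < 0$, and $x \ge X$, $x < X$ when a true crossing $X$ is
declared) use 0.0125 / 0.025. Null scenarios without a crossing simply omit
the $X$-based splits. A subgroup leaving an arm with fewer than two patients
counts as a non-rejection, which depresses subgroup power at small $N$
honestly rather than discarding replicates. The survival endpoint is
compared with the standard logrank test (via `survival::survdiff`, two-sided
from the $\chi^2_1$ tail; the one-sided variant signs the
observed-minus-expected difference), evaluated on the
administratively-censored records at database lock. All $N$ patients enter
every analysis.

## Design choices that were genuinely open

- **Burn-in scheme.** "Equal probability" admits both a Bernoulli coin and a
  forced balance. The default is a balanced permutation (exactly $L$ per
  arm, order random) because the prediction step assumes $L$ points per arm;
  `burn_in = "bernoulli"` provides the alternative.
- **$\pi_n$ anchoring.** The sequence is indexed by enrollment position and
  anchored at $n = LK$, for every $N$ including 233; so with $LK = 10$,
  $\pi_{10} = 1/K$ exactly and the first adapted patient (n = 11) already
  uses a slightly smaller value.
- **Tie-breaking** at the predicted argmax is uniform among tied arms, to
  avoid a systematic tilt toward low arm indices.
- **Refit cadence** is every patient (the GP hyperparameter *search* every
  5th per arm, as above).
- **$K > 2$**: all formulas are written for general $K$ with
  $\pi_{LK} = 1/K$, although the shipped scenarios are two-armed.

## Monte-Carlo sizes and what the tests show

The test suite and the acceptance script re-simulate the studies at sizes
chosen for a single CPU: 500 replicates for the case-study effect scenarios
at $N = 233$, 200 for the survival nulls, 80–600 per learner for
calibration checks at $N = 40$–80, and 300 for the continuous ordinal
comparisons; every stochastic assertion carries its own 3-standard-error
Monte-Carlo band at the size actually run. Calibration of all test
specifications is verified under the matched null scenarios (`s1`, `cs1`,
`cs2`) for fixed randomization *and* for every learner — adaptive
allocation could in principle distort a naive end-of-trial test, and these
checks show that within Monte-Carlo resolution it does not here. The
split-at-0 versus split-at-$X$ comparison uses paired replicates and a 0.1
band on the rejection-rate difference; the step scenario `s6` shows the
largest genuine gap (about 0.05), since the patients between $-8$ and 0
carry a 7-unit outcome jump.

Passing these simulations shows the design behaves as described **under its
own generative assumptions**. Real trials differ in ways the generator does
not emulate: time trends in patient characteristics, biomarker measurement
error, delayed or missing continuous outcomes, non-exponential survival,
informative dropout correlated with prognosis rather than with the latent
death time, and model misspecification beyond the six shipped curve shapes.
The inference reported here is also naive with respect to the adaptive
allocation — no randomization test or bias-corrected estimator is included
(deliberately out of scope), so mean estimates from adapted arms inherit
selection effects even where test levels hold.

## Known limitations

- Exact learner settings of the original studies are not public; the
  defaults above are standard reconstructions, and headline numbers that
  depend on them are reproduced only within stated tolerance bands.
- The exponential cell means interact with informative dropout as described;
  absolute survival estimates are inflated by design.
- Continuous scenarios' exact curves are package defaults; numeric targets
  tied to them are not asserted, only ordinal structure.
- Learners are univariate (continuous setting) or two-binary-cell (survival
  setting); no general multivariate biomarker support is exposed.
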