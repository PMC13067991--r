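---
title: "Training-window selection for one-step-ahead prediction under non-stationarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-window selection for one-step-ahead prediction under non-stationarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forwardsl)
```

## The problem

Smartphone sensing makes it cheap to collect high-frequency behavioural
covariates (app usage, time at locations) alongside sparser self-reports of
mood obtained by experience sampling (EMA): a handful of "beeps" per day on
an 11-point scale. A natural goal is to predict the next self-report from
the sensor features, one step ahead, refitting as each new observation
arrives. The obstacle is non-stationarity: the relationship between
behaviour and mood drifts — someone's phone use may predict stress during a
work period and relaxation on holiday. A model trained on *all* past data
averages over regimes; a model trained on a short recent window forgets the
drift but pays in variance. The *training window* is therefore the key
tuning knob, and the right window depends on the (unknown, individual)
rate of change.

`forwardsl` implements and evaluates strategies for this choice:

* **single-window heuristics** — the expanding window (all past data), the
  last day, the last two days;
* a **candidate library** of windows spanning 5%–25% of the series length
  in 1% steps (21 windows) plus the three heuristics, `K = 24` candidates;
* **multi-window combiners** — the simple average of all 24 candidate
  predictions, the *discrete super learner* (dSL; pick the candidate with
  the lowest cross-validated error, i.e. the cross-validation selector),
  and the *ensemble super learner* (eSL; a convex combination of all
  candidates);
* the **nested forward-validation** engine that constructs the combiners
  honestly and evaluates every method on genuinely held-out next points.

## The data-generating process

The simulator draws
$$ y_t = x_t^\top \beta_t + \varepsilon_t, \qquad
   \varepsilon_t \sim N(0, \sigma_t^2), \qquad t = 1, \dots, T, $$
with $p = 4$ independent standard-normal covariates and coefficients that
drift along a sine curve,
$$ \beta_{t,j} = \tfrac12 + \tfrac12 \sin\!\Big( 2\pi r \tfrac{t-1}{T-1}
   + \phi_j \Big), $$
so every coefficient stays in $[0, 1]$ and completes $r$ full oscillations
over the series ($r = 0$: stationary; $r = 1$: one full cycle). Each
coefficient receives its own uniform random phase $\phi_j$ so the columns
do not drift in lockstep. The series length is `n_days * beeps_per_day`,
covering the standard design grid 14/28/56 days by 6/8/12 beeps
(T from 84 to 672).

Parameters that matter, with defaults:

* `rate` $r \in [0,1]$ — fraction of a sine oscillation (no default; it is
  the quantity under study).
* `snr = 4` — per-time-point signal-to-noise ratio. In the default
  `constant_snr` mode the noise variance tracks the signal variance,
  $\sigma_t^2 = \sum_j \beta_{t,j}^2 / \mathrm{snr}$ (the signal variance
  for unit-variance independent covariates), so predictability does not
  drift even though the coefficients do. The value 4 ($R^2 = 0.8$) is a
  deliberately strong-signal regime: the window question is about bias
  from stale data, and it is only visible when the systematic part of the
  error is not swamped by noise. At `snr = 1` the noise floor compresses
  all methods toward the same error and the expanding window barely
  degrades between $r = 0$ and $r = 1$; at `snr = 4` its error roughly
  triples, the bias-driven pattern the method comparison is about. A
  `fixed_sigma` mode (homoskedastic, `sigma`) is provided for
  parameter-recovery checks where a closed-form standard error is wanted.
* `seed` — one RNG stream per dataset; identical configs reproduce
  bit-identically.

```{r dgp}
dat <- simulate_dataset(dgp_config(n_days = 14, beeps_per_day = 6,
                                   rate = 0.5, seed = 1))
dat
range(dat$beta_true$beta)
```

## Candidate windows and learners

A `window_spec` resolves, at time $t$, to the index range it trains on:
`expanding` to $(1, t)$; a count window $w$ to $(\max(1, t-w+1),\, t)$; a
day window to $w = d \times$ beeps; a fraction window to
$w = \lfloor q T \rfloor$ (floor, minimum 1). Nominal windows longer than
the available history are truncated rather than refused — candidates are
only *evaluated* on the final portion of the series where every nominal
window fits (see the fold schedule below). Training always ends at $t$ and
predicts $t + 1$ from the single covariate row $x_{t+1}$; nothing later is
touched.

Two learner families are supported: OLS (with intercept by default —
configurable, and turned off in oracle tests against the interceptless
generating process) and random forests via `ranger` (500 trees, `mtry =
ceiling(p/3)`, minimum node size 5 — stock regression defaults, since
forests need little tuning here; 50 trees suffice in reduced studies).
Forest fits are seeded per (time point, candidate) so results are
reproducible and independent of evaluation order.

Two numerical guards deserve explanation:

* **Rank-deficient OLS windows.** The one-day window at 6 beeps has 6
  observations for 5 parameters, and shorter fraction windows have fewer.
  Designs with fewer rows than columns fall back to ridge with penalty
  `ridge_epsilon = 1e-6` (a numerical fallback, not meaningful
  shrinkage), with a warning.
* **Forecast clipping** (`clip_predictions = TRUE`). Near-square OLS fits
  interpolate their training points, and their out-of-window
  extrapolations have essentially unbounded variance — single forecasts a
  thousand units off-scale occur routinely, and a method library that
  *averages* candidates inherits those explosions. Every forecast is
  therefore clipped to the range of outcomes observed *before* the
  predicted point. This is the standard guard for regression forecasts
  from short histories (simple range clamps were common among M4
  forecasting competition entries, the same literature that motivates the
  averaging combiner), it uses only past data so the no-leakage contract
  is intact, and it mirrors the applied setting, where affect scores are
  scale-bounded anyway. Exact-algebra tests disable it.

## Combining candidates

At each evaluation point the inner loop (below) supplies a matrix of
candidate predictions at past validation points together with the realized
outcomes. From it:

* `average_predict` — the equal-weight mean of all 24 candidates;
* `fit_discrete_sl` — the argmin of the per-candidate mean squared
  prediction error (MSPE), ties broken by library order (fraction grid
  ascending, then last day, last two days, expanding);
* `fit_ensemble_sl` — weights $\hat\omega$ solving
  $$ \min_{\omega \ge 0,\ \sum_k \omega_k = 1}
     \sum_v \Big( y_v - \sum_k \omega_k \hat y_v^{(k)} \Big)^2 . $$

The eSL weight problem is solved exactly as a quadratic program
(`pracma::quadprog`). Exactness is not cosmetic: it guarantees by
construction that the ensemble's in-sample objective is no worse than any
single candidate's (every vertex of the simplex is feasible), which is the
defining promise of the ensemble. The classical meta-learner —
non-negative least squares followed by normalization to sum one — is
available as `solver = "nnls"`; because renormalized NNLS solves a
different problem, it carries a guard that falls back to the best vertex
whenever it would otherwise violate that promise. If all candidates are
numerically identical the problem is degenerate and uniform weights are
returned with a note.

## Nested forward validation

Honest evaluation of a procedure that *itself* uses cross-validation needs
two nested rolling-origin loops:

1. **Outer loop.** The largest nominal window spans 25% of the series and
   a further 5% is reserved so candidate error estimates have stabilized;
   evaluation therefore starts after a burn-in of
   $\lceil 0.30\,T \rceil$ and every later point is a one-step-ahead
   outer validation point — the final 70% of the series.
2. **Inner loop.** At outer training size $\tau$, each candidate is refit
   at every inner validation index $v$ (window ending $v - 1$, predicting
   $y_v$) for $v$ from $\lceil 0.30\,\tau \rceil + 1$ through $\tau$ —
   the same burn-in rule applied to the inner data, a mirrored layout
   chosen because the inner folds must respect exactly the constraints
   the outer folds do. The inner errors yield the dSL selection and eSL
   weights, which are rebuilt at **every** outer point by default
   (`refresh_every` relaxes this for expensive learners).

A candidate's prediction at index $v$ depends only on data before $v$, so
the engine computes each (index, candidate) prediction once and reuses it
across all folds that contain it. This is bit-identical to naive
refitting — asserted in the test suite against an independent
loop-over-everything reference at $10^{-10}$ — and reduces the cost of a
T-point evaluation from $O(T^2 K)$ to $O(T K)$ fits.

The evaluated set comprises all 24 candidates, the three combiners, and a
`rolling_mean` baseline that predicts the next outcome by the mean outcome
over the last day (window configurable; the baseline ignores covariates
entirely).

```{r fv}
lib <- build_candidate_library(length(dat$y), beeps_per_day = 6)
fv <- run_outer_loop(dat, lib, learner_spec("ols", seed = 1))
round(sort(fv$mspe)[1:5], 3)
```

## Evaluation metrics and the best-possible benchmark

`rank_methods` orders methods by MSPE within each unit (participant or
replicate; rank 1 best, ties averaged) and averages ranks across units;
`summarize_conditions` averages MSPEs over replicates within each design
cell. `truth_benchmark` reports the realized best-possible selection: the
per-point minimum squared error over all evaluated methods, whose MSPE is
by construction a lower bound for every method in that replicate. This is
a deliberate simplification of estimating the ideal window from
independent test sets drawn from the generating process — the package's
version is exact, assumption-free, and bounds *all* methods rather than
only the candidates, at the price of being computable only when the full
error matrix is at hand. It is reported for OLS libraries only (forest
libraries are compared against each other), since with forests the bound
is dominated by fit noise rather than window choice.

## The empirical-style feature pipeline

For real (or realistically synthetic) data the covariates must first be
built from sensor event streams. `aggregate_features` totals event
durations per channel over trailing windows of 3/6/12/24 hours at each
questionnaire timestamp, under three alignment conventions: *detection*
(window ends at the beep), *time-shifted* (ends a configurable gap before
the beep, leaving time to intervene), and *lagged* (ends at the previous
beep). Events straddling a window edge contribute their overlap duration;
no interval ever extends past its anchor. `compute_affect_composites`
builds the positive-affect outcome as the mean of the happy / energetic /
relaxed items and negative affect as the mean of sad / anxious / stressed
/ irritated, all on the 0–10 scale. `preprocess_design` drops features
with variance below `1e-8` ("near zero" made concrete; the threshold is an
argument) and imputes remaining missing values with the per-column median
of *past* observations only — a whole-series median would quietly leak
future information into one-step-ahead training, so rows with no past
observation simply stay missing.

`generate_ema_fixture` makes all of this testable without participant
data: Poisson sensor event streams, EMA items generated so the composites
follow a time-varying linear function of the *same detection-mode
features the pipeline later computes*, with sine-varying coefficients at a
chosen rate. The fixture thus has known ground truth; a stationary,
noiseless fixture is recovered by the pipeline's expanding OLS to
$10^{-2}$ in the test suite. Items are rounded to the integer 11-point
scale by default; `round_items = FALSE` keeps them continuous, which the
exact-recovery test uses because integer rounding adds irreducible
quantization error. What the fixture does *not* emulate: within-day
activity rhythms, missing beeps, autocorrelated outcomes, or nonlinear
feature–outcome links — so passing tests demonstrate the pipeline's
correctness, not that real sensor data carries this much signal.

## The simulation study driver

`run_study` crosses days × beeps × rate × replicates, simulates, builds
the library, forward-validates, and aggregates into the three standard
tables (raw per-replicate MSPEs, condition summaries, rank table),
optionally written as CSVs. Replicate seeds are drawn once from the
master seed and bound to the cell's position in the canonical grid
enumeration, so results are reproducible and independent of execution
order; failed cells warn and are skipped rather than aborting the run.
The full published-scale design (9 cells × 21 rates × 200 replicates) is
supported but the package's own checks run reduced versions: the test
suite uses 100 OLS replicates of the smallest design (14 days × 6 beeps)
at the two extreme rates, 20 forest replicates at 50 trees, and the
acceptance script 60 OLS replicates per rate — sizes chosen so the whole
verification cycle completes in minutes on one core while leaving the
compared mean MSPEs separated by many Monte-Carlo standard errors.

## Known limitations

* Coefficient drift is smooth and sinusoidal; abrupt regime switches are
  out of scope.
* The generating process is contemporaneous (lag-0) and linear; there are
  no autoregressive dynamics, and the candidate libraries are
  algorithmically homogeneous (one learner family at a time).
* Prediction horizons beyond one step are not implemented.
* The inner-fold layout mirrors the outer burn-in rule; other layouts
  (fixed inner fold counts, gapped folds) are plausible and would change
  super-learner construction slightly.
* `rate` is bounded at one full oscillation; faster drift would need a
  finer beep grid to remain identifiable.
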