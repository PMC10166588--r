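---
title: "Dual-trace signal detection: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-trace signal detection: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsdroc)
```

## The model

`dtsdroc` models confidence-rating detection data as a mixture of two
traces. On a *noise* (normal) trial the observer samples a strength value
from N(0, 1); on a *signal* (abnormal) trial, with probability `HT` an
all-or-none detection fires and produces the most-confident "abnormal"
response, and otherwise strength is sampled from N(d′, 1). Ordered
criteria `c₁ < … < c_{K−1}` map strength to K ordered confidence
categories. Sweeping the criteria gives the operating points

$$\mathrm{FPR}(c) = \Phi(-c), \qquad
  \mathrm{TPR}(c) = HT + (1 - HT)\,\Phi(d' - c).$$

Assumptions worth making explicit:

* **Equal variances.** Both strength distributions have unit variance;
  the model has no signal-variance parameter. The curvature asymmetry of
  the predicted ROC comes entirely from the HT component.
* **HT acts on signal trials only.** The linear component has a
  y-intercept (`TPR → HT` as `FPR → 0`) but no x-axis analogue: noise
  trials are pure SDT. This matches the interpretation of the threshold
  trace as detection of an actually present focal sign.
* **HT mass lands in the single most-confident "abnormal" category.**
  This is the standard dual-process convention and is required for the
  cumulative form above to hold at *every* criterion. Whether threshold
  detections should instead spread over all "sure abnormal" bins is not
  determined by the ROC itself; the choice is isolated inside
  `category_probabilities()` so it can be revisited.
* `d_prime` is unconstrained in sign (small negative fitted values are
  legitimate sampling noise around zero); `ht` lives in `[0, 1)`.

## Rating scale and binning

The reference response scale has 90 points on a half-circle arc
(radius 860 px), points 1–45 denoting "normal" (sure → guess) and 46–90
"abnormal" (guess → sure). For ROC construction the 90 points are binned
into 20 ordered categories with fixed edges every 4.5 points of the
continuous 0–90 scale, i.e. bin *j* covers `(4.5(j−1), 4.5j]`. 90/20 is
not an integer, so integer ratings alternate 4/5 per bin; the payoff is
that the normal/abnormal boundary 45|46 falls exactly on a bin edge, so
no bin mixes the two response halves. Cumulating counts from the
"sure abnormal" end yields exactly 19 operating points; tied consecutive
points from empty bins are retained so the count is invariant.

## Hierarchical Bayesian inference

`fit_hbm()` fits, by MCMC (JAGS):

* **Trial layer** — the category counts of each subject × condition cell
  follow the DTSD multinomial `category_probabilities()`. There are no
  per-trial latent variables; the multinomial is the exact marginal of
  the trial-level generative process.
* **Subject layer** — additive random effects on d′ (identity scale) and
  on probit(HT) (link scale), shared across conditions within subject,
  so condition contrasts are within-subject.
* **Population layer** — a linear model on each parameter's link scale
  with design terms intercept, group, condition, and group × condition
  (terms absent from the data are dropped).
* **Criteria** — one population-level ordered vector (first criterion
  plus positive increments) with a subject-level additive shift, shared
  across conditions within subject. Fully subject-specific criteria were
  also evaluated during development; with 19 criteria per subject and a
  few dozen trials they mix worse and give the same or wider population
  intervals, so the pooled-shape/shifted variant is the default. Sharing
  across conditions keeps the parameter count sane for 40-trial
  subjects.

Priors (all configurable via `prior_config`): Normal(0, 1) on link-scale
fixed effects; Half-Normal(0.5) on the random-effect sds; first
criterion Normal(−1.5, 1); criterion increments Half-Normal(0.2) (18
increments of mean ≈ 0.16 span a realistic criterion range of about
three strength units); Half-Normal(0.5) on the criterion-shift sd.
Subject effects use a **non-centered parameterization**
(`u = sd · z`, `z ~ N(0,1)`): with 10–20 subjects the group-level scales
are weakly identified and the centered version intermittently stalls
(R-hat on `sd` above 1.05); non-centering removed every such failure in
a six-seed pilot without changing the posteriors.

Numerical safeguards: category probabilities are floored at 1e−10 inside
the sampler (guards against CDF-difference underflow in extreme tails
during burn-in); HT effects are reported on the probability scale at the
*typical subject* (random effects at zero), i.e.
`Φ(β₀ + β) − Φ(β₀)`, which is the natural-scale contrast a reader
expects. Convergence is checked with Gelman–Rubin R-hat on all
population parameters; any value above 1.05 aborts with a diagnostic
table rather than returning a silently bad fit.

Sampler profiles: `full` (4 chains × 5,000 + 5,000), `recovery`
(4 × 3,000 + 3,000; used by `scripts/acceptance.R`), and `fast`
(4 × 1,000 + 1,000; used throughout the test suite). Posterior means of
the population effects are stable to well under 0.02 between profiles on
fixed data, which is the package's own self-consistency bound.

`hdi()` computes the shortest contiguous interval over the sorted draws;
it agrees with `coda::HPDinterval` to floating-point precision and is
kept in the package so the interval definition is part of the tested
surface.

## Maximum likelihood

`fit_mle()` maximizes the same multinomial likelihood per ROC with an
unconstrained parameterization (probit for HT, log-increments for
criteria), 16 random restarts (d′ ∈ [0, 3], HT ∈ [0, 0.6]; criteria
started at empirical quantiles), ties broken toward the smaller d′.
Invalid regions (underflowed increments) are penalized rather than
raised, so the optimizer can traverse them. Standard errors come from
the observed information with a delta-method transform for HT and are
`NA` when the information matrix is singular — routine for sparse
20-trial ROCs, and precisely the instability that motivates the
hierarchical estimator. A brute-force grid search with profiled criteria
serves as an independent oracle in the test suite.

## The synthetic-data generator

`simulate_ratings()` draws, per subject, link-scale random effects
(identity for d′, probit for HT — so subject-level HT values are valid
by construction, never truncated or resampled), then per trial a
category from the DTSD multinomial and a uniform integer rating within
the category's 4–5 scale points. The within-bin placement is cosmetic
for ROC purposes but lets the data round-trip through the binning code.
The default between-subject sd of 0.2 on each link scale is a choice,
not an estimate: it produces the modest observer heterogeneity one sees
in trained-reader studies while keeping the population cell parameters
interpretable. Seeding is hierarchical (one substream per subject), so
enlarging a design never perturbs earlier subjects' data.

`simulate_trajectories()` emulates cursor movements on the same arc
geometry as the task (860 px radius, 0–180° ↔ scale points 1–90, arc
angle θ ↔ confidence θ/2 + 0.5): the radius grows linearly from the
scale centre while the heading points at an `early_target` confidence
until `switch_time`, then turns toward `late_target` with a smooth
anchor onto the trial's clicked rating, so the final sample always lies
on the arc at the rated position. Heading noise is drawn once per
movement phase per trial — emulating trial-to-trial variation in smooth
movement plans — rather than jittering every sample, which would make
early destination vectors (rays between two near-centre points)
arbitrarily volatile. What the generator does *not* emulate: velocity
profiles, pauses and reversals, wall-clock timing, or any dependence of
movement noise on confidence; passing tests therefore validate the
analysis pipeline's geometry and aggregation, not the realism of human
motor behavior.

## Trajectory analysis

Preprocessing recentres on the first sample, trims to movement onset
(first sample more than 5 px from the start), normalizes time from onset
to click onto 0–100% — by timestamps when present, by sample index
otherwise (the default for synthetic data, which is sampled uniformly) —
and linearly resamples at 21 points. A cursor that never leaves the 5 px
radius is flagged `no_movement` and excluded downstream.

Destination vectors are ray–arc intersections: for each consecutive pair
of resampled points, the ray from the earlier through the later point is
intersected with the arc's circle (forward root of the quadratic), and
the intersection must lie in the right half-plane (the scale's side);
otherwise the destination is missing. This deliberately measures where
the cursor is *heading*, not its instantaneous polar angle — the two
differ exactly during mid-flight changes of mind, which is the signal of
interest. Zero-length steps inherit the previous destination. A
trajectory that re-aims sharply can produce a momentarily off-scale ray;
this yields a missing value rather than a clamped one.

Aggregation histograms destinations into 18 five-point confidence bins
(configurable) at each of the 20 time steps, normalizing each time row
over its non-missing trials. The three-way interaction map is the
cellwise triple difference (experienced − inexperienced) ×
(abnormal − normal) × (long − short), z-scored **jointly over the whole
grid** (a per-time-row standardization would erase the very time
dependence the map is meant to display), with `|z| > 1.96` contours as a
descriptive, not inferential, threshold. Degenerate input (all cells
identical) has zero spread and is mapped to an all-zero z-grid.

## What precision the recovery design can support

The package's recovery experiments run at the study's own sizes: 13
subjects × (20 signal + 20 noise) trials per condition for the
condition-effect study, and a {10, 20} subjects × {20, 60, 180} trials
grid at d′ = 1.5, HT = 0.2 for the fixed-parameter study. It is worth
computing what those sizes can deliver. The per-signal-trial Fisher
information for (d′, HT) with criteria known gives, at the
condition-recovery design:

```{r fisher}
K <- 20
cr <- qnorm(seq_len(K - 1) / K)
catp <- function(d, ht) category_probabilities(dtsd_params(d, ht, cr), TRUE)
fisher <- function(d, ht, eps = 1e-5) {
  p0 <- catp(d, ht)
  pd <- (catp(d + eps, ht) - catp(d - eps, ht)) / (2 * eps)
  ph <- (catp(d, ht + eps) - catp(d, ht - eps)) / (2 * eps)
  matrix(c(sum(pd^2 / p0), sum(pd * ph / p0),
           sum(pd * ph / p0), sum(ph^2 / p0)), 2)
}
n_sig <- 13 * 20                       # signal trials per condition
V <- solve(fisher(1.0, 0.1) * n_sig) + solve(fisher(1.2, 0.2) * n_sig)
sqrt(diag(V))                          # SE floor for (delta d', delta HT)
```

Roughly 0.16 for the d′ contrast and 0.09 for the HT contrast — *floors*
that no correct trial-level likelihood can beat, because they already
assume the criteria are known. Posterior HDI95% widths of the
hierarchical fit land near these floors (about 0.5–0.6 and 0.25–0.3),
and across reseeded replicates the posterior means scatter with about
these sds around the true effects (0.2 and 0.1). Two practical
consequences, both visible in the test suite: a single 13-subject
simulation will not reliably produce an HDI excluding zero for a d′
effect of 0.2, and the replicate-stability bound for the recovered d′
effect is frozen at 0.25 (double the piloted six-seed scatter), not at
some tighter aspirational value. Users planning real studies of this
size should treat these numbers as the attainable resolution.

## Problem sizes in the tests

The test suite keeps MCMC affordable by scaling *resolution*, not
structure: most inference unit tests run on 6-category scales (5
criteria) with 4–10 subjects, where a four-chain fit takes seconds;
the end-to-end recovery checks run the full 20-bin designs with the
`fast` profile (4,000 post-warmup draws). Coverage is checked over 20
small replicates against a loose ≥ 80% bound. Convergence-gated results
(`R-hat ≤ 1.05`) make these runs trustworthy despite the short chains.

## Known limitations

* The HT-mass placement convention (single top category) is one of two
  defensible readings of the model; all downstream quantities are
  conditional on it.
* Criteria are shared across conditions within subject by default;
  condition-specific criteria would need either more trials or a
  hierarchical prior across conditions.
* The MLE's CI95% relies on asymptotic normality that sparse ROCs do not
  support; its instability is reported, not repaired.
* The trajectory generator is a geometry emulator, not a motor-control
  model; the interaction map's ±1.96 contour is descriptive and carries
  no multiplicity control.
* No model comparison (unequal-variance SDT, two-high-threshold) is
  provided; the package estimates the dual-trace model, it does not test
  it against alternatives.
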