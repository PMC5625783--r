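---
title: "Evaluating ED90-targeted phase 2a designs under possible non-monotonicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ED90-targeted phase 2a designs under possible non-monotonicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A phase 2a proof-of-concept trial in rheumatoid arthritis measures the
change from baseline in the DAS28 disease-activity score at day 56
(negative change = improvement) across placebo and six active doses
(0.03, 0.3, 3, 10, 20, 30 mg/kg; 64 subjects in total). The analysis model
estimates the dose-response curve, the target dose is the ED90 — the
lowest dose achieving about 90% of the maximal placebo-adjusted effect —
and posterior probabilities of a drug effect drive interim and final
success/futility decisions.

The design question this package exists to study: what happens to those
operating characteristics when the true dose response is *not* monotone?
Biologic compounds can show a U-shaped (umbrella) dose response — for
example through binding-affinity or immunogenicity mechanisms at high
dose — and a monotone analysis model then systematically misreads the
curve. `ed90sim` simulates whole trials under four data-generating truths
and two analysis models, and aggregates success rates, type-I error, ED90
selection, per-dose bias and ROC curves.

## Data-generating truths

All truths share a placebo effect of −0.5 DAS28 points and Normal
subject-level noise:

| profile   | mean response at dose d                      | residual variance |
|-----------|----------------------------------------------|-------------------|
| flat      | −0.5                                         | 0.25              |
| emax      | −0.5 − 1.7 d / (2.5 + d)                     | 1.44              |
| loglinear | −0.5 − log(d + 1)                            | 1.44              |
| ushape    | (−0.5, −0.7, −1.6, −1.8, −1.2, −1, −0.6) at the seven nominal doses | 1.44 |

The variances are the design values of the study being emulated: 1.44 is a
residual variance typical of DAS28 change scores in an active-treatment
population, 0.25 the tighter spread seen under a null effect. The U-shape
is tabulated only at the nominal doses, and no interpolation is offered:
adaptive allocation only ever assigns nominal doses, so an off-grid query
is a user error, not a modelling need. Under the 90%-of-maximum rule the
true ED90 is 20 mg/kg for the emax truth and 3 mg/kg for the U-shape
(the adjacent 0.3 mg/kg carries nearly the same effect, which is why
selection tables group 0.3 and 3 together).

## Analysis models

**Bayesian Emax model.** `fit_emax()` fits
E0 + Emax·d/(ED50 + d) with Normal residuals by
Metropolis-within-Gibbs: the (E0, Emax) block and the residual variance
use their exact conjugate updates (Normal linear model and inverse-gamma),
and log(ED50) moves by an adaptive random-walk Metropolis step tuned
during burn-in to a 20–50% acceptance rate. Default priors are vague —
E0, Emax ~ N(0, 1e4), ED50 ~ N(3, 100) truncated to positive values
(the mean curve is singular at d = −ED50), σ² ~ IG(0.5, 0.7) — and the
default chain retains 2500 draws after a burn-in of 500. Initial values
are deliberately data-plausible (placebo mean, top-dose contrast, prior
mean of ED50, sample variance); a longer burn-in changes nothing
measurable on these sample sizes. The structural property that matters:
*every* posterior draw of the fitted curve is monotone, whatever the data
say.

**Bayesian NDLM.** `fit_ndlm()` places a second-order normal dynamic
linear model over the dose *index* 1..7 (the doses are treated as equally
spaced; they are approximately half-log spaced by design, and the model
never needs the numeric dose): level θ_j and local slope δ_j evolve as
θ_j = θ_{j−1} + δ_{j−1} + ω_j, δ_j = δ_{j−1} + v_j. The Gibbs sampler
alternates a forward-filtering backward-sampling draw of the full state
sequence (its exact Gaussian full conditional; dose indices without
observations are pure evolution steps) with exact inverse-gamma updates
of the observation variance σ² and the two evolution variances. The
fitted curve is free to rise and fall — the property that lets it track a
U-shape.

Priors: θ_1, δ_1 ~ N(0, 1e4). The evolution variances default to the
vague IG(0.5, 72), whose scale is so large relative to six squared
increments that almost no smoothing is imposed — each θ_j then tracks its
own dose mean. Anchoring δ_1 at zero instead of giving it a prior was
considered and rejected: it would force the placebo-adjacent slope toward
zero and bias low-dose fits. The observation variance deliberately does
*not* share the IG(0.5, 72) scale: with 64 subjects a scale-72 prior
would swamp the residual sum of squares and inflate the estimated σ² by
an order of magnitude, destroying both power and type-I error in ways no
sensible design evaluation would accept; it uses the same weak
IG(0.5, 0.7) as the Emax model so that σ² is learned from the data. All
inverse-gamma parameters are shape/scale (density ∝ x^(−a−1) e^(−b/x)),
and all of this is configurable through `ndlm_prior()`.

## ED90 estimation and decisions

Effects are placebo-adjusted improvements, effect(d) = fitted(0) −
fitted(d), so positive values favour the drug. `estimate_ed90()` applies
the 90%-of-maximum, lowest-qualifying-dose rule to *each posterior draw*
and reports the selection frequencies as an ED90 posterior over the
active doses; the point estimate is the modal dose with ties broken
downward. A "≥ 90% of max" threshold rather than "closest to 90%" keeps
the rule deterministic and monotone; selection over the nominal grid also
means the estimate can never exceed the maximum planned dose of
30 mg/kg. Draws in which no dose beats placebo are excluded from the
selection frequencies; if *no* draw shows a positive effect the estimate
is the "no effective dose" sentinel (reported as missing in selection
tables), and the highest dose is carried forward solely so that decision
probabilities remain computable.

Decision rules (`decision_thresholds()`), with p₀ = Pr(effect at ED90 > 0),
p_csd = Pr(effect at ED90 > 0.95) and p_dmax = Pr(effect at best dose > 0);
0.95 DAS28 points is the clinically significant difference (CSD):

* interim futility: p₀ < 0.20;
* interim success (default `"full"` criterion): the complete conjunction
  p_csd > 0.70 and p_dmax > 0.95 and p₀ > 0.95 must already hold at the
  interim. Requiring the final-analysis evidence before stopping early is
  what keeps early stopping for success essentially impossible under a
  flat truth even with six interim looks; stopping on p₀ alone
  (`"effect_only"`) inflates the early type-I error to tens of percent
  and concentrates all early stopping at the first interim;
* final success (default `"effect_only"` criterion): p₀ ≥ 0.95, the same
  bar in every scenario, which keeps the final-analysis type-I error
  design-independent. The CSD conjunction is available as the `"full"`
  final criterion for designs that want the final claim anchored at the
  clinically significant difference.

Because for the Emax model the sign of every per-dose effect equals the
sign of −Emax, p₀ is the same at every active dose: Emax-model decisions
reduce to the posterior probability that Emax is negative, and the choice
of ED90 dose only matters for the NDLM and for allocation.

## Design scenarios

* **S1 fixed**: 16 placebo + 8 per active dose, one final analysis.
* **S2 non-adaptive cohorts**: 8 cohorts of 8 (2 placebo + one subject
  per active dose), interims at 8, 16, 24, 32, 40, 48 completers.
* **S3 half-adaptive**: the first 32 subjects use the fixed cohort
  pattern; afterwards each subject is randomised to placebo with
  probability 0.25 (capped by the overall 25% placebo budget of 16) or to
  an active dose drawn from the current ED90 selection posterior;
  interims at 32, 40, 48.
* **S4 fully adaptive**: as S3 but adaptation starts after cohort 1 and
  interims run from 8 to 48.

Allocation is per subject (`allocate_next()`); the allocation posterior
refreshes at every interim fit. Cohort composition within the fixed
blocks spreads the 2:1:…:1 ratio evenly (each cohort holds every active
dose once), the natural reading when only the ratio and cohort size are
given. Completer counts are treated as enrolment counts: no accrual
process or day-56 readout lag is modelled, so a trial that stops at an
interim stops having enrolled exactly the analysed subjects. Mean sample
sizes are therefore lower bounds on what a trial with ongoing accrual
during follow-up would enrol — a known, deliberate simplification.

## Reproducibility and numerics

One root seed per study spawns one seed per trial
(`run_study()`), and within a trial the data, the samplers and the
adaptive allocation all consume a single RNG stream, so every trial is
exactly reproducible in isolation. Setting the sampler seed in
`mcmc_control()` additionally pins individual fits. The FFBS backward
pass symmetrises the conditional covariance and floors its diagonal at
zero before the Cholesky factor; degenerate single-draw posteriors give
width-zero intervals rather than errors; DIC is reported with its
effective-parameter count p_D, which is flagged (not errored) if a
pathological posterior drives it negative.

The samplers are written in C++ (via Rcpp) because a design evaluation
fits the model a few thousand times; a single Emax fit takes a few
milliseconds, an NDLM fit about ten.

## What the tests do and do not show

The test suite checks the samplers against independent oracles — a
brute-force joint-Gaussian smoother for the NDLM state draws and the
closed-form Normal posterior for the conjugate Emax block — and exercises
whole-trial properties (placebo budgets, early-stopping monotonicity,
equivalence of the cohort design to the fixed design when interim bars
are unreachable, bit-reproducibility under fixed seeds). Operating
characteristics are recomputed at desk scale, 300–500 simulated trials
per condition rather than thousands, so their Monte-Carlo error is one
to two percentage points; `scripts/acceptance.R` uses the same sizes.
Passing these simulations says the machinery is right under the stated
generative assumptions — independent Normal responses, a single endpoint,
no dropout, no covariates, no accrual dynamics. It does not validate the
models against real DAS28 trajectories, longitudinal readouts, or safety-
driven dose decisions, all of which are out of scope.

## Known limitations

* The Emax posterior on U-shaped data is genuinely bimodal (a
  "flat curve, large variance" explanation competes with a "monotone
  drop" explanation), so the posterior probability of a drug effect is
  sensitive to how thoroughly a sampler traverses the large-ED50 region;
  exact conjugate steps with an adaptive Metropolis update on log(ED50)
  explore it fully, and samplers that mix less freely there will report
  higher success probabilities on such data.
* The NDLM's equal-spacing assumption makes the fitted curve a function
  of dose rank, not dose; conclusions about doses between grid points are
  outside the model.
* Decision thresholds are not recalibrated per design; ROC sweeps
  (`roc_sweep()`) are the provided tool for comparing models at matched
  type-I error.
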