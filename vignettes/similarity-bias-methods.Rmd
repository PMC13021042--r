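---
title: "Models and methods for similarity-induced working-memory bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for similarity-induced working-memory bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simbias)
```

## The phenomenon and the two candidate mechanisms

When an observer holds a feature (a color, a shape) in working memory and
is asked whether a new probe looks similar to it, the subsequent memory
report tends to be pulled toward probes judged *similar* — even at the
same physical memory–probe distance at which other trials drew a
*dissimilar* judgment. Two mechanisms can produce such a pull:

1. **Representational integration (joint density).** The memory density
   and the probe density are combined multiplicatively, as in optimal cue
   integration: the normalized product of two von Mises densities is
   again von Mises, with mean `atan2(kP*sin(D), kM + kP*cos(D))` degrees
   past the target (toward the probe) and concentration
   `sqrt(kM^2 + kP^2 + 2*kM*kP*cos(D))`. The entire density — mode
   included — shifts.
2. **Probabilistic swaps (mixture density).** The two items stay separate
   but the observer occasionally reports the probe instead of the memory
   item. The response density is `a*vM(S_M, kM) + (1-a)*vM(S_P, kP)`:
   skewed toward the probe, yet its dominant mode remains at the target
   whenever `a > 0.5`.

The two mechanisms are deliberately kept on a common footing: both are
densities over the same discrete circular support, both are fitted with
the same objective, and they differ only in the printed combination rule.

```{r signature}
g  <- circular_grid()
jd <- joint_density(0, 8, 60, 8, g)
md <- mixture_density(0, 8, 60, 8, 0.8, g)
c(joint_mode = circ_mode(jd), mixture_mode = circ_mode(md),
  mixture_mean_bias = round(model_bias(md, 0, 60), 2))
```

The mode shift (joint) versus mean-without-mode shift (mixture) is the
qualitative signature that model comparison leans on.

## Circular support and numerical conventions

* All densities live on a fixed 1°-resolution grid of 360 points,
  matching the 360-valued stimulus wheels of the experiments the
  simulator emulates. Masses are probabilities per bin (they sum to 1),
  not per-radian densities; the product rule is computed literally as a
  pointwise multiplication followed by renormalization over the grid.
  The closed-form von Mises product is retained purely as a test oracle;
  agreement is at the level of numerical round-off (~1e-15) and grid
  refinement to 3600 points moves product means by well under 0.01°.
* Positional angles are in [0, 360); signed offsets in (−180, 180], with
  the antipode mapped to +180 so ties are broken deterministically.
* Von Mises weights are evaluated as `exp(kappa*(cos(theta)-1))`, which
  is overflow-safe for any concentration; Bessel-function ratios use
  scaled `besselI`.
* The circular mean is the argument of the resultant vector and is
  treated as undefined (an error, not an NA) when the resultant length
  falls below 1e-10, e.g. for the uniform density.
* The bias of a density is its circular-mean displacement from the
  target, signed positive toward the probe. For weak probes
  (`kP/kM <= 0.25`) this bias grows with probe distance up to the
  analytic turnover at `acos(-kP/kM)` (95.7°–104.5° for ratios
  0.1–0.25) and declines slightly beyond it; over the sampled
  16°–105° range the profile is therefore monotone except in the last
  few degrees.
* The equiluminant CIELAB wheel places hue index 0 on the positive a*
  axis and increases counterclockwise. Neither phase nor direction is
  empirically constrained; any fixed choice is observationally
  equivalent for the analyses, so both are configuration, not inference.

## The synthetic-data generator

The generator stands in for unreleased human data; its defaults encode
the study conditions of the three designs.

* **exp1** — 12 blocks × (12 baseline + 36 comparison) trials; a single
  probe uniform at 16°–105° from the target (side equiprobable) with a
  similar/dissimilar judgment.
* **exp2** — 4 blocks × 10 trials in each of short-delay baseline,
  long-delay baseline, same-side and opposite-side conditions; two
  consecutive 2AFC probe pairs, each holding a similar probe at ±16°–45°
  and a dissimilar probe exactly 180° from it.
* **exp3** — 4 blocks × (15 baseline + 15 experimental) trials with one
  2AFC pair, for large individual-differences cohorts.

Generative observer defaults: `kappa_M = 12` (a realistic single-item
precision, circular SD ≈ 17°), `kappa_P = 3` (probe traces are much
coarser than the actively maintained item; the ratio 0.25 produces mean
similar-judgment biases of 7–9°, in the empirically observed range),
`lapse_rate = 0.05`, and `p_high_conf = 0.8` (high-confidence retention
near the 68%+ rates typical of these tasks). For exp3 populations,
`kappa_M` is log-normal with median 12 and `sdlog = 0.4`, giving an
interquartile range of roughly 9–16 — wide enough that precision, not
sampling noise, dominates between-person variance.

Two modelling choices in the generator are genuinely open and are made
as follows:

* **Similarity judgments** are not modelled in the literature this
  package follows; we use a logistic rule on the *noisy memory sample*
  `X_M ~ vM(S_M, kappa_M)`: `P(similar) = logistic((c - |X_M - S_P|)/b)`
  with criterion `c = 60°` and slope `b = 15°`. Conditioning on `X_M`
  rather than on `S_M` is essential: it is what makes the same physical
  probe distance yield different judgments on different trials, and thus
  what gives the ambivalent-probe analysis something to detect. The
  criterion sits near the middle of the exp1 sampling range so that both
  judgment types occur at intermediate distances.
* **Sequential integration** across exp2's two judgments: each chosen
  (judged-more-similar) probe is multiplied into the current memory
  density in order, each time with weight `kappa_P`. With same-side
  probes the two shifts accumulate; with opposite-side probes the second
  shift largely cancels the first — the cancellation signature the
  design exists to show. The two-step mechanism is not otherwise
  constrained by data.

Confidence is generated as: lapse → rating 3 (uniform report); otherwise
rating 1 with probability `p_high_conf`, else 2. Delay conditions are
metadata only (equal `kappa_M` by default). Per-participant RNG
substreams are derived from the master seed, so cohorts are reproducible
and a participant's data do not depend on cohort size.

What the generator does **not** emulate: reaction times, display timing,
practice and fatigue effects, stimulus-specific anisotropies of real
shape/color spaces, serial dependence between trials, and any
correlation between judgment criteria and memory precision. Passing
tests therefore validate the machinery and the models' distinguishing
predictions, not the empirical claims themselves.

## The analysis pipeline

Signed offsets are computed per trial relative to the design's reference
probe (the single probe in exp1; the *first pair's similar probe* in
exp2/exp3), positive toward it; baseline magnitudes receive random
signs. Analyses use high-confidence (rating 1) trials by default, with
per-cell retention fractions reported.

The ambivalent-probe analysis bins probe distances into 5°-wide bins
(configurable) and, per participant, keeps only bins in which both
judgments occurred; the similar/dissimilar means are averaged across a
participant's ambivalent bins, equating physical distance across
judgment types by construction. Per-degree distance granularity would
leave almost no ambivalent cells at realistic trial counts; 5° is the
coarsest width that still resolves the 16°–105° range into the 18 bins
used in the distance-profile analyses.

Memory precision is the maximum-likelihood mean-zero von Mises
concentration of high-confidence baseline offsets (no guess parameter:
confidence filtering is the guess control; the full
von-Mises-plus-uniform mixture is `fit_standard_wm()`). Distribution
plots use Cousineau–Morey within-subject standard errors. The exp3
outlier rule is bivariate: drop participants beyond 3 SD on either
variable, always reporting the correlation both with and without them.
Power utilities use the noncentral-t distribution (one-sample test) and
the Fisher-z approximation (correlation), matching the standard
power-analysis tooling to the printed sample sizes (15, 22, 99).

## Fitting and model comparison

The fitting objective follows the mean-matching procedure: choose
parameters whose predicted average signed response error — the expected
circular-mean displacement toward the probe, averaged over the fitted
trials — is closest to the observed average, collapsed across probe
distances. The prediction is computed analytically from the density
(equal in expectation to simulating responses and averaging, without
Monte-Carlo noise); a literal simulate-and-average variant is available
via `objective = "simulated"`. Signed error is the default quantity
matched (it is the bias the models exist to explain); absolute error is
available behind a flag.

Optimization is exhaustive grid search — `kappa_P` log-spaced on
0.1–100 (61 points), `alpha` on 0–1 in steps of 0.01 — followed by local
refinement of `kappa_P`. With one or two free parameters this is fully
reproducible and immune to local minima.

One subtlety is resolved in the package's own way: matching a single
mean constrains the mixture's two parameters only up to a
one-dimensional ridge (many `(alpha, kappa_P)` pairs produce the same
mean bias). Among grid points whose objective is within 0.25° of the
minimum, the fit therefore selects the pair with the highest summed
log-likelihood. This keeps the printed objective primary while making
the mixture parameters identifiable; parameter-recovery simulations
(median over 50 replicates of 300 trials) recover `kappa_P` within a few
percent for the joint model and `alpha` within ±0.02 of a true 0.85.

Likelihoods are evaluated on the grid: a trial's likelihood is the
fitted density's probability mass at the observed response bin. AIC and
BIC use `k` = free parameters summed across participants (1 per
participant for joint, 2 for mixture) and `n` = total fitted trials —
the likelihood is a product over trials, so trials are the natural
sample size for BIC. Both per-participant-then-summed and pooled
aggregations of log-likelihood are available via `compare_models()`
operating on fit lists.

`kappa_M` provenance is an explicit argument of every fit
(`kappa_M_source`), defaulting to a fit of the same dataset's baseline
condition via `fit_standard_wm()` (kappa component only). It is
parameterized rather than hard-coded because reasonable workflows
import the precision estimate from a separate baseline session.

## Problem sizes

The shipped recovery studies use 300 fitted trials per participant, 50
replicates for parameter recovery, and 20 replicates of 16-participant
cohorts for model recovery; the end-to-end cohort checks use 16 (exp1),
28 (exp2) and 110 (exp3) simulated participants — the analyzed sample
sizes of the designs being emulated. These sizes give stable medians and
preference rates while keeping a full run of the suite and the
acceptance script in the minutes range on a single core.

## Known limitations

* The joint model is fitted at the density level; whether integration
  operates on the noisy sample or the density is not distinguishable
  from the data the package models, and only the density-level form is
  fitted. Trial-level variants exist only inside the simulator.
* The mean-matching objective discards distributional information by
  construction; the likelihood enters only through the ridge tie-break
  and the information criteria. A fully likelihood-based fit would be a
  different (and stronger) estimator than the procedure reproduced here.
* Simulated cohorts are far cleaner than human data: no attentional
  fluctuations beyond a constant lapse rate, no heteroscedasticity
  across the wheel, no response-production noise beyond the 1° grid.
  Effect sizes from simulations should be read as upper bounds.
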