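---
title: "Estimating the cone of perceived central sound: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the cone of perceived central sound: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecone)
library(dplyr)
```

## The problem

When a sound and a visual stimulus occur together, the perceived location
of the sound is pulled toward the visual stimulus — the ventriloquism
effect. In the experimental paradigm this package analyses, listeners hear
a voice spatialized at one of nine azimuths (−40° to +40° in 10° steps,
negative to the listener's left) while a face is shown centrally, and
report whether the voice came from the left, the middle, or the right
(3AFC). The quantity of interest is the **cone width**: the range of
azimuths a participant perceives as central. If a visual stimulus captures
sound location, the cone should widen, and if social gaze cues matter, a
face making direct eye contact should widen it more than the same face
with eyes closed.

## The response model

For one participant in one visual condition, let $x$ be azimuth in
degrees. The probability of each response is modelled with two opposed
logistic curves and a complementary middle category:

$$
p_L(x) = \frac{1}{1 + e^{\beta_L (x - \mu_L)}}, \qquad
p_R(x) = \frac{1}{1 + e^{-\beta_R (x - \mu_R)}}, \qquad
p_M(x) = 1 - p_L(x) - p_R(x).
$$

$\mu_L$ and $\mu_R$ are the curve midpoints in degrees, $\beta_L, \beta_R
> 0$ the steepnesses per degree. The three proportions sum to one by
construction, so the middle curve is never fitted independently — this is
what makes the three-curve fit *joint* and respects the non-independence
of the categories.

All four parameters are estimated at once by minimizing the sum of squared
differences between observed and predicted proportions over all azimuths
and all three categories (the residual variance across the three
functions, up to a constant), using the Nelder–Mead simplex. Squared error
on proportions, with equal category weights, is the simplest loss
consistent with that objective; whether trial counts should weight the
categories is an open modelling choice, and the unweighted version is the
one implemented.

The **cone width** is the distance between the azimuth where the left
curve crosses the middle curve and the azimuth where the right curve
does:

```{r}
fit_params <- list(mu_left = -12, beta_left = 0.3,
                   mu_right = 12, beta_right = 0.3)
find_crossings(fit_params)
```

## Numerical choices

* **Positivity of slopes** is structural: the optimizer works on
  $\log\beta$, so a "wrong-sign" psychometric function cannot be
  produced, only a degenerate one.
* **Restarts.** The simplex is run from five starts: a data-driven start
  (midpoints where the empirical left/right proportions cross 0.5 by
  linear interpolation, slope 0.2/deg) and four deterministic
  perturbations of it (midpoints shifted ±6°, slope scaled ×0.4 and
  ×2.5). The perturbation set is mirror-symmetric, so reflected datasets
  yield reflected fits. The best (lowest-SSE, converged) restart is kept.
  Tolerances: absolute and relative loss tolerance 1e−10, at most 2000
  iterations per restart.
* **Crossing location.** Each crossing is bracketed by a sign change on a
  0.1° grid over a search range of ±90° — deliberately wider than the
  stimulus range, since fitted crossings can fall outside ±40° — and
  refined by bisection to well under 1e−4°. The left crossing must be a
  *descending* crossing of $p_L - p_M$ and the right an *ascending*
  crossing of $p_R - p_M$: when the two slopes differ strongly, the tail
  of one curve can leak past the complement of the other and create a
  second, oppositely-signed crossing far on the wrong side, which the
  direction rule discards. Among admissible crossings the one nearest 0°
  is used.
* **Fit acceptance.** A fit is rejected — the "unable to fit" exclusion
  trigger — if the optimizer fails to converge from every start, if the
  predicted middle proportion is materially negative at a design azimuth,
  or if either crossing is missing or the implied width non-positive.
  "Materially" means below −0.01 on a proportion (`middle_tol` in
  `fit_control()`): because the two side curves are free, the tail of one
  routinely exceeds the complement of the other by ~1e−6 at ±40°, and a
  strict zero would reject half of all perfectly interpretable fits. A
  dip of more than a percentage point, in contrast, signals genuinely
  crossed curves with no meaningful middle region.
* **Degenerate inputs.** Fewer than four informative azimuths is a data
  error; all-middle responding leaves the side curves unidentifiable and
  surfaces as a missing crossing.
* **Identifiability at small trial counts.** When an empirical category
  transition is steeper than the 10° azimuth spacing can resolve, the SSE
  surface has a flat ridge in the corresponding (midpoint, slope) pair:
  visibly different parameter vectors fit the observed proportions
  equally well (losses agreeing to 8+ digits) and the implied cone width
  is determined only to about 0.1°. The attained optimum value, by
  contrast, is exactly invariant under left/right reflection of the
  data, and the tests check symmetry at both levels.

## Exclusion rules

Participants are excluded wholesale (all conditions) when any rule
trips:

1. **Vigilance**: more than 20% of catch trials failed (strict
   inequality — exactly 20% is retained).
2. **Edge accuracy**: accuracy below 80% (strict) at −40° or +40° in any
   condition, where only the matching side response counts as correct;
   these azimuths are easy enough that failures indicate technical
   problems rather than perception. Per-condition assessment is the
   default (the stricter reading); pooling across conditions is available
   via `pooled_edges`.
3. **Fit failure** in any single condition, as defined above.

The behavioural rules are evaluated for every participant; fits are run
only for participants who survive them. This mirrors the sequential
accounting used when reporting exclusions in this paradigm and avoids
attributing a meaningless extra "fit failure" to, say, a uniformly
guessing responder who is already excluded for edge accuracy. A
participant can still carry both behavioural reasons at once.

## Group-level inference

Cone widths (one per participant × condition) enter a linear mixed model
with a participant random intercept and no random slopes. For two-group
cohorts, ethnicity and its interaction with condition are fixed effects.
All models are fitted by **maximum likelihood, not REML**: REML
log-likelihoods are not comparable across fixed-effect structures, and the
whole inferential procedure rests on comparing them, so ML is the only
coherent choice. Significance comes from likelihood-ratio tests that drop
the effect of interest from the appropriate model (the interaction from
the full model, each main effect from the additive model); the statistic
is $2\Delta\ell$ truncated at zero against a $\chi^2$ with the difference
in fixed-coefficient count as degrees of freedom.

Pairwise condition contrasts are differences of estimated marginal means
(averaging over other fixed factors with equal weight), with standard
errors from the fixed-effect covariance, **residual degrees of freedom**
(observations − fixed coefficients − participants), Wald-t 95% intervals,
and unadjusted p-values. The residual-df convention is simple and
slightly conservative relative to the likelihood-ratio test; no
Satterthwaite or Kenward–Roger approximation is attempted. The mixed-model
likelihood optimization itself is delegated to `lme4`; the likelihood-ratio
construction, the contrast machinery and the df convention are this
package's own.

## The synthetic observer

Because trial-level data from such studies are rarely deposited, every
stage is validated against a generative observer with known ground truth.
The generator uses *the same functional family the analysis fits* — two
opposed logistics with common slope, middle as complement — so parameter
recovery is well-posed, plus a small lapse rate (default 0.02) mixing in
uniform responding as controlled misspecification: the analysis model
deliberately has no lapse parameter, matching the plain-logistic fit it
emulates. Lapses shift observed proportions but not the crossing points,
since the same constant enters every category.

Defaults, chosen once as a realistic central-listener profile:

| parameter | default | meaning |
|---|---|---|
| `boundary_left`, `boundary_right` | ±10° | category boundaries, audio-only |
| `slope` | 0.25 /deg | transition steepness |
| `lapse_rate` | 0.02 | uniform-response probability |
| `face_widening` | 2° per boundary | any face vs. audio-only baseline |
| `capture_widening` | 1.5° per boundary | direct gaze vs. eyes closed |
| `between_participant_sd` | 3° | SD of a participant-level boundary shift |

Widening each boundary by $w$ widens the cone by about $2w$, so the
defaults inject a ≈3° gaze effect and a ≈4° face-vs-baseline effect —
the magnitudes typical of these visual-capture phenomena. The
participant-level shift acts on both boundary magnitudes at once, i.e. a
random intercept on cone width, matching the inference model; it is
clamped so at least 1° of half-separation remains, keeping the middle
category well defined (no published per-participant variance estimates
exist, so the 3° SD is a generator choice, not an empirical value).
Honest participants pass each vigilance trial with probability 0.98.
Contaminants come in three flavours, each designed to trip exactly one
exclusion rule: uniform responders and side-biased responders (one side
with probability 0.9 everywhere) fail edge accuracy, and vigilance
failers miss catch trials half the time.

What the generator does **not** emulate: real spatialized audio and its
quality variation across headphones, attention drift over a session,
response times, asymmetric cones (empirically, capture can be stronger on
one side), or ethnicity-linked differences (the labels are carried purely
as covariates and generated with identical parameters). Passing recovery
tests therefore shows the estimator is faithful to this model class, not
that the model exhausts real data.

## Validation studies and their sizes

The test suite validates the pipeline at these scales, chosen to give
stable error-rate estimates at desk scale:

* optimizer oracle: one near-exact dataset (1000 trials/cell) against an
  exhaustive 20×20×10×10 parameter grid;
* crossing solver: 50 random parameter sets against a 1e−3° brute-force
  scan;
* recovery and power: 100 replicate cohorts of 40 honest participants,
  10 trials/cell, with the default ≈3° injected gaze effect;
* type-I error: 500 replicate null cohorts of 20 participants;
* exclusion exactness: a 13-participant cohort with one planted
  contaminant per mode, plus hand-built boundary cases at exactly 20%
  vigilance failure and exactly 80% edge accuracy.

## A complete run

```{r, eval = FALSE}
res <- run_pipeline(list(
  simulate = list(n_participants = c(white = 68, east_asian = 57),
                  design = "exp1"),
  seed = 1,
  output_dir = "exp1_run"
))
res$inference
```

## Known limitations

* The SSE loss treats all azimuths and categories equally; a
  likelihood-based multinomial fit would weight cells by information but
  is a different estimator from the one this package implements.
* Residual-df contrasts are approximate for unbalanced data (e.g. after
  per-condition fit failures); the likelihood-ratio tests remain the
  primary inference.
* Cone width is a single symmetric summary; asymmetric capture shows up
  only in the individual crossing azimuths, which the pipeline reports
  but does not test.
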