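# gazecone

Analysis tools for audiovisual **ventriloquism** experiments that measure
how a central visual stimulus — in particular a face making direct eye
contact — pulls perceived sound locations toward it.

## The problem and the statistic

In the paradigm this package supports, listeners hear a voice spatialized
at one of nine azimuths (−40°…+40° in 10° steps; negative = left) while a
face is displayed centrally, and answer *left*, *middle* or *right*
(3AFC). For each participant and visual condition the package fits, **all
three at once**, the category response curves

```
pL(x) = 1 / (1 + exp( βL (x − μL)))        "left"   (decreasing)
pR(x) = 1 / (1 + exp(−βR (x − μR)))        "right"  (increasing)
pM(x) = 1 − pL(x) − pR(x)                  "middle" (complement)
```

by Nelder–Mead simplex minimization of the squared error across all three
curves, then computes the **cone width**: the distance in degrees between
the azimuth where `pL` crosses `pM` and the azimuth where `pR` crosses
`pM` — the range of sound locations the listener perceives as central. If
visual capture is at work, the cone is wider when a face is present, and
wider still when the face makes direct eye contact.

Group-level inference uses a linear mixed model on cone widths
(`width ~ condition (× ethnicity) + (1 | participant)`, fitted by ML),
likelihood-ratio tests obtained by dropping the effect of interest, and
pairwise condition contrasts with residual-df Wald-t intervals.

The package also ships:

* the participant exclusion rules used in this paradigm (vigilance
  failures > 20%, accuracy < 80% at the easiest ±40° azimuths, failure to
  fit the logistic functions), with an auditable report;
* a synthetic-observer generator with known ground-truth cone widths and
  plantable contaminant participants, so the whole pipeline is verifiable
  without access to raw study data;
* a `run_pipeline()` orchestrator plus a thin CLI
  (`inst/cli/gazecone.R`) covering simulate → QC → fit → infer;
* `tidy()`/`glance()` methods and `autoplot()`/`plot_cone_widths()`
  figures.

## Worked example

```r
library(gazecone)

cohort <- simulate_cohort(
  cohort_spec(n_participants = c(white = 10, east_asian = 10), seed = 42)
)
res <- apply_exclusions(cohort$trials)   # QC + joint fits + cone widths
inf <- analyze_cone_widths(res$widths)
inf
#> Cone-width mixed-model analysis
#>   20 participants, 40 observations, conditions: eyes_closed, direct_gaze
#>
#> Likelihood-ratio tests (effect dropped from its model):
#>               effect     chi2 df   p_value logLik_full logLik_reduced
#>            condition 12.96948  1 0.0003166      -128.3         -134.8
#>            ethnicity  1.62656  1 0.2021800      -128.3         -129.1
#>  condition:ethnicity  0.06197  1 0.8034091      -128.3         -128.3
#>
#> Pairwise condition contrasts (degrees, unadjusted p):
#>                   contrast estimate     se df     t   p_value ci_low ci_high
#>  direct_gaze - eyes_closed    4.163 0.9729 16 4.279 0.0005754    2.1   6.225
```

Reading the output: the direct-gaze cone is estimated 4.2° wider than the
eyes-closed cone (this cohort was simulated with a ≈3° true effect plus
sampling noise from 10 trials per azimuth), the likelihood-ratio test for
the condition effect is χ²(1) = 12.97, and ethnicity — generated with no
effect — shows none. Per-participant fits can be inspected directly:

```r
counts <- aggregate_counts(cohort$trials)
fit <- fit_joint(dplyr::filter(counts, participant_id == "P001",
                               condition == "direct_gaze"))
find_crossings(fit)       # crossing azimuths, cone width, status
autoplot(fit)             # observed proportions + fitted curves
```

See the vignette (`vignettes/cone-width-methods.Rmd`) for the model,
numerical choices, exclusion rules, and what the synthetic observer does
and does not emulate.

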