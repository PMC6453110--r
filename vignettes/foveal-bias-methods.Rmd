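---
title: "Methods: modelling central-versus-peripheral perceptual decisions in the dark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling central-versus-peripheral perceptual decisions in the dark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Under daylight (photopic) illumination vision is mediated by cones, whose
density peaks at the fovea; under dim (scotopic) illumination it is mediated
by rods, which are absent from the fovea. Night vision therefore has a
functional foveal scotoma. An optimal perceptual decision maker should know
this and discount foveal signals in the dark. `scotovis` implements the
tools to ask whether human observers do: a two-interval forced-choice design
in which centre-surround grating stimuli — continuous (C) when centre and
surround stripes share an orientation, discontinuous (D) when they are
orthogonal — are presented at eccentricities of 0, 4 or 8 degrees, and the
observer reports which interval appeared continuous (comparison task),
or first selects an interval to judge and then reports its appearance
(selection + appearance tasks).

Two hypotheses make opposite predictions for stimuli at the scotopic
scotoma. Under the *perceptual-gap* account the observer either perceives a
gap or does not trust filled-in content, and bases decisions on the
peripheral stimulus alone. Under the *filling-in* account the scotoma is
perceptually completed from its surround and the inferred content is
trusted like veridical input, so a foveal stimulus always looks continuous
and ties are resolved indifferently. A third reference, the
*photopic-veridical* observer, sees everything correctly in the light.
`prediction_table()` enumerates these rules exactly; all predicted
proportions are 0, 0.5 or 1.

## The generative observer model

`observer_params()` parameterizes a simulated participant:

| parameter | meaning | unit / range | default |
|---|---|---|---|
| `accuracy(lighting, ecc)` | P(veridical percept) outside the scotoma | [0, 1] | photopic 0.99; scotopic 0.95 (4°), 0.966 (8°) |
| `p_fill` | P(scotoma percept is "continuous") | [0, 1] | 0.95 |
| `reliability r(e)` | reliability score per eccentricity | log-odds | (1.43, 0.54, 0) at (0°, 4°, 8°) |
| `tie_bias` | extra tie-break log-odds per pair | log-odds | 0 |
| `lapse` | P(uniform random response) | [0, 0.5] | 0.02 |
| `type_pref` | selection bonus for perceived-continuous stimuli | log-odds | 0 |
| `p_break` | P(fixation deviation > 2°) | [0, 1] | 0.05 |

Percepts take values C, D or GAP. Inside the scotopic scotoma (retinal
eccentricity 0) the percept is C with probability `p_fill` and GAP
otherwise, *irrespective of the stimulus actually shown*; elsewhere it
matches the truth with probability `accuracy`. A GAP percept carries no
stimulus evidence: it is never the instructed target in the comparison task
(the decision falls to the other interval), it is never selected against a
non-GAP alternative, and in the appearance task it is reported
"discontinuous" (a perceived gap does not look continuous), so a partially
filled-in observer reports a foveal scotopic stimulus as continuous at rate
`p_fill (1 - lapse) + lapse / 2`.

When the two percepts tie (both match or both miss the instructed target),
the lower-eccentricity interval is chosen with probability

$$P(\text{choose less eccentric}) \;=\; \sigma\!\big(r(e_\text{low}) - r(e_\text{high})\big),$$

with $\sigma$ the standard logistic. This functional form makes biases
*logit-additive across eccentricity pairs by construction*: the log-odds of
the 0°|8° bias equals the sum of the 0°|4° and 4°|8° log-odds, which is
exactly the property the additivity analysis measures. The defaults
$r = (1.43, 0.54, 0)$ were fixed once from the reported magnitude of the
ambiguous-condition biases via this map ($\sigma(0.89) \approx 0.71$,
$\sigma(0.54) \approx 0.63$) and are not tuned thereafter. Lapses apply at
the decision stage, not the percept stage, so same-eccentricity accuracy
remains interpretable as `accuracy` itself.

Two deliberate modelling notes. First, a *constant* foveal bonus added to
every pair containing 0° cancels exactly in the $(0|4)+(4|8)$ versus
$(0|8)$ comparison; it cannot produce non-additivity. The `tie_bias`
parameter therefore attaches to individual pairs, and the non-additive
generator used in testing puts 0.5 logits on the 0°|4° pair alone. Second,
because the scotoma percept is independent of the stimulus shown, the
simulated same-eccentricity accuracy at the scotopic fovea is exactly
chance; the generator makes no attempt to reproduce residual foveal
discriminability a few points above chance.

## The analysis chain

`filter_valid()` removes trials whose maximum fixation deviation exceeds 2
degrees (strictly greater; exactly 2 is valid). `apply_exclusions()` then
drops observers with fewer than 12 valid trials in any grouped condition
(experiments 1–2; the same absolute floor of 12 is kept in experiment 2
despite its 16 repetitions) or fewer than 6 in any ungrouped condition
(experiment 3), and observers at or below 75% accuracy in control
conditions — same-eccentricity conditions in experiment 1 (except 0°
scotopic, where discrimination is impossible), appearance-task conditions
in experiment 2 (except a discontinuous stimulus at the 0° scotopic
scotoma). For experiment 3 the accuracy rule is applied to the observer's
overall unambiguous-trial accuracy, since a per-condition reading is not
determined by the design; this is a package choice.

Conditions with reversed temporal sequences (0°|4° and 4°|0°) and opposite
screen sides are merged, normalized lower-eccentricity-first, and responses
of discontinuity-instructed observers are recoded to "which appeared
continuous" before pooling. Retinal eccentricity is screen position minus
fixation position, so the fixation-manipulation experiment normalizes onto
the same grouped pairs. Point estimates are means across observers of
per-observer proportions (the unit plotted in the study's figures), not
pooled-trial proportions.

## Resampling and transformation statistics

Confidence intervals are bias-corrected and accelerated (BCa) percentile
bootstrap intervals from 20,000 resamples. The resampling unit is the
observer by default; `bootstrap_config(unit = "trial")` is accepted for
sensitivity analyses because the original description does not fix the
unit. Numerical choices: the bias correction $z_0$ uses the fraction of
bootstrap means strictly below the observed mean; the acceleration comes
from jackknife skewness; when the observed mean falls at an extreme of the
bootstrap distribution the interval falls back to plain percentile bounds
with a warning; all-identical input returns a zero-width interval; fewer
than 1000 resamples triggers a stability warning; a seed makes endpoints
bit-for-bit reproducible.

Proportions are linearized for the additivity analysis with the logit
$y \mapsto \log(y/(1-y))$. (The printed equation in the source article
omits the division; only the odds form is a logit and only it makes
additivity meaningful, so the odds form is implemented.) Proportions of
exactly 0 or 1 are first moved inward by $48^{-1}$ — half of the resolution
attainable with 24 repetitions per grouped condition; the clamp is applied
*only* at the extremes, never as universal shrinkage. Trial-order trends
are assessed by ordinary least squares on the across-observer mean at each
within-condition trial number; a homoscedastic OLS error model is used
since nothing finer is specified.

## Stimulus rendering

`render_stimulus()` draws the calibrated stimulus: surround disc of 6°
exterior diameter, centre disc of 0.7° (inside the rod-free fovea),
sinusoid of 1.4 cycles/degree at Michelson contrast 0.99, phase 0, at 40
pixels/degree. The centre-surround border is sharp; the exterior edge ramps
to the background with a raised cosine over 0.25°. The background is mean
gray — equal to the grating mean, so the smoothed edge is
luminance-neutral — and the centre phase is locked to the surround phase
(both 0), the natural reading of a single fixed phase. Physical luminances
of the display and the neutral-density filter stack are carried as sidecar
metadata only; no gamma or optics model is applied. Images are written as
8-bit PNG under a linearized-luminance assumption.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analysis assumes:
near-perfect peripheral discrimination, chance-level foveal discrimination
in the dark, probabilistic filling-in, logit-additive eccentricity biases,
per-observer stimulus-type preferences, lapses, and occasional fixation
breaks. It does not model reaction times, learning or fatigue (its
observers are stationary by construction), sensory noise correlated across
intervals, or residual foveal discriminability at the scotopic fovea.
Passing the recovery and calibration tests therefore shows the *pipeline*
is correct and well-calibrated under the assumed generative structure — it
does not by itself validate the psychological model on real observers; for
that the chain is applied to deposited raw data through the column-mapping
adapter (`read_trials()` with `column_map()`).

Problem sizes used by the test suite were chosen to mirror the study
design: cohorts of 22 observers by 288 trials per session, 100 replicate
simulations for calibration and power checks, 500 replicates for bootstrap
coverage, and 20,000 bootstrap resamples throughout.

## A worked example

```{r, eval = FALSE}
library(scotovis)

sched <- rbind(build_schedule(1, seed = 1, lighting = "scotopic"),
               build_schedule(1, seed = 1, lighting = "photopic"))
trials <- simulate_experiment(sched, observer_cohort(22), master_seed = 1)
kept <- apply_exclusions(filter_valid(trials)$valid, 1)$trials
proportion_less_ecc(kept, config = bootstrap_config(seed = 1))
prediction_table(1)
```

Equivalently, `run_pipeline()` executes the whole chain from a single
configuration (file or list) and writes proportions, predictions, the
additivity report, the trend fit, the exclusion report and a manifest whose
counts are conserved across every filtering stage.

## Known limitations

* The adapter for deposited raw data needs a user-supplied column map; the
  deposit's schema is not bundled.
* Experiment 3 predictions are not defined (none exist for it); its
  analysis reuses the comparison-task machinery after retinal-eccentricity
  normalization.
* The trial-order analysis ignores the short breaks after 33% and 66% of
  trials; schedules are a single uniform shuffle.
* BCa intervals with very small cohorts (< 10 observers) can be unstable;
  the warnings are deliberate, not decorative.
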