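---
title: "Crowd aggregation of traced trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowd aggregation of traced trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracewoc)
```

## The problem

Tracing a curve with a finger is a continuous visuomotor task whose errors
accumulate: a deviation at one point drags the rest of the stroke with it,
and the same person tends to deviate in the same places, in the same
direction, trial after trial. The wisdom-of-the-crowd question is whether
pooling many people's traces recovers the target curve better than any one
tracer does — and by how much, under what aggregation rule, and whether the
crowd must really be made of *different* people.

This vignette documents the models, conventions and numerical choices the
package commits to. Everything here is the package's own account of its
design; no number is asserted that the test suite or the acceptance script
does not itself compute.

## Geometry: templates, segments, reference points

Templates are closed planar curves in millimetres, in the native touch
convention (origin top-left, y downward; every statistic is
translation/reflection invariant). Five analytic families are built in —
two ellipses (semi-axes 55 × 35 and 60 × 20 mm), three- and four-petal
polar roses `r(θ) = 35 + 20 cos(kθ)` scaled to a 110 mm box, and a
lemniscate of Bernoulli of half-width 55 mm — all centred in the
216 × 135 mm tablet drawing area. The published task used curves from the
pure-frequency family whose exact parameters travel with the deposited
data, so the built-in shapes are representative stand-ins of matching
character; a `custom` loader (`read_template_csv()`) accepts any closed
polyline, and every statistic is defined relative to whichever template is
used.

The dense polyline is divided into segments of equal **arc length**
(boundaries at `kL/n`, half-open intervals, traversal starting at the
polyline's first point — a fixed convention the statistics are invariant
to). Each segment contributes one **reference point**: the coordinate-wise
(marginal) median of its dense points, with the even-count median taken as
the midpoint of the two central values. "Median centre of mass" admits a
second reading, the geometric (spatial) median; the marginal median was
chosen as the simplest construction consistent with both words, it is the
convention applied uniformly to binning, subsampling and aggregation, and
at the bin widths used the two differ by far less than any effect studied.
Defaults of 50 reference points for the ellipses and 100 for the other
templates keep the geometry faithful while leaving several raw samples per
bin per pass.

## From raw traces to individual trajectories

Each 30 s trace is spliced into **8 raw individual trajectories of equal
wall-clock duration** (5 and 12 supported for robustness analyses).
Splicing is by timestamp, not sample count, so irregular sampling cannot
skew slice lengths; the final sample joins the last slice. True
single-pass segmentation is deliberately avoided: delimiting a "lap" is
ill-posed exactly for the least accurate tracers, and any rule that works
only for good traces biases the comparison.

Raw samples are assigned to the Euclidean-nearest reference point (exact
ties, which arise only in constructed fixtures, break to the lowest
index), and each bin's samples are reduced to their median centre of mass.
Empty bins stay missing — never interpolated — and all downstream
aggregation and scoring is defined over available bins, with coverage
reported. No smoothing, filtering or resampling touches the raw samples.

Cleaning applies three independent filters before any analysis: traces
shorter than 25 s; traces whose standard deviation in either axis is
below half the template's (computed over the template's dense polyline);
and traces with a jump between consecutive samples exceeding a quarter of
the screen dimension. The jump rule is applied **per axis**
(`|Δx| > 54 mm` or `|Δy| > 33.75 mm`), the most natural reading of "a
quarter of the dimensions" and the more conservative one; the criterion-ii
standard deviation uses the raw trace. A trace may fail several filters;
the report tallies each independently.

## Aggregation and scoring

The crowd trajectory takes the per-bin median (or mean) centre of mass
across individual trajectories. Crowds "one per subject" default to each
subject's **first** time slice — the choice is arbitrary and configurable
(`segment = "random"` or an index); first-slice keeps results
deterministic. Errors are per-bin Euclidean distances to the reference
points, summarised by their arithmetic mean; multi-template statistics are
unweighted arithmetic means of per-template values.

Two exact properties anchor the test suite. With mean aggregation the
crowd's per-bin error can never exceed the per-bin mean of individual
errors (convexity of the norm), bin-wise and hence overall. And the
per-bin median is insensitive to any single arbitrarily wild input among
three or more — the robustness that motivates the median default.

## The synthetic cohort model

The generator (`generate_cohort()`) produces the statistical structure the
analysis is designed to detect, with defaults chosen once as the study
conditions:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 200 | cohort size |
| `age_range` | 6–18 y | ages drawn uniformly |
| `bias_amplitude` | 2.5 mm | marginal sd of the subject bias field at the reference age |
| `bias_modes` | 3 | sinusoidal components of the bias field |
| `trial_noise` | 1.5 mm | sd of within-trial wander at the reference age |
| `wander_correlation_length` | 20 mm | arc-length memory of the wander |
| `jitter` | 0.3 mm | per-axis sensor noise per sample |
| `age_reference`, `age_exponent` | 10 y, 1 | skill scaling `g(age) = (10/age)^1` |
| `passes` | 8 | template laps per 30 s trace |
| `sample_rate`, `duration` | 85 Hz, 30 s | tablet touch stream |
| `outlier_fraction`, `outlier_scale` | 0.05, 20 mm | wild subjects |

The finger follows the template at constant nominal speed (8 laps in 30 s,
so the default splicing yields about one lap per slice), displaced along
the local normal by `bias(s) + wander(S)` plus isotropic jitter.

**Bias** is a smooth periodic field
`Σ_k A_k sin(2πks/L + φ_k)`, `k = 1..3`, with Rayleigh amplitudes and
uniform phases — equivalently Gaussian sine/cosine coefficients — so the
field is a stationary Gaussian process on the circle whose marginal sd is
exactly the configured amplitude and whose mean across subjects is zero at
every arc position. This gives a closed-form bias-induced error floor,
`E|bias| = amplitude · √(2/π)` (`bias_error_floor()`), which the
within-subject plateau should recover: the parameter-recovery test checks
it to 15%. **Wander** is a stationary Ornstein–Uhlenbeck process in
cumulative traversed arc length; with a 20 mm correlation length and
~290 mm curves, successive laps are effectively independent, which is what
lets self-aggregation cancel wander but not bias. Amplitudes 2.5/1.5 mm at
age 10 with `g(age) = 10/age` place individual errors around 2.5–3 mm and
the young/old contrast near the published magnitudes. Outliers replace the
bias amplitude with 20 mm — an order of magnitude beyond typical bias, the
scale at which a twentieth of the cohort visibly corrupts mean but not
median aggregation. No speed–curvature coupling is modelled: under
nearest-point binning the aggregation statistics are insensitive to
kinematics along the curve.

**What the generator does not emulate**: population-level systematic bias
(every subject's field is independently zero-mean, whereas real cohorts
plausibly share error structure — see Limitations), drift or fatigue
within a trial, finger-width censoring near corners, and the true spatial
structure of human bias fields. Passing tests therefore certify the
pipeline's statistical machinery under a known generative model, not the
magnitudes of any particular human dataset.

## Analysis conventions

* **Within-subject curves** enumerate all `C(8, k)` subsets per subject
  (56 at `k = 3`), averaging errors over subsets then subjects.
* **Between-subject curves** draw subjects *without replacement* within a
  draw — a crowd of `n` means `n` distinct people — with one uniformly
  chosen slice per subject, 10 000 Monte-Carlo draws by default, seeded.
* **Bootstrap** resamples whole subjects with replacement up to the
  original cohort size (500 virtual experiments, central 95% quantiles).
  For between-subject curves the interval re-runs a reduced Monte Carlo
  per virtual experiment and is off by default; point estimates always use
  the full draw count.
* **Outperformance** compares the crowd error against *all* individual
  trajectories (all slices, not one per subject), matching the way the
  histogram is accumulated.
* The **skill sweep** ranks subjects by true skill (their mean individual
  error) corrupted by Gaussian noise scaled to the skill sd; the crossover
  percentile is read off the empirical distribution of individual errors
  at the crowd error, the simplest definition consistent with the
  outperformance framing.
* **Age profile** averages slices within subject, subjects within integer
  age and template, then templates.

## Numerical choices and degenerate inputs

Zero-length polyline edges are dropped with a warning; a segmentation
that would leave a segment without dense points rejects the template.
Traces need two samples and strictly increasing timestamps at load;
cleaning never errors, and an all-removed cohort is valid. An error
profile over zero non-missing bins is an explicit error, not an `NaN`.
Coordinates survive the on-disk CSV round trip exactly (17 significant
digits). All Monte-Carlo components take explicit seeds; cohort generation
derives independent per-subject sub-seeds from the master seed so cohorts
are reproducible regardless of evaluation order.

## Problem sizes in the test suite

The suite exercises the full study conditions (200 subjects × 5 templates,
30 s at 85 Hz) where the claims require them — the crowd-vs-individual
ratio, outperformance and age-group signatures — and smaller single-
template cohorts (15–100 subjects) for unit-level properties, with
Monte-Carlo sizes of 400–1200 draws and bootstrap sizes of 100–500 chosen
to keep each check's sampling error an order of magnitude below the margin
it asserts. The acceptance script uses one default cohort plus three
targeted configurations (fixed-amplitude recovery, zero-bias scaling,
outlier-free comparison).

## Limitations

* With strictly zero-mean subject biases, the crowd error at large `n` is
  pure resampling noise, and the coordinate-wise median is asymptotically
  `√(π/2) ≈ 1.25×` less efficient than the mean for Gaussian offsets. The
  median- and mean-aggregated *trajectories* coincide to a small fraction
  of the individual error, but their *errors* differ by ~10% relative in
  this regime — an intrinsic property of the zero-mean model, not of the
  implementation. Real cohorts, whose crowd error is dominated by shared
  systematic structure, show much smaller relative differences. Relatedly,
  the clean `1/√n` crowd-scaling statement is exact for mean aggregation
  and is measured that way; the median's finite-`n` order-statistic
  constants flatten the log–log slope to ≈ −0.44.
* Binning to nearest reference points leaves a small discretisation floor
  (~0.1 mm on the default geometry, measured by noiseless simulation), so
  crowd errors do not fall to zero even as `n → ∞`.
* The within-subject plateau recovers the bias floor only when every
  subject shares the configured amplitude; under age scaling or outliers
  the plateau estimates the cohort-averaged floor instead.
* Single traces per subject × template are assumed (the task design); the
  "crowd within" therefore always means time slices of one trace, not
  separate trials.
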