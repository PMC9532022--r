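# tracewoc

Wisdom-of-the-crowd (WOC) analysis of traced trajectories.

When many people trace the same closed curve on a touchscreen, each trace
is noisy and systematically biased — yet the *aggregate* of many traces can
reproduce the curve far more accurately than any individual does. This
package implements the full analysis pipeline for quantifying that effect
in continuous motor tasks, together with a synthetic cohort generator so
every stage is testable without behavioural data. It is aimed at
researchers in motor control, collective behaviour and behavioural data
analysis.

## The method

A **template** is a closed curve divided into `n` segments of equal arc
length; the **reference point** `r_j` of segment `j` is the median centre
of mass (coordinate-wise median) of its dense points. Each subject's 30 s
trace is spliced into 8 **raw individual trajectories** of equal duration.
Every sample of a raw trajectory is assigned to its nearest reference
point, and the per-bin median centre of mass gives the **individual
trajectory** `x = (x_1, …, x_n)`, one point per reference point. The
**WOC trajectory** of a crowd is the per-bin median centre of mass across
individual trajectories, one per subject:

    w_j = median-CM { x_j^(i) : subject i }        j = 1, …, n

and every trajectory is scored by its mean Euclidean distance to the
reference points:

    E(x) = (1/n) Σ_j ‖ x_j − r_j ‖.

The analyses built on this scoring are:

* **Aggregation curves** — `E` of the aggregate as a function of how many
  trajectories are pooled, either repeated trials of one subject
  (exhaustive subsets; the "crowd within") or one trial from each of `n`
  distinct subjects (seeded Monte Carlo). Subjects repeat their own
  systematic biases, so the within-subject curve plateaus near the
  bias-induced error floor while the between-subject curve keeps falling.
* **Outperformance percentile** — the fraction of individual trajectories
  whose error exceeds the crowd's.
* **Age stratification** — individual and crowd errors for subjects
  younger/older than a skill threshold (default 10.5 years), plus the
  per-age error profile and each group's trajectory **diversity** (mean
  distance to the group's collective trajectory).
* **Subject-level bootstrap** confidence intervals (virtual experiments
  resampling whole subjects with replacement).
* **Skill-selection sweep** — how accurately a selector must identify the
  top performer before one selected individual beats the crowd.

The synthetic generator writes the same structure the analysis assumes to
detect: smooth periodic per-subject bias fields (zero-mean across
subjects), correlated within-trial wander, sensor jitter, age-dependent
skill and a small fraction of outlier subjects. See the methods vignette
(`vignettes/crowd-tracing.Rmd`) for the model and every default.

## Worked example

```r
library(tracewoc)

cfg <- synthetic_config(n_subjects = 40, seed = 11)   # five templates
fit <- woc(generate_cohort(cfg), n_reps = 500, n_boot = 100,
           n_values = c(1, 2, 4, 8, 16, 32))
summary(fit)
```

```
Per-template wisdom-of-the-crowd summary (errors in mm):
     template individual_error woc_error outperformance within_k_max
      ellipse            2.898     0.605            100        2.591
 thin_ellipse            2.652     0.386            100        2.330
  three_petal            2.627     0.367            100        2.314
   four_petal            2.501     0.370            100        2.175
   lemniscate            2.658     0.583            100        2.364
 between_n_max
         0.562
         0.453
         0.470
         0.449
         0.660

Across templates: individual 2.67 mm -> crowd 0.46 mm (5.8x)
Age groups (threshold 10.5 y): individual young 3.35 / old 1.83 mm; crowd young 0.90 / old 0.55 mm
Cleaning: 200 of 200 traces retained
```

Reading the output: individuals miss the templates by ~2.7 mm on average
while the 40-subject crowd misses by ~0.46 mm, a 5.8-fold improvement that
beats 100% of the 1600 individual trajectories. Aggregating a subject's
own 8 trials (`within_k_max`) barely helps — systematic biases do not
cancel within a person — whereas 32 distinct subjects (`between_n_max`)
reach ~0.5 mm. The young crowd (0.90 mm) beats the average older
individual (1.83 mm). `plot(fit)` draws the template with its crowd
trajectory, both aggregation curves, the individual-error histogram and
the age profile.

Lower-level building blocks (`segment_template()`, `clean_cohort()`,
`splice_trace()`, `subsample_individual()`, `aggregate_trajectories()`,
`between_subject_curve()`, `bootstrap_ci()`, …) are exported and
documented; `run_pipeline()` executes simulate → clean → process → analyse
as one reproducible job with a JSON summary.

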