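# hapticforce

Tools for studying how people tune their finger **indentation forces**
while actively exploring the **softness** of deformable objects, and for
whom: sensorimotor/psychophysics researchers who run (or simulate)
two-alternative forced-choice (2AFC) compliance-discrimination
experiments and need the full path from raw force traces to
repeated-measures inference.

Softness is judged by pressing repeatedly into an object; the peak force
of each press is adjusted to the object from three sources: *predictive
signals* (knowing the softness category in advance, induced by blocked
vs random trial presentation), *sensory signals* (evidence accumulated
between the first and last press of a trial), and *motivation* (reward
moderating how much sensory evidence is gathered and used).  Stimuli are
characterized by compliance `c` (mm/N).  The package implements:

* **Stimulus model** — compliance estimation as the OLS slope of
  displacement on force over 0–9 N; the printed four-category stimulus
  set (0.12–0.88 mm/N); JND-spaced comparisons from Weber fractions
  (21.2% at the hard anchor, 13.5% at the soft anchor, log-interpolated).
* **Experiment designs** — fully counterbalanced schedules: 4 sessions ×
  4 blocks × 96 trials (1,536) with 24/6 repetitions per combination for
  the predictability experiment; 4 × 112 trials (448) with 14
  repetitions, motivation/demotivation halves, and the 50/100-point,
  1,000-points-per-euro reward scheme for the motivation experiment.
* **Synthetic explorer** — a generative model planting the force
  adjustments,
  `F = mu + a_i + beta_pred*w_k*[blocked] + (beta_sens*w_k*g + gamma)*s_j + eps`,
  plus a cumulative-evidence 2AFC observer
  (`d' ∝ (Δc/(w·c))·sqrt(n)`), rendered as 3 ms force/displacement
  traces with half-sine pulses, >180 ms gaps and sub-180 ms shaking
  artifacts.
* **Force features** — 45 ms moving-average smoothing, derivative
  sign-change peak detection with a 180 ms refractory rule, contact
  bouts above 0.1 N, per-trial features (first/middle/last peak, count,
  effort = sum of peaks, last-touched stimulus).
* **Statistics** — linear contrast tests on difference-score matrices
  (`L_i = Σ w_k m_ik`, one-sample t, one-sided for directed
  hypotheses), paired t tests, CoV convergence, Studebaker's
  rationalized arcsine transform, Cousineau–Morey within-participant
  SEs.
* **Questionnaire** — PMI (10–50 points) and PANAVA (−22–38) composite
  scoring with reverse coding, social-desirability residual correction,
  and the strict motivation > demotivation inclusion criterion.

## Worked example

```r
library(hapticforce)

ds <- simulate_experiment1(n_participants = 16, seed = 1,
                           blocked_reps = 4, random_reps = 2)
run_experiment1_analysis(ds)
#> Softness-exploration analysis report (experiment 1, n = 16)
#>                                 label statistic df         p               tail    effect
#> 1                   baseline_contrast   0.04335 15 9.660e-01          two_sided  0.004459
#> 2                 predictive_contrast  14.55868 15 1.479e-10 one_sided_positive  1.031390
#> 3                    sensory_contrast  28.66608 15 8.135e-15 one_sided_positive  2.028863
#> 4          accuracy_blocked_vs_random  -0.57190 15 5.759e-01          two_sided -0.366211
#> 5    accuracy_indentation_correlation   0.83650 14 5.373e-05          two_sided  0.836497
#> 6 indentation_count_blocked_vs_random   1.06075 15 3.056e-01          two_sided  0.092773
#> 7                     cov_convergence  11.46370 15 4.027e-09 one_sided_positive  0.023753
#> 8                 first_vs_last_force -41.86145 15 5.943e-17          two_sided -0.299327
#> 9                   last_touch_choice  35.78051 15 6.123e-16          two_sided 24.397786

estimate_effects(ds)
#> $beta_pred   0.0516   # planted 0.05 N per contrast-weight unit
#> $beta_sens   0.101    # planted 0.10
#> $gamma_drift 0.299    # planted 0.30 N
```

The baseline contrast (first indentation, random condition) is null, as
it must be when neither predictive nor sensory signals are available;
the predictive and sensory contrasts are strongly positive (forces
increase toward harder categories); forces rise from first to last
indentation (negative `first_vs_last_force` t) while their coefficient
of variation falls (`cov_convergence`); the last-touched stimulus
matches the upcoming choice about 74% of the time (effect is the
percentage-point excess over 50%).

The motivation experiment adds questionnaire scoring and inclusion:

```r
ds2 <- simulate_experiment2(n_participants = 30, seed = 1, reps = 14)
run_experiment2_analysis(ds2, ds2$questionnaires$items)
#> Softness-exploration analysis report (experiment 2, n = 18)
#>                            label statistic df         p               tail   effect
#> 1     questionnaire_manipulation    7.4564 17 9.386e-07          two_sided  9.83796
#> 2        accuracy_rau_motivation    5.1721 17 3.828e-05 one_sided_positive  4.62033
#> 3              effort_motivation   13.5456 17 7.720e-11 one_sided_positive 13.53198
#> 4               sensory_contrast   17.1935 17 1.743e-12 one_sided_positive  0.23673
#> 5 sensory_by_motivation_contrast    4.0377 17 4.272e-04 one_sided_positive  0.10305
#> 6       sensory_by_half_contrast   -0.3471 17 7.328e-01          two_sided -0.01235
```

Participants failing the manipulation check are excluded (here 18 of 30
remain); when motivated, the included participants answer more
accurately, spend more effort, and adjust forces to sensed softness
more strongly (`sensory_by_motivation_contrast`), while the
experimental half does not explain the moderation
(`sensory_by_half_contrast`, the confound check).

Full force traces can be rendered and re-analyzed through the
extraction path:

```r
ds <- simulate_experiment1(n_participants = 3, seed = 1,
                           blocked_reps = 1, random_reps = 1, traces = TRUE)
feats <- extract_features(ds$traces, ds$trials)
run_experiment1_analysis(feats)
```

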