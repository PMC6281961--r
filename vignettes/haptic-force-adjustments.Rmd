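---
title: "Modeling and analyzing indentation-force adjustments in haptic softness exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing indentation-force adjustments in haptic softness exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapticforce)
```

## The scientific problem

People judge the softness of an object by pressing a finger into it
repeatedly.  The peak normal force of each press is not fixed: it is
tuned to the object.  Three sources can drive that tuning:

* **predictive signals** — knowledge available before touch (here:
  whether all trials of a block come from one softness category, making
  the upcoming category predictable);
* **sensory signals** — information accumulated during the exploration
  itself (here: the contrast between the first and the last indentation
  of a trial);
* **motivation** — the rewarding value of the task, which shifts the
  trade-off between movement cost and the benefit of extra sensory
  evidence.

Stimuli are characterized by *compliance* (mm/N): surface displacement
per unit force, the physical correlate of softness.  `hapticforce`
implements the full workflow for studying force tuning in a
two-alternative forced-choice (2AFC) compliance-discrimination task:
schedule construction, a generative simulator with planted effects,
peak-force extraction from force traces, and the repeated-measures
statistics.

## The generative model

The simulator plants the hypothesized adjustments directly in the peak
forces.  For participant $i$, softness category $k$ with centered
contrast weight $w_k$ (soft $\to$ hard), and indentation $j$ of $n$ at
relative position $s_j = (j-1)/(n-1)$:

$$
F_{ikj} = \mu + a_i
  + \beta_{\mathrm{pred}}\, w_k\, \mathbb{1}[\text{blocked}]
  + \left(\beta_{\mathrm{sens}}\, w_k\, g + \gamma\right) s_j
  + \varepsilon_{ikj},
$$

with $a_i \sim \mathcal N(0, \sigma_P^2)$ a participant offset, $g$ the
motivation gain ($g > 1$ in motivation-part trials, multiplying both the
sensory slope and the indentation count), $\gamma$ a
category-independent drift from first to last indentation, and
$\varepsilon_{ikj} \sim \mathcal N(0, \sigma_j^2)$ where $\sigma_j$
tapers linearly from `sd_trial` at the first indentation to
`sd_last_ratio * sd_trial` at the last.  The taper, together with the
drift in the mean, plants the convergence of movement parameters that
the coefficient-of-variation test detects.

Indentation counts are discretized log-normal draws around a
participant-level median (population median 6, matching a typical
average of about six presses per trial with individual medians spanning
roughly 3–13), truncated at the two presses minimally needed to compare
two stimuli.

The 2AFC response comes from a cumulative-evidence observer,

$$
d' = \frac{|\Delta c|}{w\, c_{\mathrm{std}}}\sqrt{g_e\, n}\; b, \qquad
P(\text{correct}) = \Phi\!\left(d'/\sqrt{2}\right),
$$

where $w$ is the category's Weber fraction (interpolated linearly in log
compliance between a hard anchor at 0.14 mm/N, fraction 0.212, and a
soft anchor at 0.74 mm/N, fraction 0.135), $g_e$ the evidence gain per
indentation, and $b$ a force bonus applied to hard stimuli only
(`force_benefit_hard`), reflecting that higher forces aid discrimination
especially for hard objects.  Setting $g_e = 0$ yields exact chance
performance; the defaults produce overall accuracies in the low 90s
percent range, comparable to practiced observers.  Two behavioral
details are planted because the analysis battery measures them: the
last-touched stimulus coincides with the upcoming choice with
probability 0.75, and stimulus visits otherwise alternate freely with
switch probability 0.5.

Rendered traces are half-sine pulses sampled every 3 ms with apexes on
the grid, inter-pulse gaps above the 180 ms refractory interval,
optional finger-shaking ripples (period < 180 ms, amplitude-modulated by
the pulse envelope) and sample-level sensor noise inside contact.
Displacement is compliance times force for the contacted stimulus, so
the compliance estimator recovers the stimulus exactly from noiseless
traces.

### Choice of default effect sizes

The paper-style experiments report which contrasts reach significance,
not raw effect magnitudes, so the generator's defaults were fixed once
from an a-priori power analysis of the linear contrast test: with
per-indentation noise 0.5 N and the printed trial counts, a predictive
slope of 0.05 N per weight unit, a sensory slope of 0.1 N per weight
unit, a drift of 0.3 N and a motivation gain of 1.5 give the designated
tests at least 80% one-sided power at $n = 16$, while leaving the
baseline contrast (first indentation, random condition) exactly null.
The slopes translate into force spreads of a few tenths of a newton
across categories — the order of magnitude a practiced participant
shows around a ~4 N baseline press.

## Extraction of peak forces

Force traces are smoothed with a centered 45 ms moving average (15
samples at 3 ms; truncated windows at the edges avoid phantom edge
peaks).  Peaks are samples where the forward difference turns from
positive to negative; on plateaus the first plateau sample wins
(deterministic tie-break).  Candidates closer together than 180 ms are
thinned greedily, highest first, which removes shaking ripples and
movement pauses; because pulses last 300 ms, every ripple crest lies
within 150 ms of its apex and is always suppressed.  Contact bouts are
maximal runs with smoothed force strictly above 0.1 N — the same
threshold the rig uses to blank the finger cursor; whether the analysis
used the same value is not stated, so it is configurable.  The peak
*amplitude* is read from the unsmoothed trace at the detected peak time:
smoothing locates, the sensor measures.  This makes noise-free recovery
exact instead of attenuated by the kernel (about 1% at the apex of a
300 ms pulse).  Trials without a detected indentation are excluded and
counted in the QC log.

## The analysis battery

Per-trial features (first, middle, last peak force; count; effort = sum
of peak forces; last-touched stimulus) are averaged into participant ×
condition cells.  Difference scores isolate the effects: blocked −
random (predictive; averaged over both exploration moments by default —
the analysis conditions on presentation order × category without
restricting the moment, and a `moments` switch restricts to the first
indentation if wanted), last − first (sensory), and the
motivation-minus-demotivation difference of the sensory scores
(moderation; with two categories this contrast equals the interaction
of a 2 × 2 ANOVA).  Each matrix is tested with a one-sample t test on
per-participant contrast scores $L_i = \sum_k w_k m_{ik}$, one-sided
where the directed hypothesis "larger for harder" exists, two-sided
elsewhere.  Weights default to the equally spaced centered integers
((−3, −1, 1, 3) or (−1, 1)); the statistic is invariant to their
rescaling, and the exact spacing the original analysts used is
immaterial for that reason.  No multiple-testing correction is applied,
matching the analysis being reproduced.

Supporting procedures: paired t tests (algebraically identical to the
two-category contrast), Pearson correlation between indentation count
and accuracy, the coefficient-of-variation convergence test (SD/mean of
first vs last peaks per participant, one-sided), Studebaker's
rationalized arcsine transform for accuracy (the canonical counts-based
form, chosen because only "rationalized arcsine" is specified), and
Cousineau–Morey within-participant standard errors for condition-mean
displays.

Questionnaire scoring: PMI (10 five-point items, reverse-coded by a
configurable polarity key since the published instrument's per-item key
is not reprinted) spans 10–50 points; PANAVA (6 positively and 4
negatively scored seven-point items) spans −22–38; both map linearly to
0–100% and average into the uncorrected motivation score.  The
corrected score is the residual of a pooled OLS regression on the
social-desirability points (mean-centering as the documented fallback
when those are constant); participants enter the final sample iff the
corrected motivation-part score strictly exceeds the demotivation-part
score.  The criterion is applied to corrected scores by default
(`use = "uncorrected"` switches to raw), as the residual correction
exists precisely to improve the validity of that comparison.

## Reproducibility and numerical choices

Everything derives from one integer seed through a documented splitting
scheme: per-(participant, session, block) sub-seeds for schedule
shuffling, and three dataset-level streams (participant parameters,
trial draws, trace rendering), so the trial table is identical whether
or not traces are rendered.  Derivatives below $10^{-9}$ N count as
flat in the peak detector, so constant baselines cannot seed candidate
peaks through floating-point ripple.  Peak forces are floored at 0.2 N
(a press always exerts force); contrast tests refuse zero-variance
score vectors rather than returning infinite t values.

## What the simulations do and do not show

The generator reproduces the statistical structure the analysis
assumes: linear-in-category adjustments, participant random effects,
log-normal indentation counts, refractory-separated pulses,
sub-refractory artifacts, and a motivation moderator.  It does not
emulate biomechanical finger–tissue contact, reaction times, 3D
kinematics, learning across sessions, or any coupling between force
noise and the observer beyond the planted force bonus.  Recovery of
planted parameters therefore validates the pipeline's correctness —
that the analysis measures what the model plants, at the study's sample
sizes — not the physiological realism of the model.  Test problem
sizes: the calibration suite runs 10,000 null replicates at $n = 16$
with one trial per comparison-positioning cell (the type-I rate of the
t test does not depend on the per-cell trial count); power suites run
200 replicates at $n = 16$ with the printed 14 repetitions for the
motivation design and scaled repetition counts (4 blocked / 2 random)
for the four-category design; the unbiasedness check runs 200
replicates at $n = 64$.

## A worked example

```{r example, eval = FALSE}
ds <- simulate_experiment1(n_participants = 16, seed = 1,
                           blocked_reps = 4, random_reps = 2)
report <- run_experiment1_analysis(ds)
report$tests
estimate_effects(ds)
```
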