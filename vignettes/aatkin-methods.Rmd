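---
title: "Models and methods behind aatkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aatkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

aatkin analyses whole-body approach–avoidance (AAT) and interpersonal-distance
(IPD) behaviour recorded as head-position time series in virtual reality.
This vignette is the package's own account of the science in its code: the
kinematic extraction procedure, the trial quality-control cascade, the
Bayesian hierarchical models and their posterior summaries, the approach-bias
d-scores, and the synthetic-cohort generator used to validate all of it.

## The experimental structure the package assumes

A cohort consists of male subjects labelled by sexual orientation
(gynophilic or androphilic) who interact with full-body avatars of either
sex. In the AAT task a subject steps forward (approach) or backward
(avoidance) in response to the avatar's sex, under two counterbalanced
response mappings, and rates each avatar's sexual attractiveness on a 1–5
scale; the avatar appears at 1.5 m. In the IPD task the subject walks from
2 m toward the avatar and confirms the preferred conversation distance with
a button press. Head position is tracked at roughly 85 Hz; x and z span the
horizontal plane, y is vertical.

## Kinematic extraction

Each trial's trajectory is processed in four steps:

1. **Uniform resampling.** Tracker logs are only approximately regular, and
   polynomial smoothing assumes equal spacing, so trajectories are linearly
   interpolated onto an 85 Hz grid spanning the recorded range.
2. **Savitzky–Golay smoothing** with an 11-sample window and degree-2
   polynomial, per coordinate. At the series edges the window shrinks
   symmetrically (the first and last couple of points, where a symmetric
   window supports no more points than the polynomial has coefficients, pass
   through unchanged). Interior points equal the local least-squares
   quadratic evaluated at the window centre, which the test suite verifies
   against a brute-force per-window fit.
3. **Speed** is the magnitude of the derivative of horizontal (x, z)
   position, by central differences (one-sided at the ends). Vertical head
   bob is deliberately ignored: whole-body steps are horizontal, and mixing
   in vertical motion would only add bob noise to the speed curve.
4. **Parameter extraction.** Movement onset is the first sample whose speed
   exceeds 0.10 m/s and stays above it for `sustain_samples` (default 3,
   about 35 ms) consecutive samples; the sustain requirement rejects
   isolated noise spikes that a bare threshold would accept. Initiation RT
   is onset minus stimulus onset. The movement segment ends at the first
   sample after the speed maximum that falls below the 10 cm/s sway cutoff
   (or at the rating onset if it never does). Peak velocity is the maximum
   speed in the segment. Step size is the *net* displacement from onset to
   segment end projected on the subject-to-avatar axis — net projected
   displacement, not path length, because a step's size is how far the body
   ends up, not how much it wobbled on the way. A trial is *missing* when
   no onset precedes the rating onset, and *incorrect* when the signed
   projected displacement from the stimulus-onset position ever reaches
   10 cm against the instructed direction.

The 10 cm/s sway cutoff and the 0.10 m/s onset threshold are numerically
identical but conceptually different knobs, so they are separate
configuration keys (`sway_cutoff`, `onset_threshold`) that happen to share
a default.

For IPD trials, the stopping distance is the horizontal Euclidean distance
between the head at the confirm press (interpolated between samples) and
the avatar, and peak velocity is the maximum speed before the press; trials
whose speed never exceeds the onset threshold are flagged missing (no
forward movement).

Whether onset should be detected on raw or smoothed speed is genuinely
open; aatkin uses the smoothed curve, consistent with extracting all other
parameters from the same smoothed signal.

## Quality control

The AAT cascade applies, in order: (1) drop unextractable (missing) trials;
(2) drop incorrect-direction trials; (3) per subject and per dependent
variable, flag Tukey-fence outliers (outside Q1 − 1.5·IQR to Q3 + 1.5·IQR,
quartiles by linear interpolation) across the subject's remaining trials
pooled over the four avatar-sex × direction cells; (4) for RT only,
additionally drop trials under 250 ms; (5) log2-transform retained RTs to
reduce skewness. Exclusions are per-DV: a trial outlying in RT stays in the
step-size analysis, so the trial table carries one keep flag per DV and no
stage ever modifies a value. Whether the fences should pool the four design
cells within subject or be computed per cell is ambiguous; pooling is the
default reading and `qc_config(aat_grouping = "per_cell")` provides the
alternative. The 250 ms floor is applied after the fences, following the
narrative order of the recipe; only trials that survived the fences are
counted as floor exclusions. The IPD cascade drops no-forward-movement
trials and then applies the fences separately per subject × avatar-sex
cell, independently for IPD and peak velocity.

## Hierarchical models

All models are Gaussian linear mixed models with effect-coded factors
(gynophilic −0.5 / androphilic +0.5; female +0.5 / male −0.5; approach
+0.5 / avoidance −0.5) and fully crossed population-level terms, so each
coefficient is a cell-mean difference on the outcome scale.

* **Implicit AAT model:** outcome ~ orientation × avatar sex × direction,
  with a varying intercept plus crossed avatar-sex, direction and
  sex-by-direction slopes per subject, and a varying intercept plus
  direction slope per avatar.
* **Explicit AAT model:** outcome ~ direction × attractiveness rating, the
  rating entered on its raw 1–5 scale centred at the midpoint (3), with a
  varying intercept and direction slope per subject and per avatar.
* **Implicit IPD model:** IPD ~ orientation × avatar sex, varying intercept
  plus avatar-sex slope per subject, varying intercept per avatar. The
  avatar-sex slope is *not* given to avatars: avatar sex is constant within
  an avatar, so such a slope is unidentifiable.
* **Explicit IPD model:** IPD ~ avatar sex × standardized attractiveness,
  varying intercept plus avatar-sex slope per subject, varying intercept
  per avatar. Standardization differs from the AAT explicit model on
  purpose: the rating is the focal continuous predictor here and its effect
  is reported per SD.

Priors are weakly informative and scale-adapted: Normal(0, 1) on
population effects, Student-t(3, 0, 1) on the intercept, half-t(3, 0, 1)
on every scale parameter, all multiplied by the outcome's standard
deviation (and the intercept prior centred at the outcome mean), so the
same declaration works for log2 RT, centimetres and m/s alike. With a
standardized outcome the declared unit scales apply unchanged.

Sampling uses JAGS with its block-updating linear-model sampler, 4 chains.
The analysis profile runs 8000 iterations per chain with 10% warm-up; the
test profile, used throughout the test suite and the acceptance script,
runs 1000 with 10% warm-up. Within a multi-term varying block, effects are
modelled jointly via the scaled inverse-Wishart parameterization (a latent
multivariate normal under a Wishart-precision prior with df K+1, rescaled
by half-t scale factors), which yields near-uniform marginal priors on the
correlations and keeps every conditional update conjugate. Convergence is
assessed with split-R-hat on all monitored parameters; any value at or
above 1.1 flags the fit as non-converged — the flag is attached to the
result, never silently dropped. Divergence counts are reported as zero
structurally (a Gibbs sampler has no divergent transitions); the
convergence gate rests entirely on R-hat.

## Posterior summaries

For each population effect the package reports:

* the posterior median (the point estimate throughout),
* the 95% highest-density interval — the shortest contiguous interval
  containing 95% of the draws, found exactly by scanning the sorted draws,
* **pb**, the posterior median p-value: the percentage of draws that are
  zero or of sign opposite to the median. Draws exactly at zero count
  against the effect (a conservative convention), and a median of exactly
  zero reports 50%. The conventional reporting flag is pb ≤ 2.5%,
  resembling a two-sided 5% test; it is a flag, not a filter.
* **δt**, a Cohen's-d-like standardized effect: each coefficient draw
  divided by the square root of the sum of all varying-effect variances
  plus the residual variance for that draw. The exact convention for
  mixed-model standardization is not uniquely fixed in the literature;
  total (varying plus residual) variance is this package's documented
  choice, making δt an effect in units of the full outcome SD.
* **Bayesian R²** per draw: Var(fitted)/(Var(fitted) + σ²), with fitted
  values including all varying effects.

Posterior-predictive cell contrasts (e.g. the approach-minus-avoidance
difference within an orientation × avatar-sex cell) are linear
combinations of coefficient draws under the coding map and get the same
median/HDI/pb summary; with unit weight on a single term the contrast
reproduces that term's summary exactly, which the tests assert.

## Approach-bias d-scores and the correlation table

Per subject and DV, using only post-QC trials toward the subject's
preferred avatar sex: d = (mean of avoidance trials − mean of approach
trials) / SD of all those trials pooled (sample, n−1, convention — the
recipe says only "overall standard deviation"). Under this formula a
subject who approaches *faster* than they avoid has d > 0 for RT (smaller
RT minus larger RT) but d < 0 for step size (larger steps minus smaller
steps); this sign asymmetry is intentional, is asserted by a regression
test, and explains why step-size biases correlate *negatively* with IPD
aggregates. Note the tension worth knowing about: verbal descriptions of
such biases ("stronger approach bias") suggest a single sign convention,
but the printed formula does not deliver one across DVs; aatkin implements
the formula and documents the asymmetry rather than flipping signs per DV.

Subject-level variables (mean IPD and mean approach peak velocity toward
the preferred sex, plus the three d-scores) enter a Pearson correlation
table with pairwise-complete observations. Each r gets a pb-style flag
from the Fisher-z normal approximation of its posterior,
z ~ N(atanh(r), 1/√(n−3)) — deterministic, dependency-free, and accurate
at the cohort sizes involved.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. It emulates:

* the full design (72 subjects, 48 gynophilic / 24 androphilic; 10 male
  and 10 female avatars; 160 AAT and 40 IPD trials per subject; 85 Hz),
* latent attraction: +1 for preferred-sex pairs, −1 otherwise
  (configurable), plus pair noise of SD 0.6; ratings arise by thresholding
  at cutpoints (−1.5, −0.5, 0.5, 1.5), so typical preferred/non-preferred
  pairs rate 4 and 2 with the tails reaching 5 and 1,
* trial DVs from linear models on each analysis scale — log2 ms for RT
  (baseline 9.2 ≈ 590 ms, direction effect −0.10, attraction-by-direction
  −0.04), cm for step size (baseline 53) and IPD (baseline 97, sex effect
  −6.7, orientation effect −13.2, interaction +9.8, attraction slope
  −3.5), m/s for peak velocity (baseline 0.85) — with Gaussian subject and
  stimulus intercepts and residual noise,
* trajectories: a minimum-jerk (quintic) step — smooth and bell-shaped in
  velocity, with closed-form peak speed 15D/(8T) that makes extraction
  testable in closed form — embedded in band-limited postural sway. The
  sway is a sum of three low-frequency sinusoids per horizontal axis with
  total SD `sway_sd` (default 8 mm) and band edge 0.3 Hz, giving the
  deterministic speed bound `sqrt(2)·sway_sd·2π·0.3·sqrt(6)` ≈ 4.4 cm/s,
  safely below the 10 cm/s cutoff.

Two design points deserve emphasis. First, each simulated step is *timed
so that its speed profile crosses the 0.10 m/s onset criterion exactly at
the trial's sampled latency*; a threshold detector can only ever see the
crossing, so anchoring the ground truth to the crossing is what makes
"extraction recovers the injected RT within one sample period" a
well-posed test. Second, step duration is derived from the trial's
generated amplitude and peak velocity (T = 15·D/(8·V)), so amplitude and
peak speed can be modulated independently while remaining mutually
consistent with the minimum-jerk shape.

What the generator does **not** emulate: biomechanical gait (weight
shifts, double steps), tracker dropout and quantization, anticipatory
drift before onset, heavy-tailed RT contamination, or rating noise within
a subject-avatar pair. Consequently the QC cascade removes only boundary
cases on clean synthetic data, and the exclusion rates of a synthetic run
are in the ballpark of, but deliberately not calibrated to, those of real
cohorts — raw-trajectory noise levels for this paradigm are not publicly
documented, so `sway_sd` and the residual SDs were chosen once as
plausible and left alone. Passing tests therefore certify the *pipeline's
arithmetic and inference machinery*, not robustness to every artefact of
real tracking data.

## Numerical and design choices collected

* Quartiles use linear interpolation between order statistics (the common
  default); the fences inherit it.
* The onset detector's sustain requirement (3 samples) is a noise guard on
  top of the bare threshold criterion.
* The movement-end rule (first sub-cutoff sample after the peak) is this
  package's construction; the extraction recipe it implements does not
  specify one. Its bias is a small, systematic undercount of the step's
  sub-threshold tails (about half a centimetre for a 50 cm step), well
  inside the one-sample-period tolerance the tests enforce.
* Degenerate inputs: fewer than 4 finite values leave the Tukey fences
  unestimable and keep everything; a d-score with under 2 trials per
  direction or zero pooled SD is absent with a logged reason; a constant
  column yields an absent correlation.
* Problem sizes in the test suite are deliberately small (e.g. 24 subjects
  × 20 trials for the 20-replicate parameter-recovery study; a 72-subject,
  80-AAT-trial cohort in the acceptance script) so the whole suite runs on
  one CPU in minutes while still exercising every code path at realistic
  shapes.

## Known limitations

* The sampler is Gibbs-based; posterior geometry pathologies that HMC
  diagnostics (divergences) would expose are instead guarded only by
  R-hat and effective-sample-size behaviour across 4 chains.
* The scaled inverse-Wishart correlation prior is close to, but not
  identical to, an LKJ(2) prior; at the group counts involved (20–72) the
  likelihood dominates and the difference is immaterial for the reported
  effects.
* With `aat_grouping = "pooled_within_subject"`, condition effects
  contribute to a subject's IQR, making the fences slightly wider than
  per-cell fences; both conventions are available.
* The generator's ratings are deterministic given a pair's latent
  attraction; real ratings fluctuate across repetitions of the same
  avatar.
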