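---
title: "Modelling gaze allocation in dynamic scenes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gaze allocation in dynamic scenes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `gazescape`, the
assumptions and tunable parameters of each stage, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the problem left them open.

## The model

The response is binary: whether a 40 x 40 px grid cell (one of 32 x 18 = 576
covering the video) was fixated in a given frame. Because each frame has one
fixated and 575 non-fixated cells, using all cells would drown the positive
class; instead one control cell is drawn uniformly per frame (case-control
sampling), giving a balanced response. With z-standardized cell predictors,
the probit mixed model is

$$\Phi^{-1}\!\big(P(\text{fixated})\big) = \beta_0 + \beta_1\,\mathrm{centrality}
+ \beta_2\,\mathrm{saliency} + \beta_3\,\mathrm{ROI}
+ \beta_4\,\mathrm{saliency\times ROI}
+ \beta_5\,\mathrm{saliency\times valence}
+ u_{\text{participant}} + u_{\text{video}},$$

with crossed Gaussian random intercepts. Five nested models introduce the
fixed effects incrementally (centrality; +saliency; +ROI; +saliency x ROI;
+saliency x valence), so each predictor's contribution to explained variance
is bounded from below even under predictor correlation. Valence enters only
through its interaction in model 5; the incremental table lists no valence
main effect, and we follow that reading. Goodness of fit is
$R^2 = \mathrm{cor}(y, \hat p)^2$ using population-level predictions (random
effects at zero) — the conditional alternative is defensible but mixes
cluster information into a quantity meant to describe the fixed structure,
and we record this as a deliberate choice. Because estimates depend on the
random control draw, the entire procedure is repeated over control redraws
(100 at full scale) and summarized by means with empirical 2.5th/97.5th
percentile-rank intervals (the `m = p(n+1)` linear-interpolation quantile;
at modest redraw counts this form is calibration-correct where R's default
quantile is anti-conservative).

Estimation uses `stats::glm` (IRLS, probit, epsilon 1e-10, max 100
iterations) for fixed-effects-only fits and `lme4::glmer` with the bobyqa
optimizer and Laplace likelihood for the mixed models. Fits with
|beta| > 10 on standardized predictors are treated as separated and flagged
non-converged; rank-deficient columns are dropped and recorded. `nAGQ = 0`
(penalized least squares only) is available for bootstrap loops and is
flagged in the fit metadata; on balanced case-control data it agrees with
Laplace fixed effects to well under 1e-3 in our reference simulations.

## Predictor maps

**Low-level saliency** follows the graph-based scheme: per frame, feature
channels for intensity, a colour-opponent pair (LMS cone transform, L-M and
S-luminance axes), orientation (Gabor energy pooled over 4 orientations) and
flicker (absolute intensity difference to the previous frame; zero for the
first frame) are computed on a down-scaled lattice (default 32 x 24,
Gaussian falloff sigma = 0.15 x lattice width). Each channel map defines a
Markov chain with transition weights
$w(i,j) \propto |M(i)-M(j)|\,e^{-d(i,j)^2/2\sigma^2}$; its equilibrium
distribution is the activation. A second pass with weights
$\propto A(j)\,e^{-d^2/2\sigma^2}$ concentrates mass. Channels are combined
with equal weights and up-sampled. Two numerical points are worth noting:

* The first-pass weight matrix is symmetric, so the chain is reversible and
  its equilibrium is exactly the normalized degree vector — no iteration is
  needed, and the result is identical (to ~1e-13) to dense power iteration.
  The second pass is not symmetric and is solved by power iteration,
  accelerated by the Kronecker factorization of the distance kernel.
  The test suite keeps an independent dense-matrix solver as the oracle;
  note that on two-valued maps the dissimilarity graph is bipartite and a
  naive power iteration oscillates — the oracle therefore iterates the lazy
  chain, which has the same equilibrium.
* A constant channel map carries no contrast information; we define its
  activation as uniform and skip the concentration pass. This makes a
  uniform grey video produce exactly uniform saliency, which the raw
  second pass would violate through boundary-induced centre bias.

The combined stack is blurred along time (Gaussian, SD 2 frames, kernel
truncated at 4 SD and renormalized at the sequence edges) and then each
frame is divided by its mean, so the average saliency is exactly 1 — the
chance level for saliency-blind viewing. Whether blurring precedes or
follows normalization was an open choice; we blur first, then normalize, so
the mean-1 contract holds exactly on the final maps.

**Centrality** is $1/(1+d)$ with $d$ the pixel distance to the frame centre;
the +1 regularizes the singularity a pure inverse distance has at the
centre. **ROI masks** are unions of circular head regions, 1 on heads and 0
elsewhere. The analysis grid keeps the published 40 px cell size; under the
stated display geometry 40 px subtends about 1.2 degrees rather than the
quoted 2.5 degrees — the geometry utilities follow the trigonometry, the
grid follows the stated pixel size, and the discrepancy is simply noted.

## Gaze preprocessing

Parameters (defaults): baseline window 300 ms before onset; onset exclusion
150 ms (half-open: samples at exactly 150 ms are kept); re-entry band 3
sample SDs (n-1 denominator; with SD = 0 only values equal to the mean
re-enter); drift reference point = screen/video centre, so drift-free data
pass through unchanged. The recursion removes the current minimum and
maximum together before testing each against the remaining distribution,
and stops when both re-enter. Baselines are invalid when the window contains
a blink or the recursion discarded samples on either axis; invalid baselines
are replaced by the participant's mean valid baseline per axis. Frame
alignment averages the valid in-bounds samples inside each frame's
half-open interval (about 8-9 samples at 250 Hz / 30 fps); whether the
original analysis used one sample or an average per frame is unstated, and
averaging is our documented choice. Frames without valid samples are
excluded downstream.

## Case-control matrix and standardization

The observation matrix holds exactly two rows per labelled frame. Control
cells are drawn from an independent seeded stream per participant x video,
so redraws never touch fixated rows and every stage is reproducible from a
master seed. Predictors and the participant's own valence rating are
z-standardized over the emitted rows; the standardization population is
recomputed for every control redraw (the constants actually used are stored
alongside the matrix). Zero-variance predictors are flagged degenerate and
standardized to zero rather than propagating NaNs.

## Consistency analysis

Per-unit (participant x video) fits use plain probit GLMs: with a single
participant and video per fit, random intercepts are unidentifiable, so the
mixed-model form is dropped there on purpose. Non-converged units (including
separation) become missing entries, completed by predictive mean matching:
a linear model predicts the missing term's weight from the unit's other
observed terms plus the participant- and video-mean weights (falling back
to the means-only model when the whole unit is missing, the usual case);
the imputed value is drawn uniformly from the 5 observed entries with the
closest predictions, 5 imputed tables per redraw iteration. Weights are then
z-standardized within each video across participants — removing per-video
offsets exactly — and Cronbach's alpha treats videos as items and
participants as cases. Alpha is computed per completed table and summarized
across all tables (imputations x redraw iterations); computing alpha per
dataset and then summarizing, rather than pooling weights first, is our
choice. Note two derivations that shaped the tests: adding a constant to one
participant's profile is only *approximately* neutral (it perturbs each
video's scale estimate), whereas per-video shifts cancel exactly; and the
null distribution of alpha at 32 cases has spread ~0.29 driven by the
chi-square noise of the case-sum variance, so near-zero means rather than
tight per-draw bounds are the honest null check.

The ratings ICC is the two-way random-effects, absolute-agreement,
single-rater form (ICC(2,1)) with the standard F-based interval; the source
analysis does not name a form and this is the conventional choice for
raters-crossed-with-targets designs.

## Valence reclassification

All ordered integer threshold pairs (t1, t2), 1 <= t1 < t2 <= 8, are
enumerated; ratings <= t1 are negative, <= t2 neutral, else positive; the
pair minimizing the total pairwise category-size difference wins. Boundary
ratings fall left (<= convention) and ties break toward the a-priori pair
(3, 6), then lexicographically — both conventions are ours and are fixed so
results are deterministic.

## Physiology

Heart rate: instantaneous rate 60/RR bpm per interval; each one-second bin
averages the intervals overlapping it, weighted by overlap fraction (this
fractional-overlap reading of second-by-second sampling is our documented
choice). The last pre-stimulus second is the baseline and is subtracted
from the 20 stimulation seconds. EDA subtracts the value at trial start and
averages. R-peak detection (band-pass 5-35 Hz, squared derivative, adaptive
threshold relative to the trace's own amplitude distribution, 250 ms
refractory) replaces the original semi-automatic editing; peak times can
also be supplied directly.

## The synthetic-data generator

`make_study()` emulates the study conditions: 20 s clips at 30 fps with
moving tinted luminance blobs and skin-toned head discs (reflecting
boundaries, constant head radius), 250 Hz gaze, ratings on 1-9 scales, and
trial-locked physiology. Gaze is generated per frame as a draw from a
softmax over grid cells, with utilities combining the ground-truth weights
(defaults 0.3 centrality, 0.5 saliency, 0.5 ROI, -0.1 saliency x ROI,
mirroring the magnitudes typical of naturalistic-scene studies) with the
video's z-standardized grid predictors. Estimation uses case-control probit,
a different link, so generated and estimated weights agree in sign and
order, not numerically; recovery checks are therefore monotonicity and
confidence-interval coverage of zero effects, calibrated by Monte-Carlo
before the acceptance suite was fixed. Two consequences of the softmax link
deserve emphasis:

* Participant and video intercepts are constant across cells within a
  frame and cancel in the softmax, so the generator's random-intercept SDs
  do not move cell choices; mixed-model variance recovery is instead tested
  on directly generated binary data. Observer heterogeneity that *does*
  reach the data comes from stable per-participant offsets on the
  centrality/saliency/ROI weights (SD 0.15 by default) — exactly the
  individual differences the consistency analysis is built to detect.
* The control-redraw bootstrap sees only the control half of the sampling
  variance. Our pre-build calibration showed zero-effect CI coverage of
  ~83-87% at 10 redraws, rising toward the nominal 95% as redraws grow;
  recovery runs therefore use 50 redraws.

Gaze noise: jitter SD 5 px and drift SD 5 px at the reference width of
1280 px, scaled proportionally at reduced resolutions so the angular noise
is resolution-invariant. Baseline contamination is per-trial (probability
0.06 for displaced-outlier contamination, 0.03 for a blink run, 10% of
baseline samples affected within a contaminated trial), which reproduces a
replaced-baseline rate near the observed ~8% of trials; contaminating every
trial would leave no valid baseline to impute from. Rating noise SDs
(1.15 / 1.75 / 3.4 for valence / arousal / relevance, rater bias SD 0.5,
video means spread over [2, 8]) were pilot-calibrated once to reproduce
inter-rater ICCs of about 0.65 / 0.47 / 0.19 at 32 raters x 90 videos.
Physiology defaults: 70 bpm baseline, 5 bpm dip over stimulation seconds
2-7, EDA responses of 0.3 uS on a 5 uS tonic level.

What the generator does **not** emulate: saccade dynamics and fixation
durations (one cell per frame, no within-frame dynamics — the frame-level
simplification is our choice), photorealistic content, semantic or
object-level structure, auditory influence, smooth pursuit, or heart-rate
variability beyond the programmed dip. Passing tests therefore demonstrate
that the *machinery* — maps, preprocessing, sampling, estimation,
imputation, reliability — behaves correctly under known truth, not that the
substantive effect sizes transfer to real recordings.

## Problem sizes and runtime choices

The packaged analyses run at reduced scale: mini studies of 4 participants
x 6 videos x 120 frames at 160 x 90 px (the 32 x 18 grid is preserved by
keeping the width a multiple of 32), recovery studies of 8 x 10 x 120 at
64 x 36 px, 10-50 control redraws, and 5 imputations. These sizes were
chosen so the full suite runs comfortably on a single CPU while leaving
every statistical contract intact; all of them scale up by configuration
(`study_config`, `n_bootstrap`, `scene_spec`) to the full 32 x 90 x 600
layout. Recovery bootstrap loops use `nAGQ = 0`; single fits default to
Laplace.

## Known limitations

* Algorithmic, not bit-exact, parity with the original MATLAB saliency
  implementation (multi-scale pyramids are out of scope; one activation
  scale with the published lattice defaults).
* The case-control bootstrap quantifies control-sampling uncertainty only;
  its intervals are not full sampling-variance intervals (see the coverage
  discussion above). Relatedly, when gaze is generated with nonzero weights
  on predictors that are spatially correlated with a null predictor (heads
  are bright and salient, so ROI co-varies with saliency), the probit
  estimate of the null weight acquires a small link-mismatch bias (~0.03 in
  our recovery setup) that those narrow intervals do not absorb; coverage
  statements therefore refer to the all-zero-weight design.
* PMM's predictive model is linear with a small predictor set; with
  pathological missingness patterns (an entire participant or video
  missing) it degrades to mean-matching.
* The EDA model is a single fixed-shape response per trial; no SCR
  decomposition or tonic drift.
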