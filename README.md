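# gazescape

Modelling gaze allocation in dynamic naturalistic scenes.

When people freely view complex videos, where they look is shaped by several
competing cues: the tendency to fixate near the screen centre (central bias),
bottom-up conspicuity of image regions (low-level saliency), and socially
relevant content such as human heads. `gazescape` implements, as a tested and
reusable R pipeline, an analysis that disentangles these influences from raw
eye-tracking data and quantifies how stable each observer's cue preferences
are across a diverse stimulus set. It is aimed at visual-neuroscience and
social-attention researchers working with video stimuli and gaze recordings,
and at methodologists who want a fully synthetic, ground-truth-controlled
testbed for fixation-selection models.

## What it computes

**Predictor maps.** For every video frame the package builds three pixel-level
predictor maps: graph-based low-level saliency (intensity, colour-opponent,
orientation and flicker channels combined with equal weights, activated as
the equilibrium distribution of a Markov chain over the image lattice,
temporally blurred with a Gaussian of SD 2 frames and normalized to a
per-frame mean of 1), central bias `C(x, y) = 1 / (1 + d)` with `d` the
distance to the frame centre, and binary circular head-ROI masks.

**Gaze preprocessing.** Raw 250 Hz gaze streams are cleaned by excluding the
first 150 ms after stimulus onset, estimating a drift baseline from the last
300 ms of the pre-stimulus fixation (with a recursive outlier-removal
algorithm: the minimum and maximum are removed and re-entered only if within
3 SD of the remaining values, recursively), imputing invalid baselines from
the participant's valid trials, subtracting the drift, and collapsing samples
to one gaze point per frame.

**Fixation-selection models.** Maps are collapsed onto a 32 x 18 grid of
40 px cells. Each fixated cell is paired with one randomly drawn non-fixated
cell (case-control sampling, 575 candidates), predictors are z-standardized,
and the binary fixated/control response is modelled with probit regression:

    Phi^-1( P(fixated) ) = b0 + b1*centrality + b2*saliency + b3*ROI
                           + b4*saliency:ROI + b5*saliency:valence
                           + u_participant + u_video

with crossed random intercepts, fitted by Laplace maximum likelihood
(lme4, bobyqa). Five nested models add the predictors incrementally;
goodness of fit is the squared correlation between responses and fitted
probabilities (an R-squared analogue), and all estimates are averaged over
repeated control redraws with empirical 2.5/97.5 percentile intervals.

**Consistency and ancillary analyses.** Per participant x video probit fits
yield a weight table whose non-converged entries are completed by predictive
mean matching (5 imputations); weights are z-standardized within each video
and their internal consistency across videos is measured with Cronbach's
alpha. The package also computes the mean saliency at looked-at pixels
(chance reference 1), individualized reclassification of 1-9 valence ratings
into three balanced categories by exhaustive threshold search, intraclass
correlations of ratings (ICC(2,1), absolute agreement), and trial-level
autonomic summaries (second-by-second heart rate from R-peaks with
fractional-overlap weighting, baseline-corrected EDA means).

**Synthetic studies.** `make_study()` generates complete studies with known
ground truth — moving-blob scenes with head discs, gaze drawn from a softmax
over grid cells with configurable predictor weights, ratings with calibrated
inter-rater consistency, and stimulus-locked heart-rate decelerations and
skin-conductance responses — so every stage is testable without external
recordings.

## Worked example

```r
library(gazescape)

cfg <- study_config(n_participants = 4, n_videos = 6,
                    scene = scene_spec(width_px = 160, height_px = 90,
                                       n_frames = 120, n_blobs = 3,
                                       n_heads = 2),
                    n_bootstrap = 10)
study <- make_study(cfg, seed = 1)
res <- run_pipeline(study, seed = 2)
res
#> pipeline_result: 4 x 6 study, 5568 observation rows, 5 models, 10 bootstrap iterations
#>   mean looked-at saliency: 5.282
#>   R^2 by model: 0.125, 0.320, 0.335, 0.336, 0.337
```

The mean looked-at saliency (5.28) is well above 1, the value expected if
gaze ignored low-level saliency — the synthetic observers were generated
with a positive saliency weight. The R-squared sequence shows explained
variance rising as saliency and the social-ROI predictor join centrality
(0.13 to 0.32 to 0.34) and flattening for the interaction terms, mirroring
the incremental-model logic. `summary_table(res$bootstrap)` gives the full
per-model weight table with percentile intervals, `res$consistency$alpha`
the per-predictor Cronbach's alpha, `res$icc` the rating ICCs, and
`res$physio` per-trial heart-rate and EDA changes.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/gazescape.R run --seed 1 --out results_dir
```

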