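---
title: "Population coding of motion summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding of motion summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsumstats)
```

## The scientific problem

Head-fixed mice can be trained to categorize the *global mean direction* of
a random-dot kinematogram (RDK) as "left" or "right" of a learned vertical
boundary, even when the individual dots move in directions drawn uniformly
from a window as wide as 270 degrees around that mean. The question this
package addresses is how visual cortical populations support that ability:
do single neurons encode the ensemble mean direction (a summary statistic),
how does heterogeneity (the ensemble variance) change that code, and where
along the cortical hierarchy does the representation become categorical?

The experimental design behind the analyses: eight mean directions spaced
45 degrees apart (22.5 to 337.5, the four nearest the horizontal axis
forming the "right" category), crossed with a homogeneous condition (all
dots coherent) and one heterogeneous range (90, 180 or 270 degrees) per
session; 20 trials per cell, 320 trials per session, pseudo-randomized so
that consecutive trials never repeat both direction and variance; 4 s of
stimulus at 30 Hz calcium imaging, with choices reported by wheel turn
after the stimulus.

Because the raw recordings are not deposited, every analysis here is
validated against a synthetic-session generator with planted ground truth,
and can equally be applied to user data written in the same plain-text
session schema (`write_session()` / `read_session()`).

## The synthetic world

`simulate_session()` chains five generative stages, each exposed on its
own:

1. **Schedule** (`design_session()`): balanced, adjacency-constrained trial
   order drawn by constrained sequential sampling with restarts. The
   adjacency rule is read as a conjunction — consecutive trials may share a
   direction or a variance condition, but not both.
2. **Stimulus** (`sample_dot_directions()`): 500 i.i.d. uniform dot
   directions on mean ± range/2, wrapped to the circle, with draws exactly
   equal to the mean rejected and resampled (no dot ever carries the global
   mean itself; with quantized RNG output this makes the exclusion
   testable).
3. **Rates** (`simulate_trial_rates()`): four coding modes per neuron.
   `linear_sum` averages a von-Mises-shaped tuning bump
   `exp(kappa (cos d - 1))` over the individual dot directions — the
   local-motion null model. `sharpened_mean` evaluates the bump at the
   dots' circular mean with a per-range gain — global-mean coding, the
   alternative the population data support. `untuned` and `category`
   complete the repertoire for null calibrations and for modeling
   parietal-like category cells. The generative bump is a modeling choice
   (no generative form is prescribed by the experiment); a von Mises shape
   was chosen for smoothness with a single width parameter.
4. **Calcium** (`simulate_calcium()`): causal exponential kernel
   (GCaMP6f-like decay, 0.5 s default), slow sinusoidal drift, i.i.d.
   Gaussian frame noise.
5. **Behavior** (`simulate_choices()`): a cumulative-normal psychometric in
   the signed horizontal distance from the vertical boundary, with a lapse
   term. Defaults sigma = 30 degrees, lapse = 0.1 reproduce the observed
   ~80% overall accuracy regime.

### Why the default SNR is deliberately modest

The default tuning amplitude is 0.15 dF/F against 0.5 dF/F frame noise —
single-neuron, single-frame discriminability of neighboring directions
near d' = 0.2. Two reasons, fixed once and not revisited:

* It reproduces the weak-single-neuron / strong-population regime of real
  cortical imaging: only a minority of synthetic neurons pass the
  direction-selectivity criteria, yet population decoders recover the
  stimulus reliably.
* It keeps pairwise decoding accuracies off the ceiling. If every
  direction pair decodes at 100%, the neural dissimilarity matrix is flat
  and representational-similarity regression degenerates; worse, the
  saturating nonlinearity turns model mismatch into a small but perfectly
  consistent spurious loading on the (collinear) category model — a known
  hazard of this regression that the package's acceptance suite checks is
  absent at the chosen SNR.

What a green test on this world does **not** establish: robustness to
correlated (shared) trial-to-trial variability, to neuropil contamination
or segmentation errors, to non-exponential indicator dynamics, or to eye
and body movements — none of which are simulated. Dot positions and
lifetimes are also not simulated; only dot directions matter to every
analysis downstream of the stimulus.

## Preprocessing

`clean_traces()` subtracts the running 8th percentile within a centered
900-frame window (truncated at the edges — the window specification is
silent on edge handling) and smooths with a Savitzky–Golay filter (order 3,
length 11), implemented as a local polynomial projection so cubic segments
pass through unchanged, including at the trace edges. The running
percentile is computed exactly (sorted sliding buffer in C++), not on a
decimated grid.

`detect_events_and_qc()` estimates each neuron's noise from its negative
excursions (negatives pooled with their absolute values; threshold =
3 x IQR of the pool, linear-interpolation quantiles so thresholds are
bit-reproducible), zeroes sub-threshold samples, and drops neurons whose
count of negative events exceeds 5% of their positive events. An *event*
is a maximal run of consecutive supra-threshold frames — the counting unit
had to be fixed here; a run-based definition makes the 5% rule invariant
to frame rate. Traces with no negative samples get threshold 0 and a flag
rather than an error.

## Single-neuron analyses

Tuning curves are stimulus-window AUCs: the trial-averaged 0–4 s signal's
mean times the window duration (equivalent up to a constant to trapezoidal
integration). The direction selectivity index is
`DSI = (R_pref - R_antipref) / R_pref`, and the tuning-curve *slope*
averages the zero-centered curve's equidistant offset pairs (±45, ±90,
±135) and fits an ordinary least-squares line over the five points from
-180 to 0. A neuron is direction-selective when `DSI > 0.4` **and** its
slope exceeds the 95th percentile of slopes from direction-label-shuffled
surrogates (label shuffles within condition preserve per-direction trial
counts). Argmax ties break toward the numerically smallest direction, with
a flag.

`simulate_het_tuning()` asks what heterogeneous-condition tuning *should*
look like if neurons merely summed local motions: each
homogeneous-condition curve is averaged over a uniform direction window of
the session's range, resampled populations are aligned on their peaks and
averaged, 1000 times. The window average is computed by attenuating the
curve's circular harmonics — harmonic n is multiplied by
`sinc(n * range / 2)` — which is exact for band-limited curves. (A
piecewise-linear interpolation of the 8 samples was considered and
rejected: the chords of a cosine sampled at 45 degrees attenuate the
range-180 window average to 0.604 instead of the analytic 2/pi = 0.637, a
5% bias with no offsetting benefit.) For cosine tuning this reproduces the
analytic attenuation factors exactly: 2/pi at 180 degrees, 0 at 360.

The peak confusion matrix tracks whether neurons keep their preferred
direction across conditions: cell (i, j) is the proportion of all recorded
neurons peaking at direction i under heterogeneity and j under coherence,
tested against label-shuffled surrogates with Benjamini–Hochberg
correction over the 64 cells. One caution established while testing: the
surrogate shares a single shuffle across neurons, so populations of
near-duplicate neurons (noiseless simulations) make the null lumpy and
conservative; with realistic independent trial noise the null spreads and
the test behaves nominally.

## Population response curves and categorical bias

The PRC fixes the presented direction and reads activity across neurons
grouped by preferred direction (determined per condition from the 4-s
window), re-indexed by the wrapped offset preferred-minus-presented and
averaged over trials and directions — group-then-average, neurons within a
preference bin first. Its slope per time bin uses the same
averaged-offset-pairs OLS as single-neuron slopes; correct trials only by
default (task sessions), with a flag for passive data. The bottom-percent
analysis re-derives the preference map *within* each subset of neurons
ranked by how their tuning slope compares to its own shuffle null, and
refuses subsets of fewer than 8 neurons (they cannot tile the offsets).

Categorical bias fits the stimulus-window-averaged PRC, re-anchored to
absolute direction, with a wrapped normal
`amplitude * sum_k exp(-(theta - mu + 360k)^2 / (2 sigma^2)) + offset`,
truncated at |k| <= 3 (terms beyond that are negligible for sigma <= 90).
Amplitude and offset are profiled out linearly at each (mu, log sigma)
evaluated by Nelder–Mead from three width starts; mu is initialized at the
empirical argmax and optimized on the circle, so wrap-adjacent peaks are
recovered without aliasing. The experiment's bare density has no scale or
baseline; both were added because PRCs do — only mu feeds downstream, so
the choice is benign. The signed bias maps mu minus the presented
direction so that displacement toward the nearest horizontal category
center (0 for right, 180 for left) is positive; at the 8 sample directions
the nearest center is always unambiguous. Group summaries apply Tukey
1.5 x IQR fences per condition before t-tests with FDR correction.

## Decoding

The inverted encoding model uses eight channel basis functions
`cos(d/2)^6` at the canonical directions. Two numerical facts drive the
implementation: the basis tiles the circle (channel sum constant to 1e-6),
and — since `cos^6` contains only circular harmonics 0–3 — the eight
channel profiles span a 7-dimensional space, so the normal-equation
matrices `C1 C1'` and `W'W` are *exactly* singular. Both inverses are
therefore Moore–Penrose pseudoinverses (SVD, relative tolerance 1e-10);
every basis response vector lies in the 7-dimensional span, so the
algebraic round trip `invert(fit(W C)) = C` still holds to machine
precision. Homogeneous trials are decoded leave-one-trial-out per time
bin; heterogeneous trials with the homogeneous-trained weights. The
channel-tuning-function slope sign-reverses offsets +45/+90/+135 and fits
OLS across the resulting eight points (keeping the duplicated points, as
specified for this analysis — unlike the PRC slope, which averages pairs
into five points; both conventions are retained deliberately).

No SVM implementation ships with the analysis environment, so the package
carries a minimal linear SVM: L2-regularized squared hinge with
inverse-class-frequency weights, standardized features, solved by BFGS —
convex and smooth, so the optimizer is reliable at these sizes. Variance
(hom vs het) is decoded leave-one-trial-out; category left-vs-right
likewise, with heterogeneous transfer. Within- vs between-category
discrimination uses the four 90-degrees-apart direction pairs on each side
of the boundary (pairs are specified as absolute directions, which
sidesteps an index-origin ambiguity in pair lists), with repeated
stratified 5-fold cross-validation (100 random partitions by default) and
heterogeneous transfer. Temporal generalization trains each decoder at one
bin and tests at all bins; its diagonal reproduces the corresponding
transfer time course exactly.

## Representational similarity analysis

Per time bin, shrinkage-LDA classifiers decode all 120 pairs of the 16
stimulus conditions (8 directions x hom/het) from pseudo-trials: trials
split into four order-stratified chunks (balancing slow drift), each
pseudo-trial the average of a random 25% of a chunk, 500 per condition and
chunk by default. Covariance shrinkage toward a scaled identity engages
when features approach the per-fold sample count, and is flagged. The
resulting 16 x 16 accuracy matrix (higher = more dissimilar) is regressed
on three z-scored model RDMs — mean direction (one minus cosine similarity
of channel-basis response vectors; the metric had to be fixed here, and
1 - Pearson gives the same ordering), variance (binary same/different) and
category (binary side-of-boundary) — using only off-diagonal upper-triangle
entries. The mean and category models are collinear by construction;
the regression separates them only when the neural RDM carries graded
direction structure, which is why the default SNR matters (above).

## Inference

Time-resolved group statistics use cluster-mass permutation tests:
bin-wise t-tests at a two-tailed p < 0.05 cluster-forming threshold,
cluster statistic = summed t (mass; cluster *extent* is deliberately not
the default — where both appear in the source protocols, mass is the
stated statistic), null = maximum absolute cluster mass over sign-flip
permutations, add-one p-values so p is never zero, positive and negative
clusters handled separately, 5000 permutations and FWER alpha = 0.05 by
default. The 2-D variant uses 4-connectivity on the train x test grid and
reduces exactly to the 1-D test on one-bin-thick maps. Calibration is part
of the acceptance suite: on pure-null data (10 subjects x 100 bins, 200
datasets, 500 permutations) the family-wise false-positive rate stays
within two binomial standard errors of the nominal 0.05.

## Scaling, determinism, limitations

* Defaults mirror the experimental design (20 trials per cell, 500 dots,
  30 Hz, 5000 permutations, 500 pseudo-trials, 100 CV repetitions). The
  test and acceptance suites run the same machinery on desk-scale sessions
  (tens of neurons, 5 trials per cell, 5 Hz, coarser bins, fewer
  permutations) so everything completes on one CPU in about a minute;
  calibration studies keep their stated designs (dataset counts,
  permutation counts, subject counts).
* All randomness flows through R's global RNG; `simulate_session()` and
  `run_full_analysis()` take explicit seeds, and the pipeline derives
  per-stage seeds from the master seed so stages are independently
  reproducible. Rerunning with the same seed reproduces output files
  hash-for-hash.
* Known limitations: no shared (correlated) variability in the generator;
  the wrapped-normal fit assumes a unimodal PRC; the IEM's pseudoinverse
  makes channel estimates minimum-norm, so reconstructions from
  structureless data are flat rather than undefined; the SVM's
  regularization constant is exposed but fixed at 1 by default (the
  original fitting routine's setting is unknown); linear mixed-effects
  modeling of d' is out of scope — `summarize_behavior()` exports the
  per-condition d' table for external tools.
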