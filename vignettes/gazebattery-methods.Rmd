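---
title: "Methods: event detection and task measures for 30 Hz webcam gaze data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event detection and task measures for 30 Hz webcam gaze data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazebattery)
```

## Scope and problem setting

Webcam-based eye tracking estimates gaze from ordinary video at roughly
30 Hz, with spatial noise one to two orders of magnitude above laboratory
eye trackers. At that sampling rate the standard velocity- and
acceleration-threshold event classifiers are unreliable, so this package
implements detection and scoring methods designed for low-rate, noisy gaze
prediction time series:

* a spatio-temporal density clustering rule for fixations,
* changepoint segmentation (exact-K dynamic programming and linearly
  penalized optimal partitioning) for smooth-pursuit onset/offset and for
  blink onsets/offsets in eye-aspect-ratio (EAR) or blink-probability
  series,
* the five-task behavioral battery measures (fixation accuracy/precision,
  zone classification, free-viewing statistics, pursuit angle and timing,
  cued-blink counts and latencies),
* saliency-map comparison indices (AUC, CC, SIM), and
* hierarchical 20% winsorized aggregation with cross-task score
  transformation.

Because the pipeline's inputs are normally private participant videos run
through trained deep-learning gaze models, the package ships a first-class
synthetic battery simulator. Every stage of the pipeline is validated
against traces whose ground truth the simulator knows exactly.

## Geometry and conventions

All stimuli live in a fixed frame-unit (FU) coordinate system with
54.05 FU per degree of visual angle and a 1600 x 900 FU (29.6 x 16.65 deg)
window. Screen coordinates are top-left-origin with y pointing down, which
is convenient for stimulus placement but wrong for angle arithmetic; all
angle computations therefore happen in a centered analysis frame (origin at
the window center, y up, angles counterclockwise from +x in [0, 360)), with
explicit conversion functions in both directions. Timestamps map to frame
indices by `round((t - t0) * fps)` with half-up rounding — a deterministic,
order-preserving choice.

Two conventions the robust statistics depend on are fixed explicitly
because several incompatible definitions circulate:

* **Winsorized mean (20%)** clips at the 10th and 90th percentiles computed
  with linear interpolation between order statistics
  (`quantile(type = 7)`), then averages. Groups smaller than 3 fall back to
  the plain mean.
* **RMS vs STD precision** both use the population (divide-by-n)
  convention: RMS is the root mean squared Euclidean distance between
  *consecutive* samples, STD the root mean squared distance from the window
  mean. For white noise the ratio RMS/STD converges to sqrt(2), a closed
  form the test suite checks at n = 10,000.

## The synthetic battery

`make_trial()` reproduces the five task parameterizations: 13 fixation
targets (center plus three eccentricity rings of four, spanning
-11.1..11.1 deg by -6.2..6.2 deg) at 2500 ms per location; a non-visible
4 x 4 zone grid (cells 7.4 x 4.16 deg) visited once each for 1500 ms with
200 ms gaps; step-ramp pursuit (initiation delay exponential with mean
0.5 s plus a 0.2 s offset, truncated at 5 s before the offset is added;
15 deg/s along one of 12 evenly spread directions, starting 3 deg before
the center and ending 8.3 deg past it); seven auditory blink cues at
1.4 +- 0.2 s intervals; and a 3 s free-viewing display whose ground truth
is a mixture of Gaussian saliency hotspots.

`simulate_gaze_trace()` composes three layers:

1. **Ideal oculomotor response.** Fixation and zone trials hold the
   previous target until 200 ms after each onset (saccade latency) and then
   step; pursuit starts 250 ms after target motion onset at gain 0.9;
   free viewing samples fixation targets from the hotspot mixture with
   dwell times of 200-400 ms. These defaults sit near typical human values
   so recovery tests run under realistic dynamics; they are parameters of
   `oculomotor_params()`, not constants.
2. **Model noise.** Each gaze model is summarized by a `noise_profile()`:
   an accuracy bias magnitude (direction drawn once per participant),
   AR(1) Gaussian sample noise, and a dropout probability for
   face-detection failures. The AR(1) structure is essential: the
   benchmarked models report *independently measured* RMS and STD, and for
   the most precise model RMS < STD, which white noise cannot produce. With
   stationary radial dispersion STD, the implied sample-to-sample RMS is
   `STD * sqrt(2 * (1 - rho))`, so rho is solved from the printed RMS/STD
   pair per preset (MPIIGaze 3.70/2.96/2.33 deg bias/STD/RMS, ETHXGaze
   3.40/2.39/1.80, FAZE 2.44/1.63/0.47 — rho 0.69, 0.72, 0.96).
3. **Dropouts**, flagged invalid with `NA` coordinates; detectors either
   skip or interpolate over them.

One consequence worth knowing: with rho = 0.96 the noise decorrelates over
~0.8 s, so the dispersion measured *within* a 2.5 s fixation window sits
below the marginal STD (the acceptance report's simulated FAZE window STD
is ~1.1 deg against the 1.63 deg marginal). The presets are calibrated to
the marginal statistics, which is what the large-sample invariance tests
check; window-level dispersion is an emergent property of the correlation
time.

The blink simulator emits an EAR-style dip (baseline 0.3 to floor 0.05) or
a probability-style pulse per cue, with asymmetric lid kinematics — fast
closure over the first third of the 300 ms blink, slower reopening — plus
Gaussian noise. Ground-truth event frames are defined as the first frame of
the new regime (the ceiling of the event time), matching the convention the
detectors use to convert breakpoints to frames.

## Event detection

**Fixations.** Two valid samples are neighbors iff they are within `eps`
degrees *and* at most six frames (~200 ms) apart; fixation clusters are
connected components with at least two members, summarized by centroids.
`eps` defaults to half the model's measured RMS (1.13, 0.89, 0.26 deg for
the three presets). The neighbor-graph realization (a spatio-temporal
DBSCAN variant) is this package's concrete reading of "density-based
clustering with spatial and temporal thresholds"; only the thresholds, not
the exact rule, are pinned down by the method's description.

**Changepoints.** Both engines minimize the within-segment squared
deviation from the segment mean (summed over coordinates for multivariate
series), the standard L2 segmentation cost. `changepoints_exact_k()` finds
the globally optimal K-breakpoint segmentation by dynamic programming with
a minimum segment length of 3; `changepoints_penalized()` performs optimal
partitioning with a linear penalty per breakpoint, defaulting to
`3 * sigma^2 * log(n)` with sigma estimated robustly from the differenced
series (`mad(diff(x)) / sqrt(2)`). Ties are broken toward the
lexicographically smallest breakpoint tuple, making every result
deterministic. Both engines are verified against exhaustive search on
hundreds of short random series — they are exact algorithms, so agreement
is required to be perfect, not approximate.

**Smooth pursuit.** Within the interval from trial initiation to target
stop, each coordinate is smoothed with a Savitzky-Golay filter (order 1,
window n/3, reduced to the nearest odd length), first-differenced to a 2-D
velocity series, and segmented with K = 2. The derivative is kept as a 2-D
vector rather than collapsed to speed so that direction changes remain
visible to the cost. Known limitation: the n/3 window scales with the
self-paced initiation delay while the movement itself lasts only ~23 frames
(0.75 s at 30 Hz). Once the delay exceeds roughly 0.9 s the smoothing
window exceeds the movement, the two velocity transitions merge into a
single bump, and breakpoints shift early by up to ~10 frames even on
noiseless data — a property of the prescribed method, not of its
implementation. Validation therefore uses a canonical step-ramp trial with
a 0.4 s delay, inside the method's operating regime; with FAZE-preset noise
the median absolute onset error over 100 replicates is 2 frames, while over
trials with fully random exponential delays it is ~3.5 frames.

An all-static trace still yields the tie-break segmentation; callers get a
`low_velocity` quality flag instead of an error.

**Blinks.** Penalized segmentation proposes candidate changepoints; a
changepoint survives only if a local extremum of the right polarity,
beyond the running median by 3 MADs, lies within +-6 frames (the symmetric
reading of the verification window); survivors are clustered by
single-linkage agglomeration with a 25-frame threshold — on sorted 1-D
indices this is exactly "split at gaps > 25", which the tests cross-check
against `hclust`. Clusters of two or more changepoints become blinks
(earliest member = onset, latest = offset); singletons are discarded since
no duration is definable. The prominence rule (median +- 3 MAD) is this
package's own concretization of "a peak".

**Angle estimation** smooths with window n/2, regresses x and y separately
on time, and takes `atan2(slope_y, slope_x)` — well-defined for vertical
motion, where regressing y on x would degenerate.

## Measures and aggregation

Per-presentation gaze is summarized by coordinate-wise medians; zone cells
are half-open (left/top edges inclusive, boundary points go right/down) and
out-of-window medians clamp to edge cells. Grid coarsening to 2 x 2, 2 x 1
or 1 x 2 relabels by spatial containment, so correct classifications can
never become incorrect and accuracy is monotone nondecreasing — and because
vertical gaze noise dominates in webcam models, the column split (2 x 1)
systematically beats the row split (1 x 2), which the property tests
reproduce with anisotropic noise. Free-viewing trials discard the first
cluster (initial center fixation); gaze entropy is Shannon entropy of
fixation counts over a bin grid, normalized by `log(#bins)` to [0, 1]. The
bin grid defaults to the 4 x 4 zone grid; the entropy definition is a
package decision (the method literature leaves it open), so simulated
entropy values are comparable within this package but not directly to
other implementations.

Heatmaps convolve an isotropic Gaussian (sigma = 1 deg, the approximate
foveal radius) over fixation centroids on a 0.25 deg/cell grid (four cells
per sigma keeps the sampling accurate); mass outside the window is
truncated. AUC is the fixation-thresholded (Judd-style) variant with tie
averaging — a constant map scores exactly 0.5 and fixations on a unique
maximum score 1 up to single-cell FPR granularity. CC is the Pearson
correlation over cells; SIM is the histogram intersection after sum-1
normalization.

Aggregation applies the winsorized mean level by level (locations, then
trials, then participants), returning intermediates for inspection.
Cross-task score transformation log-transforms fixation accuracy and
angular deviation, inverts [0, 1] scores as `1 - value` (keeping them
positive, unlike negation), and z-scores each task over participants with a
guarded zero-variance branch; after transformation lower is uniformly
better.

## Validation design and what it does (not) show

All validation is parameter recovery on synthetic sessions: zero-noise
sessions must attain every ideal (accuracy 0, RMS/STD 0, zone accuracy 1
with an identity confusion matrix, blink count 7, angular deviation 0), and
noisy sessions must recover injected events within stated tolerances
(blink recall >= 95% with <= 5% spurious events over 200 trials; onset
errors of 1-2 frames). Problem sizes — 10 trials per simulated session,
100-200 replicates per recovery experiment, n = 10,000 for closed-form
checks — were chosen as the smallest sizes at which the binomial/sampling
tolerances above are meaningful.

The simulator emulates sampling rate, model noise structure, systematic
bias, dropouts and oculomotor latencies, but not microsaccades, drift
during "stationary" fixation beyond the AR(1) process, pupil dynamics,
smooth-pursuit catch-up saccades, or non-stationary model failure modes
(e.g. head pose excursions). Passing recovery tests therefore demonstrates
the correctness of the algorithms under the stated noise model, not
performance on arbitrary real recordings. Two deliberate test-condition
choices: the saliency discrimination experiment (gaze simulated from map A
must prefer map A over an independent map B) runs with the systematic bias
set to zero, since at single-trial scale a 2.4 deg bias displaces the whole
scanpath and the experiment would measure the bias rather than the metric
chain — in multi-participant studies random bias directions average out;
and the simulated FAZE angular deviation comes out near 7-8 deg, dominated
by AR(1) drift over the short movement window, closely matching what the
corresponding real-data benchmark reports for that model.

## Numerical choices

Fractional Savitzky-Golay windows floor to the largest odd integer not
exceeding the request (minimum 3, maximum the largest odd <= n), with
one-sided polynomial fits at the boundaries. Changepoint costs are computed
from cumulative sums in O(1) per segment; degenerate inputs (too-short
series, empty groups, all-invalid traces, zero-variance z-scores,
constant maps) either return documented neutral values or raise errors
naming the problem. All generation and detection is deterministic given
seeds; the command-line chain is byte-for-byte reproducible, which the
acceptance checks verify by diffing full output directories.
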