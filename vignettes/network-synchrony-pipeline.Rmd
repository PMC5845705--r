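---
title: "Analyzing emerging network synchrony from paired calcium imaging and MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing emerging network synchrony from paired calcium imaging and MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmea)
```

## The problem

Developing neuronal cultures self-organize from independently firing
cells into networks with population-wide synchronous events: brief,
network-spanning bursts of activity separated by quiescence. Two
complementary recordings capture this process — fluorescence calcium
imaging (2 Hz frame rate, single-cell spatial resolution, slow indicator
kinetics) and extracellular microelectrode arrays (MEA; tens of kHz,
millisecond resolution, no single-cell identity). `calmea` implements
the full analysis chain for such paired recordings: soma segmentation and
tracking, trace extraction and quality control, spike detection, network
activity traces, peak-prominence event statistics, pharmacological
response quantification, and an operational classification of each
recording as synchronous, loosely synchronous or asynchronous.

Because raw recordings of this kind are rarely shareable, the package
includes a first-class synthetic-data generator producing paired movies
and voltage recordings with complete ground truth (cell positions, event
schedules, spike times, per-cell pharmacological response classes). Every
pipeline stage is tested against that ground truth.

## The imaging half

**Segmentation.** Reference images are means of 50 consecutive frames
(non-overlapping blocks by default; one segmentation per 25 s at 2 Hz),
min-max scaled to [0, 1] (a constant image maps to zeros). Foreground
(cell) markers come from a morphological sequence: an opening with a
soma-scale disc (radius 6 px by default — the structuring element is not
identifiable from the data, so it is exposed as a parameter), the
top-hat residual, an erosion with a radius-2 disc, regional maxima, and a
3×3 erosion–dilation cleanup of the maxima mask. Two details deserve
mention:

* Regional maxima are restricted to pixels above `marker_min_height`
  (default 0.1 of the scaled range). Without a height floor, every noise
  ripple in the background is a regional maximum; the floor interprets
  the thresholding of "high-intensity objects" that the marker pipeline
  presumes.
* For a smooth blob the regional maximum is a single pixel, which a 3×3
  opening would annihilate. A maxima component that the cleanup removes
  entirely is therefore kept unchanged — it is already below the cleanup
  scale, so there is nothing to clean.

Background markers: foreground pixels are flattened to the image median,
the image is Otsu-binarized, and the watershed ridge lines of the
Euclidean distance transform (flooded from the cell bodies) become
background markers, dilated by a radius-2 disc; overlap is removed from
the foreground so the marker sets never touch. The final watershed floods
the Sobel gradient magnitude `sqrt(gx^2 + gy^2)` with minima imposed at
both marker sets (Meyer flooding, 8-connectivity, FIFO tie-break); the
basin grown from the background and the watershed lines are background
(label 0), every other basin is one cell. Filters use replicate padding
at the image border. Centroids are unweighted pixel means in 0-based
(row, column) coordinates.

**Tracking.** Step-to-step linking minimizes summed centroid distance
under gating: pairs farther than 20 px cost 5000, any track or detection
may stay unmatched at cost 500, and the assignment is solved exactly
with the Hungarian algorithm on the standard augmented matrix (so a pair
is matched only when its distance beats 1000, the cost of leaving both
unmatched). Costs are raw Euclidean distances in pixels. The solver
first decomposes the problem over connected components of usable edges
(an edge costing at least twice the non-assignment cost can never be
matched), which keeps dense fields fast without changing the optimum.
Tracks must reach age 20 steps and visibility 0.5 to survive filtering.

**Traces.** Per original frame (full 2-Hz resolution), a track's trace is
the mean intensity over its region from the owning segmentation step;
invisible steps reuse the last known region. Traces are min-max
normalized, so 1 is the cell's maximum over the recording and values are
fractions of the fluorescence saturation level.

**Quality control.** Two filters: (1) traces whose 0.0013–0.02 Hz
band-passed version exceeds sd 0.05 are removed as noisy; (2) traces
rising less than 10% of the normalized range during the high-potassium
epoch (mean during the epoch minus the pre-epoch median) are removed as
inactive or non-neuronal. The in-band sd is evaluated on the drug-free
baseline epoch by default (`trace_params(qc_scope = "full")` restores
the whole-trace variant). The reasoning: the filter is meant to remove
recording noise, which is stationary, while treatment responses are the
very signal later analyses quantify — a 3-minute depolarization bump of
0.4 of max contributes roughly 0.08 in-band sd and would otherwise
remove exactly the strongly-responding neurons that downstream analyses
must keep, which is incompatible with near-complete retention on clean
recordings.

## The MEA half

Raw voltage is median-referenced (the across-electrode median at each
sample is subtracted, which removes any common-mode artifact exactly) and
band-pass filtered 200–3000 Hz with a zero-phase order-3 Butterworth
filter. Spikes are detected in 30-s windows with 80% overlap: per
window, the noise scale is `median(|x|) / 0.6745` (the robust Gaussian
estimate; the plain median is available via
`mea_params(threshold_rule = "median")`) and excursions of either
polarity beyond five times that scale yield one spike at the excursion
extremum. Overlapping-window duplicates are merged keeping the first
detection within the 1.5-ms per-electrode dead time, and each spike
carries a cutout from 1 ms before to 2.2 ms after its extremum.
Summaries: a per-electrode rate raster (2-s bins, white-to-black
grayscale saturating at 0.5 Hz) and a combined network rate over all
non-reference electrodes (10-s windows stepping 2 s), min-max normalized
before peak detection because the prominence criterion (0.05) is
unitless while the rate is in Hz.

## Activity peaks and pharmacology

`find_peaks()` detects local maxima (plateau centres; signal endpoints
are not peaks) and computes topographic prominence — height above the
higher of the two flanking minima separating the peak from higher
terrain, with the signal edges acting as terrain ends. The network
criterion is prominence 0.025 on the normalized network trace (the sum
of band-passed 0.005–0.2 Hz, per-trace-normalized traces, normalized
again); the same criterion applies to single-cell traces. Width is full
width at half prominence, linearly interpolated.

Per-epoch metrics compare median peak prominence and median inter-peak
interval between an application epoch and baseline (change, and change
divided by baseline; a zero or absent baseline yields a flagged `NA`
rather than an infinity). For the slow-acting gap-junction blocker CBX
only the final 3 minutes of the application window are analyzed. The
per-cell excitatory GABA score low-pass filters the trace at 0.024 Hz
and subtracts the baseline-epoch sum from the GABA-epoch sum; because
epochs can differ in length, each sum defaults to the per-sample mean
times a 180-s reference duration (raw sums via
`duration_normalize = FALSE`). Distributions are reported as histograms
(prominence bin 0.005, interval bin 1 s, change bin 5%) in percent of
neurons, with cumulative or reverse-cumulative sums ending (or starting)
at exactly 100%.

Paired comparisons use the two-tailed Wilcoxon signed-rank test (zero
differences dropped, exact null up to 25 nonzero pairs, normal
approximation above) and Pearson correlation with the t-based two-tailed
p-value; no multiple-testing correction is applied, so reported p-values
are raw.

## Classifying the activity pattern

The published patterns were identified visually; `classify_network()`
operationalizes them and always reports its three diagnostics next to
the label so the rule is auditable:

* **asynchronous** — fewer than 2 network peaks per 5 minutes, or mean
  event participation below 0.2;
* **synchronous** — participation at or above 0.5 *and* in-event /
  out-of-event activity ratio at or above 3;
* **loosely synchronous** — otherwise; fewer than 10 traces gives
  "undetermined".

Participation at a network peak is the fraction of cells with a
single-cell activity peak within ±5 s. The activity ratio uses the raw
normalized trace above its per-cell median (not the band-passed signal,
whose high-pass rebound rings for hundreds of seconds after each event
and would contaminate the "quiet" intervals), with a guard band of twice
the event half-width excluded from the out-of-event side so indicator
decay tails do not count as between-event activity.

## What the generator emulates

`synthetic_ground_truth()` + `render_calcium_movie()` /
`render_mea_recording()` produce paired recordings with:

* network events as a renewal process — intervals uniform on 0.54–1.46
  times the mean interval, so the default 0.03 Hz rate gives intervals
  spanning roughly 18–49 s;
* per-cell participation 0.8 with ±0.5 s jitter (synchronous),
  plus/only independent Poisson events (loosely synchronous /
  asynchronous);
* calcium transients with a 1-s linear rise and 4-s exponential decay
  (network peak widths then land on the several-second scale typical of
  population calcium signals); per-event amplitudes are drawn skewed
  (`0.05 + 0.85 * U^6` of the saturation level), so most transients are
  small relative to the largest one that sets each trace's normalization
  maximum — the amplitude statistics that make near-complete QC
  retention possible at all, since the in-band QC sd of a normalized
  event train scales with the typical-to-maximum amplitude ratio;
* four GABA response classes (strongly depolarized +0.4, weakly +0.15,
  none 0, inhibited −0.1 of max, with participation multipliers 0.5 /
  1 / 1 / 0 during the epoch) in proportions 5 / 25 / 40 / 30% by
  default;
* a sustained +0.3-of-max rise during the K⁺ epoch for every neuron
  (blobs flagged non-neuronal lack it, exercising the viability
  filter);
* somata as 2-D Gaussians (sigma = radius/2, radius 4 px at the
  emulated 10× magnification) with per-cell brightness 35–65 counts on
  a 100-count background with i.i.d. Gaussian pixel noise (sd 2); no
  photobleaching or optics model;
* extracellular spikes as a biphasic 1-ms template (amplitude 10× the
  noise sd by default) dense around network events and sparse Poisson
  background elsewhere, at 10 kHz by default (50 kHz supported but
  slow), with an optional common-mode waveform added identically to all
  60 electrodes (one reference).

The default full recording is a 20-minute drug-free baseline, a 30-s K⁺
application, and a 2-minute recorded washout (recordings should not end
on the elevated K⁺ plateau — a trace that ends high leaks strongly into
the 0.0013-Hz end of the QC band). The pharmacological series
(`protocol_full_series()`) applies GABA 100 µM, bicuculline 10 µM,
carbenoxolone 25 µM, glutamate 30 µM and KCl 5 mM in order with 3-min
washouts.

What the generator does *not* emulate: overlapping or migrating somata
(drift is piecewise-constant per block), neurites, photobleaching,
indicator saturation dynamics, bursting structure within events,
electrode-specific gain or correlated noise, and any biophysical
receptor mechanism — response classes are phenomenological amplitudes
only. Passing tests therefore demonstrate correctness of the analysis
chain on data matching its assumptions, not robustness to every
pathology of real recordings.

## Numerical choices

* All trace filters are zero-phase (forward-backward) Butterworth,
  order 2 per pass (order 3 for the MEA band-pass); signals are
  mirror-padded (odd reflection, up to six cycles of the lowest cutoff)
  to suppress edge transients. Coefficients come from `signal::butter`;
  the filtering pass itself runs in compiled code and is tested against
  `signal::filtfilt` to near machine precision.
* Min-max normalization maps a constant input to zeros everywhere the
  degenerate case can occur (preprocessing, traces, network trace).
* The watershed flood orders pixels by height with FIFO tie-break;
  pixels where two basins meet become watershed lines (label 0), as do
  pixels unreachable from any marker.
* Wilcoxon zero differences are dropped before testing; all-zero
  differences yield a flagged undefined p.
* An epoch without peaks yields flagged `NA` metrics, never an
  infinity; relative change is undefined when the baseline metric is 0.

## Problem sizes used in verification

The test-suite and acceptance benchmarks run at sizes chosen to exercise
the full pipeline while staying desk-scale: QC retention uses twenty
200-cell recordings (192×192 px, 22.5 min at 2 Hz); spike-detector
recovery uses 60 electrodes × 300 s at 10 kHz; segmentation and tracking
recovery use 50-cell fields, the latter over 40 segmentation steps with
up to 5 px/step drift; interval recovery uses twenty 50-cell,
10-minute trace sets. The published per-week ROI counts and
network-pattern counts ship as plain-text tables and are summed —
not re-derived — by the report module.

## Known limitations

* Under the default generator conditions roughly 1% of cells draw
  per-event amplitude sequences whose true in-band (0.0013-0.02 Hz) sd
  sits marginally above the 0.05 QC threshold, so an occasional
  recording retains 97-99% of traces rather than the typical 99-100%;
  the QC benchmark reports the minimum across twenty recordings and
  inherits that tail.
* The operational classifier is calibrated on the generator's three
  modes; real recordings near the synchronous/loose boundary will be
  sensitive to its thresholds (all exposed in `classify_params()`).
* Segmentation assumes non-overlapping, roughly circular somata; there
  is no merge/split handling in tracking and no motion model beyond
  nearest-centroid gating.
* The spike detector does not sort units; electrodes record multi-unit
  activity.
* Absolute biological quantities from the original study (event rates,
  peak widths, correlation coefficients of specific cultures) derive
  from recordings that are not available; the package verifies its
  arithmetic and its recovery of known synthetic ground truth instead.

## A worked five-minute example

```{r example, eval = FALSE}
sim <- simulate_network_recording(seed = 1, n_cells = 50)
res <- analyze_movie(sim$movie)
nt <- network_trace(res$traces)
peaks <- find_peaks(as.numeric(nt), 0.025, frame_interval_s = 0.5)
classify_network(res$traces, peaks)
```

The `analysis/` directory contains the numbered scripts that run the
cohort-scale version of this workflow and write the report tables under
`results/`.
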