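---
title: "Spatio-temporal mapping of intestinal motility: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal mapping of intestinal motility: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmapr)
```

# The measurement model

`stmapr` analyzes motility of a tubular organ — in the motivating
application the intestine of the agastric ballan wrasse — from time-lapse
binary masks. The organ hangs along the image rows with the oral end at
row 1. Two measurements are taken per frame:

* **Diameter.** Rectangular ROIs of width `roi_width_mm` (default 0.5 mm)
  are stacked along the long axis; within each ROI the diameter is the
  transverse distance between the outermost foreground pixels. The ROI
  grid is fixed over the stack-wide foreground extent, so a frame in
  which the (shortened) organ no longer reaches a bin records `NA` there,
  never 0: shortening must not masquerade as contraction.
* **Length.** The longitudinal extent of the foreground (first to last
  occupied row). How length "should" be read off a preparation that is
  anchored at the anal end is not fully determined by the recording
  set-up; the longitudinal-extent rule is the simplest assumption and is
  what the simulator emulates.

Recordings at 3.5 frames/s are thinned by keeping every third frame
(~1.2 frames/s): a temporal resolution at which the analyzed motility
patterns are stable while the data volume stays manageable. All
downstream analysis works on the resulting diameter matrix *D[x, t]*
(positions × frames, mm).

# Detection: local minima with similar-diameter extension

A contraction in one frame is a local minimum of the diameter profile
whose **depth** reaches `depth_threshold`. Depth is measured as the
minimum's value subtracted from the lower of its two *valley-bounding*
flanking maxima: walking outward from the minimum, each flank is the
largest value seen before the profile drops below the minimum again.
This prominence-style reading, rather than "nearest bump", is forced by
the worked profile `8, 8, 3, 3.5, 3, 8, 8`: a 0.5-mm wiggle between two
equal 3-mm minima must not split or reject the obvious 5-mm-deep valley.
Plateau minima return the whole plateau.

The threshold's unit is a design decision: the original description sets
"threshold = 1" without units, and the only reading under which flat or
gently noisy profiles are not littered with detections is one *diameter
unit of the acquisition*, i.e. a pixel-equivalent. The default is 0.1 mm
(one pixel at a 10 px/mm scale), configurable everywhere.

Each accepted minimum extends to the maximal contiguous run of
neighbours whose diameter lies within `similarity_tol` of the minimum
(default: equal to the depth threshold; "similar diameter" is otherwise
unquantified). All cells of a run share the run's **amplitude**: the
lower flanking maximum minus the run minimum — the conservative of the
two flank conventions, configurable in spirit by the per-profile helpers.
A run touching the profile edge uses its single available flank.

Runs are computed independently per frame and assembled into the
amplitude/`NA` cell matrix (the numerical binary ST map). Connected
components of cells — 8-connectivity by default, so a diagonal step of
one bin per frame keeps a travelling wave connected; 4-connectivity
available — are the contraction events. Detection is translation
equivariant (adding a constant to all diameters changes nothing), which
the tests assert.

# Classification

Event features follow directly from the cell set: initiation site = the
position of the earliest cell (oral-most on ties, for determinism);
propagating distance = spatial extent; duration = temporal extent; a
simple linear regression of position (response) on time over *all* cells
gives slope and *r²* (the squared Pearson correlation, identical to the
OLS coefficient of determination for one regressor); velocity = |slope|;
direction from the slope sign. Relative amplitude is the percent
decrease from the *maximum diameter of the position where the
contraction occurred*, the maximum being taken over the analysis window
(whether the original analysis used the window or the whole recording is
not stated; the window is the choice here and is configurable via
`window`). The amplitude convention matters: a prominence-based percent
amplitude is systematically attenuated wherever the baseline tapers,
while the percent-drop-from-maximum reading recovers injected amplitudes
exactly on synthetic data.

The rules, in order of precedence:

1. distance ≤ 1.0 mm → **standing** (non-propagating; the *r²* rule is
   never consulted — propagating-contraction analysis applies only to
   events longer than 1.0 mm);
2. otherwise *r² ≥ 0.8* → **ripple**;
3. otherwise (including an undefined *r²*, e.g. a single-frame event
   wider than 1 mm) → **slow propagating**.

Both constants are exposed (`standing_max_mm`, `ripple_min_r2`) and the
acceptance sweep recovers them from the classifier's behaviour.

Initiation sites are binned into four intestinal segments with length
fractions 0.39, 0.23, 0.23, 0.15 (Segment 1 = anterior bulbous foregut,
Segment 4 = hindgut); boundaries are inclusive on the right, so an event
exactly at a boundary belongs to the more oral segment. Frequencies are
contractions per minute per mm of segment length (cpm), with segment
lengths taken as fraction × total length at window start.

# Pre/post-treatment statistics

The treatment contrast works on per-replicate log₂(after/before) ratios
of any summary metric over 10-minute windows before and after treatment.
Zero or missing values on either side leave the ratio undefined; such
pairs are excluded (never zero-filled) and counted. Ratios are tested
against 0 with a one-sample t-test; because variation between individual
intestines is large, the convention is a 90% confidence level with two
reporting tiers, `*` for 0.05 ≤ p < 0.1 and `**` for p < 0.05.
Zero-variance inputs are flagged rather than given a fabricated p.

Parameter values are additionally categorized as low (≤ Q1), medium, or
high (≥ Q3) by sample quartiles, because the underlying distributions
are roughly exponential and mean comparisons would be dominated by the
mass of small values. The quartile convention is linear interpolation
between order statistics (plotting position (k−1)/(n−1); R's type 7) and
is recorded in the output, since category membership near a cutoff
depends on it.

Across contraction types, medians are compared with Kruskal–Wallis
followed by Dunn's pairwise z tests on joint ranks with tie correction.
The post-hoc adjustment is Holm by default — the cited post-hoc tool's
default — and configurable to none or Bonferroni, since the original
description does not state it. Across segments, frequencies are compared
with one-way ANOVA and Tukey's HSD; compact-display letters are derived
from the Tukey p matrix by insert-and-absorb, so groups that are not
significantly different share a letter.

Length responses are quantified as percent reduction (mean pre-treatment
length minus the post-treatment minimum, as percent of the pre mean) and
as discrete shortening events: local minima of the length trace with
prominence at least 1% of the window's mean length (configurable).
Whether "events of length reduction" means such discrete episodes or
something else is not defined in the source description; the local-minima
reading is an explicit assumption.

# The synthetic generator and what it does (not) show

`simulate_diameter_matrix()` builds a baseline profile
D₀(x) = d_anal + (d_oral − d_anal)·exp(−(x/0.35L)²) — a bulbous foregut
tapering toward the anal end, defaults 4 → 1.5 mm over L = 60 mm, 0.5 mm
bins, 1/1.2 s frames, 10-minute windows — and subtracts, per event,
amplitude_frac · D₀(x) · G(x − c(t)) · H(t), where G is a Gaussian (or
optional square) spatial kernel, H a raised-cosine on/off envelope, and
the centre path c(t) moves at the event's velocity. Slow events add a
single-cycle `cos − 1` waviness calibrated so the path's generative *r²*
hits a target below 0.8. The `cos − 1` form matters: it starts at zero
displacement and is orthogonal to the linear trend, so the path's
regression slope remains exactly ±v; a sine term leaks a linear
component of size 6A/(πT) into the slope, inflating retrograde and
deflating anterograde velocities. Gaussian noise and clipping at zero
complete the matrix; identical spec + seed + events are bit-identical.

`simulate_masks()` rasterizes a diameter matrix into symmetric tube
masks (diameter rounded to whole pixels), closing the loop mask →
diameter → mask within one pixel-equivalent. `simulate_length_trace()`
injects transient dips and sustained reductions into a length trace.

`sample_ground_truth()` draws events for recovery experiments, and its
choices are worth stating because they define what the passing tests do
and do not demonstrate:

* Square kernels give amplitude-independent footprints, so ground truth
  is unambiguous. Relative amplitudes span 5–85%, floored so absolute
  depth stays ≥ 0.2 mm (twice the detection threshold) along the path —
  very shallow events on the thinnest gut are below the method's
  resolution by construction and are not sampled.
* Propagating distances span 4.5–13.5 mm with durations 12–300 s.
  Velocities span 0.012–1.69 mm/s for ripples and 0.012–0.12 mm/s for
  slow events. The extreme printed velocities are *jointly infeasible*
  with the defining thresholds at this sampling geometry: a 0.001–0.002
  mm/s wave cannot travel more than 1 mm within any realistic duration
  (it would be classified standing by definition), and a wavy slow path
  much faster than ~0.12 mm/s jumps more than one 0.5-mm bin per 0.83-s
  frame and breaks the connectivity that makes it one event. The sampled
  spans cover the bulk of the observed distributions (slow median 0.057
  mm/s, 70% ≤ 0.1 mm/s).
* Velocities near one bin per frame (~0.6 mm/s) resonate with the grid:
  a perfectly constant-speed wave aliases and its regression slope
  acquires a bias of order dx/T. Events in that band run ≥ 20 s so the
  quantization pattern averages out.
* Standing events snap to a bin centre; sub-bin placement attenuates a
  narrow event's sampled depth, which is a raster artefact rather than a
  detector property.

Passing recovery tests therefore show that the detector and classifier
are *correct implementations of their definitions* over the observed
parameter ranges on clean, well-separated events — not that real
recordings, with overlapping events, drifting baselines, segmentation
errors and occlusion, are recovered with these error bounds. The noise
robustness actually asserted is modest (counts stable with noise up to a
tenth of the depth threshold on well-separated events).

The statistical calibration experiment likewise simulates at the *count*
level (Poisson counts per segment and window, 12 replicate intestines,
foregut rate halved and hindgut rate doubled after treatment), which
exercises the ratio/t-test machinery end to end but not the imaging
chain; its problem sizes (2000 null replicates, 100 meta-replicates) are
chosen to bound Monte-Carlo error on the tier rates at a few tenths of a
percent.

# Numerical choices and degenerate inputs

* Half-integers in gray-map rendering round to even (R's `round`), so
  the midpoint of a symmetric range renders as 128; constant matrices
  render uniform 128 with a warning.
* Spatial interpolation (nine inserted values by default) is for
  rendering only; detection always runs on the native grid, as binary
  maps are built without interpolation. Original samples are copied, not
  blended, so a missing neighbour cannot poison them.
* Ties in the initiation-site frame resolve to the oral-most cell;
  component ids are renumbered in (frame, position) order — both purely
  for deterministic output.
* Single-cell/single-frame events have undefined slope, *r²* and
  velocity (`NA`, direction `"none"`), never zeros.
* An all-missing profile row normalizes to itself with a warning; a
  profile segment shorter than 3 bins yields no minima; a run spanning a
  whole profile has no flanks and is discarded.
* Events are tibbles throughout; matrix-shaped objects (`diameter_matrix`,
  cell matrices, rendered maps) stay matrix-backed with `as_tibble()` /
  `autoplot()` bridges, because a 120 × 720 grid in long form is the
  wrong default representation for detection arithmetic.

# Known limitations

* Detection operates frame-wise; a model-based space-time wave fit would
  pool information across frames and likely lower the velocity floor at
  which propagation is resolvable on this grid (~0.01 mm/s here).
* The regression runs over all event cells, so the similar-diameter band
  width enters *r²*; very short propagating events (just above 1 mm) on
  wide bands can fall below 0.8 even when their centre path is linear.
  This is a property of the published definition, not of this
  implementation; the guard bands in the recovery experiment make it
  explicit.
* Overlapping events merge into one connected component; the simulator
  flags overlapping footprints but the detector makes no attempt to
  split them.
* `measure_diameters` assumes the long axis is the image row axis after
  orientation correction; strongly curved or folded preparations violate
  the transverse-bin model.
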