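---
title: "Monitoring activity and detecting falls from low-resolution thermal streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring activity and detecting falls from low-resolution thermal streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofall)
```

## The problem

Ambient monitoring of older adults living alone has to work without
cameras: acceptance hinges on privacy. A 32x24 thermopile array (and,
cheaper still, stacks of 8-pixel thermopile line sensors) sees a person
only as a warm blob a few pixels across, which is exactly the point --
nothing identifiable is ever recorded. `thermofall` implements the two
analyses such a sensor supports:

1. **Activity scoring** -- how much of each hour was the room's occupant
   moving about? Scores aggregated per hour and month give clinicians a
   picture of daily rhythm and its disruptions.
2. **Fall detection** -- classify short frame windows as *fall* versus
   *non-fall* from the shape and motion of the blob, and raise alerts.

No public dataset of such recordings exists, so the package also ships a
synthetic scene simulator that generates labeled streams with the
statistical structure the two pipelines assume. All defaults below are
the package's study conditions; the tests and the acceptance script run
against them unchanged.

## Activity scoring

### Background subtraction

The room's apparent temperature drifts slowly -- characteristic times of
tens of minutes -- while a person moves on a scale of seconds. The
separation of time scales lets a simple low-pass filter stand in for the
person-free "background": per pixel, the weighted moving average (WMA)
of the last $L$ samples with linearly increasing weights,

$$\mathrm{ref}_p = \frac{\sum_{i=1}^{L} i \, x_{p,t-L+i}}{\sum_{i=1}^{L} i}.$$

A pixel is *active* when it exceeds its reference by more than
$\Delta T$ (default 1.5 °C; only positive exceedance counts, since the
subject is warmer than the room), and a frame is active when at least
`min_active_pixels` pixels are (default 2 for 2D frames; 1 for 1D
records, whose bins are already 4-pixel averages, so a single bin is
less noise-prone). The hourly activity score is the percentage of active
frames. The score formula is the package's choice -- the fraction-of-
active-frames reading is the one consistent with hourly percentage
charts in the single digits for a normally active person.

Two numerical choices matter:

* **Window and decimation.** The WMA window is 600 samples with
  background updates decimated to roughly 1 Hz, i.e. a 10-minute
  window: long against movement, short against drift. Updating every
  frame would only multiply cost, not accuracy.
* **Masked updates.** By default only currently-inactive pixels feed
  the WMA (active pixels push their current reference value instead),
  so a person sitting still for many minutes does not melt into the
  background. The plain WMA is available via `mask_update = FALSE`. The
  model is seeded with the first frame of the capture; if a person is
  already present in frame one, that hour's first seconds are scored
  conservatively.

Hours are only scored when captured without interruption: at the nominal
rates (16 fps for the array, 5 Hz for the line-sensor records) a 1-hour
capture must hold at least 57,600 / 18,000 records. Hours failing the
rule are *missing*, never zero -- a distinction the monthly aggregation
preserves by excluding them from both the mean and the (population)
standard deviation.

### Record format and codec

Captures are plain text: per 2D frame a `# <ISO-8601>` header plus 24
rows of 32 temperatures; 1D records are 33-column CSV (timestamp + 4
sensors x 8 bins). The 2D orientation is fixed as rows = 24, columns =
32 (the sensor's native matrix shape); a transposed source would simply
swap the two loop bounds, but only one orientation is accepted so files
are unambiguous. Mounting height of the line sensors is not hard-coded:
the rows each 1D sensor integrates are a `project_to_1d()` argument. Measurements are serialized as fixed-point decimals
with 8 fractional digits of which the last five are zeros -- the sensor
delivers no information there -- and the codec elides exactly those five
characters per field, restoring them on decompression. Fields that ever
fail the all-zeros premise are passed through verbatim with a flag
rather than corrupted or dropped; this keeps the stream robust and the
round trip lossless by construction. On 2D captures the measured saving
is ~41% of file size; 1D records sit just under 40% because the
timestamp and separators are incompressible. The codec's own measured
rate is the quantity the package reports; byte counts of any other
serialization dialect are not comparable.

## Fall detection

### From frames to graphs

Each frame is binarized (fixed threshold, default 28 °C, a plausible
apparent human temperature against ~21 °C rooms; Otsu's between-class-
variance criterion is available via `mode = "otsu"` but costs more and
adds nothing when the contrast is this strong), cleaned by one 3x3
closing plus removal of components under 3 px, and thinned to a
single-pixel skeleton with the two-sub-iteration Zhang–Suen rule set,
followed by pruning of spurs shorter than 2 px interleaved with
re-thinning until convergence. Border pixels count as background for
all neighbourhood rules. One degeneracy of the classic rule set is
handled explicitly: an isolated 2x2 square satisfies the deletion
conditions at all four pixels simultaneously, so a sub-iteration is
never allowed to delete the last pixels of a component (its first
pixel in column-major order survives). Thinning and pruning therefore
preserve the number of 8-connected components exactly.

The skeleton becomes a graph by path subsampling: endpoints and branch
points are always nodes, plus every 2nd pixel along each path (stride
2); edges join consecutive retained pixels, so graph components mirror
skeleton components. A classification window of 24 frames (1.5 s at
16 fps -- enough to span a standing-to-down transition) is combined into
one spatiotemporal graph: disjoint union of the per-frame graphs plus
one temporal edge from every node to its Euclidean-nearest node in the
next frame (ties break to the smaller row, then column; deterministic
by construction). One nearest-neighbour link per node is the minimal
rule that encodes motion without quadratic edge growth.

### Embedding and classification

Each window graph is embedded Graph2Vec-style: its Weisfeiler–Lehman
subtree labels (initial label = degree bucket 0/1/2/3+, three
refinement iterations) form a document, and a 30-dimensional vector per
graph is trained PV-DBOW fashion against negative samples from the
label unigram distribution (200 epochs, initial learning rate 0.05 with
linear decay, 5 negative samples; `grid_search_k()` reproduces the
dimension selection). Because the labels are purely structural and
coordinates never enter the features, the embedding is invariant to
where the person stands and how the nodes are enumerated -- documents
are sorted into canonical multiset order before training for exactly
that reason. Unseen windows are embedded in inference mode against the
frozen label vectors.

A random forest (200 trees) separates the two classes, evaluated by
stratified 5-fold cross-validation with *fall* as the positive class.
The embedding is fitted once on all windows: it is label-free, so this
leaks nothing -- which the permutation-null test verifies directly
(shuffled labels drive CV accuracy to 50%). Whether the original
laboratory figures were cross-validated or held out is not knowable
from the outside; stratified CV is this package's protocol and is
recorded as such.

## The simulator

`scene_config()` fixes the study conditions: 24x32 grids at 16 fps (1D
records at 5 Hz), mean background 21 °C drifting as a mean-reverting
Ornstein–Uhlenbeck process with time constant 1200 s and stationary SD
0.5 °C (the simplest process that is "slow drift with a characteristic
time of tens of minutes"), i.i.d. pixel noise of SD 0.3 °C, and a body
at 31 °C (subjects vary by ±2 °C and 10.5–13.5 px of height). The
subject is an ellipse whose axes interpolate between upright (tall) and
horizontal (wide, centroid near the floor rows; row index increases
downward). Scripts provide the class structure:

* **fall** -- upright, then a 1 s transition through a transitional pose
  to horizontal on the floor;
* **lie / sit / pickup** -- the same machinery at voluntary speed (4 /
  2.5 / 3 s; pickup bends down and straightens back up), which is the
  physically honest discriminator: falls are fast;
* **walk** -- constant upright translation at 1.5–3 px/s.

`build_dataset()` reproduces the acquisition design: 120 fall and 120
non-fall windows from 10 subjects, round-robin so per-subject class
balance holds to ±1, non-falls cycling through the four confounders
known to trigger false alarms in the field. Every window is 24 frames
around the postural transition (or mid-walk). A fixed seed makes every
operation bit-reproducible.

What the simulator does **not** emulate: occlusions and furniture,
multiple heat sources (cookers -- a documented false-positive source in
deployment), pets, camera-angle foreshortening, sensor dropout, or
realistic gait. Passing tests therefore show that the pipeline recovers
the geometry and dynamics it is designed around, not field performance
in real homes.

## Problem sizes and degenerate inputs

The test-suite and acceptance runs use the full 240-window corpus for
classification (about 5,800 frames through the skeleton chain) and
scale the activity-score recovery runs to one simulated hour at 2 fps
(7,200 frames) -- occupancy fractions are rate-independent, so nothing
is lost relative to 16 fps. Degenerate inputs are defined, not fatal:
Otsu on a constant frame warns and returns an empty mask; empty masks
thin to empty skeletons and embed through an empty document to a
zero-information vector; all-empty windows are skipped by the stream
windower; cold background models refuse detection; invalid hours are
missing, not zero.

## Known limitations

* The per-frame skeleton of a 5-or-so-pixel-wide blob is short; most of
  the discriminative signal lives in the *temporal* structure of the
  combined graph, which is why windows shorter than ~1 s degrade
  quickly.
* Inference-mode embedding of a window far outside the training
  distribution (e.g. two people) is undefined behaviour by design --
  multi-person scenes are out of scope.
* The alert protocol records the five notification fields but the
  package does not model call-center response; deployment statistics
  are not reproducible from code.
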