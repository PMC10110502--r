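---
title: "Methods and design notes for pgcprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pgcprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcprot)
```

# Scope

`pgcprot` quantifies protrusion plasticity and migration of amoeboid cells
(the motivating system is the zebrafish primordial germ cell) from
time-lapse fluorescence microscopy: cortical angular intensity profiles,
bleb frequency and size, actin-rich protrusion time, track kinetics with
tissue-drift correction, kymograph flow, ratiometric biosensor readouts,
stain quantification, nuclei density, gel-encounter response scoring, and
the statistical decision rules that go with them. A synthetic-microscopy
generator with exact ground truth backs every stage, so the whole pipeline
is testable offline.

# Conventions

* Images are `Y x X` matrices; pixel centers sit on an integer grid with
  0-based `(y, x)` coordinates. Movies are `T x Y x X` arrays inside an
  `ImageStack` that carries `pixel_size_um` and `frame_interval_s`.
* Angles are degrees in `[0, 360)`, measured by `atan2(dy, dx)` in array
  coordinates (y = row index). All angular arithmetic is circular
  (`circ_diff_deg()` wraps differences into `(-180, 180]`).
* No TIFF dependency exists in the supported environment, so serialized
  stacks use a plain-text format (one numeric matrix per frame plus a JSON
  sidecar with the calibration). The in-memory contracts are unchanged.

# Cortical profiling

Segmentation follows the classical recipe: threshold (Otsu over a 256-bin
histogram by default; a manual threshold is a first-class option since Otsu
is unreliable when the intensity histogram has more than two modes), keep
the largest connected component, fill holes. The cortex ring is the set
difference between the mask and its 4-fold erosion. The structuring element
is a 3x3 cross (4-connectivity) by default — the literature's generic
"erode" does not pin the neighbourhood, and Fiji's default is the 8-connected
box, so the element is exposed as an option (`elem = "box"`) for users who
need to match Fiji pixel-for-pixel. If erosion empties a very small mask,
the whole mask is returned with a `degenerate` flag instead of erroring, so
batch runs survive.

The masked signal is sliced into 120 angular bins of 3 degrees about the
mask centroid and averaged per bin. Per-frame profiles of one cell are
averaged bin-wise (the one-profile-per-cell mode; 20 consecutive frames of a
polarized, forward-moving cell is the conventional input), then a circular
Gaussian `c + A exp(-d(theta, mu)^2 / (2 sigma^2))` is least-squares fitted.

Numerical choices worth knowing:

* **Fit abscissae.** Each bin is represented by the mean angle of its own
  pixels rather than the geometric bin center. With only ~8 pixels per bin,
  the pixel-angle distribution inside a bin is uneven, and using bin centers
  biases the recovered `sigma` by several tenths of a percent; mean pixel
  angles reduce the noiseless recovery error to below 0.1%.
* **Optimizer.** L-BFGS-B (bounds: `A >= 0`, `sigma` in `[0.01, 180]`)
  followed by a Nelder–Mead polish; the polish also rescues the occasional
  abnormal L-BFGS-B termination. `converged` is honest: flat profiles and
  optimizer failures return `converged = FALSE` with diagnostics, never a
  fabricated fit.
* **Centering.** Plot normalization divides by the fitted peak height
  `A + c` and rotates by the integer bin shift closest to `180 - mu`;
  the sub-bin remainder is recorded, not interpolated, so bin means stay
  exact.
* **Group comparison.** The Kolmogorov–Smirnov input unit is genuinely
  ambiguous in the conventions this follows; both modes are provided
  (`per_cell`: pool each cell's bin values; `pooled`: compare group-mean
  profiles), with `per_cell` as default.

# Synthetic data: the stated world

The generator emulates, in 2D+t, the phenomenology the pipeline measures —
it is a ground-truth harness, not a biophysical simulation:

* **Shape.** A star-convex radial function `r(theta, t)` around a moving
  center; blebs are transient Gaussian bumps in `r(theta)` (linear rise to a
  peak, linear decay). Truth stores the dense contour polygon per frame, and
  `rasterize_truth()` reproduces the movie's mask pixel-exactly through the
  same radial rule.
* **Cortex.** The ring (outer 4 px of the radius) carries
  `interior + c + A exp(-d(theta, mu)^2 / (2 sigma^2))`: the cortical
  enrichment rides on the cytoplasmic baseline, as for a cortex marker over
  cytoplasmic background. The interior level defaults to 40% of the peak
  amplitude — bright enough that thresholding sees one cell, dim enough to
  leave ring contrast. During the first ~10 s of a bleb the ring value over
  the cap drops to baseline (young blebs are cortex-free).
* **Bleb schedule.** Event count ~ Poisson(rate x duration); starts are
  uniform over frames that let the event run its full course inside the
  movie (one pre-bleb frame, full duration). Boundary-truncated events are
  ambiguous for any scorer, human or automated, so the world excludes them;
  counts remain Poisson at the configured rate. Event heights vary by ±30%
  so size metrics carry spread.
* **Tracks.** Constant-step biased random walks (turn-angle s.d.
  `(1 - persistence) * 180` degrees) plus a uniform tissue drift; somatic
  tracks carry the drift only. With `speed_cv = 0` (default) path length is
  exactly `speed x duration`, which the tests exploit; the demo sets
  `speed_cv = 0.25` for realistic spread.
* **Noise.** Additive Gaussian only. A green recovery test therefore
  establishes correctness of the measurement chain, not robustness to photon
  shot noise, uneven illumination, z-drift or segmentation failure modes of
  real embryos.

Generators are pure functions of `(params, seed)`: the RNG state is saved,
seeded, and restored around every call, so identical calls are bit-identical
and independent of caller state.

# Bleb detection

The protocol-faithful metrics consume annotations (human scoring or generator
truth). `detect_blebs()` is a benchmarking convenience: new-area regions
between consecutive frames are candidates if they reach a minimum fraction
of the cell area quickly enough and show a cortical-signal deficit; they are
linked across frames by overlap with a dilated copy of the previous region
(the gain rim advances outward as the bleb grows). The deficit reference is
the same angular sector of the *previous* frame's ring — with a polarized
cortex, a global ring mean cannot distinguish a cap at the dim back of the
cell, and the cap itself suppresses the current frame's ring. Default
deficit ratio 0.8 reflects a cap at cytoplasmic baseline. Detection achieves
precision = recall = 1 only under favorable conditions (zero noise, bright
near-uniform cortex, temporally separated events, fixed threshold); it is
not a general-purpose detector and is never silently substituted for
annotations.

# Kinetics

Speed is path length over duration and straightness is net displacement over
path length (the conventions of the commercial tracking software this
mirrors; the mean instantaneous speed is available as an option). Drift
correction subtracts, per interval, the mean displacement of the `k = 5`
somatic tracks nearest at the interval start, then re-integrates.

Kymograph rows are bilinear samples along a line at 1-px steps. Flow speed
is the median per-row-pair displacement, where each displacement is the
argmax of the mean-subtracted, Hann-windowed, FFT-evaluated
cross-correlation, refined by a continuous-lag search on the
sinc-interpolated correlation. Two deliberate deviations from the obvious
recipe, both visible in the tests: three-point parabolic refinement was
dropped because it biases half-pixel displacements of smooth patterns by
more than 2% (larger than the accuracy the package promises), and the
default search range is 1/8 of the row length with near-ties resolved toward
the smallest displacement, because periodic patterns alias at
`d ± period`. Positive flow means motion toward increasing position along
the line; orient the line front-to-back to make retrograde flow positive.

# Ratio and stain quantification

Ratio maps are plain per-pixel acceptor/donor inside the mask where the
donor exceeds a floor (default 5% of the in-mask donor median, guarding
against division blow-ups). Spectral bleed-through and photobleaching
corrections are out of scope. The front/back ratio quarters the mask by
*extent* along its principal second-moment axis (equal lengths, not equal
pixel counts — "first and last quarter of the cell" read geometrically);
the axis sign is set by the supplied movement direction when the two
disagree. Stain quantification projects (`average` over the first 10 slices
by default, or `sum` over all), takes the cell-region mean and subtracts the
mean of two background-region means; negative corrected values are allowed
but flagged.

# Gel-encounter scoring

Scoring uses the fixed 6-minute window (1 min before to 5 min after
contact). Loss of polarity takes precedence: the front type must be
`unpolarized` for at least the dwell time (default 30 s); otherwise a
circular polarity change of at least the turn threshold (default 45°)
relative to the window start is a turn; otherwise no change. The numeric
thresholds are package choices — the original scoring was visual and
double-blinded, with no published criteria — and are exposed in the
configuration and echoed in the output. Response time is measured over the
whole movie, regardless of the window.

# Statistics

The decision tree: D'Agostino–Pearson normality on both groups (implemented
from the standard skewness and kurtosis transforms; `n >= 8` required, and
the Monte-Carlo calibration of the full tree is itself a test); if both pass
at `alpha = 0.05`, an F-test gates pooled-t versus Welch; otherwise
Mann–Whitney. All tests two-sided; summaries are median and IQR. Choices the
source conventions leave open, fixed here: normality and variance alphas at
0.05; groups below n = 8 (normality test undefined) and constant samples
route to Mann–Whitney with a warning. Fisher's exact test is implemented
directly from the conditional hypergeometric definition (two-sided p = total
probability of tables no more probable than the observed one) and is
enumeration-checked over all small tables; the KS test delegates to base R
(exact for small untied samples) and is enumeration-checked likewise;
Bonferroni is `min(1, p * m)`.

# The demo and what green means

`demo_replica()` builds two tissues differing in bleb rate (1.6 vs 0.8
events/min), cortical width (80° vs 40°) and hence actin-rich time, with
equal speeds, and pushes 30 cells per group through the full pipeline. The
configured contrasts come out significant and the equal-speed comparisons do
not; outputs are byte-identical across reruns of the same seed. This
establishes that the measurement chain recovers what the generator encodes
at realistic noise — not that it reproduces any in-vivo effect size, since
the original imaging data are not public.

# Known limitations

* 2D+t only; no 3D bleb volumes, no 3D cortical shells, no nuclear surface
  segmentation (the density statistic consumes centroid tables).
* No image registration; drift is handled at the track level.
* The bleb detector is a benchmark helper, not a production detector.
* The noise model is additive Gaussian; tolerance to realistic microscopy
  artifacts is untested by design.
* Erosion connectivity in the reference protocol is unknowable from the
  published material; results here use the cross element unless told
  otherwise.
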