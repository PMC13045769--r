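---
title: "Methods: Z-distribution analysis and drift correction of SPM image series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-distribution analysis and drift correction of SPM image series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmkit)
```

## The problem

A scanning tunnelling microscopy (STM) experiment on a molecular monolayer
— for example a metalloporphyrin adlayer on Au(111) imaged under
electrochemical potential control — produces long series of images whose
pixel values (the Z channel: tip height in constant-current mode, or
tunnelling current in constant-height mode) carry the quantitative signal.
Different molecular regions (the alkyl background, dark molecules, bright
molecules) image at discrete apparent heights, so the Z values of one frame
form a multi-modal 1-D distribution. Tracking how the modes of that
distribution move (heights) and exchange mass (pixel populations) across a
potential series turns a stack of pictures into an electrochemical
observable. spmkit implements that pipeline: raw-file ingestion, per-line
background removal, outlier clipping, two segmenters of the Z distribution,
and a translational drift corrector for long sequences.

## Filtering

**Line-wise parabolic flattening.** Raw frames show apparent tilt and bow
from sample inclination and piezo creep, generally different per scan line.
`flatten_line_parabola()` fits each horizontal line independently with a
least-squares parabola in the physical X coordinate and subtracts it, using
a QR solve with all rows handled in one multi-response fit. The residual of
each row is exactly orthogonal to \{1, X, X²\}, so flattening is idempotent
and invariant under any added per-row quadratic. The fit uses raw X rather
than the column index; the two are affinely equivalent but one convention
has to be frozen for reproducibility. Rows shorter than 3 points are an
error (the fit would be underdetermined), not a silent degradation.

A consequence worth knowing: the fit absorbs whatever part of the molecular
signal projects onto a quadratic along each row. Rows crossing tall
molecules are therefore rebased slightly lower than empty rows, which
broadens the Z modes by roughly the row-to-row scatter of molecular
coverage and can compress apparent heights by several picometres on dense
monolayers (the tall class loses the most). This is inherent
to per-line background subtraction, not an artefact of this implementation;
the tests quantify it on synthetic ground truth.

**Percentile equalisation.** `equalize()` computes the Z values at a lower
and upper percentile of the frame's Z distribution (defaults 1 and 99,
symmetric outlier exclusion; the pair is exposed independently), reassigns
values beyond the limits to the nearest limit, then shifts the frame so its
minimum is exactly 0. Relative differences among unclipped pixels are
untouched, ordering is preserved, and a constant frame maps to all zeros.
Percentiles use linear interpolation between order statistics
(`quantile(type = 7)`); clip counts in the tests depend on that convention,
so it is frozen and documented. Flattening always runs before equalisation
when both are enabled — residual tilt stretches the Z distribution and
would corrupt the percentile limits.

## Segmentation by Gaussian mixture

`fit_gmm()` fits a K-component univariate Gaussian mixture to the frame's
Z values by expectation-maximisation, authored in the package so that
every numerical choice is explicit:

* initialisation: k-means++ seeding from the user's seed, followed by full
  Lloyd k-means refinement (the seeding alone occasionally leaves EM in a
  degenerate local optimum that splits the dominant background mode);
* convergence: relative log-likelihood change below 1e-6, at most 500
  iterations; responsibilities computed with the log-sum-exp trick;
* variance floor 1e-12 to prevent component collapse;
* components reported sorted by ascending mean, labels (1-based, following
  R convention) re-permuted consistently; a fixed seed gives bit-identical
  results.

The mixture weight of a component is reported as its "responsibility": the
fraction of the Z distribution that component accounts for. Per-point
posteriors are used only internally, for the arg-max hard labelling.
`cluster_heights()` references every component mean to the lowest one —
for a 3-cluster monolayer fit these are the dark-molecule and
bright-molecule heights above the background — and `pixel_fractions()`
counts hard-assigned pixels. Model order stays a manual choice:
`gmm_sweep()` fits k = 2..k_max and emits segmented control images for
visual inspection; log-likelihoods are reported but no information
criterion is applied automatically, because the meaningful minimum k is a
question about which molecular regions must be separated, not about fit
quality.

In a series, every frame is fitted independently with the same seed — no
warm starting — so a frame's result never depends on its neighbours.

## Segmentation by fixed thresholds

For video-rate series (hundreds of strongly correlated frames) the mixture
refit per frame is unnecessarily slow. `calibrate_scheme()` averages the Z
range of the first N frames (assumed acquired at equilibrium), divides
that reference extension into a user-chosen number of equal-width
intervals anchored at Z = 0 — the frames are equalised upstream, so their
minimum is rebased to 0 — and freezes the interior boundaries for the
whole series. Anchoring at 0 rather than at each frame's minimum keeps the
scheme genuinely constant; later frames exceeding the calibrated extension
fall into the top interval (half-open `[low, high)` intervals, top closed
above) so no pixel is ever dropped. Zero-extension calibration frames are
excluded from the average with a warning. `apply_scheme()` is a single
`findInterval()` pass — linear in the pixel count, no optimisation.

## Drift correction

Long series drift slowly and nonlinearly, so a recognisable feature walks
across the field of view. The corrector is anchor-based and headless: the
interactive draggable-square picker of notebook environments is replaced
by a plain text anchor track (`file name, x centre, y centre` per sampled
frame), which makes the whole path scriptable and testable; any picker can
write that file. The first anchor is the reference; anchor deviations are
fitted per axis as a function of frame index — a natural cubic spline
through the anchors (natural boundary conditions; the interpolation
reproduces every anchor exactly) or a least-squares polynomial — and
evaluated at every frame. The classical two-step "interpolate, then fit
the interpolated points" collapses to fitting the anchors directly: the
targets are mathematically equivalent and the direct fit avoids smoothing
artefacts from the intermediate resampling. Beyond the last anchor the
deviation is held constant (spline and polynomial extrapolation both
diverge); the reference-frame deviation is forced to exactly (0, 0).

Frames are first embedded in a zero border (`expand_grid()`; default pad
1.5x the maximum anchor deviation) and then rigidly translated by the
negated, whole-pixel-rounded deviation. Translation without resampling
preserves the multiset of non-zero Z values bit-exactly and leaves the
trace of the original position in the border; sub-pixel correction would
require interpolating Z values, which changes the very distribution the
segmenters analyse, so it is deliberately not done. A translation that
would push data off the canvas is an error naming the frame and the pad
required.

## The synthetic generator

All tests run offline against `make_monolayer_image()` /
`make_drift_series()`, which emulate exactly the statistics the analysis
assumes: a periodic lattice (square or triangular) of blob-shaped
molecules with discrete height classes over a low background, per-row
smooth quadratic backgrounds, additive Gaussian noise, sparse single-pixel
spikes, and, for series, a smooth nonlinear translational drift with
fresh noise per frame. One global seed drives independent substreams for
placement, backgrounds, noise and outliers, so changing the noise knob
never reshuffles the scene.

Default conditions (chosen once, as a realistic porphyrin-like adlayer):
128x128 px frames, 8 px lattice period, molecule radius 3.3 px, class
offsets 0/+25/+45 pm with probabilities 0.5/0.3/0.2, noise 4 pm (mode
separation over 6 noise sd), outlier fraction 0.2% at ±200 pm, per-row
backgrounds up to ~10 pm of offset/tilt/bow. Molecules are rendered as
flat-top discs with a cosine edge taper of 0.3 px half-width, composited
by pointwise maximum so a noiseless centre equals its class offset
exactly. The disc profile, rather than a Gaussian bump, is a deliberate
design choice: the generator's purpose is discrete height classes, and a
Gaussian bump's Z histogram has density spread over all intermediate
heights with no mode at the class height, which no Z-distribution
segmenter could (or should) recover. The narrow edge taper exists only as
anti-aliasing; its pixels are the one part of the model that sits between
modes, and they are what limits height recovery to about ±1 pm in the
tests. A `blob_shape = "gaussian"` option is kept for experiments.

The dim schedule of `drift_spec()` emulates a potential-step
(chronoamperometric) response: from a given frame on, a chosen fraction of
one class's molecules has its offset scaled down. The fraction matters —
if the whole class dims uniformly, a per-frame refitted mixture simply
tracks the shifted mode (or splits the merged one) and reports unchanged
fractions; a partial dimming moves real mass from the middle mode into
the low one, which is both what the electrochemistry does (part of the
population goes dark) and what makes the lowest-cluster fraction rise
under both segmenters.

What the generator does **not** emulate: intra-molecular structure (ethyl
lobes, metal centres), tip convolution and tip changes, scan-line noise
correlation, creep distortion within a frame, and Z drift between frames.
Passing tests therefore demonstrate correctness of the numerics and the
recovery of programmed statistics under the stated noise model — not
robustness to every artefact of real instruments.

## Problem sizes and numerical conventions

The test-suite and acceptance-script workloads use 128x128 px frames
(64x128 to 164x164 after expansion for drift work), series of 20-60
frames, and 50,000-point mixture draws — sizes at which every fit
converges in well under a second and the whole suite runs in seconds,
while keeping estimator noise far below the tolerances being checked.
Other frozen conventions: grid row 1 holds the smallest Y and rasters are
written top-row-first (vertically flipped relative to the physical Y
axis); PNG intensities are `round half up` of the per-image linear map,
with a constant image mapping to 0; XYZ files are written X-fastest with
10 significant digits and parsed by coordinate, so any complete-grid line
order is accepted; the binary raw-scan dialect is the toolkit-defined
little-endian layout documented in `?read_s94` (the vendor layout is not
public, so only this dialect is guaranteed); ties in mixture means are
broken by stable ordering.

## Known limitations

* Per-line flattening biases cluster means slightly on dense monolayers
  (see above); plane or masked-region fits are out of scope.
* The threshold segmenter assumes the first N frames are representative
  equilibrium frames; a drifting Z range during calibration shifts all
  boundaries.
* Drift correction is whole-pixel and purely translational; shear,
  rotation and intra-frame distortion are explicitly not corrected.
* The mixture fit is 1-D by construction: pixels are clustered by height
  only, never by spatial context.
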