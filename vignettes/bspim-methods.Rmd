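---
title: "Simulating and detecting nematode biospeckle in light-sheet scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting nematode biospeckle in light-sheet scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspim)
```

## The measurement this package models

Free-living nematodes (FLN) are 40 µm–1.5 mm soil worms that are nearly
transparent, unstainable in practice, and therefore hard to see against a
granular substrate. Biospeckle selective plane illumination microscopy
(BSPIM) detects them by their *motion* rather than their contrast: a coherent
light sheet illuminates one optical section of a transparent-soil sample, a
camera records a time-lapse of the laser speckle, and any moving scatterer
(a live animal) decorrelates the interference pattern over time while the
static matrix leaves it frozen. Scanning the sheet through the sample and
collapsing each time-lapse into an activity index gives a 3D map of
biological activity, in which live animals can be counted automatically.

`bspim` implements the full computational chain:

1. a seeded physics-based simulator of such acquisitions (there is no public
   reference dataset, so the simulator stands in for the instrument),
2. the generalized-differences (GD) activity index and the transect
   signal-to-noise (S/N) metric,
3. the 3D detection pipeline (8-bit conversion, boxcar background
   subtraction, anisotropic Gaussian smoothing, thresholded 3D
   connected-component counting),
4. evaluation experiments: count recovery over 0–20 inserted animals and
   brightfield-versus-GD S/N comparison.

## The speckle model

Fully developed speckle is modelled per pixel as a circular complex Gaussian
field amplitude $E$ with unit mean intensity; the detected intensity
$I = |E|^2$ is then exponentially distributed with contrast
$\sigma/\langle I\rangle = 1$, the classic signature of polarized fully
developed speckle. Temporal decorrelation follows a stationary AR(1)
process,

$$E_{t+1} = \rho\,E_t + \sqrt{1-\rho^2}\,\eta_t,$$

with $\eta_t$ fresh circular complex Gaussian noise. The field
autocorrelation at lag $k$ is exactly $\rho^k$, the marginal distribution is
invariant, and $\rho = 1$ gives a perfectly static pattern. This reproduces
the statistics that the GD index actually measures — temporal variation of
intensity — at a tiny fraction of the cost of wave-optics propagation, which
is deliberately out of scope.

Spatial speckle grain is imposed by low-pass filtering the *initial* complex
field with an L2-normalized Gaussian kernel (`grain_sigma_px`, default 2 px;
circular convolution keeps the field exactly stationary, borders included).
Innovations are spatially white, so spatial correlation inside actively
decorrelating regions fades over the stack; this affects only the texture
within an active footprint, not the per-pixel temporal statistics the index
integrates, and it keeps the simulator fast enough for full-scale sweeps.

A camera model completes the chain: intensities are scaled by
`exposure_scale` (DN per unit mean speckle intensity, default 60 so the
background sits at about a quarter of the 8-bit range), optionally
multiplied by a static brightness map, read noise of `read_noise_sd`
(default 1 DN) is added, and values are clipped and quantized to the sensor
range. Read-noise quantization is drawn exactly from the discrete
distribution of `round(v + sigma * N)` via a tabulated CDF, and the same
draws are consumed whether or not frames are materialized, so the streamed
GD volume is bit-identical to GD computed from stored frames at the same
seed. The simulator uses its own xoshiro256++ generator seeded from the
scan seed, independent of R's RNG, which makes scans reproducible across
platforms and R versions.

## The scene model

A scene is a calibrated voxel grid (default 256 × 256 px at 16 µm/px — the
pixel size that puts a ~5 cm² field of view on a 1392 × 1040 sensor — and
80 planes at 125 µm) containing:

* **Nematodes** — capsules (cylinder + hemispherical caps) with lengths
  drawn from 200–800 µm (mid-range of the 40–1500 µm envelope), width
  25 µm, random in-plane azimuth, tilt limited to ±30° (animals settle
  roughly horizontally), and slight refractive brightness (×1.5) so they are
  visible in brightfield. A *live* animal carries a decorrelation
  coefficient `rho_live` (default 0.7 at 10 fps — strong frame-to-frame
  decorrelation, as expected for a motile worm whose body moves by more than
  a wavelength between frames). Its *activity footprint* is the body dilated
  by `wriggle_um` (default 45 µm): the animal moves during the 6.4 s stack,
  so the decorrelating region is the area the body sweeps, not its
  instantaneous silhouette. A *dead* (heat-killed) animal keeps the
  background coefficient — temporally indistinguishable from the matrix —
  while remaining slightly bright in brightfield, so it is visible but GD-
  silent. Centroid drift between stage positions is off by default, which
  keeps ground-truth counts exact.
* **Background** — static matrix with `rho_bg = 1`; the "soil" medium adds
  a unit-mean lognormal static brightness texture (`clutter_sd` 0.8,
  correlation length 3 px) emulating refractive-index heterogeneity.
  Crucially this clutter is *static*: it corrupts brightfield images but
  carries no temporal signal.
* **Root** (optional) — a thick capsule whose pixels are driven far above
  sensor full scale, reproducing the raised-exposure trick that saturates
  root tissue: a saturated pixel reads the maximum DN in every frame and
  therefore scores GD = 0, removing the root's own biospeckle.

Placement is rejection-sampled with a minimum in-plane body-segment
separation (default 400 µm). Analysis of the detection pipeline shows that
two parallel animals ~160 µm apart would fuse into one smoothed blob above
the detection threshold, so a 2-sigma spacing rule would not keep the
ground-truth count well defined; 400 µm guarantees the smoothed blobs
separate cleanly below threshold.

The light sheet selects, at each stage position, the slab of the scene
within half a sheet thickness of the focal plane. With the 1 mm
detection-mode sheet stepped at 125 µm (the package default, matching the
automated-detection protocol; 30 µm is the thin rendering-mode sheet) a
single animal contributes activity to about `ceiling(1000/125) = 8`
consecutive positions — deliberate oversampling so small or mobile animals
cannot fall between sections, later merged by 3D connectivity.

## The GD index and its numerical treatment

For each pixel of a 64-frame stack,

$$GD = \sum_i \sum_j \left|I_{i+j} - I_i\right|,$$

the sum of absolute intensity differences over frame pairs. The summation
limits are not standardized; the package default is the full all-pairs sum
(every $i$, every $j \ge 1$ with $i + j \le N$), consistent with reading GD
as the *total* variation within the stack, and a `max_lag` variant is
provided because lag-limited GD is also in use. Under all-pairs the sum is
computed exactly via the sorted-order identity
$\sum_{i<j}|x_i-x_j| = \sum_k (2k-1-N)\,x_{(k)}$ (a per-pixel counting sort
for 8/16-bit data), which turns an $O(N^2)$ pixel loop into $O(N)$ plus a
histogram scan. The largest possible value, $2016 \times 255$ for 64 8-bit
frames, is far inside exact integer range, and a constant pixel scores
exactly zero. GD is not normalized by pair count by default (an option
exists for cross-N comparability).

The transect S/N metric is $SN = (I_s - \langle I\rangle)/\sigma$ computed
along a straight line profile; $\langle I\rangle$ and $\sigma$ are the mean
and *sample* (n−1) standard deviation of **all** samples including the
signal pixel, as the metric's definition gives no grounds for excluding it,
and a zero-variance profile raises an error rather than returning infinity.
One consequence worth stating: with the signal included, SN on an image
where the object dominates the profile is bounded by
$\sqrt{L/w}$ for a transect of $L$ samples crossing an object $w$ samples
wide — so GD S/N values in the hundreds are not reachable under this
estimator, while the *fold change* over brightfield (driven by how close
the brightfield SN is to zero under heavy static scatter) still spans the
published range.

## The detection pipeline

`detect_nematodes()` composes, in order:

1. **GD reconstruction** — one GD image per position, stacked on the
   calibrated voxel grid (16 × 16 × 125 µm by default).
2. **8-bit conversion** — one global min–max affine map of the whole volume
   onto [0, 255], rounded half-up (constant volumes map to 0). A global map
   is used rather than per-slice scaling so that per-slice contrast jumps
   cannot fabricate z-structure.
3. **Boxcar background subtraction** — subtraction of the local
   moving-average mean of radius 2 mm (125 px), applied in 2D within each
   slice (long-range variation arises in the illumination plane), reflect
   padding, negatives clipped; a 3D mode is available. The radius is
   enforced to at least one pixel.
4. **3D Gaussian smoothing** — separable, reflect padding, sigma 80 µm
   converted per axis to voxel units (5 px in-plane, 0.64 voxel in z at
   default calibration), kernels truncated at 4 sigma and L1-normalized.
5. **Thresholded 3D component counting** — binarize at ≥ 40 (8-bit DN),
   label connected components at 26-connectivity (the usual 3D
   object-counter convention; configurable to 18 or 6 — corner adjacency is
   what merges the 8-slab footprint of one animal into one object), discard
   components below 50 voxels ("voxel size of 50" is read as a minimum
   component voxel count, the object counter's size filter), and report
   centroids as unweighted means of member-voxel centers in micrometres
   (0-based voxel indices, origin at the first voxel's center).

The threshold is applied after smoothing, per the stated stage order, and
negative residuals are clipped before smoothing. Because static clutter is
temporally constant, its GD is only the read-noise floor; after global
rescaling, background subtraction and smoothing it sits far below the
threshold, which is why heat-killed animals and soil heterogeneity yield
zero detections while live animals survive all five stages.

## The evaluation experiments

**Count recovery.** `run_recovery_experiment()` sweeps true counts (default
0–20) with replicates (3 clean / 5 soil), one seeded scene and scan per run,
and `summarize_recovery()` regresses detected on inserted counts. Both
per-replicate-row and per-mean regressions are available; the headline
statistic follows the usual presentation of such experiments — mean detected
count per inserted count, free intercept — with a through-origin option
since recovery lines are anchored at zero. Spearman's rank correlation is
computed alongside (exact p for n ≤ 10 without ties, t-approximation
otherwise). R² of a zero-variance detection column is defined as 0.

**S/N fold change.** `run_sn_experiment()` builds single-animal scenes over
a range of static clutter levels (default log-sd 0.5–2.5, 96 scenes, a
1024 px field), orients the body in-plane perpendicular to a full-width
transect through its centroid, and computes SN on one raw brightfield frame
and on the GD image of the same position along the same transect.
`sn_fold_change()` reports per-pair folds `SN_GD / SN_brightfield`,
excluding (with a warning) pairs whose brightfield SN is not positive, plus
mean, standard error, min and max. The batch is larger than the minimum
needed so that the batch *maximum* — the quantity compared against the
published up-to-60-fold gain — is a stable statistic.

## What the simulator does and does not emulate

Emulated: fully developed speckle statistics (exponential intensity,
contrast 1), temporal decorrelation by live animals including the swept
wriggle footprint, static granular clutter of refractive-index-mismatched
soil, sensor saturation of roots, read noise and quantization, the
overlapping-sheet acquisition geometry, and dead animals that are visible
in brightfield yet silent in GD.

Not emulated: optical point-spread functions and diffraction, polarization,
multiple scattering, photobleaching, intra-stack root growth, animal
locomotion between stage positions (off by default so ground truth stays
exact), shot noise (read noise is the only noise source), and spatially
correlated innovations inside active regions. Passing tests therefore
demonstrate that the *algorithms* recover what this class of physics puts
in; they cannot certify performance on real instruments, where optics and
biology add variability the model omits.

## Numerical choices and degenerate inputs

* Half-up rounding (`floor(x + 0.5)`) for quantization and 8-bit rescaling.
* Reflect (half-sample symmetric) padding for boxcar and Gaussian filters;
  circular padding for the stationary field filters.
* Constant volumes rescale to all zeros; constant transects raise an error;
  empty detection results are valid (count 0); an empty S/N batch returns
  an empty summary rather than crashing.
* Scene placement failures (grid too small, separation unattainable) raise
  errors naming the violated constraint.
* Per-position RNG streams are derived as `seed * 2^20 + position`, so any
  position can be re-simulated independently and identically.

## Problem sizes

The bundled experiments run at the acquisition's native size — 80 positions
× 64 frames at 256² px for recovery sweeps, 1024² px single positions for
the S/N batch — with images scaled to keep a full sweep within minutes on
one core; unit tests use 32–256 px grids with 6–16 frames. These sizes are
the package's default study conditions, not limits of the implementation.

## Known limitations

* The AR(1)-plus-camera model has no spatial PSF, so object edges are
  sharper than real optics would give; the 80 µm smoothing stage dominates
  the effective resolution in practice.
* The wriggle dilation treats the swept region as uniformly decorrelating;
  a real animal decorrelates the center of its track more than the edges.
* GD images of the soil medium inherit no *temporal* clutter; colloidal
  Brownian motion of the matching liquid is not modelled, so the simulated
  GD background is cleaner than a real cuvette's.
* The S/N estimator includes the signal pixel in the profile statistics
  (see above), bounding achievable GD S/N by transect geometry.
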