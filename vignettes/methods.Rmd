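---
title: "Methods: radial T-cell density profiling and fibrosis quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial T-cell density profiling and fibrosis quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

The scientific object is the *infiltration gradient*: the density of
labeled T cells as a function of inward Euclidean distance $d$ from the
outer tumor border. Two hypotheses are contrasted:

- **Impeded entry** (a fibrotic capsule filters cells): density follows an
  exponential decay $\rho(d) = A\,e^{-\lambda d}$, with amplitude $A$
  (cells/mm² at the border) and decay rate $\lambda$ (per µm).
- **Unimpeded movement**: density is flat; operationally, the OLS slope of
  $\rho$ on $d$ is not significantly different from zero.

To compare decay *rates* between two groups whose absolute cell numbers are
not comparable (e.g. endogenous vs transferred labeled cells), densities
restricted to the capsule depth $[0, D)$, $D = 250$ µm, are
log-transformed; under the exponential model $\ln\rho$ is linear in $d$
with slope $-\lambda$, so the group difference in decay rate is the
group×distance interaction of the pooled OLS
$\ln\rho \sim d \times \text{group}$, and its t-test is the reported
comparison. This one-test construction was chosen over eyeballing CI
overlap of separate fits; the interaction estimate equals the difference of
the separately fitted slopes algebraically (tested), and on balanced
designs its p-value tracks a Welch-style two-fit comparison (tested with a
documented tolerance of 0.05 on the p scale).

## Estimation details

- The exponential fit is nonlinear least squares, initialized from the
  log-linear fit of the positive-density points. `nls` cannot iterate on
  zero-residual data, so when the initializer already fits to machine
  precision (exact model points, constant profiles) the initializer is
  returned as the solution with zero SEs. Non-convergence on real data is
  an explicit error, never a silent fallback.
- A fit whose $\lambda$ CI touches 0 is flagged `boundary_flat` — the
  exponential degenerates to a flat line — rather than rejected.
- Zero-density bands are **excluded** from the log transform, with a logged
  count. No pseudo-count is added: any offset changes the slope that is
  being tested. The exclusion is itself information (it only occurs when a
  band has no detected cells).
- Fits default to **group-mean profiles** (one point per band, the mean
  across samples). Pooled per-sample points are available
  (`fit$mode = "pooled"`); reports name the mode. Unweighted OLS is the
  default; band-area weighting exists as an option and is always logged.
- Per-band group summaries use the sample (animal/section) as the
  replication unit — never the pixel — to avoid pseudo-replication. SEM is
  reported only for $n \ge 2$; zero-area bands contribute no density value
  (absent, not 0, so 0/0 never enters a group mean).

## Outlier screen

The iterative two-sided Grubbs screen removes the extreme point while
$G = \max_i |x_i-\bar x|/s$ exceeds
$G_{crit} = \frac{N-1}{\sqrt N}\sqrt{\frac{t^2}{N-2+t^2}}$, $t$ the upper
$\alpha/(2N)$ Student-$t$ quantile with $N-2$ df, recomputed after each
removal. $\alpha$ defaults to 0.05 (the screen's named use did not state a
level). Constant data (zero SD) admits no declarable outlier.

# Geometry

- **Distances** are exact Euclidean distance-transform values to the
  nearest outside pixel, computed with the Felzenszwalb–Huttenlocher
  algorithm (exact integers in squared-pixel units; verified against the
  brute-force oracle on random masks). The origin is the **outer** tumor
  border — the capsule's outer edge; the capsule's inner edge is
  descriptive metadata, not a second origin. Holes in a mask are filled
  first: the margin is the external contour.
- **Bands** are uniform and half-open, $[i w, (i+1) w)$, so a cell at
  exactly $D$ falls outside the capsule set (deterministic tie-break).
  $w$ defaults to 50 µm — not dictated by the source analysis, but it keeps
  the 250-µm capsule an integer number of bands — and is recorded in every
  output. `max_depth` must be a multiple of $w$.
- **Binning** uses the distance-map value at the pixel containing the
  cell's intensity-weighted centroid (the per-cell vs per-region ambiguity
  was resolved per-cell). Cells outside the tumor or deeper than the
  partition go to an `unassigned` bucket; counts always conserve.
- **Volumes** follow the Cavalieri principle, $V = \sum_i S_i \,\Delta z$.

# Detection

Threshold + connected components (8-connectivity in 2D, 26 in 3D by
default: conservative merging of diagonal pixels of one cell) with a
physical-area filter; the upper limit of 200 µm² is the stated artifact
cutoff, the lower limit defaults to 0 (none was stated) and is recorded
when set. Centroids are intensity-weighted for sub-pixel stability.
Imaris-style Gaussian blob detection is deliberately *not* used: one
threshold-and-size detector across 2D and 3D keeps the two arms
comparable. Consequences, documented and tested:

- Touching cells merge (no watershed). At the default synthetic densities
  this loses ~10% of cells at the border and biases $\lambda$ low by a few
  percent — within the 15% recovery tolerance of the acceptance suite.
- Component-count monotonicity in the threshold holds on cell-like images
  (uniform-intensity disks over background) and is tested on that class.
  On arbitrary grayscale images it can fail — raising the threshold can
  split a component when a dim bridge drops out — which is a property of
  threshold-plus-components itself, not of this implementation.

The background-derived threshold rule is $\tau = \text{mean} + k\,SD$ of
all pooled cell-channel pixels of control images ($k$ default 5 in the
pipeline config). Fixed instrument thresholds (SHG binarization, sample
data) are required inputs, echoed into every output row: the source
workflows used "fixed threshold levels" without publishing them, and a
false default would silently change every downstream number.

# Fibrosis

SHG collagen density is the white-pixel fraction of the binarized channel
inside a measurement region. The stated 2-px hand-drawing error is
realized as erosion/dilation by a Euclidean disk (isotropic); the reported
interval is the range of fractions over the whole perturbation family with
radius up to `perimeter_error_px`, which brackets the point estimate and
widens monotonically by construction. Multiple regions per sample (the
synthetic stand-in places axis-aligned boxes inscribed mid-annulus) are
averaged unweighted per sample, with per-region values logged — how the
source averaged its boxes was unstated. Trichrome quantification is a
hue/saturation rule (green–cyan arc, hue 90–210°, saturation ≥ 0.2) on a
tissue mask, not stain deconvolution (a non-goal); it is exact on
two-class synthetic renderings.

# The synthetic world

The generator emulates the imaged tissue, not the optics:

- A circular tumor (256-gon outline; sagitta < 10⁻⁴ of the radius) of
  radius 1000 µm in a 2048-µm field at 2 µm/px. Real 3-week tumors are
  millimetres across; the radius also matters statistically (below).
- Cells as uniform-intensity disks, radius 3 µm ± 0.5 µm jitter (no
  measured size distribution exists for the dye-labeled cells; this is a
  simulation choice), peak intensity 100 over truncated-Gaussian background
  (mean 10, SD 2; negative draws are clamped at 0 with a logged count).
- Placement by an **inhomogeneous Poisson process realized by thinning**
  (exact target density, no discretization bias): candidates uniform at the
  law's maximum rate, accepted with probability $e^{-\lambda d}$, where $d$
  is the **exact** point-to-polygon distance — deliberately independent of
  the pixel distance map under test. Defaults: $A = 2000$ cells/mm²,
  $\lambda = 0.01$/µm (≈1100 cells/section, a realistic infiltrate) vs a
  flat 500 cells/mm² for the comparison group; $n = 8$ sections/group.
- Cell overlaps are allowed (no hard-core repulsion); the detector's merge
  behavior is exercised, not hidden.
- Collagen as Bernoulli-saturated pixels: probability 0.6 inside the
  250-µm capsule annulus, 0.1 deeper (0.3 capsule fraction for the
  low-fibrosis cohort).
- Volumetry solids (hemisphere/cylinder/ellipsoid) with analytic volumes,
  sampled at slice mid-depth.

Not emulated: point-spread functions, photobleaching, mosaic stitching
seams, realistic trichrome rendering (a two-class color image suffices to
test the hue rule), anisotropic pixels (rejected, not resampled — the
distance analysis presumes one µm/px scale). A green test therefore
establishes correctness of the measurement and inference chain on tissue
with known geometry and law, not robustness to optical artifacts.

## Why the tumor radius is 1000 µm

Per-band Poisson counts give density variances proportional to 1/area.
With a small tumor (radius ≲ 400 µm) annulus areas shrink quickly with
depth, and that monotone heteroskedasticity inflates the unweighted OLS
flat-line test's type-I error to ~0.09. At radius 1000 µm, band areas over
the first 400 µm vary by < 40% and both the flat-line test and the slope
comparison sit at ~0.052 (calibration study run before the defaults were
frozen; re-verified by the 500-simulation acceptance check, band
[0.03, 0.07]). This is a genuine small-geometry caveat for users: on small
tumors, prefer the area-weighted fit option.

# Determinism and provenance

One config-level seed drives named substreams per sample
(`substream_seed`), so identical config + seed reproduces every CSV
byte-for-byte (tested) while samples stay independent. Every report embeds
a provenance block: package version, seed, MD5 of the canonical resolved
config. Unknown config keys are rejected outright — a typo must not
silently fall back to a default. Dropped entities (oversize components,
zero-density bands, unassigned cells, truncated noise draws) are each
logged with counts that reconcile against the conservation invariants.

# Known limitations

- No watershed splitting or learned segmentation; dense infiltrates
  undercount (quantified above).
- 2D band analysis only (per-section), matching the per-section design;
  no geodesic (in-tissue) distances.
- The TIFF codec covers the baseline uncompressed subset the pipeline
  writes and reads (8/16-bit unsigned, float32, interleaved samples);
  compressed or tiled files are rejected with explicit errors.
- Capsule regions are inputs (ROIs); automatic capsule segmentation from
  SHG is future work.
- Grubbs screening assumes approximate normality of the screened summary
  values; it is a flagging tool, not a replacement for robust analysis.
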