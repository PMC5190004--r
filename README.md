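# tilgrad

Spatial analysis of T-cell infiltration into solid tumors and of
peritumoral fibrosis, for microscopy sections and z-stacks.

## The problem

Solid tumors often grow a dense collagen capsule at their border. Whether
adoptively transferred or host T cells actually penetrate past that capsule
is a spatial question: it is answered not by the total number of cells in a
section, but by how cell density changes with depth. `tilgrad` implements
that analysis as a reusable, tested pipeline:

1. **Detection** — labeled cells in a calibrated section are segmented by an
   intensity threshold and connected components, with an upper size limit of
   200 µm² to reject non-cellular objects (the threshold may be fixed, or
   derived from control tissue as mean + k·SD of background
   autofluorescence). In 3-D stacks the same logic counts spots.
2. **Geometry** — the tumor outline (a polygon ROI or a binary mask) is
   turned into an exact Euclidean distance map of inward distance from the
   outer tumor border, partitioned into concentric half-open bands
   `[d, d+w)` (default w = 50 µm).
3. **Density profile** — cells are binned by the distance at their centroid;
   per-band densities (cells/mm²) are aggregated across samples (the animal
   is the replication unit) into mean ± SEM with t-based 95% CIs.
4. **Inference** — the profile is fit with an exponential decay
   `ρ(d) = A·e^(−λd)` (impeded infiltration) and with a line
   `ρ(d) = a + b·d`, whose slope-zero t-test is the "flat profile" test
   (unimpeded infiltration). To compare two groups, densities within the
   capsule (0–250 µm from the outer border) are log-transformed and the
   group×distance interaction of a pooled OLS gives the slope-difference
   p-value. An iterative two-sided Grubbs screen
   (`G = max|xᵢ−x̄|/s` vs `G_crit(α,N)`) is provided for outlier flagging.
5. **Fibrosis** — the SHG (second-harmonic, fibrillar collagen) channel is
   binarized at a fixed threshold and the white-pixel fraction measured in
   hand-drawn capsule regions, with bounds from eroding/dilating the region
   by a 2-px disk (the stated hand-drawing error). Trichrome sections are
   quantified as green–cyan (hue/saturation rule) area percent of tissue.
6. **Volumetry** — tissue volume from serial sections by the Cavalieri
   principle (Σ areaᵢ × Δz), with homing densities in cells/mm³.

Because the original imaging data of this kind is rarely deposited, the
package ships a synthetic-section generator with exact ground truth (tumor
polygon, capsule annulus, per-cell true border distances from an
inhomogeneous Poisson placement law, Bernoulli collagen fields, analytic
solids for volumetry). Every stage is validated against that ground truth.

## Worked example

Two synthetic cohorts — an exponential-decay group (host T cells present,
fibrotic capsule) and a flat group (T-cell-deficient hosts) — analyzed end
to end:

```r
library(tilgrad)
cfg <- list(seed = 1, figures = FALSE,
            bands = list(width_um = 50, max_depth_um = 250),
            synthetic = list(n_per_group = 4, image_shape_px = c(512, 512),
                             pixel_size_um = 2, tumor_radius_um = 450))
res <- run_infiltration(cfg, output_dir = "out")
res$profile$group_summary
```

Output (abridged; the decay group's banded profile):

```
 band_lo_um band_hi_um n mean_density_per_mm2   sem
          0         50 4               1350.3 61.71
         50        100 4                929.2 19.58
        100        150 4                604.9 16.42
        150        200 4                274.2 44.31
        200        250 4                219.3 26.15

exponential fit, T-cell-sufficient group:
  A = 1726.9 cells/mm^2, lambda = 0.00901 /um (R^2 = 0.986)
flat-line test, T-cell-deficient group: p = 0.098
slope comparison (0-250 um, log scale): delta = 0.00922, p = 5.8e-05
```

Reading: density in the decay group falls ~e-fold every ~110 µm of depth
(λ ≈ 0.009/µm, generated at 0.01/µm); the flat group is not distinguishable
from a horizontal line (p = 0.098 > 0.05); and the two log-scale capsule
slopes differ significantly (p ≈ 6·10⁻⁵). CSV tables
(`cell_records.csv`, `profile_per_sample.csv`, `profile_summary.csv`) and a
JSON report with full provenance (config hash, seed, parameters) are
written to `out/`.

Command line (same sub-stages, exit codes 0/2/3):

```sh
Rscript inst/cli/tilgrad.R run-infiltration --config config.json --out outdir --seed 1
Rscript inst/cli/tilgrad.R run-fibrosis    --config config.json --out outdir
Rscript inst/cli/tilgrad.R volume          --config config.json --out outdir
```

## Documentation

See `vignettes/methods.Rmd` for the model, parameter, and design notes:
what the synthetic generator does and does not emulate, numerical choices
(tie-breaks, boundary fits, zero-density bands), and known limitations.
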