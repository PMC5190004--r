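# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / closed form, not by calling the code they check.

# Brute-force squared Euclidean distance to the nearest outside pixel.
brute_sq_edt <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  off <- which(!mask, arr.ind = TRUE)
  ins <- which(mask, arr.ind = TRUE)
  if (!nrow(off)) stop("oracle needs an outside pixel")
  for (k in seq_len(nrow(ins))) {
    i <- ins[k, 1]; j <- ins[k, 2]
    out[i, j] <- min((off[, 1] - i)^2 + (off[, 2] - j)^2)
  }
  out
}

# Brute-force pairwise segment-crossing simplicity oracle (O(n^2), scalar).
oracle_polygon_simple <- function(v) {
  n <- nrow(v)
  seg <- function(i) list(a = v[i, ], b = v[i %% n + 1, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  hits <- function(p, q, r, s) {
    d1 <- cross(r, s, p); d2 <- cross(r, s, q)
    d3 <- cross(p, q, r); d4 <- cross(p, q, s)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    on <- function(a, b, c) cross(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
    on(r, s, p) || on(r, s, q) || on(p, q, r) || on(p, q, s)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j == i || j == i %% n + 1 || j %% n + 1 == i) next
    si <- seg(i); sj <- seg(j)
    if (hits(si$a, si$b, sj$a, sj$b)) return(FALSE)
  }
  TRUE
}

# Greedy nearest-centroid matching of detected records to true cells within
# a radius; returns recall and precision.
match_detections <- function(det_xy, true_xy, radius_um) {
  if (!nrow(det_xy) || !nrow(true_xy))
    return(list(recall = 0, precision = 0, matched = 0))
  d2 <- outer(det_xy[, 1], true_xy[, 1], "-")^2 +
        outer(det_xy[, 2], true_xy[, 2], "-")^2
  matched <- 0
  used_det <- rep(FALSE, nrow(det_xy)); used_true <- rep(FALSE, nrow(true_xy))
  repeat {
    d2[used_det, ] <- Inf; d2[, used_true] <- Inf
    m <- which.min(d2)
    if (!length(m) || d2[m] > radius_um^2) break
    i <- (m - 1) %% nrow(det_xy) + 1; j <- (m - 1) %/% nrow(det_xy) + 1
    used_det[i] <- TRUE; used_true[j] <- TRUE
    matched <- matched + 1
    if (all(used_det) || all(used_true)) break
  }
  list(recall = matched / nrow(true_xy),
       precision = matched / nrow(det_xy),
       matched = matched)
}

# Expected cell count of the radial law integrated over a circular tumor
# band [lo, hi) um from the border (disk radius R_um), per section.
expected_band_count <- function(law, R_um, lo, hi) {
  f <- if (law$law == "exponential") {
    function(d) law$amplitude_per_mm2 / 1e6 * exp(-law$decay_per_um * d) *
      2 * pi * (R_um - d)
  } else {
    function(d) law$density_per_mm2 / 1e6 * 2 * pi * (R_um - d)
  }
  stats::integrate(f, lo, hi)$value
}

# Small synthetic spec for fast tests: 320 x 320 px at 2 um/px, 300-um tumor.
small_spec <- function(seed = 1, law = list(law = "exponential",
                                            amplitude_per_mm2 = 2000,
                                            decay_per_um = 0.01), ...) {
  synthetic_spec(image_shape_px = c(320, 320), pixel_size_um = 2,
                 tumor = list(center_px = NULL, radius_um = 300),
                 placement_law = law, seed = seed, ...)
}

# Compact pipeline config for determinism/degenerate-input tests.
small_config <- function(seed = 1, groups = NULL, n_per_group = 2) {
  list(seed = seed, figures = FALSE,
       bands = list(width_um = 50, max_depth_um = 250),
       synthetic = list(
         n_per_group = n_per_group,
         image_shape_px = c(320, 320), pixel_size_um = 2,
         tumor_radius_um = 300,
         groups = groups %||% list(
           list(label = "gA", law = "exponential", amplitude_per_mm2 = 2000,
                decay_per_um = 0.01, capsule_fraction = 0.6,
                interior_fraction = 0.1),
           list(label = "gB", law = "flat", density_per_mm2 = 500,
                capsule_fraction = 0.3, interior_fraction = 0.1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
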