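#' Specification for a synthetic tumor section or lymph-node stack
#'
#' Describes the ground-truth world the generator realizes: a roughly
#' circular tumor mass with a fibrotic capsule annulus, point-like labeled
#' cells placed by an inhomogeneous Poisson process whose intensity depends
#' on inward distance from the tumor border, truncated-Gaussian background
#' autofluorescence, and (for volumetry) an analytic solid sampled as serial
#' z slices.
#'
#' Defaults describe a 3-week syngeneic pancreatic tumor imaged at moderate
#' magnification: a 1000-um-radius mass in a 2048 x 2048 um field at 2 um/px,
#' a 250-um fibrotic capsule, 3-um-radius cells at peak intensity 100 over a
#' background of mean 10 and SD 2, and an exponential infiltration law with
#' amplitude 2000 cells/mm^2 at the border decaying at 0.01 per um.
#'
#' @param image_shape_px integer (height, width) in pixels
#' @param pixel_size_um in-plane scale, um per pixel
#' @param tumor list: either `list(center_px = c(x, y), radius_um = r)` or
#'   `list(polygon = <n x 2 matrix of pixel (x, y)>)`
#' @param capsule_width_um capsule annulus depth from the outer border (um)
#' @param placement_law either
#'   `list(law = "exponential", amplitude_per_mm2 = A, decay_per_um = lambda)`
#'   (expected density A exp(-lambda d) at inward distance d) or
#'   `list(law = "flat", density_per_mm2 = rho)`
#' @param cell_radius_um mean rendered cell radius
#' @param cell_radius_jitter_um half-width of uniform radius jitter
#' @param cell_peak_intensity rendered disk intensity (added over background)
#' @param background list(mean, sd) of the Gaussian background, truncated at 0
#' @param collagen list(capsule_fraction, interior_fraction): probability a
#'   pixel of the SHG channel is saturated, inside vs. deeper than the capsule
#' @param n_slices,z_step_um stack geometry for 3D generation
#' @param node list describing the volumetric solid for
#'   [generate_node_stack()]: `shape` one of `"hemisphere"`, `"cylinder"`,
#'   `"ellipsoid"`; `radius_um` (or semi-axes `c(a, b, c)` for ellipsoid);
#'   `n_cells` planted spot count
#' @param seed integer; the same spec with the same seed is bit-identical
#' @return a `SyntheticSpec`
#' @export
synthetic_spec <- function(image_shape_px = c(1024, 1024),
                           pixel_size_um = 2,
                           tumor = list(center_px = NULL, radius_um = 1000),
                           capsule_width_um = 250,
                           placement_law = list(law = "exponential",
                                                amplitude_per_mm2 = 2000,
                                                decay_per_um = 0.01),
                           cell_radius_um = 3,
                           cell_radius_jitter_um = 0.5,
                           cell_peak_intensity = 100,
                           background = list(mean = 10, sd = 2),
                           collagen = list(capsule_fraction = 0.6,
                                           interior_fraction = 0.1),
                           n_slices = 1,
                           z_step_um = 2,
                           node = list(shape = "hemisphere", radius_um = 200,
                                       n_cells = 200),
                           seed = 1L) {
  law <- placement_law$law %||% stop("placement_law$law required")
  if (!law %in% c("exponential", "flat")) stopf("unknown placement law '%s'", law)
  if (law == "exponential") {
    if ((placement_law$amplitude_per_mm2 %||% -1) < 0 ||
        (placement_law$decay_per_um %||% -1) < 0)
      stopf("exponential law needs amplitude_per_mm2 >= 0 and decay_per_um >= 0")
  } else if ((placement_law$density_per_mm2 %||% -1) < 0) {
    stopf("flat law needs density_per_mm2 >= 0")
  }
  if (capsule_width_um < 0) stopf("capsule_width_um must be >= 0")
  for (f in c("capsule_fraction", "interior_fraction")) {
    v <- collagen[[f]] %||% 0
    if (v < 0 || v > 1) stopf("collagen$%s must be in [0, 1]", f)
  }
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  structure(list(image_shape_px = as.integer(image_shape_px),
                 pixel_size_um = pixel_size_um,
                 tumor = tumor, capsule_width_um = capsule_width_um,
                 placement_law = placement_law,
                 cell_radius_um = cell_radius_um,
                 cell_radius_jitter_um = cell_radius_jitter_um,
                 cell_peak_intensity = cell_peak_intensity,
                 background = background, collagen = collagen,
                 n_slices = as.integer(n_slices), z_step_um = z_step_um,
                 node = node, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Tumor outline as an (x, y) pixel-coordinate polygon. Circular tumors are
# approximated by a regular 256-gon (sagitta < 1e-4 of the radius).
tumor_polygon <- function(spec) {
  if (!is.null(spec$tumor$polygon)) return(as.matrix(spec$tumor$polygon))
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  ctr <- spec$tumor$center_px %||% c((nx - 1) / 2, (ny - 1) / 2)
  r_px <- spec$tumor$radius_um / spec$pixel_size_um
  if (ctr[1] - r_px < 0 || ctr[1] + r_px > nx - 1 ||
      ctr[2] - r_px < 0 || ctr[2] + r_px > ny - 1)
    stopf("tumor (radius %g um) does not fit inside the %d x %d px image",
          spec$tumor$radius_um, ny, nx)
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  cbind(ctr[1] + r_px * cos(th), ctr[2] + r_px * sin(th))
}

# Place cells by thinning: a homogeneous Poisson process at the law's
# maximum intensity over the tumor, thinned with acceptance probability
# law(d)/max, where d is the EXACT Euclidean distance from the candidate
# centroid to the tumor boundary polygon (deliberately independent of the
# pixel distance transform under test). Returns centroids in um plus true
# distances. Exposed for law-fidelity testing without paying rendering cost.
#' Sample ground-truth cell placements for a synthetic section
#' @param spec a `SyntheticSpec`
#' @param poly optional precomputed tumor polygon (pixel coordinates)
#' @param mask optional precomputed tumor raster mask
#' @return data.frame with x_um, y_um, true_distance_um
#' @export
place_cells <- function(spec, poly = NULL, mask = NULL) {
  ps <- spec$pixel_size_um
  poly <- poly %||% tumor_polygon(spec)
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  mask <- mask %||% rasterize_polygon(poly, ny, nx)
  area_mm2 <- polygon_area(poly) * ps^2 / UM2_PER_MM2
  law <- spec$placement_law
  max_rate <- if (law$law == "exponential") law$amplitude_per_mm2 else law$density_per_mm2
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      true_distance_um = numeric(0))
  if (max_rate <= 0) return(empty)
  n_cand <- rpois(1, max_rate * area_mm2)
  if (n_cand == 0) return(empty)
  # uniform points inside the polygon by bounding-box rejection
  bb <- apply(poly, 2, range)
  got_x <- numeric(0); got_y <- numeric(0)
  while (length(got_x) < n_cand) {
    need <- n_cand - length(got_x)
    draw <- max(need * 2, 64)
    cx <- runif(draw, bb[1, 1], bb[2, 1])
    cy <- runif(draw, bb[1, 2], bb[2, 2])
    ok <- cpp_points_in_polygon(cx, cy, poly[, 1], poly[, 2])
    # candidate must also fall on an in-mask pixel so that ground truth and
    # the rasterized tumor mask agree at the half-pixel boundary layer
    pxi <- pmin(pmax(round(cy), 0), ny - 1)
    pxj <- pmin(pmax(round(cx), 0), nx - 1)
    ok <- ok & mask[cbind(pxi + 1, pxj + 1)]
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    got_x <- c(got_x, cx[take])
    got_y <- c(got_y, cy[take])
  }
  d_um <- points_to_polygon_boundary(got_x, got_y, poly) * ps
  accept <- if (law$law == "exponential")
    runif(n_cand) < exp(-law$decay_per_um * d_um) else rep(TRUE, n_cand)
  data.frame(x_um = got_x[accept] * ps, y_um = got_y[accept] * ps,
             true_distance_um = d_um[accept])
}

# Truncated-at-zero Gaussian background; negative draws are clamped and the
# clamp count is logged (never silently clipped elsewhere in the pipeline).
truncated_background <- function(n, mean, sd) {
  v <- rnorm(n, mean, sd)
  neg <- v < 0
  if (any(neg)) {
    tg_log("background noise: %d of %d draws truncated at 0", sum(neg), n)
    v[neg] <- 0
  }
  v
}

render_cells <- function(img, cells_px, radii_px, peak) {
  ny <- nrow(img); nx <- ncol(img)
  for (i in seq_len(nrow(cells_px))) {
    cx <- cells_px[i, 1]; cy <- cells_px[i, 2]; r <- radii_px[i]
    x0 <- max(0, floor(cx - r)); x1 <- min(nx - 1, ceiling(cx + r))
    y0 <- max(0, floor(cy - r)); y1 <- min(ny - 1, ceiling(cy + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
    sub <- img[ys + 1, xs + 1, drop = FALSE]
    hit <- dd <= r^2
    sub[hit] <- pmax(sub[hit], peak)
    img[ys + 1, xs + 1] <- sub
  }
  img
}

#' Generate one synthetic tumor section with ground truth
#'
#' Realizes the stated world: cells are placed by thinning a homogeneous Poisson
#' process so that the expected density at inward distance d from the outer
#' tumor border is `A exp(-lambda d)` (exponential law) or `rho` (flat law);
#' each cell is rendered as a disk at peak intensity over truncated-Gaussian
#' background in the `cell_signal` channel; the `collagen_shg` channel is a
#' Bernoulli field of saturated pixels with probability `capsule_fraction`
#' inside the capsule annulus and `interior_fraction` deeper inside the
#' tumor. Identical spec + seed gives bit-identical output.
#'
#' @param spec a `SyntheticSpec`
#' @return list with `stack` (`ImageStack`, channels cell_signal +
#'   collagen_shg), `truth` (list: `true_cells` data.frame with x_um, y_um,
#'   area_um2, true_distance_um; `tumor_mask`; `capsule_mask`;
#'   `placement_law`), and `roi` (tumor outline `RegionOfInterest`)
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  ps <- spec$pixel_size_um
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  poly <- tumor_polygon(spec)
  mask <- rasterize_polygon(poly, ny, nx)
  cells <- place_cells(spec, poly = poly, mask = mask)

  radii_um <- spec$cell_radius_um +
    runif(nrow(cells), -1, 1) * spec$cell_radius_jitter_um
  radii_um <- pmax(radii_um, ps / 2)  # every cell covers >= its own pixel
  cell_img <- matrix(truncated_background(ny * nx, spec$background$mean,
                                          spec$background$sd), ny, nx)
  cell_img <- render_cells(cell_img,
                           cbind(cells$x_um / ps, cells$y_um / ps),
                           radii_um / ps, spec$cell_peak_intensity)

  # capsule annulus from the pixel distance map of the rasterized tumor
  sq <- cpp_sq_edt(mask)
  d_px_map <- sqrt(sq)
  capsule <- mask & (d_px_map * ps < spec$capsule_width_um)
  shg <- matrix(0, ny, nx)
  p_in <- matrix(0, ny, nx)
  p_in[capsule] <- spec$collagen$capsule_fraction %||% 0
  p_in[mask & !capsule] <- spec$collagen$interior_fraction %||% 0
  sat <- matrix(runif(ny * nx) < p_in, ny, nx)
  shg[sat] <- 255

  px <- array(0, dim = c(1L, ny, nx, 2L))
  px[1, , , 1] <- cell_img
  px[1, , , 2] <- shg
  stack <- image_stack(px, pixel_size_um = ps,
                       channel_roles = c("cell_signal", "collagen_shg"),
                       source_id = sprintf("synthetic_section_seed%d", spec$seed))
  truth <- list(
    true_cells = data.frame(x_um = cells$x_um, y_um = cells$y_um,
                            area_um2 = pi * radii_um^2,
                            true_distance_um = cells$true_distance_um),
    tumor_mask = mask, capsule_mask = capsule,
    placement_law = spec$placement_law)
  roi <- region_of_interest(poly, label = "tumor_mask",
                            source_id = stack$source_id)
  list(stack = stack, truth = truth, roi = roi)
}

#' Generate a synthetic tissue stack with analytic volume
#'
#' Serial z slices through a solid of known volume (hemisphere flat side at
#' z = 0, cylinder, or axis-aligned ellipsoid), rendered as a filled tissue
#' cross-section per slice in an `other`-role channel, with `node$n_cells`
#' point cells scattered uniformly inside the solid in a `cell_signal`
#' channel.
#'
#' @param spec a `SyntheticSpec`; uses `node`, `n_slices`, `z_step_um`,
#'   `pixel_size_um`, `image_shape_px`, `background`, `cell_peak_intensity`
#' @return list with `stack` and `truth` (analytic `true_volume_um3`,
#'   per-slice areas, planted cell count and positions)
#' @export
generate_node_stack <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed + 1L)
  ps <- spec$pixel_size_um
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  nz <- spec$n_slices
  if (nz < 1) stopf("n_slices must be >= 1")
  dz <- spec$z_step_um
  shape <- spec$node$shape %||% "hemisphere"
  ctr <- c((nx - 1) / 2, (ny - 1) / 2)
  # cross-section radius (um) at slice center z
  sect_radius <- switch(shape,
    hemisphere = function(z) { r2 <- spec$node$radius_um^2 - z^2
                               ifelse(r2 > 0, sqrt(r2), NA_real_) },
    cylinder = function(z) rep(spec$node$radius_um, length(z)),
    ellipsoid = function(z) {
      ax <- spec$node$radius_um
      if (length(ax) == 1) ax <- rep(ax, 3)
      f <- 1 - (z - ax[3])^2 / ax[3]^2  # ellipsoid sitting on z = 0..2c
      ifelse(f > 0, sqrt(f) * ax[1], NA_real_)
    },
    stopf("unknown node shape '%s'", shape))
  true_volume <- switch(shape,
    hemisphere = 2 / 3 * pi * spec$node$radius_um^3,
    cylinder = pi * spec$node$radius_um^2 * nz * dz,
    ellipsoid = { ax <- spec$node$radius_um
                  if (length(ax) == 1) ax <- rep(ax, 3)
                  4 / 3 * pi * ax[1] * ax[2] * ax[3] })

  n_cells <- spec$node$n_cells %||% 0
  # uniform points inside the solid by rejection in the bounding cylinder/box
  cells <- matrix(numeric(0), 0, 3)
  if (n_cells > 0) {
    zmax <- switch(shape, hemisphere = spec$node$radius_um,
                   cylinder = nz * dz,
                   ellipsoid = { ax <- spec$node$radius_um
                                 if (length(ax) == 1) ax[1] * 2 else ax[3] * 2 })
    rmax <- max(sect_radius(seq(0, zmax, length.out = 101)), na.rm = TRUE)
    while (nrow(cells) < n_cells) {
      m <- (n_cells - nrow(cells)) * 3 + 16
      x <- runif(m, -rmax, rmax); y <- runif(m, -rmax, rmax); z <- runif(m, 0, zmax)
      r_at_z <- sect_radius(z)
      ok <- !is.na(r_at_z) & (x^2 + y^2 <= r_at_z^2)
      cells <- rbind(cells, cbind(x, y, z)[ok, , drop = FALSE])
    }
    cells <- cells[seq_len(n_cells), , drop = FALSE]
  }

  px <- array(0, dim = c(nz, ny, nx, 2L))
  xs_um <- ((0:(nx - 1)) - ctr[1]) * ps
  ys_um <- ((0:(ny - 1)) - ctr[2]) * ps
  slice_areas <- numeric(nz)
  bg <- spec$background
  for (k in seq_len(nz)) {
    zc <- (k - 1) * dz + dz / 2  # slice samples the solid at its mid-depth
    if (shape == "cylinder") zc <- (k - 1) * dz
    r <- sect_radius(zc)
    tissue <- if (is.na(r)) matrix(FALSE, ny, nx) else
      outer(ys_um^2, xs_um^2, "+") <= r^2
    slice_areas[k] <- sum(tissue) * ps^2
    sl <- matrix(truncated_background(ny * nx, bg$mean, bg$sd), ny, nx)
    sl[tissue] <- sl[tissue] + 50  # tissue autofluorescence pedestal
    px[k, , , 2] <- sl
    px[k, , , 1] <- matrix(truncated_background(ny * nx, bg$mean, bg$sd), ny, nx)
  }
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      zi <- pmin(nz, pmax(1, floor(cells[i, 3] / dz) + 1))
      xi <- round(cells[i, 1] / ps + ctr[1]); yi <- round(cells[i, 2] / ps + ctr[2])
      if (xi >= 0 && xi < nx && yi >= 0 && yi < ny)
        px[zi, yi + 1, xi + 1, 1] <- spec$cell_peak_intensity
    }
  }
  stack <- image_stack(px, pixel_size_um = ps, z_step_um = dz,
                       channel_roles = c("cell_signal", "other"),
                       source_id = sprintf("synthetic_node_seed%d", spec$seed))
  list(stack = stack,
       truth = list(true_volume_um3 = true_volume,
                    slice_areas_um2 = slice_areas,
                    n_cells = n_cells,
                    cells_um = cells))
}
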