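#' Tumor border and mask from an ROI polygon or a binary mask
#'
#' For an ROI input the polygon is rasterized (pixel centers inside).
#' For a mask input, holes are filled (the tumor margin is the external
#' contour) and, if several components are present, the largest is kept with
#' a logged warning; its outer boundary is traced as the border polygon.
#'
#' @param x a `RegionOfInterest` or a logical (y, x) matrix
#' @param image_shape_px (height, width) in pixels; required for ROI input
#' @return list with `mask` (logical matrix) and `border` (n x 2 matrix of
#'   0-based (x, y) coordinates)
#' @export
extract_tumor_border <- function(x, image_shape_px = NULL) {
  if (inherits(x, "RegionOfInterest")) {
    if (is.null(image_shape_px)) stopf("image_shape_px required for ROI input")
    mask <- rasterize_polygon(x$vertices, image_shape_px[1], image_shape_px[2])
    if (!any(mask)) stopf("ROI rasterizes to an empty mask")
    return(list(mask = mask, border = x$vertices))
  }
  mask <- x
  if (!is.matrix(mask) || !is.logical(mask)) stopf("mask must be a logical matrix")
  if (!any(mask)) stopf("empty mask")
  lab <- cpp_label2d(mask, 8L)
  npx <- tabulate(lab[lab > 0])
  if (length(npx) > 1) {
    tg_log("extract_tumor_border: %d components; keeping largest (%d px), dropping %s px",
           length(npx), max(npx),
           paste(sort(npx, decreasing = TRUE)[-1], collapse = "+"))
  }
  dominant <- which.max(npx)
  mask <- lab == dominant
  mask <- fill_holes(mask)
  border <- cpp_trace_boundary(mask)
  list(mask = mask, border = border)
}

# Fill interior holes: background components not touching the image frame
# are holes.
fill_holes <- function(mask) {
  bg <- cpp_label2d(!mask, 4L)
  edge_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  edge_ids <- edge_ids[edge_ids > 0]
  hole <- !mask & !(bg %in% edge_ids)
  mask | matrix(hole, nrow(mask), ncol(mask))
}

#' Inward Euclidean distance map of a tumor mask
#'
#' Per-pixel exact Euclidean distance (in micrometres) from each in-tumor
#' pixel to the nearest outside pixel, computed with an exact distance
#' transform. Pixels outside the tumor carry NA. The whole border must be in
#' frame: an all-TRUE mask is rejected.
#'
#' @param mask logical (y, x) tumor mask
#' @param pixel_size_um micrometres per pixel
#' @return a `DistanceMap`: list(values_um matrix with NA outside,
#'   pixel_size_um)
#' @export
compute_distance_map <- function(mask, pixel_size_um) {
  if (!any(mask)) stopf("empty mask")
  if (all(mask)) stopf("mask has no outside pixels: tumor border must be in frame")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  d <- sqrt(cpp_sq_edt(mask)) * pixel_size_um
  d[!mask] <- NA_real_
  structure(list(values_um = d, pixel_size_um = pixel_size_um),
            class = "DistanceMap")
}

#' Partition a distance map into uniform concentric bands
#'
#' Half-open bands `[i*w, (i+1)*w)` from the outer border inward, to
#' `max_depth_um`. A pixel at exactly a band edge belongs to the deeper
#' band. Trailing bands deeper than the tumor's maximum depth are permitted
#' and carry zero area (logged).
#'
#' @param dmap a `DistanceMap`
#' @param band_width_um band width w > 0 (um)
#' @param max_depth_um total depth covered; must be >= w
#' @return a `BandPartition`: data.frame(band, lo_um, hi_um, mid_um, n_px,
#'   area_um2) with attributes `pixel_size_um`, `band_width_um`
#' @export
partition_bands <- function(dmap, band_width_um, max_depth_um) {
  stopifnot(inherits(dmap, "DistanceMap"))
  if (band_width_um <= 0) stopf("band_width_um must be > 0")
  if (max_depth_um < band_width_um) stopf("max_depth_um must be >= band_width_um")
  edges <- seq(0, max_depth_um, by = band_width_um)
  if (abs(edges[length(edges)] - max_depth_um) > 1e-9)
    stopf("max_depth_um (%g) must be a multiple of band_width_um (%g)",
          max_depth_um, band_width_um)
  v <- dmap$values_um[!is.na(dmap$values_um)]
  # half-open [lo, hi): findInterval with left-closed intervals
  bin <- findInterval(v, edges, rightmost.closed = FALSE, left.open = FALSE)
  bin[bin > length(edges) - 1] <- NA  # deeper than max depth
  n_px <- tabulate(bin[!is.na(bin)], nbins = length(edges) - 1)
  if (any(n_px == 0))
    tg_log("partition_bands: %d trailing/empty band(s) with zero area", sum(n_px == 0))
  out <- data.frame(band = seq_len(length(edges) - 1),
                    lo_um = head(edges, -1), hi_um = tail(edges, -1),
                    mid_um = (head(edges, -1) + tail(edges, -1)) / 2,
                    n_px = n_px,
                    area_um2 = n_px * dmap$pixel_size_um^2)
  structure(out, class = c("BandPartition", "data.frame"),
            pixel_size_um = dmap$pixel_size_um, band_width_um = band_width_um,
            max_depth_um = max_depth_um)
}

#' Cavalieri volume estimate from serial section areas
#'
#' Volume = sum of slice areas times the section spacing.
#'
#' @param slice_areas_um2 numeric vector of per-slice tissue areas (um^2)
#' @param z_step_um section spacing (um), > 0
#' @return a `VolumeEstimate`: list(slice_areas_um2, z_step_um, volume_um3,
#'   volume_mm3)
#' @export
cavalieri_volume <- function(slice_areas_um2, z_step_um) {
  if (!length(slice_areas_um2)) stopf("need at least one slice area")
  if (any(slice_areas_um2 < 0)) stopf("slice areas must be >= 0")
  if (z_step_um <= 0) stopf("z_step_um must be > 0")
  v <- sum(slice_areas_um2) * z_step_um
  structure(list(slice_areas_um2 = slice_areas_um2, z_step_um = z_step_um,
                 volume_um3 = v, volume_mm3 = v / UM3_PER_MM3),
            class = "VolumeEstimate")
}

#' @export
print.VolumeEstimate <- function(x, ...) {
  cat(sprintf("VolumeEstimate: %d slices x %g um -> %.6g um^3 (%.6g mm^3)\n",
              length(x$slice_areas_um2), x$z_step_um, x$volume_um3, x$volume_mm3))
  invisible(x)
}

#' Tissue areas per slice by intensity threshold
#'
#' Helper for stack volumetry: per-slice area (um^2) of pixels at or above
#' `tau` in the channel with the given role.
#'
#' @param stack an `ImageStack`
#' @param tau intensity threshold
#' @param role channel role to threshold (default `"other"`, the tissue
#'   channel of synthetic node stacks)
#' @return numeric vector of areas, one per slice
#' @export
slice_tissue_areas <- function(stack, tau, role = "other") {
  stopifnot(inherits(stack, "ImageStack"))
  idx <- which(stack$channel_roles == role)
  if (!length(idx)) stopf("stack has no %s channel", role)
  ps2 <- stack$pixel_size_um^2
  vapply(seq_len(n_slices(stack)), function(z) {
    m <- stack$pixels[z, , , idx[1]]
    sum(m >= tau) * ps2
  }, numeric(1))
}
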