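#' Cell detection parameters
#'
#' Threshold-and-size detection mirrors the original slide analysis: pixels
#' at or above an intensity threshold form candidate components, and
#' components larger than 200 um^2 are discarded as non-cellular (staining
#' artifacts, vessels). There is no stated lower size limit; a nonzero
#' `min_area_um2` may be set to suppress single-pixel noise and is recorded
#' in output provenance.
#'
#' @param threshold absolute intensity cutoff tau (foreground is `>= tau`);
#'   may be left NULL only if resolved later via
#'   [estimate_background_threshold()]
#' @param min_area_um2 lower area bound, default 0
#' @param max_area_um2 upper area bound, default 200
#' @param connectivity 2D pixel connectivity, 4 or 8 (default 8)
#' @param min_volume_um3,max_volume_um3 3D analogues of the area bounds
#' @param connectivity_3d 3D connectivity, 6 or 26 (default 26)
#' @return a `DetectionParams` object
#' @export
detection_params <- function(threshold = NULL, min_area_um2 = 0,
                             max_area_um2 = 200, connectivity = 8,
                             min_volume_um3 = 0, max_volume_um3 = Inf,
                             connectivity_3d = 26) {
  if (!is.null(threshold) && threshold < 0) stopf("threshold must be >= 0")
  if (min_area_um2 >= max_area_um2)
    stopf("min_area_um2 (%g) must be < max_area_um2 (%g)", min_area_um2, max_area_um2)
  if (!connectivity %in% c(4, 8)) stopf("2D connectivity must be 4 or 8")
  if (!connectivity_3d %in% c(6, 26)) stopf("3D connectivity must be 6 or 26")
  structure(list(threshold = threshold, min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2, connectivity = connectivity,
                 min_volume_um3 = min_volume_um3, max_volume_um3 = max_volume_um3,
                 connectivity_3d = connectivity_3d),
            class = "DetectionParams")
}

#' Background-derived detection threshold
#'
#' Pools every cell-channel pixel of the control images (e.g. unlabeled
#' wild-type tissue imaged under identical settings) and returns
#' `tau = mean + k * SD` of the pooled pixel population. This is the
#' principled default when no fixed instrument threshold is available.
#'
#' @param control_images list of `ImageStack`s with a cell_signal channel
#' @param k SD multiplier (>= 0)
#' @return threshold tau (scalar intensity)
#' @export
estimate_background_threshold <- function(control_images, k = 3) {
  if (inherits(control_images, "ImageStack")) control_images <- list(control_images)
  if (!length(control_images)) stopf("need at least one control image")
  if (k < 0) stopf("k must be >= 0")
  pool <- unlist(lapply(control_images, function(s) {
    idx <- which(s$channel_roles == "cell_signal")
    if (!length(idx)) stopf("control image '%s' has no cell_signal channel", s$source_id)
    as.numeric(s$pixels[, , , idx[1]])
  }))
  if (!length(pool)) stopf("empty pixel pool")
  m <- mean(pool)
  s <- if (length(pool) > 1) sd(pool) else 0
  m + k * s
}

#' Detect labeled cells in a single section
#'
#' Thresholds the cell-signal channel, labels connected components, filters
#' them by physical area, and returns one record per surviving component
#' with an intensity-weighted centroid in micrometres (0-based pixel-center
#' origin).
#'
#' @param stack an `ImageStack`; the first slice's cell_signal channel is
#'   analyzed (use [max_intensity_projection()] first for thicker data)
#' @param params a `DetectionParams` with a resolved `threshold`
#' @param sample_id provenance tag copied into every record
#' @return data.frame (class `cell_records`): sample_id, component_id, x_um,
#'   y_um, area_um2, mean_intensity. Attribute `n_filtered` counts
#'   components dropped by the area bounds.
#' @export
detect_cells <- function(stack, params, sample_id = stack$source_id) {
  stopifnot(inherits(stack, "ImageStack"), inherits(params, "DetectionParams"))
  if (is.null(params$threshold)) stopf("detection threshold is not resolved")
  if (is.null(stack$pixel_size_um)) stopf("missing calibration (pixel_size_um)")
  plane <- channel_plane(stack, "cell_signal", z = 1L)
  ps <- stack$pixel_size_um
  fg <- plane >= params$threshold
  empty <- data.frame(sample_id = character(0), component_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  class(empty) <- c("cell_records", "data.frame")
  if (!any(fg)) { attr(empty, "n_filtered") <- 0L; return(empty) }
  lab <- cpp_label2d(fg, as.integer(params$connectivity))
  idx <- which(lab > 0)
  ids <- lab[idx]
  inten <- plane[idx]
  ny <- nrow(plane)
  ys <- (idx - 1) %% ny          # 0-based row
  xs <- (idx - 1) %/% ny         # 0-based col
  npx <- tabulate(ids)
  area <- npx * ps^2
  wsum <- as.numeric(rowsum(inten, ids))
  cx <- as.numeric(rowsum(inten * xs, ids)) / wsum * ps
  cy <- as.numeric(rowsum(inten * ys, ids)) / wsum * ps
  keep <- area >= params$min_area_um2 & area <= params$max_area_um2
  n_filtered <- sum(!keep)
  if (n_filtered)
    tg_log("detect_cells[%s]: %d component(s) outside [%g, %g] um^2 discarded",
           sample_id, n_filtered, params$min_area_um2, params$max_area_um2)
  out <- data.frame(sample_id = rep(sample_id, sum(keep)),
                    component_id = which(keep),
                    x_um = cx[keep], y_um = cy[keep],
                    area_um2 = area[keep],
                    mean_intensity = (wsum / npx)[keep])
  class(out) <- c("cell_records", "data.frame")
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Count labeled spots in a 3D stack
#'
#' Threshold + 3D connected components with a volume filter; the spot-count
#' analogue of [detect_cells()] for z-stacks. Touching blobs merge into one
#' component (no watershed splitting) - a documented limitation shared with
#' the 2D detector. A single-slice stack falls back to [detect_cells()] with
#' a logged notice.
#'
#' @param stack a 3D `ImageStack` with a cell_signal channel
#' @param params `DetectionParams` (uses `threshold`, volume bounds,
#'   `connectivity_3d`)
#' @param sample_id provenance tag
#' @return list with `count` and `records` (data.frame: sample_id,
#'   component_id, x_um, y_um, z_um, volume_um3, mean_intensity)
#' @export
count_spots_3d <- function(stack, params, sample_id = stack$source_id) {
  stopifnot(inherits(stack, "ImageStack"), inherits(params, "DetectionParams"))
  if (is.null(params$threshold)) stopf("detection threshold is not resolved")
  nz <- n_slices(stack)
  if (nz == 1) {
    tg_log("count_spots_3d[%s]: single-slice stack, falling back to detect_cells",
           sample_id)
    rec <- detect_cells(stack, params, sample_id)
    return(list(count = nrow(rec), records = rec))
  }
  idxc <- which(stack$channel_roles == "cell_signal")
  if (!length(idxc)) stopf("stack has no cell_signal channel")
  vol <- stack$pixels[, , , idxc[1]]
  dim(vol) <- dim(stack$pixels)[1:3]  # (z, y, x)
  ps <- stack$pixel_size_um; dz <- stack$z_step_um
  voxel_um3 <- ps^2 * dz
  fg <- vol >= params$threshold
  lab <- cpp_label3d(as.logical(fg), dim(vol), as.integer(params$connectivity_3d))
  idx <- which(lab > 0)
  if (!length(idx)) {
    rec <- data.frame(sample_id = character(0), component_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      volume_um3 = numeric(0), mean_intensity = numeric(0))
    return(list(count = 0L, records = rec))
  }
  ids <- lab[idx]
  inten <- vol[idx]
  d <- dim(vol)
  zc <- (idx - 1) %% d[1]
  rem <- (idx - 1) %/% d[1]
  yc <- rem %% d[2]
  xc <- rem %/% d[2]
  nvx <- tabulate(ids)
  volume <- nvx * voxel_um3
  wsum <- as.numeric(rowsum(inten, ids))
  keep <- volume >= params$min_volume_um3 & volume <= params$max_volume_um3
  if (any(!keep))
    tg_log("count_spots_3d[%s]: %d component(s) outside volume bounds discarded",
           sample_id, sum(!keep))
  rec <- data.frame(sample_id = rep(sample_id, sum(keep)),
                    component_id = which(keep),
                    x_um = (as.numeric(rowsum(inten * xc, ids)) / wsum * ps)[keep],
                    y_um = (as.numeric(rowsum(inten * yc, ids)) / wsum * ps)[keep],
                    z_um = (as.numeric(rowsum(inten * zc, ids)) / wsum * dz)[keep],
                    volume_um3 = volume[keep],
                    mean_intensity = (wsum / nvx)[keep])
  list(count = nrow(rec), records = rec)
}

#' Write cell records to CSV
#' @param records a `cell_records` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cell_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
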