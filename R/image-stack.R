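CHANNEL_ROLES <- c("cell_signal", "collagen_shg", "trichrome_rgb", "other")

#' Construct a calibrated image stack
#'
#' The canonical pixel container for the pipeline: a non-negative intensity
#' array indexed (z, y, x, channel) with physical calibration. In-plane
#' pixels are assumed isotropic (a single micrometres-per-pixel scale);
#' anisotropic data must be resampled upstream. Coordinates are 0-based and
#' refer to pixel centers.
#'
#' @param pixels numeric array; dim (z, y, x, channel). 2D matrices and
#'   (y, x, channel) arrays are promoted to one-slice stacks.
#' @param pixel_size_um micrometres per pixel, in-plane (isotropic)
#' @param z_step_um micrometres between slices; required when more than one
#'   slice, ignored otherwise
#' @param channel_roles character vector, one role per channel, each one of
#'   `"cell_signal"`, `"collagen_shg"`, `"trichrome_rgb"`, `"other"`. At most
#'   one channel may be `cell_signal` and at most one `collagen_shg`.
#' @param source_id free-text provenance string
#' @return an `ImageStack` object
#' @export
image_stack <- function(pixels, pixel_size_um, z_step_um = NULL,
                        channel_roles = NULL, source_id = "") {
  if (is.matrix(pixels)) dim(pixels) <- c(1L, dim(pixels), 1L)
  else if (length(dim(pixels)) == 3L) dim(pixels) <- c(1L, dim(pixels))
  if (length(dim(pixels)) != 4L)
    stopf("pixels must be (z, y, x, channel); got %d dims", length(dim(pixels)))
  if (any(pixels < 0)) stopf("pixel intensities must be non-negative")
  if (!is_count(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single positive number")
  nz <- dim(pixels)[1]; nc <- dim(pixels)[4]
  if (nz > 1) {
    if (is.null(z_step_um) || !is_count(z_step_um) || z_step_um <= 0)
      stopf("z_step_um must be a positive number for a %d-slice stack", nz)
  }
  if (is.null(channel_roles)) channel_roles <- rep("other", nc)
  if (length(channel_roles) != nc)
    stopf("channel_roles has length %d but there are %d channels",
          length(channel_roles), nc)
  bad <- setdiff(channel_roles, CHANNEL_ROLES)
  if (length(bad)) stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  for (r in c("cell_signal", "collagen_shg"))
    if (sum(channel_roles == r) > 1) stopf("at most one %s channel allowed", r)
  structure(list(pixels = pixels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 z_step_um = if (nz > 1) as.numeric(z_step_um) else
                   (if (!is.null(z_step_um)) as.numeric(z_step_um) else NULL),
                 channel_roles = as.character(channel_roles),
                 source_id = as.character(source_id)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d slice(s), %d x %d px, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(x$channel_roles, collapse = ", ")))
  cat(sprintf("  pixel size %.4g um/px%s; source '%s'\n", x$pixel_size_um,
              if (!is.null(x$z_step_um)) sprintf(", z step %.4g um", x$z_step_um) else "",
              x$source_id))
  invisible(x)
}

n_slices <- function(stack) dim(stack$pixels)[1]

# Single (y, x) matrix for the channel with the requested role.
channel_plane <- function(stack, role, z = 1L) {
  idx <- which(stack$channel_roles == role)
  if (!length(idx)) stopf("stack has no %s channel", role)
  m <- stack$pixels[z, , , idx[1]]
  dim(m) <- dim(stack$pixels)[2:3]
  m
}

#' Write an image stack to a TIFF file
#'
#' Writes a multi-page baseline TIFF (one page per slice, channels
#' interleaved) with the calibration metadata embedded as JSON in the
#' ImageDescription tag, so that [read_image_stack()] round-trips exactly.
#'
#' @param stack an `ImageStack`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  desc <- list(tilgrad = list(
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    channel_roles = stack$channel_roles,
    source_id = stack$source_id))
  write_tiff(stack$pixels, path, description = desc)
}

#' Read a TIFF or OME-TIFF into an image stack
#'
#' Calibration is resolved in decreasing precedence: explicit arguments,
#' then a sidecar JSON config, then metadata embedded in the file. A sidecar
#' or argument overriding embedded metadata triggers a logged warning so the
#' override is auditable; missing calibration is an error, never a default.
#'
#' @param path TIFF path
#' @param sidecar optional path to a JSON file (or a named list) with any of
#'   `pixel_size_um`, `z_step_um`, `channel_roles`, `source_id`
#' @param pixel_size_um,z_step_um,channel_roles optional explicit overrides
#' @return an `ImageStack`
#' @export
read_image_stack <- function(path, sidecar = NULL, pixel_size_um = NULL,
                             z_step_um = NULL, channel_roles = NULL) {
  tf <- read_tiff(path)
  pages <- tf$pages
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) stopf("pages of '%s' have differing dimensions", path)
  d <- dims[[1]]
  px <- array(0, dim = c(length(pages), d))
  for (z in seq_along(pages)) px[z, , , ] <- pages[[z]]

  meta <- list()
  if (!is.null(tf$description) && grepl("^\\s*\\{", tf$description)) {
    parsed <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
    if (!is.null(parsed$tilgrad)) meta <- parsed$tilgrad
    else if (!is.null(parsed)) meta <- parsed
  }
  side <- list()
  if (!is.null(sidecar)) {
    side <- if (is.character(sidecar)) jsonlite::fromJSON(sidecar) else sidecar
    for (f in intersect(names(side), c("pixel_size_um", "z_step_um"))) {
      if (!is.null(meta[[f]]) && !isTRUE(all.equal(meta[[f]], side[[f]])))
        warning(sprintf(
          "sidecar %s = %g overrides embedded metadata value %g for '%s'",
          f, side[[f]], meta[[f]], path), call. = FALSE)
    }
  }
  pick <- function(field, explicit) explicit %||% side[[field]] %||% meta[[field]]
  ps <- pick("pixel_size_um", pixel_size_um)
  if (is.null(ps))
    stopf("missing calibration for '%s': pixel_size_um not in metadata, sidecar or arguments",
          path)
  zs <- pick("z_step_um", z_step_um)
  if (length(pages) > 1 && is.null(zs))
    stopf("missing calibration for '%s': z_step_um required for a %d-slice stack",
          path, length(pages))
  roles <- pick("channel_roles", channel_roles)
  sid <- side$source_id %||% meta$source_id %||% path
  image_stack(px, pixel_size_um = ps, z_step_um = zs,
              channel_roles = roles, source_id = sid)
}

#' Maximum-intensity projection over a z range
#'
#' Collapses the slices whose physical z position (slice index times z step,
#' starting at 0) falls inside `z_range_um` to a single slice holding the
#' per-pixel, per-channel maximum. Projection of a single-slice stack is the
#' identity, so projecting twice is idempotent.
#'
#' @param stack an `ImageStack`
#' @param z_range_um numeric length-2 inclusive interval in micrometres, or
#'   NULL for the full stack
#' @return a one-slice `ImageStack`
#' @export
max_intensity_projection <- function(stack, z_range_um = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  nz <- n_slices(stack)
  zpos <- (seq_len(nz) - 1) * (stack$z_step_um %||% 0)
  keep <- if (is.null(z_range_um)) seq_len(nz)
          else which(zpos >= z_range_um[1] & zpos <= z_range_um[2])
  if (!length(keep)) stopf("empty z range: no slice in [%g, %g] um",
                           z_range_um[1], z_range_um[2])
  proj <- stack$pixels[keep[1], , , , drop = FALSE]
  for (z in keep[-1]) proj <- pmax(proj, stack$pixels[z, , , , drop = FALSE])
  image_stack(proj,
              pixel_size_um = stack$pixel_size_um,
              z_step_um = NULL,
              channel_roles = stack$channel_roles,
              source_id = paste0(stack$source_id, "|mip"))
}
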