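#' Assign detected cells to concentric distance bands
#'
#' Each cell takes the distance-map value at the pixel containing its
#' centroid and is assigned to the half-open band `[lo, hi)` containing that
#' distance. Cells outside the tumor mask or at depths beyond the partition
#' are tallied in an `unassigned` bucket, never silently dropped; counts
#' always conserve: `sum(counts) + unassigned == nrow(cells)`.
#'
#' @param cells `cell_records` data.frame (needs x_um, y_um)
#' @param dmap a `DistanceMap` in the same coordinate frame
#' @param bands a `BandPartition` derived from `dmap`
#' @return list with `counts` (integer per band), `unassigned`, and
#'   `distances_um` (per-cell distance, NA when outside the tumor)
#' @export
bin_cells <- function(cells, dmap, bands) {
  stopifnot(inherits(dmap, "DistanceMap"), inherits(bands, "BandPartition"))
  nb <- nrow(bands)
  if (!nrow(cells))
    return(list(counts = integer(nb), unassigned = 0L,
                distances_um = numeric(0)))
  ps <- dmap$pixel_size_um
  ny <- nrow(dmap$values_um); nx <- ncol(dmap$values_um)
  col <- round(cells$x_um / ps)   # 0-based pixel containing the centroid
  row <- round(cells$y_um / ps)
  if (any(col < 0 | col >= nx | row < 0 | row >= ny))
    stopf("cell centroid outside image bounds")
  d <- dmap$values_um[cbind(row + 1, col + 1)]
  edges <- c(bands$lo_um, bands$hi_um[nb])
  bin <- findInterval(d, edges)
  bin[!is.na(bin) & bin > nb] <- NA  # deeper than the partition
  counts <- tabulate(bin[!is.na(bin)], nbins = nb)
  unassigned <- sum(is.na(bin))
  if (unassigned)
    tg_log("bin_cells: %d cell(s) unassigned (outside tumor or beyond max depth)",
           unassigned)
  list(counts = as.integer(counts), unassigned = as.integer(unassigned),
       distances_um = d)
}

#' Build a radial density profile with group summaries
#'
#' Converts per-sample band counts to densities (cells/mm^2; bands with zero
#' area contribute no value rather than 0/0) and aggregates per group across
#' samples: mean, SEM (`SD/sqrt(n)`, reported only for n >= 2) and a
#' t-based 95% confidence interval per band. The aggregation unit is the
#' sample (animal/section), not the pixel, to avoid pseudo-replication.
#'
#' @param samples list; each element list(sample_id, group, counts, bands)
#'   where `bands` is the shared `BandPartition`
#' @param conf_level confidence level for the per-band interval
#' @return a `DensityProfile`: list(per_sample data.frame, group_summary
#'   data.frame, band_edges)
#' @export
build_density_profile <- function(samples, conf_level = 0.95) {
  stopifnot(length(samples) >= 1)
  edges0 <- samples[[1]]$bands[, c("lo_um", "hi_um")]
  per <- do.call(rbind, lapply(samples, function(s) {
    if (!isTRUE(all.equal(s$bands[, c("lo_um", "hi_um")], edges0,
                          check.attributes = FALSE)))
      stopf("samples have mismatched band edges")
    b <- s$bands
    dens <- ifelse(b$area_um2 > 0, s$counts / b$area_um2 * UM2_PER_MM2, NA_real_)
    data.frame(group = s$group, sample_id = s$sample_id, band = b$band,
               band_lo_um = b$lo_um, band_hi_um = b$hi_um, mid_um = b$mid_um,
               count = s$counts, area_um2 = b$area_um2,
               density_per_mm2 = dens)
  }))
  agg <- do.call(rbind, lapply(split(per, list(per$group, per$band), drop = TRUE),
    function(g) {
      x <- g$density_per_mm2[!is.na(g$density_per_mm2)]
      n <- length(x)
      m <- if (n) mean(x) else NA_real_
      sem <- if (n >= 2) sd(x) / sqrt(n) else NA_real_
      ci <- if (n >= 2) m + c(-1, 1) * qt(1 - (1 - conf_level) / 2, n - 1) * sem
            else c(NA_real_, NA_real_)
      data.frame(group = g$group[1], band = g$band[1],
                 band_lo_um = g$band_lo_um[1], band_hi_um = g$band_hi_um[1],
                 mid_um = g$mid_um[1], n = n, mean_density_per_mm2 = m,
                 sem = sem, ci_lo = ci[1], ci_hi = ci[2])
    }))
  agg <- agg[order(agg$group, agg$band), ]
  rownames(agg) <- NULL
  structure(list(per_sample = per, group_summary = agg,
                 band_edges = edges0, conf_level = conf_level),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf("DensityProfile: %d sample(s), %d group(s), %d bands\n",
              length(unique(x$per_sample$sample_id)),
              length(unique(x$per_sample$group)),
              nrow(x$band_edges)))
  print(x$group_summary, ...)
  invisible(x)
}

# (mid_um, density) points for one group, for the regression layer.
# mode "group_means" uses per-band group mean densities (default);
# "pooled" uses every per-sample band density as its own point.
profile_points <- function(profile, group, mode = c("group_means", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "group_means") {
    g <- profile$group_summary[profile$group_summary$group == group, ]
    data.frame(d_um = g$mid_um, density = g$mean_density_per_mm2)[!is.na(g$mean_density_per_mm2), ]
  } else {
    p <- profile$per_sample[profile$per_sample$group == group, ]
    data.frame(d_um = p$mid_um, density = p$density_per_mm2)[!is.na(p$density_per_mm2), ]
  }
}

#' Overall homing density of cells in a section or a tissue volume
#'
#' Count divided by a reference section area (cells/um^2) or tissue volume
#' (cells/mm^3), the standard summary for homing experiments.
#'
#' @param count number of cells (or a `cell_records` data.frame)
#' @param reference_area_um2 total section area in um^2 (2D reference)
#' @param volume a `VolumeEstimate` (3D reference); exactly one reference
#'   must be given
#' @return a `HomingDensity`: list(count, reference, density, unit)
#' @export
homing_density <- function(count, reference_area_um2 = NULL, volume = NULL) {
  if (is.data.frame(count)) count <- nrow(count)
  if (is.null(reference_area_um2) == is.null(volume))
    stopf("supply exactly one of reference_area_um2 or volume")
  if (!is.null(reference_area_um2)) {
    if (reference_area_um2 <= 0) stopf("reference area must be > 0")
    structure(list(count = count, reference = reference_area_um2,
                   density = count / reference_area_um2,
                   unit = "cells/um^2"), class = "HomingDensity")
  } else {
    stopifnot(inherits(volume, "VolumeEstimate"))
    if (volume$volume_mm3 <= 0) stopf("reference volume must be > 0")
    structure(list(count = count, reference = volume$volume_mm3,
                   density = count / volume$volume_mm3,
                   unit = "cells/mm^3"), class = "HomingDensity")
  }
}

#' @export
print.HomingDensity <- function(x, ...) {
  cat(sprintf("HomingDensity: %d cells / %.6g -> %.6g %s\n",
              x$count, x$reference, x$density, x$unit))
  invisible(x)
}

#' Write a density profile to CSV files
#' @param profile a `DensityProfile`
#' @param per_sample_path,summary_path output CSV paths (NULL to skip one)
#' @return invisibly, the paths written
#' @export
write_density_profile <- function(profile, per_sample_path = NULL,
                                  summary_path = NULL) {
  if (!is.null(per_sample_path))
    write.csv(profile$per_sample, per_sample_path, row.names = FALSE)
  if (!is.null(summary_path))
    write.csv(profile$group_summary, summary_path, row.names = FALSE)
  invisible(c(per_sample_path, summary_path))
}
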