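CONFIG_KEYS <- c("mode", "output_dir", "seed", "detection", "bands",
                 "capsule_depth_um", "fit", "fibrosis", "synthetic",
                 "samples", "volume", "figures", "log_level")

default_config <- function() {
  list(
    mode = "synthetic",
    output_dir = "tilgrad_out",
    seed = 1L,
    detection = list(threshold = NULL, k = 5, min_area_um2 = 0,
                     max_area_um2 = 200, connectivity = 8),
    bands = list(width_um = 50, max_depth_um = 400),
    capsule_depth_um = 250,
    fit = list(mode = "group_means", weighting = "none"),
    fibrosis = list(tau_shg = NULL, perimeter_error_px = 2, n_boxes = 4),
    synthetic = list(
      n_per_group = 8,
      image_shape_px = c(1024, 1024),
      pixel_size_um = 2,
      tumor_radius_um = 1000,
      capsule_width_um = 250,
      cell_radius_um = 3,
      cell_peak_intensity = 100,
      background = list(mean = 10, sd = 2),
      groups = list(
        list(label = "host_T_sufficient", law = "exponential",
             amplitude_per_mm2 = 2000, decay_per_um = 0.01,
             capsule_fraction = 0.6, interior_fraction = 0.1),
        list(label = "host_T_deficient", law = "flat",
             density_per_mm2 = 500,
             capsule_fraction = 0.3, interior_fraction = 0.1))),
    samples = NULL,
    volume = list(n_nodes = 5, shape = "hemisphere", radius_um = 200,
                  n_cells = 200, z_step_um = 4, image_shape_px = c(128, 128),
                  pixel_size_um = 4, tissue_tau = 40, cell_tau = 60),
    figures = TRUE,
    log_level = "info")
}

merge_config <- function(base, user, path = "config") {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stopf("unknown %s key(s): %s", path, paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]]) &&
        k != "groups")
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, "$", k))
    else base[k] <- list(user[[k]])
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' JSON configuration merged over documented defaults; unknown keys are
#' rejected (a typo must not silently fall back to a default). See
#' `default_config` in the package sources for the full schema.
#'
#' @param path JSON file path, or a named list of overrides
#' @return resolved config list (class `PipelineConfig`)
#' @export
read_pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (is.character(path)) jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
          else path
  cfg <- merge_config(default_config(), user)
  if (!cfg$mode %in% c("synthetic", "samples")) stopf("mode must be synthetic or samples")
  structure(cfg, class = "PipelineConfig")
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

provenance_block <- function(cfg) {
  list(package = "tilgrad",
       version = as.character(utils::packageVersion("tilgrad")),
       seed = cfg$seed,
       config_hash = config_hash(cfg),
       config = unclass(cfg))
}

synthetic_section_spec <- function(cfg, group, seed) {
  sy <- cfg$synthetic
  law <- if (group$law == "exponential")
    list(law = "exponential", amplitude_per_mm2 = group$amplitude_per_mm2,
         decay_per_um = group$decay_per_um)
  else list(law = "flat", density_per_mm2 = group$density_per_mm2)
  synthetic_spec(
    image_shape_px = sy$image_shape_px,
    pixel_size_um = sy$pixel_size_um,
    tumor = list(center_px = NULL, radius_um = sy$tumor_radius_um),
    capsule_width_um = sy$capsule_width_um,
    placement_law = law,
    cell_radius_um = sy$cell_radius_um,
    cell_peak_intensity = sy$cell_peak_intensity,
    background = sy$background,
    collagen = list(capsule_fraction = group$capsule_fraction %||% 0.6,
                    interior_fraction = group$interior_fraction %||% 0.1),
    seed = seed)
}

resolve_threshold <- function(cfg) {
  det <- cfg$detection
  if (!is.null(det$threshold)) return(det$threshold)
  if (cfg$mode != "synthetic")
    stopf("detection$threshold is required for sample data (no control images given)")
  # background-derived rule on a generated control section (no cells)
  g0 <- list(label = "control", law = "flat", density_per_mm2 = 0,
             capsule_fraction = 0, interior_fraction = 0)
  ctrl <- generate_section(synthetic_section_spec(cfg, g0,
                                                  substream_seed(cfg$seed, 999983L)))
  tau <- estimate_background_threshold(list(ctrl$stack), k = det$k)
  tg_log("resolved detection threshold tau = %.4g (background mean + %g SD)",
         tau, det$k)
  tau
}

process_one_sample <- function(stack, roi, params, bands_cfg, sample_id) {
  geom <- extract_tumor_border(roi, image_shape_px = dim(stack$pixels)[2:3])
  dmap <- compute_distance_map(geom$mask, stack$pixel_size_um)
  bands <- partition_bands(dmap, bands_cfg$width_um, bands_cfg$max_depth_um)
  cells <- detect_cells(stack, params, sample_id = sample_id)
  binned <- bin_cells(cells, dmap, bands)
  list(cells = cells, bands = bands, counts = binned$counts,
       unassigned = binned$unassigned)
}

#' Run the infiltration-gradient analysis end to end
#'
#' Detects cells per sample, builds the banded radial density profile,
#' fits exponential-decay and linear (flat-line) models per group, performs
#' the capsule-restricted log-linear slope comparison between the first two
#' groups, and writes CSV/JSON reports (and figures) with full provenance.
#' In synthetic mode samples are generated from the config's ground-truth
#' spec; in samples mode they are read from the sample table.
#'
#' @param config a config list/path accepted by [read_pipeline_config()]
#' @param output_dir overrides the config's output directory
#' @return report list, invisibly (profile, fits, comparison, paths)
#' @export
run_infiltration <- function(config = NULL, output_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out <- output_dir %||% cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tau <- resolve_threshold(cfg)
  params <- detection_params(threshold = tau,
                             min_area_um2 = cfg$detection$min_area_um2,
                             max_area_um2 = cfg$detection$max_area_um2,
                             connectivity = cfg$detection$connectivity)
  samples <- list()
  all_cells <- list()
  if (cfg$mode == "synthetic") {
    for (gi in seq_along(cfg$synthetic$groups)) {
      grp <- cfg$synthetic$groups[[gi]]
      for (i in seq_len(cfg$synthetic$n_per_group)) {
        sid <- sprintf("%s_s%02d", grp$label, i)
        seed_i <- substream_seed(cfg$seed, gi * 1000L + i)
        sec <- generate_section(synthetic_section_spec(cfg, grp, seed_i))
        res <- tryCatch(
          process_one_sample(sec$stack, sec$roi, params, cfg$bands, sid),
          error = function(e) stopf("stage 'profile' failed for sample %s: %s",
                                    sid, conditionMessage(e)))
        samples[[sid]] <- list(sample_id = sid, group = grp$label,
                               counts = res$counts, bands = res$bands)
        all_cells[[sid]] <- res$cells
      }
    }
  } else {
    tab <- read_sample_table(cfg$samples)
    for (r in seq_len(nrow(tab))) {
      sid <- tab$sample_id[r]
      stack <- tryCatch(read_image_stack(tab$image_path[r]),
                        error = function(e) stopf("stage 'read' failed for sample %s: %s",
                                                  sid, conditionMessage(e)))
      roi <- read_roi(tab$roi_path[r])
      res <- tryCatch(
        process_one_sample(stack, roi, params, cfg$bands, sid),
        error = function(e) stopf("stage 'profile' failed for sample %s: %s",
                                  sid, conditionMessage(e)))
      samples[[sid]] <- list(sample_id = sid, group = tab$group_label[r],
                             counts = res$counts, bands = res$bands)
      all_cells[[sid]] <- res$cells
    }
  }
  profile <- build_density_profile(unname(samples))
  groups <- unique(vapply(samples, `[[`, "", "group"))

  fits <- list()
  for (g in groups) {
    pts <- profile_points(profile, g, mode = cfg$fit$mode)
    fits[[g]] <- list(
      exponential = tryCatch(decayfit_as_list(fit_exponential_decay(pts)),
                             error = function(e) list(error = conditionMessage(e))),
      linear = tryCatch(decayfit_as_list(fit_linear(pts)),
                        error = function(e) list(error = conditionMessage(e))))
  }
  comparison <- if (length(groups) >= 2) {
    gs <- profile$group_summary
    mk <- function(g) {
      s <- gs[gs$group == g, ]
      log_transform_profile(
        data.frame(d_um = s$mid_um, density = s$mean_density_per_mm2,
                   band_lo_um = s$band_lo_um, band_hi_um = s$band_hi_um),
        depth_um = cfg$capsule_depth_um)
    }
    cmp <- compare_slopes(mk(groups[1]), mk(groups[2]), labels = groups[1:2])
    list(groups = groups[1:2],
         slopes = as.list(cmp$slopes), slope_se = as.list(cmp$slope_se),
         delta = cmp$delta, delta_se = cmp$delta_se, t = cmp$t, df = cmp$df,
         p_interaction = cmp$p_interaction,
         fit_range_um = c(0, cfg$capsule_depth_um))
  } else {
    tg_log("run_infiltration: insufficient groups for slope comparison (%d)",
           length(groups))
    list(note = "insufficient groups for slope comparison")
  }

  cells_df <- do.call(rbind, unname(all_cells))
  paths <- list(
    records = file.path(out, "cell_records.csv"),
    per_sample = file.path(out, "profile_per_sample.csv"),
    summary = file.path(out, "profile_summary.csv"),
    report = file.path(out, "infiltration_report.json"))
  write_cell_records(cells_df, paths$records)
  write_density_profile(profile, paths$per_sample, paths$summary)
  report <- list(analysis = "infiltration",
                 threshold = tau,
                 fit_mode = cfg$fit$mode,
                 band_width_um = cfg$bands$width_um,
                 max_depth_um = cfg$bands$max_depth_um,
                 capsule_depth_um = cfg$capsule_depth_um,
                 fits = fits, comparison = comparison,
                 provenance = provenance_block(cfg))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (isTRUE(cfg$figures))
    try(plot_profile_png(profile, fits, file.path(out, "profile.png")),
        silent = TRUE)
  invisible(list(profile = profile, fits = fits, comparison = comparison,
                 cells = cells_df, paths = paths))
}

decayfit_as_list <- function(f) {
  list(model = f$model, estimates = as.list(f$estimates),
       se = as.list(f$se), ci = f$ci, df = f$df,
       p_slope_zero = f$p_slope_zero, rss = f$rss, r_squared = f$r_squared,
       boundary_flat = f$boundary_flat, n = f$n)
}

plot_profile_png <- function(profile, fits, path) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  gs <- profile$group_summary
  groups <- unique(gs$group)
  cols <- seq_along(groups) + 1
  graphics::plot(NA, xlim = range(gs$mid_um), ylim = c(0, max(gs$ci_hi, gs$mean_density_per_mm2, na.rm = TRUE)),
                 xlab = "distance from outer tumor border (um)",
                 ylab = "T cell density (cells/mm^2)")
  for (i in seq_along(groups)) {
    s <- gs[gs$group == groups[i], ]
    graphics::lines(s$mid_um, s$mean_density_per_mm2, col = cols[i], type = "b", pch = 19)
    ok <- !is.na(s$sem)
    graphics::arrows(s$mid_um[ok], s$mean_density_per_mm2[ok] - s$sem[ok],
                     s$mid_um[ok], s$mean_density_per_mm2[ok] + s$sem[ok],
                     angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("topright", legend = groups, col = cols, lty = 1, pch = 19)
  invisible(path)
}

# Axis-aligned square ROI boxes inscribed in the capsule annulus, the
# synthetic stand-in for the hand-placed measurement boxes on stained
# sections. Boxes sit at evenly spaced angles, centered mid-annulus.
capsule_roi_boxes <- function(spec, n_boxes = 4) {
  ps <- spec$pixel_size_um
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  ctr <- spec$tumor$center_px %||% c((nx - 1) / 2, (ny - 1) / 2)
  R <- spec$tumor$radius_um / ps
  w <- spec$capsule_width_um / ps
  side <- 0.6 * w
  rmid <- R - w / 2
  lapply(seq_len(n_boxes), function(j) {
    th <- 2 * pi * (j - 1) / n_boxes
    cx <- ctr[1] + rmid * cos(th); cy <- ctr[2] + rmid * sin(th)
    region_of_interest(rbind(c(cx - side / 2, cy - side / 2),
                             c(cx + side / 2, cy - side / 2),
                             c(cx + side / 2, cy + side / 2),
                             c(cx - side / 2, cy + side / 2)),
                       label = "capsule",
                       source_id = sprintf("capsule_box_%d", j))
  })
}

#' Run the fibrosis (collagen density) analysis end to end
#'
#' Binarizes the SHG channel at the configured fixed threshold, measures the
#' white-pixel fraction in capsule ROI boxes with perimeter-error bounds,
#' averages boxes unweighted per sample, and writes per-ROI and group
#' summary tables. `fibrosis$tau_shg` is required and validated before any
#' image is touched.
#'
#' @param config config list/path accepted by [read_pipeline_config()]
#' @param output_dir overrides the config's output directory
#' @return report list, invisibly (per_roi, per_sample, group_summary)
#' @export
run_fibrosis <- function(config = NULL, output_dir = NULL) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$fibrosis$tau_shg))
    stopf("config error: fibrosis$tau_shg is required (fixed SHG threshold)")
  if (cfg$mode != "synthetic")
    stopf("sample-table fibrosis runs need capsule ROIs per sample; only synthetic mode is bundled")
  out <- output_dir %||% cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (gi in seq_along(cfg$synthetic$groups)) {
    grp <- cfg$synthetic$groups[[gi]]
    for (i in seq_len(cfg$synthetic$n_per_group)) {
      sid <- sprintf("%s_s%02d", grp$label, i)
      seed_i <- substream_seed(cfg$seed, 20000L + gi * 1000L + i)
      spec <- synthetic_section_spec(cfg, grp, seed_i)
      sec <- generate_section(spec)
      bin <- binarize_shg(sec$stack, cfg$fibrosis$tau_shg)
      boxes <- capsule_roi_boxes(spec, cfg$fibrosis$n_boxes)
      for (b in seq_along(boxes)) {
        m <- collagen_density(bin, boxes[[b]],
                              perimeter_error_px = cfg$fibrosis$perimeter_error_px)
        rows[[length(rows) + 1]] <- data.frame(
          group = grp$label, sample_id = sid, region = boxes[[b]]$source_id,
          threshold = cfg$fibrosis$tau_shg,
          fraction = m$fraction, percent = m$percent,
          bound_lo = m$bound_lo, bound_hi = m$bound_hi,
          pixels_total = m$pixels_total, pixels_positive = m$pixels_positive)
      }
    }
  }
  per_roi <- do.call(rbind, rows)
  per_sample <- do.call(rbind, lapply(split(per_roi, per_roi$sample_id), function(s)
    data.frame(group = s$group[1], sample_id = s$sample_id[1],
               mean_fraction = mean(s$fraction),
               bound_lo = mean(s$bound_lo), bound_hi = mean(s$bound_hi))))
  per_sample <- per_sample[order(per_sample$group, per_sample$sample_id), ]
  rownames(per_sample) <- NULL
  group_summary <- do.call(rbind, lapply(split(per_sample, per_sample$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               mean_fraction = mean(g$mean_fraction),
               sd_fraction = sd(g$mean_fraction),
               min_fraction = min(g$mean_fraction),
               max_fraction = max(g$mean_fraction))))
  rownames(group_summary) <- NULL
  paths <- list(per_roi = file.path(out, "collagen_per_roi.csv"),
                per_sample = file.path(out, "collagen_per_sample.csv"),
                summary = file.path(out, "collagen_group_summary.csv"),
                report = file.path(out, "fibrosis_report.json"))
  write.csv(per_roi, paths$per_roi, row.names = FALSE)
  write.csv(per_sample, paths$per_sample, row.names = FALSE)
  write.csv(group_summary, paths$summary, row.names = FALSE)
  jsonlite::write_json(list(analysis = "fibrosis",
                            tau_shg = cfg$fibrosis$tau_shg,
                            perimeter_error_px = cfg$fibrosis$perimeter_error_px,
                            group_summary = group_summary,
                            provenance = provenance_block(cfg)),
                       paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(per_roi = per_roi, per_sample = per_sample,
                 group_summary = group_summary, paths = paths))
}

#' Run the volumetry analysis on synthetic tissue stacks
#'
#' Generates node stacks, estimates each volume by the Cavalieri principle
#' (thresholded tissue area per slice times the z step), counts labeled
#' spots in 3D, and reports homing densities in cells/mm^3.
#'
#' @param config config list/path accepted by [read_pipeline_config()]
#' @param output_dir overrides the config's output directory
#' @return report data.frame, invisibly
#' @export
run_volume <- function(config = NULL, output_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out <- output_dir %||% cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  vc <- cfg$volume
  n_slices <- ceiling(switch(vc$shape,
    hemisphere = vc$radius_um, cylinder = vc$radius_um,
    ellipsoid = 2 * max(vc$radius_um)) / vc$z_step_um)
  rows <- lapply(seq_len(vc$n_nodes), function(i) {
    spec <- synthetic_spec(image_shape_px = vc$image_shape_px,
                           pixel_size_um = vc$pixel_size_um,
                           n_slices = n_slices, z_step_um = vc$z_step_um,
                           node = list(shape = vc$shape, radius_um = vc$radius_um,
                                       n_cells = vc$n_cells),
                           seed = substream_seed(cfg$seed, 30000L + i))
    node <- generate_node_stack(spec)
    areas <- slice_tissue_areas(node$stack, vc$tissue_tau)
    vol <- cavalieri_volume(areas, vc$z_step_um)
    spots <- count_spots_3d(node$stack,
                            detection_params(threshold = vc$cell_tau,
                                             max_area_um2 = Inf),
                            sample_id = sprintf("node%02d", i))
    hd <- homing_density(spots$count, volume = vol)
    data.frame(sample_id = sprintf("node%02d", i),
               n_slices = n_slices, z_step_um = vc$z_step_um,
               volume_mm3 = vol$volume_mm3,
               true_volume_mm3 = node$truth$true_volume_um3 / UM3_PER_MM3,
               spot_count = spots$count, true_count = node$truth$n_cells,
               density_cells_per_mm3 = hd$density)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(out, "volumes.csv"), row.names = FALSE)
  jsonlite::write_json(list(analysis = "volume", table = tab,
                            provenance = provenance_block(cfg)),
                       file.path(out, "volume_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(tab)
}
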