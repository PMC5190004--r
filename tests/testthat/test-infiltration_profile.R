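make_bands <- function(dm, w = 50, depth = 250)
  suppressMessages(partition_bands(dm, w, depth))

test_that("bin_cells: empty input, edge tie-break, conservation, bounds error", {
  sec <- generate_section(small_spec(seed = 2))
  dm <- compute_distance_map(sec$truth$tumor_mask, 2)
  bands <- make_bands(dm)

  none <- data.frame(x_um = numeric(0), y_um = numeric(0))
  b0 <- bin_cells(none, dm, bands)
  expect_equal(sum(b0$counts), 0)
  expect_equal(b0$unassigned, 0L)

  # a cell sitting exactly at a band edge goes to the deeper band: find a
  # pixel whose map distance is exactly representable at an edge
  v <- dm$values_um
  hit <- which(!is.na(v) & v == 100, arr.ind = TRUE)
  if (nrow(hit)) {
    cell <- data.frame(x_um = (hit[1, 2] - 1) * 2, y_um = (hit[1, 1] - 1) * 2)
    b1 <- bin_cells(cell, dm, bands)
    expect_equal(b1$counts[3], 1L)   # band [100, 150), not [50, 100)
    expect_equal(sum(b1$counts), 1L)
  }

  # conservation on detected cells
  rec <- suppressMessages(detect_cells(sec$stack, detection_params(threshold = 20)))
  bn <- suppressMessages(bin_cells(rec, dm, bands))
  expect_identical(sum(bn$counts) + bn$unassigned, nrow(rec))

  out <- data.frame(x_um = 1e6, y_um = 0)
  expect_error(bin_cells(out, dm, bands), "outside image bounds")
})

test_that("planted-cell binning matches the true-distance histogram", {
  sec <- generate_section(small_spec(seed = 13))
  dm <- compute_distance_map(sec$truth$tumor_mask, 2)
  bands <- make_bands(dm)
  tr <- sec$truth$true_cells
  bn <- suppressMessages(bin_cells(tr, dm, bands))
  edges <- c(bands$lo_um, 250)
  true_bin <- findInterval(tr$true_distance_um, edges)
  true_bin[true_bin > 5] <- NA
  # per-cell agreement: the pixel distance map may shift a distance by up to
  # ~1 px relative to the exact polygon distance, so disagreement is only
  # tolerated for cells within one pixel pitch (2 um) of a band edge
  map_bin <- findInterval(bn$distances_um, edges)
  map_bin[!is.na(map_bin) & map_bin > 5] <- NA
  same <- (is.na(true_bin) & is.na(map_bin)) |
          (!is.na(true_bin) & !is.na(map_bin) & true_bin == map_bin)
  near_edge <- vapply(tr$true_distance_um,
                      function(d) min(abs(d - edges)) <= 2, logical(1))
  expect_true(all(same | near_edge))
  expect_gte(mean(same), 0.90)
  # and the aggregate histogram agrees closely
  h_true <- tabulate(true_bin[!is.na(true_bin)], nbins = 5)
  expect_lt(max(abs(h_true - bn$counts)) / max(h_true, 1), 0.06)
})

test_that("density profile: single sample, two-sample SEM, zero-area bands absent", {
  bands <- structure(data.frame(band = 1:2, lo_um = c(0, 50), hi_um = c(50, 100),
                                mid_um = c(25, 75), n_px = c(100, 0),
                                area_um2 = c(1e5, 0)),
                     class = c("BandPartition", "data.frame"))
  one <- build_density_profile(list(list(sample_id = "s1", group = "g",
                                         counts = c(10L, 0L), bands = bands)))
  gs <- one$group_summary
  expect_equal(gs$mean_density_per_mm2[1], 10 / 1e5 * 1e6)
  expect_true(is.na(gs$sem[1]))              # n = 1: SEM absent
  expect_true(is.na(gs$mean_density_per_mm2[2]))  # zero-area band: absent, not 0

  two <- build_density_profile(list(
    list(sample_id = "s1", group = "g", counts = c(1L, 0L), bands = bands),
    list(sample_id = "s2", group = "g", counts = c(2L, 0L), bands = bands)))
  g2 <- two$group_summary
  expect_equal(g2$mean_density_per_mm2[1], 15)   # densities 10 and 20
  expect_equal(g2$sem[1], 5)                     # two-point SEM = |d1-d2|/2
  expect_equal(g2$n[1], 2)

  bad <- bands; bad$hi_um <- c(60, 100); bad$lo_um <- c(0, 60)
  expect_error(build_density_profile(list(
    list(sample_id = "a", group = "g", counts = c(1L, 1L), bands = bands),
    list(sample_id = "b", group = "g", counts = c(1L, 1L), bands = bad))),
    "mismatched band edges")
})

test_that("scale invariance: k-fold counts give k-fold densities and means", {
  sec <- generate_section(small_spec(seed = 4))
  dm <- compute_distance_map(sec$truth$tumor_mask, 2)
  bands <- make_bands(dm)
  base <- lapply(1:3, function(i)
    list(sample_id = paste0("s", i), group = "g",
         counts = as.integer(rpois(nrow(bands), 20 + 5 * i)), bands = bands))
  p1 <- build_density_profile(base)
  p3 <- build_density_profile(lapply(base, function(s) {
    s$counts <- s$counts * 3L; s }))
  expect_equal(p3$group_summary$mean_density_per_mm2,
               3 * p1$group_summary$mean_density_per_mm2)
  expect_equal(p3$group_summary$sem, 3 * p1$group_summary$sem)
})

test_that("t-based CIs cover the flat-law density at ~95%", {
  # pre-binned Poisson world at the shipped default geometry, n = 8 samples
  areas_mm2 <- c(0.30, 0.29, 0.27, 0.26, 0.24)   # annuli of the 1-mm tumor
  rho <- 500
  bands <- structure(data.frame(band = 1:5, lo_um = seq(0, 200, 50),
                                hi_um = seq(50, 250, 50), mid_um = seq(25, 225, 50),
                                n_px = 1L, area_um2 = areas_mm2 * 1e6),
                     class = c("BandPartition", "data.frame"))
  set.seed(99)
  n_rep <- 250
  covered <- matrix(FALSE, n_rep, 5)
  for (r in seq_len(n_rep)) {
    samples <- lapply(1:8, function(i)
      list(sample_id = paste0("s", i), group = "g",
           counts = rpois(5, rho * areas_mm2), bands = bands))
    gs <- build_density_profile(samples)$group_summary
    covered[r, ] <- gs$ci_lo <= rho & rho <= gs$ci_hi
  }
  cov <- colMeans(covered)
  expect_true(all(cov > 0.90 & cov < 0.99))
})

test_that("homing density: exact quotients and unit labels", {
  h <- homing_density(50, reference_area_um2 = 1e6)
  expect_equal(h$density, 5e-5)
  expect_identical(h$unit, "cells/um^2")
  expect_equal(homing_density(0, reference_area_um2 = 100)$density, 0)
  expect_error(homing_density(5, reference_area_um2 = 0), "> 0")
  expect_error(homing_density(5), "exactly one")

  vol <- cavalieri_volume(rep(1e6, 10), 1)   # 1e7 um^3 = 0.01 mm^3
  hv <- homing_density(200, volume = vol)
  expect_equal(hv$density, 200 / 0.01)
  expect_identical(hv$unit, "cells/mm^3")
  expect_equal(hv$density * hv$reference, 200)   # density x reference = count
})

test_that("planted count / Cavalieri volume matches truth / analytic volume within 5%", {
  R <- 200
  spec <- synthetic_spec(image_shape_px = c(128, 128), pixel_size_um = 4,
                         n_slices = 50, z_step_um = R / 50,
                         node = list(shape = "hemisphere", radius_um = R,
                                     n_cells = 150), seed = 17)
  node <- generate_node_stack(spec)
  vol <- cavalieri_volume(slice_tissue_areas(node$stack, 40), R / 50)
  spots <- suppressMessages(count_spots_3d(node$stack,
                                           detection_params(threshold = 60,
                                                            max_area_um2 = Inf)))
  est <- homing_density(spots$count, volume = vol)$density
  truth <- node$truth$n_cells / (node$truth$true_volume_um3 / 1e9)
  expect_lt(abs(est - truth) / truth, 0.08)
})
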