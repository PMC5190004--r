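test_that("extract_tumor_border: square ROI, hole filling, dominant component", {
  roi <- region_of_interest(rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0)))
  g <- extract_tumor_border(roi, image_shape_px = c(120, 120))
  expect_lte(abs(sum(g$mask) - 10000), 4 * 100)  # <= 1-px perimeter ring

  m <- matrix(FALSE, 40, 40); m[5:30, 5:30] <- TRUE; m[12:18, 12:18] <- FALSE
  g2 <- extract_tumor_border(m)
  expect_true(all(g2$mask[12:18, 12:18]))        # hole filled
  expect_equal(sum(g2$mask), 26 * 26)

  m3 <- matrix(FALSE, 60, 60); m3[5:40, 5:40] <- TRUE; m3[50:52, 50:52] <- TRUE
  expect_message(g3 <- extract_tumor_border(m3), "keeping largest")
  expect_equal(sum(g3$mask), 36 * 36)
  expect_error(extract_tumor_border(matrix(FALSE, 5, 5)), "empty")
})

test_that("distance map: boundary pixels, half-plane brute force, disk center", {
  # half-plane: columns 1..31 inside at 2 um/px
  m <- matrix(FALSE, 20, 40); m[, 1:31] <- TRUE
  dm <- compute_distance_map(m, 2)
  # pixel 10 px inside the border (column 22: nearest outside is column 32)
  expect_equal(dm$values_um[10, 22], 10 * 2)
  # pixel adjacent to the border: distance <= one pixel pitch
  expect_lte(dm$values_um[10, 31], 2)
  expect_true(all(is.na(dm$values_um[, 32:40])))

  # brute-force equality on the whole half-plane
  b <- sqrt(brute_sq_edt(m)) * 2
  expect_equal(dm$values_um[m], b[m])

  # disk of radius R px: center distance within half a pixel of R * pixel_size
  n <- 101
  xy <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  disk <- matrix((xy$x - 50)^2 + (xy$y - 50)^2 <= 40^2, n, n)
  dmd <- compute_distance_map(disk, 1.5)
  expect_lt(abs(dmd$values_um[51, 51] - 40 * 1.5), 0.5 * 1.5)

  expect_error(compute_distance_map(matrix(TRUE, 5, 5), 1), "border must be in frame")
  expect_error(compute_distance_map(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("distance map equals brute force on random small masks", {
  set.seed(31)
  for (k in 1:8) {
    m <- matrix(runif(24 * 30) < runif(1, 0.3, 0.7), 24, 30)
    if (!any(m) || all(m)) next
    dm <- compute_distance_map(m, 1)
    expect_equal(dm$values_um[m], sqrt(brute_sq_edt(m))[m])
  }
})

test_that("8-neighbor distance increments never exceed pixel pitch * sqrt(2)", {
  sec <- generate_section(small_spec(seed = 6))
  dm <- compute_distance_map(sec$truth$tumor_mask, 2)
  v <- dm$values_um
  for (sh in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- v[(1 + max(0, sh[1])):(nrow(v) + min(0, sh[1])),
           (1 + max(0, sh[2])):(ncol(v) + min(0, sh[2]))]
    b <- v[(1 - min(0, sh[1])):(nrow(v) - max(0, sh[1])),
           (1 - min(0, sh[2])):(ncol(v) - max(0, sh[2]))]
    d <- abs(a - b)
    expect_lte(max(d[!is.na(d)]), 2 * sqrt(2) + 1e-9)
  }
})

test_that("band partition: one-band cover, analytic annuli, capsule band count, conservation", {
  sec <- generate_section(small_spec(seed = 2))
  dm <- compute_distance_map(sec$truth$tumor_mask, 2)
  one <- partition_bands(dm, 200, 200)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_px[1], sum(dm$values_um < 200, na.rm = TRUE))

  # disk radius 500 um at 1 um/px: band areas within 2% of pi (r1^2 - r2^2)
  n <- 1024
  xy <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  disk <- matrix((xy$x - 511.5)^2 + (xy$y - 511.5)^2 <= 500^2, n, n)
  dmd <- compute_distance_map(disk, 1)
  bands <- suppressMessages(partition_bands(dmd, 50, 250))
  for (i in 1:5) {
    r_out <- 500 - bands$lo_um[i]; r_in <- 500 - bands$hi_um[i]
    analytic <- pi * (r_out^2 - r_in^2)
    expect_lt(abs(bands$area_um2[i] - analytic) / analytic, 0.02)
  }
  # capsule set [0, 250) with w = 50 is exactly the first 5 bands
  expect_equal(sum(bands$hi_um <= 250), 5)

  # conservation: sum of band areas equals covered in-tumor area exactly (px units)
  covered <- sum(dmd$values_um < 250, na.rm = TRUE)
  expect_identical(sum(bands$n_px), covered)

  expect_error(partition_bands(dmd, 50, 40), "max_depth")
})

test_that("cavalieri volume: arithmetic, zeros, hemisphere oracle, convergence in z-step", {
  v <- cavalieri_volume(rep(1000, 10), 2)
  expect_equal(v$volume_um3, 20000)
  expect_equal(cavalieri_volume(rep(0, 5), 3)$volume_um3, 0)
  expect_error(cavalieri_volume(c(10, -1), 2), ">= 0")
  expect_error(cavalieri_volume(numeric(0), 2), "at least one")

  R <- 200; truth <- 2 / 3 * pi * R^3
  errs <- vapply(c(R / 4, R / 10, R / 50), function(dz) {
    spec <- synthetic_spec(image_shape_px = c(128, 128), pixel_size_um = 4,
                           n_slices = ceiling(R / dz), z_step_um = dz,
                           node = list(shape = "hemisphere", radius_um = R,
                                       n_cells = 0), seed = 3)
    st <- generate_node_stack(spec)
    est <- cavalieri_volume(slice_tissue_areas(st$stack, 40), dz)
    abs(est$volume_um3 - truth) / truth
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1])   # error decreases as z-step shrinks
})
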