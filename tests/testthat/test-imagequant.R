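test_that("threshold calibration places the floor between live and dead modes", {
  set.seed(11)
  dead <- list(matrix(rnorm(1e4, 10, 2), 100, 100))
  live <- list(matrix(rnorm(1e4, 100, 10), 100, 100))
  cal <- calibrate_threshold(live, dead)
  expect_lt(abs(cal$global_floor - 55), 2)
  expect_gt(cal$global_floor, 10 + 3 * 2)
  expect_lt(cal$global_floor, 100 - 3 * 10)
  ## inseparable distributions are a calibration error
  expect_error(calibrate_threshold(dead, dead), "separable")
  expect_error(calibrate_threshold(list(), dead), "non-empty")
  ## scale equivariance: scaling intensities scales the floor
  cal2 <- calibrate_threshold(lapply(live, function(m) 3 * m),
                              lapply(dead, function(m) 3 * m))
  expect_equal(cal2$global_floor, 3 * cal$global_floor, tolerance = 1e-10)
  expect_error(calibrate_threshold(live, dead, adaptive_window = 100),
               "odd")
})

test_that("plane segmentation recovers noiseless objects to the boundary ring", {
  cal <- small_params()
  sp <- small_spec()
  ## blank image -> empty mask
  blank <- matrix(sp$background, 200, 200)
  expect_equal(sum(segment_plane(blank, cal)), 0)
  ## noiseless disk of ~400 px segments to within a 1-pixel boundary ring
  img <- matrix(sp$background, 200, 200)
  rr <- row(img) - 100.5; cc <- col(img) - 100.5
  disk <- rr^2 + cc^2 <= (sqrt(400 / pi))^2
  img[disk] <- sp$live_level
  m <- segment_plane(img, cal)
  ring <- 2 * pi * sqrt(400 / pi) + 4
  expect_lt(abs(sum(m) - sum(disk)), ring)
  ## polarity: inverted (dark-object) image gives an empty mask
  inv <- matrix(sp$live_level, 200, 200)
  inv[disk] <- sp$background
  expect_equal(sum(segment_plane(inv, cal)), 0)
  ## idempotence: segmenting a {background, live}-valued mask image
  ## reproduces the mask
  again <- matrix(sp$background, 200, 200)
  again[m] <- sp$live_level
  expect_equal(unclass(segment_plane(again, cal)), unclass(m))
})

test_that("stitching arithmetic, identity and fidelity against direct rendering", {
  ## 1x1 grid: identity
  t1 <- matrix(runif(64), 8, 8)
  expect_equal(stitch_mosaic(list(list(t1)), overlap_px = 2L), t1)
  ## 13x3 of 512 px at 10% overlap: 6044 x 1434 mosaic
  sp13 <- scene_spec(nodule_count = 0L)
  expect_equal(unname(sp13$mosaic_px["cols"]), 13L * 512L - 12L * 51L)
  expect_equal(unname(sp13$mosaic_px["cols"]), 6044L)
  expect_equal(unname(sp13$mosaic_px["rows"]), 1434L)
  ## noiseless stitched plane equals the unsliced scene rendering
  pl <- small_planted()
  mo <- render_tiles(pl$scene, small_spec())
  expect_equal(stitch_mosaic(mo, 1, noise = FALSE),
               render_scene(pl$scene, small_spec(), 1))
  ## missing tile raises a stitching error naming the grid position
  expect_error(stitch_mosaic(list(list(t1, t1), list(t1)), overlap_px = 2L),
               "\\(2, 2\\)")
})

test_that("projection and composite masks obey max/OR semantics", {
  a <- matrix(0, 4, 4); a[1, 1] <- 5
  b <- matrix(1, 4, 4); b[4, 4] <- 7
  mip <- max_intensity_projection(list(a, b))
  expect_true(all(mip >= a) && all(mip >= b))
  expect_equal(mip[1, 1], 5); expect_equal(mip[4, 4], 7)
  expect_equal(max_intensity_projection(list(a)), a)
  expect_error(max_intensity_projection(list()), "non-empty")
  m1 <- matrix(FALSE, 3, 3); m1[1, 1] <- TRUE
  m2 <- matrix(FALSE, 3, 3); m2[3, 3] <- TRUE
  cm <- composite_mask(list(m1, m2))
  expect_equal(sum(cm), 2)
  expect_true(cm[1, 1] && cm[3, 3])
  expect_equal(sum(composite_mask(list(m1 & FALSE, m2 & FALSE))), 0)
  expect_gte(sum(cm), max(sum(m1), sum(m2)))
  expect_error(composite_mask(list()), "non-empty")
  expect_error(max_intensity_projection(list(a, matrix(0, 2, 2))),
               "identical shape")
})

test_that("labeling uses 8-connectivity and size filtering in um^2", {
  ps <- 2.5  # um/px
  ## two objects of 1500 and 2500 um^2; cutoff 2000 keeps only the larger
  m <- matrix(FALSE, 80, 80)
  n1 <- ceiling(1500 / ps^2); n2 <- ceiling(2500 / ps^2)
  m[2:21, 2:13] <- TRUE                  # 20 x 12 = 240 px = 1500 um^2
  m[40:59, 40:59] <- TRUE                # 400 px = 2500 um^2
  stopifnot(240 == n1, 400 == n2)
  lo <- label_and_filter(m, 2000, ps)
  expect_equal(nrow(lo), 1L)
  expect_equal(lo$area_um2, 2500)
  ## tiny positive cutoff keeps everything; total equals mask area
  lo0 <- label_and_filter(m, 1e-6, ps)
  expect_equal(attr(lo0, "total_area_um2"), sum(m) * ps^2)
  expect_equal(nrow(lo0), 2L)
  ## diagonal-touching pixels are one object
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE; d[4, 2] <- TRUE
  expect_equal(nrow(label_and_filter(d, 1e-6, 1)), 1L)
  expect_error(label_and_filter(m, 0, ps), "positive")
  ## seam-spanning flag
  lo2 <- label_and_filter(m, 1e-6, ps, seams = list(rows = 50L, cols = integer(0)))
  expect_equal(lo2$spans_tile_boundary, c(FALSE, TRUE))
})

test_that("channel quantification: streaming equals whole-mosaic exactly", {
  ## scene with objects straddling >= 3 vertical tile seams
  sp <- scene_spec(grid_rows = 2L, grid_cols = 4L, tile_px = 128L,
                   n_planes = 3L, nodule_count = 0L, seed = 9L)
  step <- sp$step_px * sp$pixel_size
  sc <- data.frame(id = 1:4,
                   x_um = c(1, 2, 3, 2.5) * step,
                   y_um = c(80, 150, 220, 300),
                   a_um = c(40, 35, 30, 25), b_um = c(25, 30, 30, 25),
                   phi = c(0, 0.5, 1, 0), plane = c(1L, 2L, 2L, 3L),
                   extent = c(2L, 2L, 3L, 2L), viable = TRUE)
  mo <- render_tiles(sc, sp)
  cal <- small_params()
  qs <- quantify_channel(mo, cal, min_size_um2 = 500, streaming = TRUE)
  qw <- quantify_channel(mo, cal, min_size_um2 = 500, streaming = FALSE)
  expect_identical(qs$live_area_um2, qw$live_area_um2)
  expect_identical(qs$object_count, qw$object_count)
  ## seam-straddling objects are each counted once
  expect_equal(qw$object_count, 4L)
  ## noiseless live area equals the rasterized planted area
  led <- perfushear:::.ledger_from_scene(sc, sp)
  qn <- quantify_channel(mo, cal, min_size_um2 = 500, noise = FALSE)
  expect_equal(qn$live_area_um2, attr(led, "total_pixel_area"),
               tolerance = 1e-12)
  qsn <- quantify_channel(mo, cal, min_size_um2 = 500, noise = FALSE,
                          streaming = TRUE)
  expect_identical(qsn$live_area_um2, qn$live_area_um2)
})

test_that("live area is monotone in the cutoff and sweep matches single runs", {
  pl <- small_planted()
  mo <- render_tiles(pl$scene, small_spec())
  cal <- small_params()
  sw <- quantify_sweep(mo, cal, cutoffs = c(500, 1500, 2500))
  expect_true(all(diff(sw$live_area_um2) <= 0))
  expect_true(all(diff(sw$object_count) <= 0))
  q1 <- quantify_channel(mo, cal, min_size_um2 = 1500)
  expect_equal(sw$live_area_um2[sw$cutoff_um2 == 1500], q1$live_area_um2)
  ## composite-mask area dominates any single plane's area
  planes <- lapply(seq_len(small_spec()$n_planes), function(p)
    segment_plane(stitch_mosaic(mo, p), cal))
  comp <- composite_mask(planes)
  expect_gte(sum(comp), max(vapply(planes, sum, 0)))
})

test_that("normalization to internal controls", {
  ## treated identical to control: mean normalized value 1
  nm <- normalize_to_control(c(2, 4, 6), c(2, 4, 6))
  expect_equal(mean(nm$treated), 1)
  expect_equal(mean(nm$control), 1)
  ## treated at half the control mean: 0.5 each
  nm2 <- normalize_to_control(c(2, 2), c(4, 4))
  expect_equal(nm2$treated, c(0.5, 0.5))
  ## invariance under common scaling
  nm3 <- normalize_to_control(c(20, 20), c(40, 40))
  expect_equal(nm3$treated, nm2$treated)
  expect_error(normalize_to_control(1, numeric(0)), "empty")
  expect_error(normalize_to_control(1, c(0, 0)), "positive")
  ## quant_result objects are accepted
  q <- perfushear:::.quant_result(100, 2L, 500)
  expect_equal(normalize_to_control(list(q), list(q))$treated, 1)
})
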