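test_that("planting nodules gives an exact, deterministic ground-truth ledger", {
  pl <- small_planted()
  led <- pl$ledger
  expect_equal(nrow(led), 12L)
  ## ledger consistency: total = sum of per-nodule areas
  expect_equal(attr(led, "total_viable_area"),
               sum(led$true_area_um2[led$viable]))
  expect_true(all(led$true_area_um2 > 0))
  ## analytic ellipse area: pi a b
  expect_equal(led$true_area_um2, pi * pl$scene$a_um * pl$scene$b_um)
  ## rasterized areas agree with analytic up to a one-pixel boundary ring
  ring <- pi * (pl$scene$a_um + pl$scene$b_um) * small_spec()$pixel_size
  expect_true(all(abs(led$pixel_area_um2 - led$true_area_um2) <= ring))
  ## determinism: same spec and seed, identical ledger
  pl2 <- plant_nodules(small_spec())
  expect_identical(pl2$ledger, led)
  ## a different seed moves the nodules
  pl3 <- plant_nodules(small_spec(seed = 4L))
  expect_false(identical(pl3$ledger$centroid_x_um, led$centroid_x_um))
})

test_that("degenerate scenes behave: empty scene, single known ellipse", {
  sp0 <- small_spec(); sp0$nodule_count <- 0L
  pl0 <- plant_nodules(sp0)
  expect_equal(nrow(pl0$scene), 0L)
  expect_equal(attr(pl0$ledger, "total_viable_area"), 0)
  ## a 50 x 25 um ellipse has area pi * 50 * 25 ~ 3927 um^2
  sc <- data.frame(id = 1L, x_um = 300, y_um = 300, a_um = 50, b_um = 25,
                   phi = 0, plane = 2L, extent = 2L, viable = TRUE)
  led <- perfushear:::.ledger_from_scene(sc, small_spec())
  expect_equal(led$true_area_um2, pi * 50 * 25)
  expect_lt(abs(led$pixel_area_um2 - pi * 50 * 25),
            pi * 75 * small_spec()$pixel_size)
})

test_that("planted scenes exercise tile seams", {
  pl <- small_planted()
  sp <- small_spec()
  seam_x <- (sp$grid_cols %/% 2) * sp$step_px * sp$pixel_size
  d <- abs(pl$scene$x_um - seam_x)
  expect_true(any(d < 1e-9))  # first nodule centred on a vertical seam
})

test_that("rendering: overlap strips identical, noiseless MIP equals the scene", {
  pl <- small_planted()
  sp <- small_spec()
  mo <- render_tiles(pl$scene, sp)
  ## noiseless signal in the overlap strip of horizontally adjacent tiles
  tl <- get_tile(mo, 1, 1, 2, noise = FALSE)
  tr <- get_tile(mo, 1, 2, 2, noise = FALSE)
  ov <- sp$overlap_px
  expect_identical(tl[, (sp$tile_px - ov + 1L):sp$tile_px], tr[, 1:ov])
  ## stitched noiseless plane equals direct scene rendering
  pln <- stitch_mosaic(mo, 2, noise = FALSE)
  expect_equal(pln, render_scene(pl$scene, sp, 2))
  ## noiseless mosaic MIP equals the pixelwise max over scene planes
  planes <- lapply(seq_len(sp$n_planes), function(p)
    stitch_mosaic(mo, p, noise = FALSE))
  mip <- max_intensity_projection(planes)
  direct <- max_intensity_projection(lapply(seq_len(sp$n_planes), function(p)
    render_scene(pl$scene, sp, p)))
  expect_equal(mip, direct)
  ## on-nodule MIP reaches the full live level
  expect_equal(max(mip), sp$live_level)
  ## tile noise is deterministic and independent of visit order
  a <- get_tile(mo, 2, 1, 3)
  b <- get_tile(mo, 1, 2, 1)
  a2 <- get_tile(mo, 2, 1, 3)
  expect_identical(a, a2)
  expect_false(identical(a, b))
})

test_that("background-only scenes render at the background level", {
  sp <- small_spec(); sp$nodule_count <- 0L
  pl <- plant_nodules(sp)
  mo <- render_tiles(pl$scene, sp)
  tile <- get_tile(mo, 1, 1, 1)
  expect_lt(abs(mean(tile) - sp$background),
            3 * stats::sd(tile) / sqrt(length(tile)) + 0.5)
})

test_that("simulated experiments plant survival fractions exactly when noise-free", {
  sp <- small_spec()
  ex <- simulate_experiment(doses = c(0, 500),
                            survival_fractions = c(1, 0.18),
                            replicates = 1L, spec = sp, cv = 0)
  tr <- ex$truth
  a0 <- tr$planted_area_um2[tr$dose == 0]
  a5 <- tr$planted_area_um2[tr$dose == 500]
  expect_equal(a5, 0.18 * a0, tolerance = 1e-12)
  ## all-survival: every dataset equals its control
  ex1 <- simulate_experiment(doses = c(0, 10), survival_fractions = c(1, 1),
                             replicates = 2L, spec = sp, cv = 0)
  expect_equal(ex1$truth$planted_fraction,
               ex1$truth$planted_area_um2 /
                 mean(ex1$truth$planted_area_um2[ex1$truth$dose == 0]))
  expect_equal(unname(tapply(ex1$truth$planted_area_um2, ex1$truth$dose, sum)[1]),
               unname(tapply(ex1$truth$planted_area_um2, ex1$truth$dose, sum)[2]))
  ## invalid fractions rejected
  expect_error(simulate_experiment(doses = c(0, 1),
                                   survival_fractions = c(1, 1.2),
                                   replicates = 1L, spec = sp), "\\[0, 1\\]")
  expect_error(simulate_experiment(doses = c(0, 1),
                                   survival_fractions = c(0.5, 0.5),
                                   replicates = 1L, spec = sp), "dose 0")
})
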