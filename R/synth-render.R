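#' Render a planted scene as a lazy Z-stack tile mosaic
#'
#' Returns a `"zstack_mosaic"` handle; individual tiles are rendered on
#' demand by [get_tile()] with per-tile, per-plane noise streams derived
#' deterministically from the master seed, so results never depend on the
#' order in which tiles are visited and a dataset far larger than memory
#' can be processed tile by tile. The noiseless signal in overlapping
#' strips of adjacent tiles is identical by construction (both tiles read
#' the same underlying scene coordinates).
#'
#' @param scene Per-nodule data frame from [plant_nodules()].
#' @param spec The [scene_spec()] used to plant the scene.
#' @return An object of class `"zstack_mosaic"`.
#' @export
render_tiles <- function(scene, spec) {
  stopifnot(inherits(spec, "scene_spec"), is.data.frame(scene))
  structure(list(scene = scene, spec = spec,
                 grid_rows = spec$grid_rows, grid_cols = spec$grid_cols,
                 tile_px = spec$tile_px, overlap_px = spec$overlap_px,
                 step_px = spec$step_px, n_planes = spec$n_planes,
                 pixel_size = spec$pixel_size, seed = spec$seed),
            class = "zstack_mosaic")
}

#' @export
print.zstack_mosaic <- function(x, ...) {
  cat(sprintf("Z-stack mosaic: %d x %d tiles of %d px, %d planes (lazy render)\n",
              x$grid_rows, x$grid_cols, x$tile_px, x$n_planes))
  invisible(x)
}

## triangular axial intensity weight of a nodule at a given plane
.plane_weight <- function(plane, center, extent) {
  lo <- center - ifelse(extent >= 3L, 1L, 0L)
  off <- plane - center
  hw <- ceiling((extent + 1) / 2)
  inside <- plane >= lo & plane <= lo + extent - 1L
  ifelse(inside, pmax(0, 1 - abs(off) / hw), 0)
}

#' Render the noiseless scene signal over a pixel region
#'
#' Direct rendering of the underlying scene (no tiling, no noise); the
#' oracle against which stitching is tested. Pixel (1, 1) of the output is
#' mosaic pixel (`row0`, `col0`) counted from 0.
#'
#' @param scene,spec As in [render_tiles()].
#' @param plane Z-plane index (1-based).
#' @param row0,col0 0-based mosaic pixel origin of the region.
#' @param nrow,ncol Region size in pixels (defaults: the full mosaic).
#' @return A numeric matrix of noiseless intensities.
#' @export
render_scene <- function(scene, spec, plane, row0 = 0L, col0 = 0L,
                         nrow = spec$mosaic_px[["rows"]],
                         ncol = spec$mosaic_px[["cols"]]) {
  stopifnot(inherits(spec, "scene_spec"))
  img <- matrix(spec$background, nrow, ncol)
  if (nrow(scene) == 0L) return(img)
  ps <- spec$pixel_size
  amp <- spec$live_level - spec$background
  wts <- .plane_weight(plane, scene$plane, scene$extent)
  for (k in which(wts > 0)) {
    nd <- scene[k, ]
    r <- max(nd$a_um, nd$b_um)
    ## nodule bounding box in region-local 1-based pixel indices
    cA <- floor((nd$x_um - r) / ps) - col0
    cB <- ceiling((nd$x_um + r) / ps) - col0
    rA <- floor((nd$y_um - r) / ps) - row0
    rB <- ceiling((nd$y_um + r) / ps) - row0
    cA <- max(1L, cA); cB <- min(ncol, cB + 1L)
    rA <- max(1L, rA); rB <- min(nrow, rB + 1L)
    if (cA > cB || rA > rB) next
    px <- (col0 + seq.int(cA, cB) - 0.5) * ps - nd$x_um
    py <- (row0 + seq.int(rA, rB) - 0.5) * ps - nd$y_um
    cs <- cos(nd$phi); sn <- sin(nd$phi)
    xr <- outer(py, px, function(y, x) (x * cs + y * sn) / nd$a_um)
    yr <- outer(py, px, function(y, x) (-x * sn + y * cs) / nd$b_um)
    hit <- xr^2 + yr^2 <= 1
    blk <- img[rA:rB, cA:cB, drop = FALSE]
    blk[hit] <- spec$background + amp * wts[k]
    img[rA:rB, cA:cB] <- blk
  }
  img
}

## deterministic per-tile/per-plane RNG seed (independent of visit order)
.tile_seed <- function(master, row, col, plane) {
  as.integer((abs(master) %% 1000003L) * 1009L +
               row * 10007L + col * 101L + plane)
}

#' Extract one tile of the mosaic
#'
#' Renders tile (`row`, `col`) at Z-plane `plane`: the noiseless scene
#' signal over the tile's footprint, plus (unless `noise = FALSE`) Poisson
#' shot noise on the signal and additive Gaussian read noise, drawn from
#' the tile's own seeded stream.
#'
#' @param mosaic A `"zstack_mosaic"` from [render_tiles()].
#' @param row,col Tile grid position (1-based).
#' @param plane Z-plane (1-based).
#' @param noise Logical; `FALSE` returns the noiseless signal.
#' @return A `tile_px x tile_px` numeric matrix.
#' @export
get_tile <- function(mosaic, row, col, plane, noise = TRUE) {
  stopifnot(inherits(mosaic, "zstack_mosaic"))
  if (row < 1L || row > mosaic$grid_rows || col < 1L || col > mosaic$grid_cols)
    stop(sprintf("no tile at grid position (%d, %d)", row, col), call. = FALSE)
  if (plane < 1L || plane > mosaic$n_planes)
    stop("plane out of range", call. = FALSE)
  sp <- mosaic$spec
  sig <- render_scene(mosaic$scene, sp, plane,
                      row0 = (row - 1L) * mosaic$step_px,
                      col0 = (col - 1L) * mosaic$step_px,
                      nrow = mosaic$tile_px, ncol = mosaic$tile_px)
  if (!noise) return(sig)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.tile_seed(mosaic$seed, row, col, plane))
  n <- length(sig)
  out <- if (sp$poisson) matrix(stats::rpois(n, sig), nrow(sig), ncol(sig))
         else sig
  out + matrix(stats::rnorm(n, 0, sp$read_noise_sd), nrow(sig), ncol(sig))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Calibration image pairs for threshold setting
#'
#' Emulates the calibration used to bracket the calcein dynamic range:
#' untreated (live, uniformly bright) versus formalin-fixed (dead, i.e.
#' background-only) fields, with the scene's noise model applied.
#'
#' @param spec A [scene_spec()].
#' @param n Number of image pairs.
#' @param size Image side in pixels.
#' @return A list with elements `live` and `dead`, each a list of `n`
#'   matrices.
#' @export
calibration_images <- function(spec, n = 3L, size = 128L) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.tile_seed(spec$seed, 9001L, 9001L, 0L))
  mk <- function(level) replicate(n, {
    sig <- matrix(level, size, size)
    out <- if (spec$poisson) matrix(stats::rpois(size^2, sig), size, size)
           else sig
    out + matrix(stats::rnorm(size^2, 0, spec$read_noise_sd), size, size)
  }, simplify = FALSE)
  list(live = mk(spec$live_level), dead = mk(spec$background))
}
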