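#' Specification of a synthetic calcein-imaging scene
#'
#' Describes the world that the synthetic generator emulates: a confocal
#' tile mosaic of a perfusion channel in which adherent 3D nodules of
#' ovarian cancer appear as bright elliptical calcein-positive objects of
#' roughly 500--3000+ um^2 on a dark background, acquired as a Z-stack
#' (about 15--20 planes at a 10 um step) of 512 x 512 pixel tiles arranged
#' in a 13 x 3 grid with 10% overlap.
#'
#' @param grid_rows,grid_cols Tile grid size (default 3 x 13).
#' @param tile_px Tile side in pixels (default 512).
#' @param overlap Fractional tile overlap (default 0.10; the overlap in
#'   pixels is `round(overlap * tile_px)`).
#' @param pixel_size Lateral pixel size in um/pixel. The acquisition
#'   optics are not calibrated here, so a single configurable value
#'   (default 2.5 um) is used; all area thresholds are stated in um^2 and
#'   converted through `pixel_size^2`.
#' @param n_planes Number of Z planes (default 18).
#' @param z_step Z step in um (default 10).
#' @param nodule_count Number of nodules planted per channel (default 150).
#' @param area_meanlog,area_sdlog Log-normal parameters of the nodule area
#'   distribution in um^2 (defaults centre the distribution near 2500 um^2,
#'   the regime of the 2000 um^2 reference cut-off).
#' @param background,live_level Background and live-signal mean intensities
#'   (arbitrary units). Defaults 10 and 100 give a shot-noise SNR of about
#'   10 at the live level.
#' @param poisson Logical, apply Poisson shot noise.
#' @param read_noise_sd Additive Gaussian read noise s.d.
#' @param seed Master seed; every random draw in the generator derives
#'   from it, so identical specs give bitwise-identical outputs.
#' @return An object of class `"scene_spec"` with derived fields
#'   `overlap_px`, `step_px` (tile pitch), and `mosaic_px` (rows, cols of
#'   the stitched mosaic).
#' @export
scene_spec <- function(grid_rows = 3L, grid_cols = 13L, tile_px = 512L,
                       overlap = 0.10, pixel_size = 2.5,
                       n_planes = 18L, z_step = 10,
                       nodule_count = 150L,
                       area_meanlog = log(2500), area_sdlog = 0.5,
                       background = 10, live_level = 100,
                       poisson = TRUE, read_noise_sd = 2,
                       seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (z_step <= 0) stop("z_step must be positive", call. = FALSE)
  if (live_level <= background)
    stop("live_level must exceed background", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  tile_px <- as.integer(tile_px); n_planes <- as.integer(n_planes)
  if (grid_rows < 1L || grid_cols < 1L || tile_px < 8L || n_planes < 1L)
    stop("invalid grid / tile / plane counts", call. = FALSE)
  overlap_px <- as.integer(round(overlap * tile_px))
  step_px <- tile_px - overlap_px
  structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols, tile_px = tile_px,
    overlap = overlap, overlap_px = overlap_px, step_px = step_px,
    mosaic_px = c(rows = grid_rows * tile_px - (grid_rows - 1L) * overlap_px,
                  cols = grid_cols * tile_px - (grid_cols - 1L) * overlap_px),
    pixel_size = pixel_size, n_planes = n_planes, z_step = z_step,
    nodule_count = as.integer(nodule_count),
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    background = background, live_level = live_level,
    poisson = isTRUE(poisson), read_noise_sd = read_noise_sd,
    seed = as.integer(seed)), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Scene: %d x %d tiles of %d px (%.0f%% overlap), mosaic %d x %d px @ %.2g um/px,\n       %d planes, %d nodules, seed %d\n",
    x$grid_rows, x$grid_cols, x$tile_px, 100 * x$overlap,
    x$mosaic_px["rows"], x$mosaic_px["cols"], x$pixel_size,
    x$n_planes, x$nodule_count, x$seed))
  invisible(x)
}

#' Plant nodules into a scene with an exact ground-truth ledger
#'
#' Draws nodule areas from the scene's log-normal distribution, places the
#' nodules without overlap (rejection sampling on bounding circles) inside
#' the mosaic with a safety margin so no nodule is clipped by the field
#' edge, and records the exact ground truth. When at least 10 nodules are
#' requested, the first one is centred on a vertical tile seam (and, if the
#' grid has more than one row, the second on a horizontal seam) so that
#' cross-tile object merging is always exercised.
#'
#' Each nodule is a filled ellipse; its axial extent spans 2--4 adjacent Z
#' planes with a triangular intensity profile peaking at 1 on the centre
#' plane (so a maximum-intensity projection recovers the full live level).
#'
#' @param spec A [scene_spec()].
#' @return A list with `scene` (per-nodule parameter data frame) and
#'   `ledger` (a `"ground_truth_ledger"` data frame: id, centroid (um),
#'   analytic `true_area_um2` = pi a b, rasterized `pixel_area_um2`,
#'   Z extent and a `viable` flag, with attribute `total_viable_area`).
#' @export
plant_nodules <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$nodule_count
  H <- spec$mosaic_px["rows"] * spec$pixel_size
  W <- spec$mosaic_px["cols"] * spec$pixel_size
  if (n == 0L) {
    scene <- .empty_scene()
    return(list(scene = scene, ledger = .ledger_from_scene(scene, spec)))
  }
  areas <- stats::rlnorm(n, spec$area_meanlog, spec$area_sdlog)
  shape <- stats::runif(n, 1, 2)              # a/b aspect ratio
  a <- sqrt(areas * shape / pi)
  b <- sqrt(areas / (shape * pi))
  phi <- stats::runif(n, 0, pi)
  margin <- a + 2 * spec$pixel_size
  if (any(2 * margin >= pmin(H, W)))
    stop("field too small for requested nodule sizes", call. = FALSE)

  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  force_seam <- n >= 10L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("field too small for requested nodule count", call. = FALSE)
    k <- placed + 1L
    if (force_seam && k == 1L && spec$grid_cols > 1L) {
      seam <- (spec$grid_cols %/% 2) * spec$step_px  # a vertical seam line
      x <- seam * spec$pixel_size
      y <- stats::runif(1, margin[k], H - margin[k])
    } else if (force_seam && k == 2L && spec$grid_rows > 1L) {
      seam <- (spec$grid_rows %/% 2) * spec$step_px
      y <- seam * spec$pixel_size
      x <- stats::runif(1, margin[k], W - margin[k])
    } else {
      x <- stats::runif(1, margin[k], W - margin[k])
      y <- stats::runif(1, margin[k], H - margin[k])
    }
    if (placed > 0L) {
      d <- sqrt((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2)
      if (any(d < a[seq_len(placed)] + a[k] + 2 * spec$pixel_size)) next
    }
    xs[k] <- x; ys[k] <- y
    placed <- k
  }
  extent <- sample(2:4, n, replace = TRUE)
  ## centre plane chosen so the whole extent fits in the stack
  lo_off <- ifelse(extent >= 3L, 1L, 0L)
  hi_off <- extent - 1L - lo_off
  plane <- vapply(seq_len(n), function(k) {
    lo <- 1L + lo_off[k]; hi <- spec$n_planes - hi_off[k]
    if (hi < lo) stop("z-stack too shallow for nodule extent", call. = FALSE)
    as.integer(sample(seq.int(lo, hi), 1L))
  }, 1L)
  scene <- data.frame(id = seq_len(n), x_um = xs, y_um = ys,
                      a_um = a, b_um = b, phi = phi,
                      plane = plane, extent = extent, viable = TRUE)
  list(scene = scene, ledger = .ledger_from_scene(scene, spec))
}

.empty_scene <- function() {
  data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
             a_um = numeric(0), b_um = numeric(0), phi = numeric(0),
             plane = integer(0), extent = integer(0), viable = logical(0))
}

## exact ledger: analytic area plus the rasterized pixel area on the
## mosaic grid (the oracle for segmentation tests)
.ledger_from_scene <- function(scene, spec) {
  n <- nrow(scene)
  pix <- vapply(seq_len(n), function(k)
    .nodule_pixel_count(scene[k, ], spec), 0)
  led <- data.frame(id = scene$id,
                    centroid_x_um = scene$x_um, centroid_y_um = scene$y_um,
                    true_area_um2 = pi * scene$a_um * scene$b_um,
                    pixel_area_um2 = pix * spec$pixel_size^2,
                    z_lo = scene$plane - ifelse(scene$extent >= 3L, 1L, 0L),
                    z_hi = scene$plane + scene$extent - 1L -
                      ifelse(scene$extent >= 3L, 1L, 0L),
                    viable = scene$viable)
  class(led) <- c("ground_truth_ledger", "data.frame")
  attr(led, "total_viable_area") <- sum(led$true_area_um2[led$viable])
  attr(led, "total_pixel_area") <- sum(led$pixel_area_um2[led$viable])
  led
}

.nodule_pixel_count <- function(nd, spec) {
  ps <- spec$pixel_size
  r <- max(nd$a_um, nd$b_um)
  c0 <- max(0L, floor((nd$x_um - r) / ps) - 1L)
  c1 <- min(spec$mosaic_px["cols"] - 1L, ceiling((nd$x_um + r) / ps) + 1L)
  r0 <- max(0L, floor((nd$y_um - r) / ps) - 1L)
  r1 <- min(spec$mosaic_px["rows"] - 1L, ceiling((nd$y_um + r) / ps) + 1L)
  if (c1 < c0 || r1 < r0) return(0)
  px <- (seq.int(c0, c1) + 0.5) * ps - nd$x_um
  py <- (seq.int(r0, r1) + 0.5) * ps - nd$y_um
  cs <- cos(nd$phi); sn <- sin(nd$phi)
  xr <- outer(py, px, function(y, x) (x * cs + y * sn) / nd$a_um)
  yr <- outer(py, px, function(y, x) (-x * sn + y * cs) / nd$b_um)
  sum(xr^2 + yr^2 <= 1)
}
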