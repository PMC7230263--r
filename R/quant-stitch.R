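#' Stitch one Z-plane of a tile mosaic
#'
#' Assembles the tiles of a plane into one mosaic image. Tiles are placed
#' at their nominal grid positions (stage mosaics are pre-registered);
#' overlap strips are fused by pixelwise maximum, which is exact for
#' identical underlying signal and robust to illumination mismatch.
#'
#' @param tiles Either a `"zstack_mosaic"` from [render_tiles()] or a
#'   list-of-lists of matrices (`tiles[[row]][[col]]`) with attributes-free
#'   equal shapes; in the latter case `overlap_px` must be given.
#' @param plane Z-plane to stitch (ignored for a plain tile list).
#' @param overlap_px Overlap in pixels for plain tile lists.
#' @param noise Passed to [get_tile()] for synthetic mosaics.
#' @return The stitched mosaic image (numeric matrix). For the reference
#'   13 x 3 layout of 512 px tiles at 10% overlap the mosaic is
#'   6044 x 1434 pixels (width 13*512 - 12*51).
#' @export
stitch_mosaic <- function(tiles, plane = 1L, overlap_px = NULL, noise = TRUE) {
  if (inherits(tiles, "zstack_mosaic"))
    return(.stitch_region(tiles, plane, noise = noise))
  ## plain list-of-lists of tile matrices
  if (!is.list(tiles) || length(tiles) == 0L)
    stop("tiles must be a zstack_mosaic or a list of tile rows", call. = FALSE)
  if (is.null(overlap_px))
    stop("overlap_px is required for plain tile lists", call. = FALSE)
  nrows <- length(tiles)
  ncols <- length(tiles[[1]])
  t1 <- tiles[[1]][[1]]
  if (!is.matrix(t1)) stop("missing tile at grid position (1, 1)", call. = FALSE)
  tp <- nrow(t1)
  step <- tp - overlap_px
  H <- nrows * tp - (nrows - 1L) * overlap_px
  W <- ncols * tp - (ncols - 1L) * overlap_px
  out <- matrix(-Inf, H, W)
  for (r in seq_len(nrows)) {
    if (length(tiles[[r]]) != ncols)
      stop(sprintf("missing tile at grid position (%d, %d)",
                   r, length(tiles[[r]]) + 1L), call. = FALSE)
    for (c in seq_len(ncols)) {
      tl <- tiles[[r]][[c]]
      if (!is.matrix(tl) || nrow(tl) != tp || ncol(tl) != tp)
        stop(sprintf("missing tile at grid position (%d, %d)", r, c),
             call. = FALSE)
      rr <- (r - 1L) * step + seq_len(tp)
      cc <- (c - 1L) * step + seq_len(tp)
      out[rr, cc] <- pmax(out[rr, cc], tl)
    }
  }
  out
}

## fuse an arbitrary column range [c_lo, c_hi] (1-based mosaic columns) of
## one plane of a synthetic mosaic, full height; fetches only the tiles
## whose footprint intersects the range
.stitch_region <- function(mosaic, plane, c_lo = 1L,
                           c_hi = NULL, noise = TRUE) {
  sp <- mosaic$spec
  H <- sp$mosaic_px[["rows"]]
  W <- sp$mosaic_px[["cols"]]
  if (is.null(c_hi)) c_hi <- W
  stopifnot(c_lo >= 1L, c_hi <= W, c_lo <= c_hi)
  tp <- mosaic$tile_px; step <- mosaic$step_px
  out <- matrix(-Inf, H, c_hi - c_lo + 1L)
  for (tc in seq_len(mosaic$grid_cols)) {
    tc0 <- (tc - 1L) * step + 1L          # first mosaic column of this tile col
    tc1 <- tc0 + tp - 1L
    if (tc1 < c_lo || tc0 > c_hi) next
    keep <- max(tc0, c_lo):min(tc1, c_hi)
    for (tr in seq_len(mosaic$grid_rows)) {
      tl <- get_tile(mosaic, tr, tc, plane, noise = noise)
      rr <- (tr - 1L) * step + seq_len(tp)
      out[rr, keep - c_lo + 1L] <-
        pmax(out[rr, keep - c_lo + 1L], tl[, keep - tc0 + 1L, drop = FALSE])
    }
  }
  out
}
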