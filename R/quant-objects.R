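#' Label connected objects and filter by minimum size
#'
#' Connected components are extracted from the binary mask with
#' 8-connectivity (diagonal-touching pixels belong to one object), areas
#' are converted to um^2 via the pixel size, and objects below the minimum
#' nodule size cut-off are discarded as sub-nodule debris. The reference
#' analyses use a 2000 um^2 cut-off with a 500--3000 um^2 sensitivity
#' sweep.
#'
#' @param mask Logical matrix (a `"binary_mask"` or plain matrix).
#' @param min_size_um2 Minimum object area in um^2; must be positive.
#' @param pixel_size Pixel size in um/pixel.
#' @param seams Optional list with `rows` and `cols` of 0-based mosaic
#'   pixel indices of tile-seam lines; objects whose bounding box crosses
#'   a seam are flagged `spans_tile_boundary`.
#' @return A `"labeled_objects"` data frame with one row per retained
#'   object: `label`, `area_um2`, centroid and bounding box in 0-based
#'   pixel coordinates, and `spans_tile_boundary`. The attribute
#'   `total_area_um2` holds the summed area, `labels` the label matrix.
#' @export
label_and_filter <- function(mask, min_size_um2, pixel_size, seams = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (min_size_um2 <= 0)
    stop("min_size_um2 must be positive", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  lab <- .label_components_8(m)
  n <- attr(lab, "n_labels")
  if (n == 0L) {
    out <- data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      bbox_r0 = integer(0), bbox_r1 = integer(0),
                      bbox_c0 = integer(0), bbox_c1 = integer(0),
                      spans_tile_boundary = logical(0))
  } else {
    idx <- which(lab > 0L)
    lv <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab)         # 0-based
    cols <- (idx - 1L) %/% nrow(lab)
    cnt <- tabulate(lv, n)
    out <- data.frame(
      label = seq_len(n),
      area_um2 = cnt * pixel_size^2,
      centroid_row = as.numeric(tapply(rows, lv, mean)),
      centroid_col = as.numeric(tapply(cols, lv, mean)),
      bbox_r0 = as.integer(tapply(rows, lv, min)),
      bbox_r1 = as.integer(tapply(rows, lv, max)),
      bbox_c0 = as.integer(tapply(cols, lv, min)),
      bbox_c1 = as.integer(tapply(cols, lv, max)))
    out$spans_tile_boundary <- if (is.null(seams)) NA else
      vapply(seq_len(n), function(k)
        any(seams$cols > out$bbox_c0[k] & seams$cols <= out$bbox_c1[k]) ||
        any(seams$rows > out$bbox_r0[k] & seams$rows <= out$bbox_r1[k]),
        TRUE)
    out <- out[out$area_um2 >= min_size_um2, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("labeled_objects", "data.frame")
  attr(out, "total_area_um2") <- sum(out$area_um2)
  attr(out, "min_size_um2") <- min_size_um2
  attr(out, "labels") <- lab
  out
}

#' Quantify total viable tumor area of one channel
#'
#' The full quantification pipeline for a Z-stack mosaic: each plane is
#' stitched and segmented, the per-plane masks are projected into a
#' composite binary mask, connected objects are size-filtered, and the
#' retained areas are summed. (The product of composite mask and MIP used
#' for visualization has the composite mask as its nonzero support, so
#' areas are computed from the mask directly.)
#'
#' With `streaming = TRUE` the mosaic is processed in vertical bands of
#' tile columns: each band is segmented with a halo wide enough to make
#' the adaptive threshold identical to the whole-mosaic computation, and
#' objects touching a band seam are merged by union-find, so the streaming
#' result is *identical* to the whole-mosaic result while only a couple of
#' tile columns (at most two grid rows' worth of tiles) are ever resident.
#'
#' @param mosaic A `"zstack_mosaic"`.
#' @param params `"calibration_params"` from [calibrate_threshold()].
#' @param min_size_um2 Minimum nodule size cut-off in um^2 (default 2000).
#' @param streaming Logical; use the memory-aware tile-band path.
#' @param noise Logical; passed to the tile renderer (synthetic data).
#' @return A `"quant_result"`: `live_area_um2`, `object_count`,
#'   `min_size_cutoff_um2`, `normalized_area` (`NA` until
#'   [normalize_to_control()]).
#' @export
quantify_channel <- function(mosaic, params, min_size_um2 = 2000,
                             streaming = FALSE, noise = TRUE) {
  if (min_size_um2 <= 0) stop("min_size_um2 must be positive", call. = FALSE)
  areas <- .channel_object_areas(mosaic, params, streaming, noise)
  keep <- areas >= min_size_um2
  .quant_result(sum(areas[keep]), sum(keep), min_size_um2)
}

#' Quantify one channel at several size cut-offs
#'
#' Computes the composite mask and object areas once and applies every
#' cut-off to the same objects, as in the 500--3000 um^2 sensitivity
#' sweep.
#'
#' @inheritParams quantify_channel
#' @param cutoffs Vector of minimum object areas in um^2.
#' @return A data frame with one row per cut-off: `cutoff_um2`,
#'   `live_area_um2`, `object_count`.
#' @export
quantify_sweep <- function(mosaic, params,
                           cutoffs = seq(500, 3000, by = 500),
                           streaming = FALSE, noise = TRUE) {
  if (any(cutoffs <= 0)) stop("cutoffs must be positive", call. = FALSE)
  areas <- .channel_object_areas(mosaic, params, streaming, noise)
  do.call(rbind, lapply(cutoffs, function(ct) {
    keep <- areas >= ct
    data.frame(cutoff_um2 = ct, live_area_um2 = sum(areas[keep]),
               object_count = sum(keep))
  }))
}

## object areas (um^2, unfiltered) of the composite-mask objects of one
## channel, by either the whole-mosaic or the streaming path
.channel_object_areas <- function(mosaic, params, streaming, noise) {
  stopifnot(inherits(mosaic, "zstack_mosaic"),
            inherits(params, "calibration_params"))
  if (streaming)
    return(.streaming_object_areas(mosaic, params, noise))
  masks <- lapply(seq_len(mosaic$n_planes), function(p)
    segment_plane(stitch_mosaic(mosaic, p, noise = noise), params))
  comp <- composite_mask(masks)
  lab <- .label_components_8(matrix(as.logical(comp), nrow(comp), ncol(comp)))
  n <- attr(lab, "n_labels")
  if (n == 0L) return(numeric(0))
  tabulate(lab[lab > 0L], n) * mosaic$pixel_size^2
}

.quant_result <- function(area, count, cutoff) {
  structure(list(live_area_um2 = area, object_count = count,
                 min_size_cutoff_um2 = cutoff, normalized_area = NA_real_),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Viable tumor area: %.0f um^2 in %d objects (cutoff %g um^2)%s\n",
              x$live_area_um2, x$object_count, x$min_size_cutoff_um2,
              if (is.na(x$normalized_area)) ""
              else sprintf(", normalized %.3f", x$normalized_area)))
  invisible(x)
}

## Streaming (memory-aware) quantification over vertical tile-column
## bands. Band boundaries split the tile overlaps at their midpoints; each
## band is segmented over [lo - halo, hi + halo] so every owned pixel sees
## its complete adaptive-threshold window, guaranteeing bitwise equality
## with the whole-mosaic path. Objects are merged across band seams with
## union-find on the 8-neighbourhood of the seam columns.
.streaming_object_areas <- function(mosaic, params, noise) {
  sp <- mosaic$spec
  W <- sp$mosaic_px[["cols"]]
  halo <- params$adaptive_window %/% 2L
  nb <- mosaic$grid_cols
  splits <- if (nb > 1L)
    (seq_len(nb - 1L)) * mosaic$step_px + mosaic$overlap_px %/% 2L else integer(0)
  lo_all <- c(1L, splits + 1L)
  hi_all <- c(splits, W)

  parent <- integer(0)
  counts <- numeric(0)
  prev_lastcol <- NULL        # labels (global ids) of previous band's last column
  offset <- 0L

  for (bandk in seq_len(nb)) {
    lo <- lo_all[bandk]; hi <- hi_all[bandk]
    sub_lo <- max(1L, lo - halo); sub_hi <- min(W, hi + halo)
    comp <- NULL
    for (p in seq_len(mosaic$n_planes)) {
      img <- .stitch_region(mosaic, p, sub_lo, sub_hi, noise = noise)
      m <- segment_plane(img, params)
      own <- m[, (lo - sub_lo + 1L):(hi - sub_lo + 1L), drop = FALSE]
      comp <- if (is.null(comp)) own else (comp | own)
    }
    lab <- .label_components_8(comp)
    nloc <- attr(lab, "n_labels")
    if (nloc > 0L) {
      counts <- c(counts, tabulate(lab[lab > 0L], nloc))
      parent <- c(parent, offset + seq_len(nloc))
    }
    glab <- lab
    glab[glab > 0L] <- glab[glab > 0L] + offset
    if (!is.null(prev_lastcol)) {
      first <- glab[, 1L]
      nr <- length(first)
      for (shift in -1:1) {
        a <- prev_lastcol
        bcol <- first
        if (shift == -1) { a <- a[-1L]; bcol <- bcol[-nr] }
        if (shift == 1)  { a <- a[-nr]; bcol <- bcol[-1L] }
        hit <- a > 0L & bcol > 0L
        if (any(hit)) for (pr in unique(paste(a[hit], bcol[hit]))) {
          ab <- as.integer(strsplit(pr, " ")[[1]])
          parent <- .uf_union(parent, ab[1L], ab[2L])
        }
      }
    }
    prev_lastcol <- glab[, ncol(glab)]
    offset <- offset + nloc
  }
  if (offset == 0L) return(numeric(0))
  roots <- vapply(seq_len(offset), function(x) .uf_find(parent, x), 1L)
  area_px <- tapply(counts, roots, sum)
  as.numeric(area_px) * mosaic$pixel_size^2
}

.uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}
.uf_union <- function(parent, a, b) {
  ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

#' Normalize viable tumor areas to the internal control group
#'
#' Each treated value is divided by the mean control live area of its own
#' growth condition; controls are normalized likewise, so the normalized
#' controls have mean 1 by construction.
#'
#' @param treated,control Numeric vectors of live areas, or lists of
#'   `"quant_result"` objects.
#' @return A list with numeric vectors `treated` and `control` (normalized
#'   areas) and `control_mean` (um^2).
#' @export
normalize_to_control <- function(treated, control) {
  tr <- .areas_of(treated)
  co <- .areas_of(control)
  if (length(co) == 0L) stop("control group is empty", call. = FALSE)
  cm <- mean(co)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean live area must be positive", call. = FALSE)
  list(treated = tr / cm, control = co / cm, control_mean = cm)
}

.areas_of <- function(x) {
  if (inherits(x, "quant_result")) return(x$live_area_um2)
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x))
    return(vapply(x, function(q) {
      if (inherits(q, "quant_result")) q$live_area_um2 else as.numeric(q)
    }, 0))
  stop("expected numeric areas or quant_result objects", call. = FALSE)
}
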