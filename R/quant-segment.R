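#' Calibrate segmentation thresholds from live/dead reference images
#'
#' Mirrors the experimental calibration in which untreated (live) and
#' formalin-fixed (dead) wells bracket the calcein dynamic range: the
#' global intensity floor is the midpoint of the robust means (medians) of
#' the two image sets, and the adaptive-threshold offset is initialized
#' from the live/dead separation.
#'
#' @param live_images,dead_images Non-empty lists of numeric matrices (or
#'   single matrices).
#' @param adaptive_window Odd window size (pixels) of the local-mean
#'   adaptive threshold (default 101).
#' @param adaptive_sensitivity Dimensionless sensitivity: a pixel must
#'   exceed its local mean by `adaptive_sensitivity * (live - background)`
#'   to pass the adaptive test (default 0.5).
#' @return An object of class `"calibration_params"` with fields
#'   `background_level`, `live_level`, `global_floor`,
#'   `adaptive_sensitivity`, `adaptive_window`.
#' @export
calibrate_threshold <- function(live_images, dead_images,
                                adaptive_window = 101L,
                                adaptive_sensitivity = 0.5) {
  if (is.matrix(live_images)) live_images <- list(live_images)
  if (is.matrix(dead_images)) dead_images <- list(dead_images)
  if (length(live_images) == 0L || length(dead_images) == 0L)
    stop("both live and dead image sets must be non-empty", call. = FALSE)
  adaptive_window <- as.integer(adaptive_window)
  if (adaptive_window < 3L || adaptive_window %% 2L == 0L)
    stop("adaptive_window must be odd and >= 3", call. = FALSE)
  live <- stats::median(unlist(lapply(live_images, as.numeric)))
  dead <- stats::median(unlist(lapply(dead_images, as.numeric)))
  if (live <= dead)
    stop("calibration failed: live and dead intensities are not separable",
         call. = FALSE)
  structure(list(background_level = dead, live_level = live,
                 global_floor = (live + dead) / 2,
                 adaptive_sensitivity = adaptive_sensitivity,
                 adaptive_window = adaptive_window),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "Calibration: background %.3g, live %.3g, floor %.3g; adaptive window %d, sensitivity %.2f\n",
    x$background_level, x$live_level, x$global_floor,
    x$adaptive_window, x$adaptive_sensitivity))
  invisible(x)
}

## box (moving-average) filter via a summed-area table; windows are
## clipped at the image border and normalized by the actual window size
.box_mean <- function(img, w) {
  h <- w %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(img, 2L, cumsum)
  S[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  r0 <- pmax(seq_len(nr) - h, 1L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h, 1L); c1 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r1 + 1L, c1 + 1L, drop = FALSE] - S[r0, c1 + 1L, drop = FALSE] -
    S[r1 + 1L, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  cnt <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  sums / cnt
}

#' Segment one image plane into a binary viability mask
#'
#' A pixel is calcein-positive when it exceeds its local mean (over the
#' calibrated adaptive window) by the calibrated offset AND lies at or
#' above the global intensity floor. Bright-object polarity: images whose
#' objects are darker than background give an empty mask. Deterministic.
#'
#' @param image Numeric matrix.
#' @param params A `"calibration_params"` object.
#' @return A logical matrix of class `"binary_mask"` (same shape).
#' @export
segment_plane <- function(image, params) {
  stopifnot(is.matrix(image), inherits(params, "calibration_params"))
  lm <- .box_mean(image, params$adaptive_window)
  offset <- params$adaptive_sensitivity *
    (params$live_level - params$background_level)
  mask <- (image > lm + offset) & (image >= params$global_floor)
  structure(mask, class = c("binary_mask", class(mask)))
}

#' Maximum-intensity projection of a Z-stack
#'
#' Pixelwise maximum over equally shaped plane images, collapsing
#' multi-plane growth into one image.
#'
#' @param planes Non-empty list of numeric matrices of identical shape.
#' @return A numeric matrix.
#' @export
max_intensity_projection <- function(planes) {
  if (!is.list(planes) || length(planes) == 0L)
    stop("max_intensity_projection needs a non-empty list of planes",
         call. = FALSE)
  .check_same_shape(planes)
  Reduce(pmax, planes)
}

#' Composite binary mask over a Z-stack
#'
#' Pixelwise logical OR of the per-plane binary masks, capturing an
#' object at whatever depth it appears.
#'
#' @param per_plane_masks Non-empty list of logical matrices of identical
#'   shape.
#' @return A logical matrix of class `"binary_mask"`.
#' @export
composite_mask <- function(per_plane_masks) {
  if (!is.list(per_plane_masks) || length(per_plane_masks) == 0L)
    stop("composite_mask needs a non-empty list of masks", call. = FALSE)
  .check_same_shape(per_plane_masks)
  out <- Reduce(`|`, per_plane_masks)
  structure(out, class = c("binary_mask", class(out)))
}

.check_same_shape <- function(lst) {
  d <- dim(lst[[1]])
  ok <- vapply(lst, function(m) is.matrix(m) && all(dim(m) == d), TRUE)
  if (!all(ok)) stop("all planes must be matrices of identical shape",
                     call. = FALSE)
  invisible(TRUE)
}
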