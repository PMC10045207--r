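#' 98th-percentile face brightness
#'
#' The exposure controller steers the near-maximum brightness of the face
#' region: the 98th percentile of pixel values inside the face bounding box.
#' The rank convention is the smallest sample value strictly greater than
#' the p-fraction of the sample (the `floor(p * n) + 1`-th order statistic,
#' clamped to n), deterministic on 8-bit data.
#'
#' @param image Gray image matrix, or an H x W x 3 array (converted to gray
#'   as the mean of the colour channels).
#' @param bbox Face box as a list or named vector with `x`, `y`, `w`, `h`
#'   (0-based pixel origin, widths in pixels).
#' @param p Percentile in (0, 1]; default 0.98.
#' @return The percentile value (same scale as the image).
#' @export
face_percentile_value <- function(image, bbox, p = 0.98) {
  if (is.array(image) && length(dim(image)) == 3L)
    image <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  stopifnot(is.matrix(image))
  bb <- as.list(bbox)
  rows <- intersect(seq_len(nrow(image)), (bb$y + 1):(bb$y + bb$h))
  cols <- intersect(seq_len(ncol(image)), (bb$x + 1):(bb$x + bb$w))
  if (length(rows) == 0L || length(cols) == 0L)
    stop("face_percentile_value: bbox does not intersect the image",
         call. = FALSE)
  px <- sort(as.vector(image[rows, cols, drop = FALSE]))
  px[min(length(px), floor(p * length(px)) + 1L)]
}

#' Iterative face-aware exposure-time adjustment
#'
#' Drives the camera exposure time so that the 98th percentile `v` of the
#' face-region pixel values lands strictly inside (190, 230) on the 8-bit
#' scale -- bright enough for a strong pulse signal, below clipping. While
#' `v` is outside the band, the exposure is multiplied by
#' `(190 + 230) / (2 v)` (one exact step for a noiseless linear sensor),
#' the scene recaptured and the face re-detected, for at most `max_iter`
#' iterations.
#'
#' @param camera Camera contract: list with `capture(exposure_ms)` returning
#'   a gray matrix or RGB array, and numeric `min_exposure`, `max_exposure`
#'   bounds in milliseconds.
#' @param detector Face detector contract: `function(image)` returning a bbox
#'   (list `x`, `y`, `w`, `h`) or `NULL` when no face is found.
#' @param initial_exposure Starting exposure time in milliseconds.
#' @param max_iter Iteration bound (default 10).
#' @param target Open target band for `v` (default `c(190, 230)`).
#' @return An `exposure_result`: `exposure_time`, `final_face_value`,
#'   `iterations_used`, `converged`, plus `clamped` and `bbox_reused` flags.
#' @export
adjust_exposure <- function(camera, detector, initial_exposure,
                            max_iter = 10L, target = c(190, 230)) {
  stopifnot(is.function(camera$capture), is.function(detector),
            initial_exposure > 0)
  l <- initial_exposure
  img <- camera$capture(l)
  bb <- detector(img)
  if (is.null(bb))
    stop("adjust_exposure: no face detected on the initial capture",
         call. = FALSE)
  clamped <- FALSE
  bbox_reused <- FALSE
  v <- NA_real_
  for (n in 0:max_iter) {
    v <- face_percentile_value(img, bb)
    if (v > target[1L] && v < target[2L]) {
      return(structure(list(exposure_time = l, final_face_value = v,
                            iterations_used = n, converged = TRUE,
                            clamped = clamped, bbox_reused = bbox_reused),
                       class = "exposure_result"))
    }
    if (n == max_iter) break
    l_new <- sum(target) / (2 * v) * l
    if (!is.null(camera$min_exposure) && l_new < camera$min_exposure) {
      l_new <- camera$min_exposure; clamped <- TRUE
      warning("adjust_exposure: exposure clamped at camera minimum")
    }
    if (!is.null(camera$max_exposure) && l_new > camera$max_exposure) {
      l_new <- camera$max_exposure; clamped <- TRUE
      warning("adjust_exposure: exposure clamped at camera maximum")
    }
    l <- l_new
    img <- camera$capture(l)
    bb_new <- detector(img)
    if (is.null(bb_new)) bbox_reused <- TRUE else bb <- bb_new
  }
  structure(list(exposure_time = l, final_face_value = v,
                 iterations_used = max_iter, converged = FALSE,
                 clamped = clamped, bbox_reused = bbox_reused),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf(
    "exposure adjustment: %s after %d iteration(s)\n  exposure %.4g ms, face 98th percentile %.1f%s\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations_used, x$exposure_time, x$final_face_value,
    if (isTRUE(x$clamped)) " (clamped at camera bound)" else ""))
  invisible(x)
}
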