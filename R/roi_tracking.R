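#' Face-box time series over stabilized frames
#'
#' Runs the injected face detector on every frame. Detection failures are
#' recorded as missing entries -- they are data (the face left the frame),
#' not errors; downstream segmentation handles the gaps.
#'
#' @param frames List of `stabilized_frame` (or any objects with an `image`
#'   field).
#' @param detector `function(image)` returning a bbox (list `x`, `y`, `w`,
#'   `h`) or `NULL`.
#' @return List of length `length(frames)`; each element a bbox or `NULL`.
#' @export
detect_face_series <- function(frames, detector) {
  if (length(frames) == 0L)
    stop("detect_face_series: empty frame sequence", call. = FALSE)
  lapply(frames, function(f) detector(if (is.list(f)) f$image else f))
}

#' Segment a detection series into usable time-frames
#'
#' Maximal runs of consecutive frames with a face detection, kept only when
#' at least `min_duration` seconds long (`ceiling(min_duration * frame_rate)`
#' frames). An empty result means the recording cannot be assessed.
#'
#' @param series Detection series from [detect_face_series()] (list with
#'   `NULL` for missing detections), or a logical vector of presence.
#' @param frame_rate Frames per second (> 0).
#' @param min_duration Minimum segment duration in seconds (default 5).
#' @return data.frame with columns `start`, `end` (1-based inclusive frame
#'   indices) and `duration` (seconds, `n_frames / frame_rate`).
#' @export
segment_timeframes <- function(series, frame_rate, min_duration = 5) {
  stopifnot(frame_rate > 0)
  present <- if (is.logical(series)) series
             else !vapply(series, is.null, logical(1))
  min_frames <- ceiling(min_duration * frame_rate)
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start = starts[keep], end = ends[keep],
             duration = r$lengths[keep] / frame_rate)
}

#' Default facial ROI layout template
#'
#' 30 measurement regions -- a 3 x 6 grid across the forehead plus a 2 x 3
#' grid on each cheek -- and 4 noise regions over the nostrils (center,
#' right) and eyes (center, right), which see the same lighting and motion
#' as the skin patches but carry no blood-volume signal. All polygons are
#' quads with vertices in coordinates relative to the face bounding box
#' (unit square).
#'
#' @return List of ROIs: each a list with `label`, `role`
#'   (`"measurement"` or `"noise"`), and `vertices` (V x 2 matrix, columns
#'   x, y in `[0,1]`).
#' @export
default_roi_layout <- function() {
  quad <- function(x0, y0, x1, y1)
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  rois <- list()
  # forehead: 3 rows x 6 columns
  fx <- seq(0.15, 0.85, length.out = 7)
  fy <- seq(0.06, 0.30, length.out = 4)
  for (r in 1:3) for (c in 1:6)
    rois[[length(rois) + 1L]] <- list(
      label = sprintf("forehead_r%dc%d", r, c), role = "measurement",
      vertices = quad(fx[c], fy[r], fx[c + 1], fy[r + 1]))
  # cheeks: 2 rows x 3 columns each side
  cy <- seq(0.52, 0.74, length.out = 3)
  for (side in c("left", "right")) {
    cx <- if (side == "left") seq(0.04, 0.34, length.out = 4)
          else seq(0.68, 0.98, length.out = 4)
    for (r in 1:2) for (c in 1:3)
      rois[[length(rois) + 1L]] <- list(
        label = sprintf("cheek_%s_r%dc%d", side, r, c), role = "measurement",
        vertices = quad(cx[c], cy[r], cx[c + 1], cy[r + 1]))
  }
  rois[[length(rois) + 1L]] <- list(label = "nostril_center", role = "noise",
    vertices = quad(0.44, 0.60, 0.56, 0.68))
  rois[[length(rois) + 1L]] <- list(label = "nostril_right", role = "noise",
    vertices = quad(0.57, 0.60, 0.66, 0.68))
  rois[[length(rois) + 1L]] <- list(label = "eye_center", role = "noise",
    vertices = quad(0.44, 0.36, 0.56, 0.44))
  rois[[length(rois) + 1L]] <- list(label = "eye_right", role = "noise",
    vertices = quad(0.60, 0.36, 0.78, 0.44))
  rois
}

#' @keywords internal
validate_roi_layout <- function(layout) {
  roles <- vapply(layout, `[[`, character(1), "role")
  nv <- vapply(layout, function(r) nrow(r$vertices), integer(1))
  if (sum(roles == "measurement") != 30L)
    stop("ROI layout must have exactly 30 measurement regions", call. = FALSE)
  if (any(nv < 4L | nv > 6L))
    stop("ROI polygons must have 4 to 6 vertices", call. = FALSE)
  invisible(layout)
}

#' Serialize / read an ROI layout as JSON
#' @param layout ROI layout (see [default_roi_layout()]).
#' @param path File path.
#' @export
write_roi_layout <- function(layout, path) {
  out <- lapply(layout, function(r)
    list(label = r$label, role = r$role,
         vertices = unname(apply(r$vertices, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_layout
#' @export
read_roi_layout <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r) list(
    label = r$label, role = r$role,
    vertices = do.call(rbind, lapply(r$vertices, function(v)
      c(x = v[[1]], y = v[[2]])))))
}

# Even-odd rule point-in-polygon, vectorized over points. Coordinates are
# 0-based pixel centers; edges are handled deterministically by the
# half-open crossing test.
#' @keywords internal
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Anchor a relative ROI layout to a face bounding box
#'
#' @param layout Relative layout (vertices in the unit square).
#' @param bbox Face box (list `x`, `y`, `w`, `h`, 0-based pixels).
#' @return Layout with vertices in absolute pixel coordinates.
#' @export
scale_layout_to_bbox <- function(layout, bbox) {
  lapply(layout, function(r) {
    v <- r$vertices
    r$vertices <- cbind(x = bbox$x + v[, 1] * bbox$w,
                        y = bbox$y + v[, 2] * bbox$h)
    r
  })
}

#' Extract raw per-ROI colour signals over one time-frame segment
#'
#' For every frame of the segment the landmark provider supplies the ROI
#' polygons in pixel coordinates; each ROI's raw signal is the mean of the
#' pixel colour values whose centers fall inside the polygon. Tracking
#' side-channels (vertex coordinates, their center-of-mass = vertex average,
#' and the pixel count) are recorded alongside -- they later become noise
#' regressors.
#'
#' @param frames List of `stabilized_frame` covering at least the segment.
#' @param segment One row of [segment_timeframes()] output (list/row with
#'   `start`, `end`).
#' @param layout_provider `function(frame_index)` returning an ROI layout in
#'   pixel coordinates (e.g. built with [scale_layout_to_bbox()]).
#' @return Named list of `roi_signals` objects: each has `label`, `role`,
#'   `means` (T x 3 matrix, columns R, G, B), `pixel_count` (length T),
#'   `landmarks` (T x 2V matrix: x1, y1, x2, y2, ...), `com` (T x 2).
#'   Degenerate ROIs (zero pixels in any frame) are dropped with a warning.
#' @export
extract_roi_signals <- function(frames, segment, layout_provider) {
  idx <- segment$start:segment$end
  layout0 <- layout_provider(idx[1L])
  nroi <- length(layout0)
  T_ <- length(idx)
  sig <- lapply(layout0, function(r) {
    v <- nrow(r$vertices)
    list(label = r$label, role = r$role,
         means = matrix(NA_real_, T_, 3,
                        dimnames = list(NULL, c("R", "G", "B"))),
         pixel_count = numeric(T_),
         landmarks = matrix(NA_real_, T_, 2 * v),
         com = matrix(NA_real_, T_, 2, dimnames = list(NULL, c("x", "y"))))
  })
  names(sig) <- vapply(layout0, `[[`, character(1), "label")
  degenerate <- character(0)
  for (ti in seq_along(idx)) {
    f <- frames[[idx[ti]]]
    img <- if (is.list(f)) f$image else f
    layout <- if (ti == 1L) layout0 else layout_provider(idx[ti])
    for (ri in seq_len(nroi)) {
      v <- layout[[ri]]$vertices
      xmin <- max(0L, floor(min(v[, 1]))); xmax <- min(ncol(img) - 1L, ceiling(max(v[, 1])))
      ymin <- max(0L, floor(min(v[, 2]))); ymax <- min(nrow(img) - 1L, ceiling(max(v[, 2])))
      if (xmax < xmin || ymax < ymin) { degenerate <- c(degenerate, names(sig)[ri]); next }
      gx <- rep(xmin:xmax, each = ymax - ymin + 1L)
      gy <- rep(ymin:ymax, times = xmax - xmin + 1L)
      inside <- points_in_polygon(gx, gy, v[, 1], v[, 2])
      npx <- sum(inside)
      if (npx == 0L) { degenerate <- c(degenerate, names(sig)[ri]); next }
      rows <- gy[inside] + 1L; cols <- gx[inside] + 1L
      lin <- cbind(rows, cols)
      s <- sig[[ri]]
      s$means[ti, ] <- c(mean(img[, , 1][lin]), mean(img[, , 2][lin]),
                         mean(img[, , 3][lin]))
      s$pixel_count[ti] <- npx
      s$landmarks[ti, ] <- as.vector(t(v))
      s$com[ti, ] <- colMeans(v)
      sig[[ri]] <- s
    }
  }
  if (length(degenerate)) {
    degenerate <- unique(degenerate)
    warning("extract_roi_signals: dropping degenerate ROI(s): ",
            paste(degenerate, collapse = ", "))
    sig <- sig[!(names(sig) %in% degenerate)]
  }
  lapply(sig, function(s) structure(s, class = "roi_signals"))
}
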