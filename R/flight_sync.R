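#' Match sensor samples to frame timestamps
#'
#' For each frame timestamp, find the index of the sensor sample with the
#' smallest absolute temporal distance. This is how asynchronously logged
#' gimbal and flight-sensor streams are aligned to the video stream: the
#' logs run at their own rates, and for every frame the temporally nearest
#' log sample is taken (no interpolation).
#'
#' @param frame_times Numeric vector of frame timestamps in seconds, sorted
#'   ascending.
#' @param sensor_times Numeric vector of sensor timestamps in seconds, sorted
#'   ascending.
#' @return Integer vector, one sensor index (1-based) per frame. Exact ties
#'   are broken toward the earlier sensor sample.
#' @export
#' @examples
#' match_sensor_to_frames(c(0, 0.07, 0.13), c(0, 0.05, 0.10, 0.15))
match_sensor_to_frames <- function(frame_times, sensor_times) {
  if (length(frame_times) == 0L || length(sensor_times) == 0L)
    stop("match_sensor_to_frames: empty timestamp sequence", call. = FALSE)
  if (anyNA(frame_times) || anyNA(sensor_times))
    stop("match_sensor_to_frames: NA timestamps", call. = FALSE)
  if (is.unsorted(frame_times) || is.unsorted(sensor_times))
    stop("match_sensor_to_frames: timestamps must be sorted ascending",
         call. = FALSE)
  # candidate = last sensor sample at or before each frame time
  lo <- findInterval(frame_times, sensor_times)
  lo[lo == 0L] <- 1L
  hi <- pmin(lo + 1L, length(sensor_times))
  d_lo <- abs(frame_times - sensor_times[lo])
  d_hi <- abs(frame_times - sensor_times[hi])
  # strict '<' keeps the earlier index on exact ties
  ifelse(d_hi < d_lo, hi, lo)
}

#' Roll angle left uncompensated by a two-axis gimbal
#'
#' A two-axis gimbal stabilizes pitch and roll of the view axis but leaves a
#' rotation of the optical plane. That residual roll is recovered from the
#' z-components of the gimbal's left-facing view vector `h` and down-facing
#' view vector `v` (geodetic coordinates) as `atan2(h_z, v_z)`.
#'
#' @param h Left-facing view vector (length-3 numeric).
#' @param v Down-facing view vector (length-3 numeric).
#' @return Roll angle in radians, in (-pi, pi]. Scale-invariant: vectors need
#'   not be normalized.
#' @export
compute_roll_angle <- function(h, v) {
  stopifnot(length(h) == 3L, length(v) == 3L)
  if (!all(is.finite(h)) || !all(is.finite(v)))
    stop("compute_roll_angle: non-finite gimbal vector", call. = FALSE)
  if (h[3L] == 0 && v[3L] == 0)
    stop("compute_roll_angle: degenerate geometry, both z-components zero",
         call. = FALSE)
  atan2(h[3L], v[3L])
}

#' @keywords internal
new_frame_record <- function(index, t, image) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  structure(list(index = index, t = t, image = image),
            class = "frame_record")
}

#' Rotate image content by an angle about the image center
#'
#' Inverse-mapped bilinear interpolation into a square, zero-padded output
#' canvas of side `max(H, W)`. Coordinates use x = column, y = row; a
#' positive `beta` rotates content from the +x axis toward the +y axis.
#' The pivot is the image center ((W-1)/2, (H-1)/2).
#'
#' @param image H x W x 3 numeric array (8-bit scale, values 0..255).
#' @param beta Rotation angle in radians.
#' @return S x S x 3 array, S = max(H, W); pixels mapped from outside the
#'   source are zero.
#' @export
rotate_image <- function(image, beta) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h == 0L || w == 0L)
    stop("rotate_image: empty image", call. = FALSE)
  if (!is.finite(beta))
    stop("rotate_image: non-finite angle", call. = FALSE)
  s <- max(h, w)
  cx_in <- (w - 1) / 2; cy_in <- (h - 1) / 2
  c_out <- (s - 1) / 2
  xo <- rep(0:(s - 1L), each = s) - c_out   # column-major over (y, x)
  yo <- rep(0:(s - 1L), times = s) - c_out
  cb <- cos(beta); sb <- sin(beta)
  # inverse map: source coords of each output pixel
  xs <- cb * xo + sb * yo + cx_in
  ys <- -sb * xo + cb * yo + cy_in
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- array(0, dim = c(s, s, 3L))
  gather <- function(ch, yi, xi) {
    ok <- yi >= 0 & yi <= (h - 1L) & xi >= 0 & xi <= (w - 1L)
    val <- numeric(length(yi))
    val[ok] <- ch[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    val
  }
  for (k in 1:3) {
    ch <- image[, , k]
    v00 <- gather(ch, y0, x0)
    v01 <- gather(ch, y0, x0 + 1)
    v10 <- gather(ch, y0 + 1, x0)
    v11 <- gather(ch, y0 + 1, x0 + 1)
    val <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
    out[, , k] <- matrix(val, nrow = s, ncol = s)
  }
  out
}

#' Derotate one frame by the gimbal roll angle
#'
#' Rotates the frame content by `-angle` (bilinear interpolation) and centers
#' it in a zero-padded square canvas, undoing the optical-plane rotation the
#' two-axis gimbal could not compensate.
#'
#' @param frame A `frame_record` (list with `index`, `t`, `image`) or a bare
#'   H x W x 3 array.
#' @param angle Roll angle in radians (as from [compute_roll_angle()]).
#' @return A `stabilized_frame`: list with square `image` and `applied_angle`
#'   (= `-angle`).
#' @export
derotate_frame <- function(frame, angle) {
  image <- if (is.list(frame)) frame$image else frame
  structure(list(image = rotate_image(image, -angle),
                 applied_angle = -angle),
            class = "stabilized_frame")
}

#' Stabilize a recording bundle
#'
#' For each frame, the temporally nearest gimbal sample is selected, the
#' residual roll angle computed from its view-vector z-components, and the
#' frame digitally derotated into a square zero-padded canvas.
#'
#' @param bundle A `recording_bundle` (see [read_bundle()] /
#'   [simulate_frames()]): needs `frames` (list of `frame_record`) and
#'   `gimbal` (data.frame with `timestamp_s`, `hx..hz`, `vx..vz`).
#' @return List of `stabilized_frame`, one per input frame.
#' @export
stabilize_sequence <- function(bundle) {
  if (is.null(bundle$gimbal))
    stop("stabilize_sequence: bundle has no gimbal log", call. = FALSE)
  if (length(bundle$frames) == 0L)
    stop("stabilize_sequence: bundle has no frames", call. = FALSE)
  g <- bundle$gimbal
  ft <- vapply(bundle$frames, function(f) f$t, numeric(1))
  idx <- match_sensor_to_frames(ft, g$timestamp_s)
  lapply(seq_along(bundle$frames), function(i) {
    m <- idx[i]
    ang <- compute_roll_angle(c(g$hx[m], g$hy[m], g$hz[m]),
                              c(g$vx[m], g$vy[m], g$vz[m]))
    derotate_frame(bundle$frames[[i]], ang)
  })
}
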