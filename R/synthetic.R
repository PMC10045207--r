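# run code with a private, restored RNG state so simulators are
# deterministic without clobbering the caller's stream
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Band-limited Gaussian process
#'
#' White Gaussian noise low-passed in the frequency domain (all components
#' above `f_max` and the DC removed), rescaled to the requested standard
#' deviation. Used for all simulated drift processes: wind-driven gimbal
#' roll, bounding-box jitter, lighting drift, flight-sensor wander. The
#' default cutoff keeps the noise below the 50 bpm edge of the HR target
#' band, which is what slow platform motion looks like spectrally.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param f_max Cutoff frequency (Hz); default 50/60 Hz (50 bpm).
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n` (zeros when `sd = 0`).
#' @export
bandlimited_noise <- function(n, fs, f_max = 50 / 60, sd = 1) {
  if (sd == 0 || n < 2L) return(numeric(n))
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- (0:(n - 1L)) * fs / n
  f <- pmin(f, fs - f)  # two-sided
  sp[f > f_max | f == 0] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

#' Synthetic flight-scene configuration
#'
#' The stated world of the simulator, mirroring the published recording
#' conditions: 15 fps video of a stationary subject, sensor logs at twice
#' the frame rate, wind-driven slow platform motion, and a G-dominant
#' pulsatile colour direction typical of skin.
#'
#' @param true_hr Heart rate in bpm (40-200; default 70).
#' @param hr_drift Linear HR drift in bpm/s (default 0).
#' @param pulse_strength Relative pulse modulation of the green channel
#'   (default 0.01, i.e. 1% of DC -- strong end of realistic rPPG).
#' @param pulse_direction Relative per-channel amplitudes, scaled by
#'   `pulse_strength` (default `c(0.5, 1, 0.7)`).
#' @param pulse_waveform `"sinusoid"` (default) or `"harmonic"` (adds a
#'   half-amplitude 2nd harmonic, to exercise harmonic-rejection logic).
#' @param skin_base_color 8-bit RGB base colour of the skin patches.
#' @param noise_scale Std (8-bit units) of the linear noise-mixture
#'   contribution added to each channel (default 2, about 3x the G-channel
#'   pulse amplitude: moderate noise).
#' @param white_noise_sd Std of i.i.d. sensor noise (default 0.3).
#' @param roll_std_rad Std of the simulated uncompensated gimbal roll
#'   (default 0.08 rad, ~4.6 degrees of wind-driven roll).
#' @param bbox_jitter_px Std of face-box/landmark jitter in pixels
#'   (default 1.5).
#' @param motion_bandwidth_hz Cutoff of all drift processes (default
#'   50/60 Hz).
#' @param dropout_windows List of `c(start, end)` frame-index (1-based)
#'   intervals where the face is undetectable.
#' @param frame_rate Frames per second (default 15).
#' @param duration Recording length in seconds (default 20).
#' @param frame_size `c(H, W)` of simulated frames (default `c(120, 160)`).
#' @param n_vertices Vertices per ROI polygon used by the signal-level
#'   simulator (4-6; default 4).
#' @param camera_gain Linear camera gain: pixel = clip(gain * exposure_ms *
#'   radiance) (default 0.1 per ms at unit radiance).
#' @param seed Integer seed; every generator is reproducible given it.
#' @return A `scene_config`.
#' @export
scene_config <- function(true_hr = 70, hr_drift = 0,
                         pulse_strength = 0.01,
                         pulse_direction = c(0.5, 1, 0.7),
                         pulse_waveform = c("sinusoid", "harmonic"),
                         skin_base_color = c(200, 160, 140),
                         noise_scale = 2, white_noise_sd = 0.3,
                         roll_std_rad = 0.08, bbox_jitter_px = 1.5,
                         motion_bandwidth_hz = 50 / 60,
                         dropout_windows = list(),
                         frame_rate = 15, duration = 20,
                         frame_size = c(120, 160), n_vertices = 4L,
                         camera_gain = 0.1, seed = 1L) {
  stopifnot(true_hr >= 40, true_hr <= 200, frame_rate > 0, duration > 0,
            n_vertices >= 4L, n_vertices <= 6L)
  structure(list(
    true_hr = true_hr, hr_drift = hr_drift,
    pulse_strength = pulse_strength, pulse_direction = pulse_direction,
    pulse_waveform = match.arg(pulse_waveform),
    skin_base_color = skin_base_color, noise_scale = noise_scale,
    white_noise_sd = white_noise_sd, roll_std_rad = roll_std_rad,
    bbox_jitter_px = bbox_jitter_px,
    motion_bandwidth_hz = motion_bandwidth_hz,
    dropout_windows = dropout_windows, frame_rate = frame_rate,
    duration = duration, frame_size = frame_size,
    n_vertices = as.integer(n_vertices), camera_gain = camera_gain,
    seed = as.integer(seed)), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "synthetic flight scene: HR %g bpm (drift %g bpm/s), %g s at %g fps, seed %d\n",
    x$true_hr, x$hr_drift, x$duration, x$frame_rate, x$seed))
  invisible(x)
}

# instantaneous HR (bpm) and pulse phase at given times
#' @keywords internal
pulse_phase <- function(config, t) {
  f <- config$true_hr + config$hr_drift * t  # bpm
  dt <- if (length(t) > 1L) t[2L] - t[1L] else 0
  phase <- 2 * pi * cumsum(f / 60) * dt
  list(hr = f, phase = phase)
}

#' @keywords internal
pulse_waveform_values <- function(config, phase) {
  w <- sin(phase)
  if (config$pulse_waveform == "harmonic") w <- w + 0.5 * sin(2 * phase)
  w
}

#' Simulate gimbal and flight-sensor logs
#'
#' Smooth band-limited random processes sampled at twice the frame rate.
#' The gimbal's left-facing and down-facing unit vectors are constructed so
#' that `atan2(h_z, v_z)` equals the simulated roll-angle process.
#'
#' @param config A [scene_config()].
#' @return List with data.frames `gimbal`
#'   (`timestamp_s, hx, hy, hz, vx, vy, vz`) and `flight` (`timestamp_s,
#'   height_m, longitude_deg, latitude_deg, vel_u, vel_v, vel_w`), plus
#'   `roll` (the ground-truth roll series).
#' @export
simulate_flight_logs <- function(config) {
  with_seed(config$seed + 101L, {
    fs <- 2 * config$frame_rate
    n <- ceiling(config$duration * fs) + 1L
    t <- (0:(n - 1L)) / fs
    bl <- function(sd) bandlimited_noise(n, fs, config$motion_bandwidth_hz, sd)
    roll <- bl(config$roll_std_rad)
    c0 <- 0.9  # magnitude of the z-components; rest fills to unit norm
    hz <- c0 * sin(roll); vz <- c0 * cos(roll)
    # independent smooth wobble in the free components: real attitude logs
    # are not rank-one functions of the roll
    hy <- bl(0.5 * config$roll_std_rad)
    vx <- bl(0.5 * config$roll_std_rad)
    gimbal <- data.frame(
      timestamp_s = t,
      hx = sqrt(pmax(0, 1 - hz^2 - hy^2)), hy = hy, hz = hz,
      vx = vx, vy = sqrt(pmax(0, 1 - vz^2 - vx^2)), vz = vz)
    flight <- data.frame(
      timestamp_s = t,
      height_m = 8 + bl(0.3),
      longitude_deg = 6.06 + bl(2e-6),
      latitude_deg = 50.78 + bl(2e-6),
      vel_u = bl(0.5), vel_v = bl(0.5), vel_w = bl(0.25))
    list(gimbal = gimbal, flight = flight, roll = roll)
  })
}

# time-match sensor logs to frame timestamps (nearest sample)
#' @keywords internal
match_logs_to_frames <- function(logs, frame_times) {
  gi <- match_sensor_to_frames(frame_times, logs$gimbal$timestamp_s)
  fi <- match_sensor_to_frames(frame_times, logs$flight$timestamp_s)
  list(gimbal = logs$gimbal[gi, , drop = FALSE],
       flight = logs$flight[fi, , drop = FALSE])
}

# regular V-gon (quad/pentagon/hexagon) around a center, as landmark base
#' @keywords internal
regular_polygon <- function(cx, cy, rx, ry, v) {
  a <- seq(0, 2 * pi, length.out = v + 1L)[1:v] - pi / 2
  cbind(x = cx + rx * cos(a), y = cy + ry * sin(a))
}

#' @keywords internal
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Simulate per-ROI colour signals with full ground truth
#'
#' Generates, at the raw-signal level, exactly what ROI extraction would
#' produce from a drone recording: 30 measurement ROIs whose channels carry
#' a pulse component at the configured rate plus a linear mixture of the
#' known noise signals plus white sensor noise, and 4 bloodless noise ROIs
#' (nostrils/eyes) that carry the lighting-noise and white-noise terms but
#' no pulse. The noise design matrix is assembled by the de-noising module
#' itself from the simulated tracking and flight series, so the generated
#' signals decompose exactly as the de-noising model assumes.
#'
#' @param config A [scene_config()].
#' @return List with `rois` (named list of `roi_signals`, measurement +
#'   noise), `flight`/`gimbal` (frame-matched data.frames), `ground_truth`
#'   (list: `hr_series`, `pulse_trace`, `visibility`, per-ROI
#'   `noise_contribution` and `white_noise` matrices, `mixing`), and
#'   `config`.
#' @export
simulate_roi_signals <- function(config) {
  logs <- simulate_flight_logs(config)
  T_ <- round(config$duration * config$frame_rate)
  t <- (0:(T_ - 1L)) / config$frame_rate
  matched <- match_logs_to_frames(logs, t)
  pp <- pulse_phase(config, t)
  pulse <- pulse_waveform_values(config, pp$phase)
  amp <- config$pulse_direction * config$pulse_strength
  H <- config$frame_size[1L]; W <- config$frame_size[2L]
  bbox <- list(x = round(W * 0.3), y = round(H * 0.15),
               w = round(W * 0.4), h = round(H * 0.65))
  layout <- scale_layout_to_bbox(default_roi_layout(), bbox)
  nv <- config$n_vertices
  with_seed(config$seed + 202L, {
    bl <- function(sd) bandlimited_noise(T_, config$frame_rate,
                                         config$motion_bandwidth_hz, sd)
    # shared face-box jitter plus small per-vertex wobble
    jx <- bl(config$bbox_jitter_px); jy <- bl(config$bbox_jitter_px)
    # lighting drift seen by every region (enters Y only through the
    # noise-ROI columns and the mixing weights)
    light <- vapply(1:3, function(i) bl(1), numeric(T_))
    noise_base <- list(nostril_center = c(90, 70, 65),
                       nostril_right = c(95, 75, 70),
                       eye_center = c(60, 55, 55), eye_right = c(62, 57, 56))
    rois <- list()
    for (r in layout) {
      cx <- mean(r$vertices[, 1]); cy <- mean(r$vertices[, 2])
      rx <- diff(range(r$vertices[, 1])) / 2
      ry <- diff(range(r$vertices[, 2])) / 2
      base_v <- regular_polygon(cx, cy, rx, ry, nv)
      wobble <- function() vapply(seq_len(nv), function(i)
        bl(0.2 * config$bbox_jitter_px), numeric(T_))
      lmx <- outer(jx, base_v[, 1], `+`) + wobble()
      lmy <- outer(jy, base_v[, 2], `+`) + wobble()
      lm <- matrix(NA_real_, T_, 2 * nv)
      lm[, seq(1, 2 * nv, 2)] <- lmx
      lm[, seq(2, 2 * nv, 2)] <- lmy
      pc <- vapply(seq_len(T_), function(i)
        max(1, round(polygon_area(cbind(lmx[i, ], lmy[i, ])))), numeric(1))
      rois[[r$label]] <- structure(list(
        label = r$label, role = r$role,
        means = matrix(NA_real_, T_, 3,
                       dimnames = list(NULL, c("R", "G", "B"))),
        pixel_count = pc, landmarks = lm,
        com = cbind(x = rowMeans(lmx), y = rowMeans(lmy))),
        class = "roi_signals")
    }
    # bloodless noise ROIs: base colour + lighting drift + sensor noise
    for (lbl in names(noise_base)) {
      wn <- matrix(stats::rnorm(T_ * 3, sd = config$white_noise_sd), T_, 3)
      rois[[lbl]]$means <- sweep(light + wn, 2, noise_base[[lbl]], `+`)
      colnames(rois[[lbl]]$means) <- c("R", "G", "B")
    }
    noise_rois <- rois[names(noise_base)]
    # ground-truth mixing weights, shared across ROIs
    K <- 4L * nv + 27L
    mixing <- matrix(stats::rnorm(K * 3), K, 3)
    gt_contrib <- list(); gt_white <- list()
    meas <- Filter(function(r) r$role == "measurement", rois)
    for (lbl in names(meas)) {
      roi <- rois[[lbl]]
      X <- assemble_noise_matrix(roi, noise_rois, matched$flight,
                                 matched$gimbal)
      contrib <- matrix(NA_real_, T_, 3)
      for (ch in 1:3) {
        xs <- scale(X$values[[ch]])        # standardized columns
        xs[, attr(xs, "scaled:scale") == 0] <- 0
        xs[is.na(xs)] <- 0
        raw <- as.vector(xs %*% mixing[, ch])
        s <- stats::sd(raw)
        contrib[, ch] <- if (s > 0) raw / s * config$noise_scale else raw
      }
      wn <- matrix(stats::rnorm(T_ * 3, sd = config$white_noise_sd), T_, 3)
      base <- config$skin_base_color
      y <- vapply(1:3, function(ch)
        base[ch] * (1 + amp[ch] * pulse) + contrib[, ch] + wn[, ch],
        numeric(T_))
      colnames(y) <- c("R", "G", "B")
      rois[[lbl]]$means <- y
      gt_contrib[[lbl]] <- contrib
      gt_white[[lbl]] <- wn
    }
    visibility <- rep(TRUE, T_)
    for (win in config$dropout_windows)
      visibility[max(1L, win[1L]):min(T_, win[2L])] <- FALSE
    list(rois = rois,
         flight = matched$flight, gimbal = matched$gimbal,
         ground_truth = list(hr_series = pp$hr, pulse_trace = pulse,
                             visibility = visibility,
                             noise_contribution = gt_contrib,
                             white_noise = gt_white, mixing = mixing,
                             bbox = bbox),
         config = config)
  })
}

#' Scene radiance image of the synthetic face scene
#'
#' Upright radiance map used by the linear camera model: a uniform
#' background with a skin-coloured face rectangle. Pixel values are
#' radiance units; the camera maps them to 8-bit by
#' `clip(gain * exposure_ms * radiance)`.
#'
#' @param config A [scene_config()].
#' @param face Draw the face rectangle (default TRUE).
#' @return List with `radiance` (H x W x 3 array) and `bbox`.
#' @export
scene_radiance <- function(config, face = TRUE) {
  H <- config$frame_size[1L]; W <- config$frame_size[2L]
  bbox <- list(x = round(W * 0.3), y = round(H * 0.15),
               w = round(W * 0.4), h = round(H * 0.65))
  rad <- array(rep(c(3, 3.2, 3.5), each = H * W), dim = c(H, W, 3L))
  if (face) {
    rows <- (bbox$y + 1):(bbox$y + bbox$h)
    cols <- (bbox$x + 1):(bbox$x + bbox$w)
    for (ch in 1:3) rad[rows, cols, ch] <- config$skin_base_color[ch] / 10
  }
  list(radiance = rad, bbox = bbox)
}

#' Linear clipped camera contract over a radiance scene
#'
#' @param radiance H x W x 3 radiance array (see [scene_radiance()]).
#' @param gain Linear gain per millisecond of exposure.
#' @param min_exposure,max_exposure Exposure bounds in ms.
#' @return Camera contract list with `capture(exposure_ms)` returning an
#'   8-bit-scale image (`round(clip(gain * l * radiance, 0, 255))`).
#' @export
synthetic_camera <- function(radiance, gain = 0.1, min_exposure = 0.01,
                             max_exposure = 1000) {
  list(capture = function(exposure_ms) {
    round(pmax(pmin(gain * exposure_ms * radiance, 255), 0))
  }, min_exposure = min_exposure, max_exposure = max_exposure)
}

#' Threshold face detector for synthetic scenes
#'
#' Finds the bounding box of bright (skin-coloured) pixels -- an honest,
#' model-free stand-in for the pluggable face-detector contract on scenes
#' where the face is the only bright region.
#'
#' @param threshold Gray level above which a pixel counts as face.
#' @param min_pixels Minimum face area in pixels; below it, no detection.
#' @return Detector contract: `function(image)` returning a bbox or `NULL`.
#' @export
synthetic_face_detector <- function(threshold = 100, min_pixels = 50) {
  function(image) {
    gray <- if (is.array(image) && length(dim(image)) == 3L)
      (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else image
    hit <- which(gray > threshold, arr.ind = TRUE)
    if (nrow(hit) < min_pixels) return(NULL)
    list(x = min(hit[, 2]) - 1L, y = min(hit[, 1]) - 1L,
         w = max(hit[, 2]) - min(hit[, 2]) + 1L,
         h = max(hit[, 1]) - min(hit[, 1]) + 1L)
  }
}

#' Simulate a full recording bundle (frames + logs)
#'
#' Renders small 8-bit frames of a skin-coloured face rectangle on a dark
#' background. The face position jitters with the motion model, the whole
#' frame content is rotated by the simulated uncompensated gimbal roll
#' (what a two-axis-gimbal camera actually records), the face modulates
#' with the pulse, and it disappears during dropout windows.
#'
#' @param config A [scene_config()].
#' @param exposure_ms Exposure time for the linear camera (default 100, which
#'   with the default gain maps radiance to the base skin colour).
#' @return A `recording_bundle`: list with `frames` (list of
#'   `frame_record`), `gimbal`, `flight` (full-rate logs), `frame_rate`,
#'   and `ground_truth` (`roll`, `bbox` per frame, `visibility`,
#'   `hr_series`).
#' @export
simulate_frames <- function(config, exposure_ms = 100) {
  logs <- simulate_flight_logs(config)
  T_ <- round(config$duration * config$frame_rate)
  t <- (0:(T_ - 1L)) / config$frame_rate
  matched <- match_logs_to_frames(logs, t)
  roll_f <- atan2(matched$gimbal$hz, matched$gimbal$vz)
  pp <- pulse_phase(config, t)
  pulse <- pulse_waveform_values(config, pp$phase)
  amp <- config$pulse_direction * config$pulse_strength
  sc <- scene_radiance(config)
  H <- config$frame_size[1L]; W <- config$frame_size[2L]
  with_seed(config$seed + 303L, {
    jx <- round(bandlimited_noise(T_, config$frame_rate,
                                  config$motion_bandwidth_hz,
                                  config$bbox_jitter_px))
    jy <- round(bandlimited_noise(T_, config$frame_rate,
                                  config$motion_bandwidth_hz,
                                  config$bbox_jitter_px))
    visibility <- rep(TRUE, T_)
    for (win in config$dropout_windows)
      visibility[max(1L, win[1L]):min(T_, win[2L])] <- FALSE
    frames <- vector("list", T_)
    bboxes <- vector("list", T_)
    bg <- scene_radiance(config, face = FALSE)$radiance
    noise_quads <- lapply(Filter(function(r) r$role == "noise",
                                 default_roi_layout()), function(r)
      list(label = r$label,
           x0 = min(r$vertices[, 1]), x1 = max(r$vertices[, 1]),
           y0 = min(r$vertices[, 2]), y1 = max(r$vertices[, 2])))
    for (i in seq_len(T_)) {
      rad <- bg
      if (visibility[i]) {
        bb <- list(x = sc$bbox$x + jx[i], y = sc$bbox$y + jy[i],
                   w = sc$bbox$w, h = sc$bbox$h)
        rows <- intersect(seq_len(H), (bb$y + 1):(bb$y + bb$h))
        cols <- intersect(seq_len(W), (bb$x + 1):(bb$x + bb$w))
        for (ch in 1:3)
          rad[rows, cols, ch] <-
            (config$skin_base_color[ch] / 10) * (1 + amp[ch] * pulse[i])
        # bloodless features: nostril/eye patches carry no pulse, so the
        # noise ROIs measure lighting/motion but not the heart rate
        patch_color <- list(nostril_center = c(90, 70, 65),
                            nostril_right = c(95, 75, 70),
                            eye_center = c(60, 55, 55),
                            eye_right = c(62, 57, 56))
        for (r in noise_quads) {
          # painted with a margin so resampling blur at the patch border
          # cannot leak pulsing skin into the noise-ROI interior
          mx <- 0.3 * (r$x1 - r$x0); my <- 0.3 * (r$y1 - r$y0)
          pr <- intersect(seq_len(H),
                          (bb$y + round((r$y0 - my) * bb$h) + 1):
                            (bb$y + round((r$y1 + my) * bb$h)))
          pc <- intersect(seq_len(W),
                          (bb$x + round((r$x0 - mx) * bb$w) + 1):
                            (bb$x + round((r$x1 + mx) * bb$w)))
          for (ch in 1:3)
            rad[pr, pc, ch] <- patch_color[[r$label]][ch] / 10
        }
        bboxes[[i]] <- bb
      }
      img <- pmax(pmin(config$camera_gain * exposure_ms * rad, 255), 0)
      if (roll_f[i] != 0) {
        rot <- rotate_image(img, roll_f[i])  # camera sees the rolled scene
        s <- dim(rot)[1L]
        r0 <- floor((s - H) / 2); c0 <- floor((s - W) / 2)
        img <- rot[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W), , drop = FALSE]
      }
      frames[[i]] <- new_frame_record(i - 1L, t[i], round(img))
    }
    structure(list(frames = frames, gimbal = logs$gimbal,
                   flight = logs$flight, frame_rate = config$frame_rate,
                   ground_truth = list(roll = roll_f, bbox = bboxes,
                                       visibility = visibility,
                                       hr_series = pp$hr)),
              class = "recording_bundle")
  })
}

#' @export
print.recording_bundle <- function(x, ...) {
  d <- dim(x$frames[[1L]]$image)
  cat(sprintf(
    "recording bundle: %d frames (%dx%d) at %g fps, %d gimbal / %d flight samples\n",
    length(x$frames), d[2L], d[1L], x$frame_rate, nrow(x$gimbal),
    nrow(x$flight)))
  invisible(x)
}

#' Simulate the reference pulse-oximetry trace
#'
#' Periodic waveform at 100 Hz whose instantaneous rate follows the
#' configured HR series; serves as the agreement reference in evaluation.
#'
#' @param config A [scene_config()].
#' @param fs Sampling rate in Hz (default 100).
#' @return List with `t` (seconds), `values`, `hr_series` (bpm at each
#'   sample), `fs`.
#' @export
simulate_reference_pleth <- function(config, fs = 100) {
  n <- round(config$duration * fs)
  t <- (0:(n - 1L)) / fs
  pp <- pulse_phase(config, t)
  with_seed(config$seed + 404L, {
    v <- pulse_waveform_values(config, pp$phase) +
      stats::rnorm(n, sd = 0.02)
    list(t = t, values = v, hr_series = pp$hr, fs = fs)
  })
}
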