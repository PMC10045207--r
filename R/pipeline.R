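#' Run the full heart-rate estimation pipeline on a recording bundle
#'
#' Executes the five stages in order: digital derotation of every frame by
#' the time-matched gimbal roll; face detection and segmentation into
#' continuous time-frames of at least the configured minimum duration; raw
#' colour-signal extraction over the facial ROI layout; least-squares
#' de-noising of every measurement ROI against the assembled noise design
#' matrix; CHROM/POS colour mixing; and windowed, SNR-gated, median-fused
#' spectral HR estimation. Failures (no usable segment, no accepted
#' spectrum) are reported as result statuses, not errors.
#'
#' @param bundle A `recording_bundle` (from [read_bundle()] or
#'   [simulate_frames()]).
#' @param config A [pipeline_config()].
#' @param detector Face detector contract; default
#'   [synthetic_face_detector()].
#' @param layout ROI layout template relative to the face box; default
#'   [default_roi_layout()].
#' @return An `hr_result` with extra fields: `segments` (data.frame),
#'   `total_valid_samples`, `mean_face_exposure`, `provenance` (config
#'   checksum, seed, stage counts).
#' @export
run_estimate <- function(bundle, config = pipeline_config(),
                         detector = synthetic_face_detector(),
                         layout = default_roi_layout()) {
  validate_roi_layout(layout)
  stabilized <- stabilize_sequence(bundle)
  detections <- detect_face_series(stabilized, detector)
  fps <- bundle$frame_rate
  segments <- segment_timeframes(detections, fps, config$roi$min_segment_s)
  present <- which(!vapply(detections, is.null, logical(1)))
  mean_exposure <- if (length(present)) {
    mean(vapply(present, function(i)
      face_percentile_value(stabilized[[i]]$image, detections[[i]]),
      numeric(1)))
  } else NA_real_
  finish <- function(res) {
    res$segments <- segments
    res$total_valid_samples <- if (nrow(segments))
      sum(segments$end - segments$start + 1L) else 0L
    res$mean_face_exposure <- mean_exposure
    res$provenance <- list(
      config_checksum = config_checksum(config),
      seed = config$seed,
      n_frames = length(bundle$frames),
      n_detected = length(present),
      n_segments = nrow(segments),
      window_counts = as.list(res$window_counts),
      accepted_window_counts = as.list(res$accepted_window_counts))
    res
  }
  if (nrow(segments) == 0L) {
    res <- estimate_hr(list(), fps, config)  # status failed_no_segments
    return(finish(res))
  }
  ft <- vapply(bundle$frames, `[[`, numeric(1), "t")
  pulses <- list()
  for (si in seq_len(nrow(segments))) {
    seg <- segments[si, ]
    seg_id <- sprintf("seg%02d", si)
    provider <- function(i) scale_layout_to_bbox(layout, detections[[i]])
    rois <- extract_roi_signals(stabilized, seg, provider)
    noise_names <- c("nostril_center", "nostril_right",
                     "eye_center", "eye_right")
    if (!all(noise_names %in% names(rois))) {
      warning("run_estimate: noise ROIs degenerate in ", seg_id,
              "; segment skipped")
      next
    }
    logs <- match_logs_to_frames(bundle, ft[seg$start:seg$end])
    for (lbl in names(rois)) {
      roi <- rois[[lbl]]
      if (roi$role != "measurement") next
      X <- assemble_noise_matrix(roi, rois[noise_names], logs$flight,
                                 logs$gimbal)
      if (nrow(roi$means) <= length(X$column_labels)) {
        warning("run_estimate: segment ", seg_id,
                " too short to de-noise ROI ", lbl)
        next
      }
      dn <- glm_denoise(roi$means, X, center = config$denoise$center)
      ps <- mix_pulse_signals(dn, config$rppg$methods,
                              roi_label = lbl, segment_id = seg_id)
      pulses <- c(pulses, ps)
    }
  }
  res <- estimate_hr(pulses, fps, config)
  if (res$status == "ok" && length(pulses) == 0L)
    res$status <- "failed_no_segments"
  finish(res)
}

# order-stable checksum of the serialized configuration (provenance only)
#' @keywords internal
config_checksum <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(b * (seq_along(b) %% 251)) %% 4294967291)
}

#' Run HR estimation from pre-extracted ROI signals
#'
#' The estimation stages downstream of image processing: de-noising each
#' measurement ROI against the assembled noise design matrix, CHROM/POS
#' colour mixing, and spectral HR estimation. Accepts the output of
#' [extract_roi_signals()] or [simulate_roi_signals()] -- i.e. recordings
#' delivered as per-ROI colour time series rather than frames.
#'
#' @param rois Named list of `roi_signals` (30 measurement + 4 noise ROIs).
#' @param flight,gimbal Frame-matched sensor data.frames (one row per
#'   segment frame).
#' @param frame_rate Frames per second.
#' @param config A [pipeline_config()].
#' @param segment_id Provenance tag.
#' @return An `hr_result`.
#' @export
run_estimate_signals <- function(rois, flight, gimbal, frame_rate,
                                 config = pipeline_config(),
                                 segment_id = "seg01") {
  noise_names <- c("nostril_center", "nostril_right",
                   "eye_center", "eye_right")
  if (!all(noise_names %in% names(rois)))
    stop("run_estimate_signals: missing noise ROIs", call. = FALSE)
  pulses <- list()
  for (lbl in names(rois)) {
    roi <- rois[[lbl]]
    if (roi$role != "measurement") next
    X <- assemble_noise_matrix(roi, rois[noise_names], flight, gimbal)
    if (nrow(roi$means) <= length(X$column_labels)) {
      warning("run_estimate_signals: series too short to de-noise ", lbl)
      next
    }
    dn <- glm_denoise(roi$means, X, center = config$denoise$center)
    pulses <- c(pulses, mix_pulse_signals(dn, config$rppg$methods,
                                          roi_label = lbl,
                                          segment_id = segment_id))
  }
  estimate_hr(pulses, frame_rate, config)
}
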