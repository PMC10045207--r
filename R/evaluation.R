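#' Reference heart rate from a pulse-oximetry trace
#'
#' Beat detection by local-maxima peak picking with a refractory period of
#' 0.33 s (no rate above 180 bpm), instantaneous HR from inter-beat
#' intervals, averaged over the valid time spans of the video recording.
#'
#' @param pleth List with `values`, `fs` (Hz) and optionally `t`, as from
#'   [simulate_reference_pleth()], or a bare numeric vector (then give
#'   `fs`).
#' @param valid_spans List of `c(start_s, end_s)` intervals; default the
#'   whole trace.
#' @param fs Sampling rate if `pleth` is a bare vector.
#' @return Mean HR in bpm over the valid spans.
#' @export
reference_hr <- function(pleth, valid_spans = NULL, fs = NULL) {
  if (is.list(pleth)) { x <- pleth$values; fs <- pleth$fs } else x <- pleth
  stopifnot(!is.null(fs), fs > 0)
  if (length(x) == 0L)
    stop("reference_hr: empty pleth trace", call. = FALSE)
  if (is.null(valid_spans))
    valid_spans <- list(c(0, (length(x) - 1) / fs))
  refractory <- ceiling(0.33 * fs)
  n <- length(x)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] > x[3:n]) + 1L
  # systolic peaks only: local maxima in the upper half of the waveform
  thr <- (stats::median(x) + max(x)) / 2
  cand <- cand[x[cand] >= thr]
  cand <- cand[order(-x[cand])]  # greedy by amplitude, enforce refractory
  taken <- integer(0)
  for (i in cand)
    if (!length(taken) || all(abs(taken - i) >= refractory))
      taken <- c(taken, i)
  beats <- sort(taken) / fs  # beat times in seconds
  if (length(beats) < 2L)
    stop("reference_hr: fewer than 2 beats in the valid spans",
         call. = FALSE)
  ibi_t <- (beats[-1L] + beats[-length(beats)]) / 2  # midpoints
  ibi_hr <- 60 / diff(beats)
  in_span <- vapply(ibi_t, function(ti)
    any(vapply(valid_spans, function(s) ti >= s[1L] && ti <= s[2L],
               logical(1))), logical(1))
  if (!any(in_span))
    stop("reference_hr: fewer than 2 beats in the valid spans",
         call. = FALSE)
  mean(ibi_hr[in_span])
}

#' Root-mean-squared error between estimated and reference HR
#'
#' @param records data.frame with columns `hr_estimated` and `hr_reference`
#'   (bpm), one row per recording.
#' @return RMSE in bpm.
#' @export
hr_rmse <- function(records) {
  if (NROW(records) == 0L)
    stop("hr_rmse: no records", call. = FALSE)
  d <- records$hr_estimated - records$hr_reference
  if (anyNA(d)) stop("hr_rmse: missing HR values", call. = FALSE)
  sqrt(mean(d^2))
}

#' Bland-Altman agreement statistics
#'
#' Bias is the mean difference (estimated minus reference); the 95% limits
#' of agreement are `bias +/- 1.96 * sd` with the population standard
#' deviation of the differences.
#'
#' @inheritParams hr_rmse
#' @return List with `bias`, `loa_low`, `loa_high` (bpm).
#' @export
bland_altman <- function(records) {
  d <- records$hr_estimated - records$hr_reference
  if (length(d) < 2L)
    stop("bland_altman: need at least 2 records", call. = FALSE)
  bias <- mean(d)
  s <- sqrt(mean((d - bias)^2))
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Motion / exposure subset split of comparison records
#'
#' Labels each recording as high motion (total valid samples strictly below
#' the threshold) or low motion, and as inside the exposure range (mean face
#' value within the closed bounds) or outside, then reports the RMSE and
#' count for the four cells and the margins -- the standard cross-table of
#' recording-condition effects.
#'
#' @param records data.frame with `hr_estimated`, `hr_reference`,
#'   `total_valid_samples`, `mean_face_exposure`.
#' @param motion_threshold_samples High/low motion cut (default 225 samples,
#'   i.e. 15 s at 15 fps).
#' @param exposure_bounds Closed inside-range bounds (default
#'   `c(190, 250)`).
#' @return List with `labels` (data.frame of per-record `motion`,
#'   `exposure`) and `table` (data.frame: `motion`, `exposure`, `n`,
#'   `rmse`), including `all` margins.
#' @export
subset_split <- function(records, motion_threshold_samples = 225L,
                         exposure_bounds = c(190, 250)) {
  if (NROW(records) == 0L)
    return(list(labels = data.frame(motion = character(0),
                                    exposure = character(0)),
                table = data.frame(motion = character(0),
                                   exposure = character(0),
                                   n = integer(0), rmse = numeric(0))))
  motion <- ifelse(records$total_valid_samples < motion_threshold_samples,
                   "high", "low")
  exposure <- ifelse(records$mean_face_exposure >= exposure_bounds[1L] &
                       records$mean_face_exposure <= exposure_bounds[2L],
                     "inside", "outside")
  cell <- function(m, e) {
    sel <- (m == "all" | motion == m) & (e == "all" | exposure == e)
    data.frame(motion = m, exposure = e, n = sum(sel),
               rmse = if (any(sel)) hr_rmse(records[sel, , drop = FALSE])
                      else NA_real_)
  }
  grid <- expand.grid(m = c("high", "low", "all"),
                      e = c("outside", "inside", "all"),
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, Map(cell, grid$m, grid$e))
  rownames(tab) <- NULL
  list(labels = data.frame(motion = motion, exposure = exposure), table = tab)
}

#' Full evaluation report
#'
#' @inheritParams subset_split
#' @return An `evaluation_report`: `rmse`, `bias`, `loa_low`, `loa_high`,
#'   `subsets` (the [subset_split()] table), `n`.
#' @export
evaluation_report <- function(records, motion_threshold_samples = 225L,
                              exposure_bounds = c(190, 250)) {
  ba <- bland_altman(records)
  structure(list(n = NROW(records), rmse = hr_rmse(records),
                 bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high,
                 subsets = subset_split(records, motion_threshold_samples,
                                        exposure_bounds)$table),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation of %d recordings\n", x$n))
  cat(sprintf("  RMSE %.2f bpm; bias %.2f bpm; 95%% limits of agreement [%.2f, %.2f] bpm\n",
              x$rmse, x$bias, x$loa_low, x$loa_high))
  cat("  subset RMSEs (bpm):\n")
  print(x$subsets, row.names = FALSE)
  invisible(x)
}
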