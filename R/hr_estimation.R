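#' Slice a pulse signal into overlapping analysis windows
#'
#' @param pulse A `pulse_signal` or numeric vector.
#' @param window Window length in samples (default 45).
#' @param stride Hop between window starts in samples (default 2).
#' @return List of numeric windows, `floor((L - window)/stride) + 1` of
#'   them; empty when the signal is shorter than one window.
#' @export
window_signal <- function(pulse, window = 45L, stride = 2L) {
  x <- if (inherits(pulse, "pulse_signal")) pulse$values else pulse
  L <- length(x)
  if (L < window) return(list())
  starts <- seq.int(1L, L - window + 1L, by = stride)
  lapply(starts, function(s) x[s:(s + window - 1L)])
}

#' Power spectrum of a window on a fine beats-per-minute grid
#'
#' The window is mean-removed, zero-padded until the frequency grid is at
#' least as fine as `grid_bpm` (the bare 45-sample transform at 15 fps has
#' 20 bpm bins -- far too coarse for bpm-level output; padding interpolates
#' the spectrum without adding information), and transformed. Power is the
#' squared magnitude on the nonnegative-frequency grid.
#'
#' @param sub_signal Numeric vector (length >= 2).
#' @param frame_rate Sampling rate in frames per second.
#' @param grid_bpm Maximum grid spacing in bpm (default 1).
#' @return A `spectrum_window`: list with `freqs_bpm` and `power`.
#' @export
compute_spectrum <- function(sub_signal, frame_rate, grid_bpm = 1) {
  L <- length(sub_signal)
  stopifnot(L >= 2L, frame_rate > 0)
  x <- sub_signal - mean(sub_signal)
  n <- max(L, ceiling(frame_rate * 60 / grid_bpm))
  xp <- c(x, numeric(n - L))
  sp <- stats::fft(xp)
  nk <- floor(n / 2) + 1L
  structure(list(freqs_bpm = (0:(nk - 1L)) * frame_rate * 60 / n,
                 power = Mod(sp[1:nk])^2),
            class = "spectrum_window")
}

#' Band-power signal-to-noise ratio of a spectral peak
#'
#' Ratio of the power within `peak_bpm +/- alpha` to all remaining power:
#' `sum(P[p-a, p+a]) / (sum(P) - sum(P[p-a, p+a]))`. Used to gate analysis
#' windows whose spectra are too noisy for HR assessment.
#'
#' @param spectrum A `spectrum_window`.
#' @param peak_bpm Peak frequency in bpm (must lie on/within the grid).
#' @param alpha Half peak width in bpm (default 3).
#' @return The SNR ratio; `Inf` when all power sits inside the peak band.
#' @export
peak_snr <- function(spectrum, peak_bpm, alpha = 3) {
  f <- spectrum$freqs_bpm
  if (peak_bpm < min(f) || peak_bpm > max(f))
    stop("peak_snr: peak frequency outside the spectral grid", call. = FALSE)
  inband <- f >= peak_bpm - alpha & f <= peak_bpm + alpha
  sig <- sum(spectrum$power[inband])
  noise <- sum(spectrum$power) - sig
  if (noise <= 0) return(Inf)
  sig / noise
}

# strictly-local maxima (positive prominence) among the given indices
#' @keywords internal
local_maxima <- function(power) {
  n <- length(power)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  1L + which(power[i] > power[i - 1L] & power[i] > power[i + 1L])
}

#' Accept or reject a window spectrum for HR estimation
#'
#' Two conditions, both required: (a) a local spectral peak inside the
#' target band whose band-power SNR reaches `snr_min`; (b) no power in the
#' low-frequency band (DC excluded) exceeding the target-band maximum --
#' this rejects windows where harmonics of prominent sub-50 bpm drift could
#' masquerade as a heart rate.
#'
#' @param spectrum A `spectrum_window` covering both bands.
#' @param snr_min Minimum peak SNR (default 0.025, i.e. 2.5%).
#' @param band Target HR band in bpm, inclusive (default `c(50, 180)`).
#' @param alpha Peak half-width in bpm for the SNR (default 3).
#' @return Logical.
#' @export
accept_spectrum <- function(spectrum, snr_min = 0.025, band = c(50, 180),
                            alpha = 3) {
  f <- spectrum$freqs_bpm
  p <- spectrum$power
  if (max(f) < band[2L])
    stop("accept_spectrum: spectrum does not cover the target band",
         call. = FALSE)
  in_band <- f >= band[1L] & f <= band[2L]
  low <- f > 0 & f < band[1L]
  if (!any(in_band)) return(FALSE)
  peaks <- local_maxima(p)
  peaks <- peaks[in_band[peaks]]
  cond_a <- any(vapply(peaks, function(i)
    peak_snr(spectrum, f[i], alpha) >= snr_min, logical(1)))
  cond_b <- !any(low) || max(p[low]) <= max(p[in_band])
  cond_a && cond_b
}

#' Per-frequency median of accepted window spectra
#'
#' Pools all accepted windows of one colour-mixing method (across ROIs,
#' segments and window positions) into a single robust spectrum: the median
#' of the power at each frequency bin (even counts: mean of the two central
#' values).
#'
#' @param spectra Nonempty list of `spectrum_window` with identical grids.
#' @return A `spectrum_window`.
#' @export
median_spectrum <- function(spectra) {
  if (length(spectra) == 0L)
    stop("median_spectrum: no accepted spectra", call. = FALSE)
  f <- spectra[[1L]]$freqs_bpm
  for (s in spectra)
    if (!isTRUE(all.equal(s$freqs_bpm, f)))
      stop("median_spectrum: spectra have different grids", call. = FALSE)
  pw <- vapply(spectra, `[[`, numeric(length(f)), "power")
  structure(list(freqs_bpm = f,
                 power = apply(pw, 1, stats::median)),
            class = "spectrum_window")
}

#' Single-value heart-rate estimate from pooled pulse signals
#'
#' Implements the windowed, SNR-gated, median-fused spectral estimator:
#' every pulse signal is sliced into overlapping windows, each window's
#' spectrum is gated by [accept_spectrum()], the surviving spectra are
#' pooled per colour-mixing method into a median spectrum, the per-method
#' HR is the frequency of that spectrum's maximum inside the target band
#' (ties broken toward the lower frequency), and the final HR is the mean
#' of the per-method values.
#'
#' @param pulse_signals List of `pulse_signal` (both methods mixed).
#' @param frame_rate Frames per second.
#' @param config A [pipeline_config()] (only the `hr` keys are used).
#' @return An `hr_result`: `hr_pos`, `hr_chrom`, `hr_final` (bpm or `NA`),
#'   `accepted_window_counts`, `window_counts`, `median_spectra`, `status`
#'   in `ok | failed_no_segments | failed_no_accepted_spectra`.
#' @export
estimate_hr <- function(pulse_signals, frame_rate, config = pipeline_config()) {
  hc <- config$hr
  res <- list(hr_pos = NA_real_, hr_chrom = NA_real_, hr_final = NA_real_,
              accepted_window_counts = c(CHROM = 0L, POS = 0L),
              window_counts = c(CHROM = 0L, POS = 0L),
              median_spectra = list(), status = "ok")
  class(res) <- "hr_result"
  if (length(pulse_signals) == 0L) {
    res$status <- "failed_no_segments"
    return(res)
  }
  hr_by_method <- c(CHROM = NA_real_, POS = NA_real_)
  for (m in c("CHROM", "POS")) {
    sigs <- Filter(function(s) s$method == m, pulse_signals)
    accepted <- list()
    n_windows <- 0L
    for (s in sigs) {
      for (w in window_signal(s, hc$window_samples, hc$stride_samples)) {
        n_windows <- n_windows + 1L
        sp <- compute_spectrum(w, frame_rate, hc$grid_bpm)
        if (accept_spectrum(sp, hc$snr_min, hc$band_bpm, hc$alpha_bpm))
          accepted[[length(accepted) + 1L]] <- sp
      }
    }
    res$window_counts[m] <- n_windows
    res$accepted_window_counts[m] <- length(accepted)
    if (length(accepted) == 0L) next
    med <- median_spectrum(accepted)
    res$median_spectra[[m]] <- med
    in_band <- med$freqs_bpm >= hc$band_bpm[1L] &
      med$freqs_bpm <= hc$band_bpm[2L]
    fb <- med$freqs_bpm[in_band]; pb <- med$power[in_band]
    hr_by_method[m] <- fb[which.max(pb)]  # which.max: first (lowest) on ties
  }
  res$hr_chrom <- hr_by_method["CHROM"]
  res$hr_pos <- hr_by_method["POS"]
  present <- !is.na(hr_by_method)
  if (!any(present)) {
    res$status <- "failed_no_accepted_spectra"
  } else {
    res$hr_final <- mean(hr_by_method[present])
  }
  res
}

#' @export
print.hr_result <- function(x, ...) {
  cat("heart-rate assessment:", x$status, "\n")
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.1f bpm", v)
  cat(sprintf("  CHROM: %s  (%d/%d windows accepted)\n",
              fmt(x$hr_chrom), x$accepted_window_counts["CHROM"],
              x$window_counts["CHROM"]))
  cat(sprintf("  POS:   %s  (%d/%d windows accepted)\n",
              fmt(x$hr_pos), x$accepted_window_counts["POS"],
              x$window_counts["POS"]))
  cat(sprintf("  final: %s\n", fmt(x$hr_final)))
  invisible(x)
}

#' Serialize an HR result as JSON
#' @param x An `hr_result`.
#' @param path File path; when `NULL` the JSON string is returned.
#' @export
hr_result_json <- function(x, path = NULL) {
  obj <- list(hr_final = x$hr_final, hr_pos = unname(x$hr_pos),
              hr_chrom = unname(x$hr_chrom),
              accepted_counts = as.list(x$accepted_window_counts),
              status = x$status)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
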