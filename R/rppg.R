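# shared guards for the two colour-mixing models
normalize_channels <- function(R, G, B) {
  n <- length(R)
  if (length(G) != n || length(B) != n || n < 2L)
    stop("colour mixing: channels must have equal length >= 2", call. = FALSE)
  mu <- c(mean(R), mean(G), mean(B))
  if (any(abs(mu) < .Machine$double.eps))
    stop("colour mixing: zero channel mean, cannot normalize", call. = FALSE)
  list(Rn = R / mu[1], Gn = G / mu[2], Bn = B / mu[3])
}

near_zero_sd <- function(x) stats::sd(x) < 1e-12 * max(1, abs(mean(x)))

new_pulse_signal <- function(values, method, roi_label, segment_id) {
  structure(list(method = method, roi_label = roi_label,
                 segment_id = segment_id,
                 values = values - mean(values)),
            class = "pulse_signal")
}

#' CHROM pulse signal from de-noised colour channels
#'
#' Chrominance-based pulse extraction: the mean-normalized channels are
#' projected onto two fixed chrominance axes, `Xs = 3 Rn - 2 Gn` and
#' `Ys = 1.5 Rn + Gn - 1.5 Bn`, and combined as `S = Xs - alpha * Ys` with
#' `alpha = sd(Xs) / sd(Ys)` so that (white-light) intensity distortions
#' cancel. The channels passed in should be the de-noised series with their
#' physical DC restored (normalization needs a real mean level).
#'
#' @param R,G,B Numeric series of equal length.
#' @param roi_label,segment_id Optional provenance tags.
#' @return A zero-mean `pulse_signal` with `method = "CHROM"`.
#' @export
chrom_signal <- function(R, G, B, roi_label = "", segment_id = "") {
  ch <- normalize_channels(R, G, B)
  Xs <- 3 * ch$Rn - 2 * ch$Gn
  Ys <- 1.5 * ch$Rn + ch$Gn - 1.5 * ch$Bn
  if (near_zero_sd(Ys)) {
    if (near_zero_sd(Xs))  # constant input: no pulse, defined as zero
      return(new_pulse_signal(numeric(length(R)), "CHROM",
                              roi_label, segment_id))
    stop("chrom_signal: degenerate signal, sd(Ys) ~ 0", call. = FALSE)
  }
  s <- Xs - (stats::sd(Xs) / stats::sd(Ys)) * Ys
  new_pulse_signal(s, "CHROM", roi_label, segment_id)
}

#' POS pulse signal from de-noised colour channels
#'
#' Plane-orthogonal-to-skin pulse extraction: the mean-normalized channels
#' are projected onto the plane orthogonal to the unit skin-tone vector via
#' `S1 = Gn - Bn` and `S2 = Gn + Bn - 2 Rn`, and fused as
#' `h = S1 + (sd(S1)/sd(S2)) * S2`. Pure common-mode intensity modulation
#' maps to exactly zero in both projections.
#'
#' @inheritParams chrom_signal
#' @return A zero-mean `pulse_signal` with `method = "POS"`.
#' @export
pos_signal <- function(R, G, B, roi_label = "", segment_id = "") {
  ch <- normalize_channels(R, G, B)
  S1 <- ch$Gn - ch$Bn
  S2 <- ch$Gn + ch$Bn - 2 * ch$Rn
  if (near_zero_sd(S2)) {
    if (near_zero_sd(S1))
      return(new_pulse_signal(numeric(length(R)), "POS",
                              roi_label, segment_id))
    stop("pos_signal: degenerate signal, sd(S2) ~ 0", call. = FALSE)
  }
  h <- S1 + (stats::sd(S1) / stats::sd(S2)) * S2
  new_pulse_signal(h, "POS", roi_label, segment_id)
}

#' Colour-mix a de-noised ROI into pulse signals
#'
#' Restores the per-channel DC level removed by the de-noising centering,
#' then applies the requested colour-mixing models once per segment.
#'
#' @param denoise Result of [glm_denoise()] for one ROI.
#' @param methods Character subset of `c("CHROM", "POS")`.
#' @param roi_label,segment_id Provenance tags carried into the signals.
#' @return List of `pulse_signal`.
#' @export
mix_pulse_signals <- function(denoise, methods = c("CHROM", "POS"),
                              roi_label = "", segment_id = "") {
  methods <- match.arg(methods, c("CHROM", "POS"), several.ok = TRUE)
  y <- sweep(denoise$denoised, 2, denoise$channel_means, "+")
  lapply(methods, function(m) {
    fn <- if (m == "CHROM") chrom_signal else pos_signal
    fn(y[, 1], y[, 2], y[, 3], roi_label = roi_label,
       segment_id = segment_id)
  })
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("%s pulse signal [%s%s]: %d samples, sd %.4g\n",
              x$method, x$roi_label,
              if (nzchar(x$segment_id)) paste0(" / ", x$segment_id) else "",
              length(x$values), stats::sd(x$values)))
  invisible(x)
}
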