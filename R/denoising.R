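#' First-order derivative of a sampled series
#'
#' Central differences on the interior, one-sided forward/backward
#' differences at the first and last sample, unit step (series are already
#' frame-matched). Output has the same length as the input, so derivative
#' columns align with their parents in the noise design matrix.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' first_derivative(c(0, 1, 4, 9))  # 1 2 4 5
first_derivative <- function(x) {
  n <- length(x)
  if (n < 2L)
    stop("first_derivative: need at least 2 samples", call. = FALSE)
  d <- numeric(n)
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d
}

# fixed assembly order of the noise design matrix; K = 4V + 27 columns for
# V polygon vertices (V in 4..6)
noise_column_labels <- function(n_vertices) {
  lm <- as.vector(t(outer(seq_len(n_vertices), c("x", "y"),
                          function(i, a) paste0("landmark", i, "_", a))))
  c(lm, paste0("d_", lm),
    "com_x", "com_y", "d_com_x", "d_com_y",
    "pixel_count",
    "height_m", "longitude_deg", "latitude_deg",
    "vel_u", "vel_v", "vel_w",
    "nostril_center", "nostril_right", "eye_center", "eye_right",
    paste0("h_", c("x", "y", "z")), paste0("v_", c("x", "y", "z")),
    paste0("d_h_", c("x", "y", "z")), paste0("d_v_", c("x", "y", "z")))
}

#' Assemble the noise design matrix for one measurement ROI
#'
#' Builds the T x K design matrix of known nuisance signals removed from the
#' ROI's colour channels: the ROI's own tracking signals (vertex
#' coordinates, center-of-mass, their first derivatives, pixel count),
#' flight-sensor signals (height, longitude, latitude, 3-component
#' velocity), the mean colours of the four bloodless noise regions
#' (nostrils and eyes, center/right), and the gimbal view vectors h, v with
#' their first derivatives. Column order is fixed and labelled so mixing
#' weights stay interpretable; K = 4V + 27 for V polygon vertices.
#'
#' The four noise-region columns are channel-matched: when channel `c` of
#' the ROI is de-noised, those columns carry channel `c` of the noise
#' regions (lighting noise is channel-specific). The returned object
#' therefore holds one T x K matrix per colour channel; all other columns
#' are shared.
#'
#' @param roi `roi_signals` of the measurement ROI.
#' @param noise_rois Named list of the 4 noise `roi_signals`
#'   (`nostril_center`, `nostril_right`, `eye_center`, `eye_right`).
#' @param flight data.frame of frame-matched flight-sensor samples with
#'   columns `height_m`, `longitude_deg`, `latitude_deg`, `vel_u`, `vel_v`,
#'   `vel_w` (T rows).
#' @param gimbal data.frame of frame-matched gimbal samples with columns
#'   `hx, hy, hz, vx, vy, vz` (T rows).
#' @return A `noise_matrix` object: list with `values` (list of T x K
#'   matrices `R`, `G`, `B`), `column_labels`, `n_vertices`, and
#'   `degenerate` (labels of constant columns, kept but flagged).
#' @export
assemble_noise_matrix <- function(roi, noise_rois, flight, gimbal) {
  T_ <- nrow(roi$means)
  need <- c("nostril_center", "nostril_right", "eye_center", "eye_right")
  if (!all(need %in% names(noise_rois)))
    stop("assemble_noise_matrix: need the 4 noise ROIs: ",
         paste(need, collapse = ", "), call. = FALSE)
  lens <- c(length(roi$pixel_count), nrow(flight), nrow(gimbal),
            vapply(noise_rois[need], function(s) nrow(s$means), integer(1)))
  if (any(lens != T_))
    stop("assemble_noise_matrix: series not aligned to the segment length",
         call. = FALSE)
  nv <- ncol(roi$landmarks) / 2L
  lm <- roi$landmarks
  d_lm <- apply(lm, 2, first_derivative)
  com <- roi$com
  gm <- as.matrix(gimbal[, c("hx", "hy", "hz", "vx", "vy", "vz")])
  shared_pre <- cbind(lm, d_lm, com, apply(com, 2, first_derivative),
                      roi$pixel_count,
                      flight$height_m, flight$longitude_deg,
                      flight$latitude_deg,
                      flight$vel_u, flight$vel_v, flight$vel_w)
  shared_post <- cbind(gm, apply(gm, 2, first_derivative))
  labels <- noise_column_labels(nv)
  vals <- lapply(c(R = 1L, G = 2L, B = 3L), function(ch) {
    nz <- vapply(noise_rois[need], function(s) s$means[, ch],
                 numeric(T_))
    x <- cbind(shared_pre, nz, shared_post)
    colnames(x) <- labels
    x
  })
  degenerate <- labels[apply(vals$G, 2, stats::sd) == 0]
  structure(list(values = vals, column_labels = labels, n_vertices = nv,
                 degenerate = degenerate),
            class = "noise_matrix")
}

#' @export
print.noise_matrix <- function(x, ...) {
  cat(sprintf("noise design matrix: %d frames x %d columns (%d-vertex ROI)\n",
              nrow(x$values$G), length(x$column_labels), x$n_vertices))
  if (length(x$degenerate))
    cat("  degenerate (constant) columns:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

# minimum-norm least squares via SVD pseudo-inverse; tolerant of
# rank-deficient (e.g. constant) columns
#' @keywords internal
min_norm_lstsq <- function(X, y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(numeric(ncol(X)))
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
}

#' Least-squares de-noising of ROI colour channels
#'
#' Models each raw colour channel as a linear mixture of the known noise
#' signals plus the pulse and an unknown residual, `Y = X M + P + E`,
#' solves for the mixing matrix `M` by (minimum-norm) least squares, and
#' returns the de-noised channels `Y - X M`. Y and the columns of X are
#' mean-centered before solving (equivalent to an intercept), so the DC
#' level cannot absorb noise weights; the channel means are reported so the
#' colour-mixing step can restore the physical DC.
#'
#' @param Y T x 3 matrix of raw channel series (columns R, G, B).
#' @param X A `noise_matrix` from [assemble_noise_matrix()], or a plain
#'   T x K matrix applied identically to all channels.
#' @param center Mean-center Y and X columns before solving (default TRUE).
#' @return List with `denoised` (T x 3, centered residuals), `mixing`
#'   (K x 3 matrix `M`), `residual_norms` (length 3), `channel_means`
#'   (length 3), `column_labels`.
#' @export
glm_denoise <- function(Y, X, center = TRUE) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 3L)
  per_channel <- inherits(X, "noise_matrix")
  Xs <- if (per_channel) X$values else list(R = X, G = X, B = X)
  labels <- if (per_channel) X$column_labels else colnames(Xs$G)
  T_ <- nrow(Y); K <- ncol(Xs$G)
  if (nrow(Xs$G) != T_)
    stop("glm_denoise: Y and X row counts differ", call. = FALSE)
  if (T_ <= K)
    stop(sprintf(paste0(
      "glm_denoise: under-determined system (T = %d <= K = %d); ",
      "lengthen the segment or reduce noise sources"), T_, K), call. = FALSE)
  mu <- colMeans(Y)
  M <- matrix(NA_real_, K, 3, dimnames = list(labels, c("R", "G", "B")))
  denoised <- matrix(NA_real_, T_, 3, dimnames = list(NULL, c("R", "G", "B")))
  for (ch in 1:3) {
    x <- Xs[[ch]]
    y <- Y[, ch]
    if (center) {
      x <- sweep(x, 2, colMeans(x))
      y <- y - mu[ch]
    }
    m <- min_norm_lstsq(x, y)
    M[, ch] <- m
    denoised[, ch] <- y - as.vector(x %*% m)
  }
  list(denoised = denoised, mixing = M,
       residual_norms = sqrt(colSums(denoised^2)),
       channel_means = mu, column_labels = labels)
}
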