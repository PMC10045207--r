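# plain-text ASCII PPM (P3) image codec: the bundle's frame format.
# Trivial by design -- a text format any tool can read, no binary payload.

#' Write / read an 8-bit RGB image as ASCII PPM (P3)
#' @param image H x W x 3 array of 8-bit values.
#' @param path File path (conventionally `.ppm`).
#' @export
write_ppm <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  vals <- as.integer(round(aperm(image, c(3L, 2L, 1L))))  # R,G,B per pixel, row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(vals[seq(1, length(vals), 3)],
                   vals[seq(2, length(vals), 3)],
                   vals[seq(3, length(vals), 3)]), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1L] != "P3") stop("read_ppm: not an ASCII PPM (P3) file",
                            call. = FALSE)
  w <- as.integer(txt[2L]); h <- as.integer(txt[3L])
  vals <- as.numeric(txt[-(1:4)])
  if (length(vals) != 3L * w * h)
    stop("read_ppm: truncated pixel data", call. = FALSE)
  aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
}

# CSV writer that round-trips doubles exactly
#' @keywords internal
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a recording bundle to a directory
#'
#' Layout: `frames.csv` (`index,timestamp_s,filename`) plus one ASCII PPM
#' per frame, `gimbal.csv` (`timestamp_s,hx,hy,hz,vx,vy,vz`), `flight.csv`
#' (`timestamp_s,height_m,longitude_deg,latitude_deg,vel_u,vel_v,vel_w`),
#' and `ground_truth.json` when the bundle carries simulator ground truth.
#'
#' @param bundle A `recording_bundle`.
#' @param dir Output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- sprintf("frame_%06d.ppm", vapply(bundle$frames, `[[`, integer(1),
                                         "index"))
  for (i in seq_along(bundle$frames))
    write_ppm(bundle$frames[[i]]$image, file.path(dir, fn[i]))
  write_csv_exact(data.frame(
    index = vapply(bundle$frames, `[[`, integer(1), "index"),
    timestamp_s = vapply(bundle$frames, `[[`, numeric(1), "t"),
    filename = fn), file.path(dir, "frames.csv"))
  write_csv_exact(bundle$gimbal, file.path(dir, "gimbal.csv"))
  write_csv_exact(bundle$flight, file.path(dir, "flight.csv"))
  meta <- list(frame_rate = bundle$frame_rate)
  if (!is.null(bundle$ground_truth)) {
    gt <- bundle$ground_truth
    meta$ground_truth <- list(roll = gt$roll, visibility = gt$visibility,
                              hr_series = gt$hr_series)
  }
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording bundle from a directory
#'
#' @param dir Directory written by [write_bundle()] (or hand-assembled with
#'   the same layout). Sensor logs are expected time-sorted; unsorted logs
#'   are sorted with a warning.
#' @return A `recording_bundle`.
#' @export
read_bundle <- function(dir) {
  fcsv <- file.path(dir, "frames.csv")
  if (!file.exists(fcsv))
    stop("read_bundle: missing frames.csv in ", dir, call. = FALSE)
  ftab <- utils::read.csv(fcsv)
  frames <- lapply(seq_len(nrow(ftab)), function(i)
    new_frame_record(as.integer(ftab$index[i]), ftab$timestamp_s[i],
                     read_ppm(file.path(dir, ftab$filename[i]))))
  sorted_log <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    d <- utils::read.csv(p)
    if (is.unsorted(d$timestamp_s)) {
      warning("read_bundle: ", name, " not time-sorted; sorting")
      d <- d[order(d$timestamp_s), , drop = FALSE]
    }
    d
  }
  meta_path <- file.path(dir, "bundle.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  fr <- meta$frame_rate
  if (is.null(fr)) {
    dt <- diff(ftab$timestamp_s)
    fr <- 1 / stats::median(dt)
  }
  structure(list(frames = frames,
                 gimbal = sorted_log("gimbal.csv"),
                 flight = sorted_log("flight.csv"),
                 frame_rate = fr,
                 ground_truth = meta$ground_truth),
            class = "recording_bundle")
}

#' Export extracted ROI signals as CSV
#'
#' One long-format row per frame, ROI and channel, with the tracking
#' side-channels repeated per row.
#'
#' @param rois Named list of `roi_signals`.
#' @param path Output CSV path.
#' @export
write_roi_signals <- function(rois, path) {
  rows <- lapply(rois, function(s) {
    T_ <- nrow(s$means)
    lm <- s$landmarks
    colnames(lm) <- paste0("v", rep(seq_len(ncol(lm) / 2), each = 2) - 1L,
                           c("x", "y"))
    do.call(rbind, lapply(c("R", "G", "B"), function(ch)
      cbind(data.frame(frame = seq_len(T_) - 1L, roi = s$label,
                       channel = ch, mean = s$means[, ch],
                       pixel_count = s$pixel_count,
                       com_x = s$com[, 1], com_y = s$com[, 2]),
            as.data.frame(lm))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
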