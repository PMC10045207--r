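#' Pipeline configuration with field-standard defaults
#'
#' All stage parameters in one validated object. The defaults are the
#' constants of the published pipeline: exposure target band (190, 230) with
#' at most 10 iterations; 5 s minimum segment; 45-sample analysis windows
#' with stride 2; SNR gate 0.025 with 3 bpm peak half-width; target band
#' 50-180 bpm on a <= 1 bpm grid; 225-sample motion split and [190, 250]
#' exposure split for evaluation.
#'
#' @param ... Overrides as nested named lists matching the default
#'   structure, e.g. `hr = list(snr_min = 0.05)`. Unknown keys are rejected.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    exposure = list(init_ms = 10, max_iter = 10L, target = c(190, 230)),
    roi = list(min_segment_s = 5),
    denoise = list(center = TRUE,
                   use_sources = "all"),
    rppg = list(methods = c("CHROM", "POS")),
    hr = list(window_samples = 45L, stride_samples = 2L, snr_min = 0.025,
              alpha_bpm = 3, band_bpm = c(50, 180), grid_bpm = 1),
    evaluation = list(motion_threshold_samples = 225L,
                      exposure_bounds = c(190, 250)),
    seed = 1L
  )
  overrides <- list(...)
  merged <- merge_config(defaults, overrides, path = "")
  structure(merged, class = "pipeline_config")
}

#' @keywords internal
merge_config <- function(base, over, path) {
  if (length(over) == 0L) return(base)
  nm <- names(over)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("pipeline_config: overrides must be named", call. = FALSE)
  unknown <- setdiff(nm, names(base))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(over[[k]]))
        stop("pipeline_config: key '", k, "' must be a named list",
             call. = FALSE)
      base[[k]] <- merge_config(base[[k]], over[[k]],
                                paste0(path, ".", k))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Read / write a pipeline configuration as JSON
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$exposure$max_iter <- as.integer(raw$exposure$max_iter)
  raw$hr$window_samples <- as.integer(raw$hr$window_samples)
  raw$hr$stride_samples <- as.integer(raw$hr$stride_samples)
  raw$evaluation$motion_threshold_samples <-
    as.integer(raw$evaluation$motion_threshold_samples)
  raw$seed <- as.integer(raw$seed)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline configuration:\n")
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA), "\n")
  invisible(x)
}
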