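# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-world ROI-signal simulation at 72 bpm
sim72 <- function() cached("sim72", {
  simulate_roi_signals(scene_config(true_hr = 72, seed = 11))
})

# frame-level bundle with a mid-recording face dropout; the visible run
# (10.3 s) matches the study's typical valid lengths -- segments near the
# 5 s minimum leave too few samples per design column for stable de-noising
bundle_short <- function() cached("bundle_short", {
  simulate_frames(scene_config(true_hr = 80, duration = 12, seed = 3,
                               dropout_windows = list(c(10, 25))))
})

# test image: smooth gradient with an off-center bright square (structure
# in every direction, so rotation errors are visible)
test_image <- function(h = 40, w = 40) {
  base <- outer(seq(0, 80, length.out = h), seq(0, 80, length.out = w), `+`)
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- base * k / 3
  img[round(h * 0.2):round(h * 0.4), round(w * 0.55):round(w * 0.8), ] <- 220
  img
}

# spectrum object on an explicit grid (for constructed-spectrum tests)
make_spectrum <- function(freqs_bpm, power) {
  structure(list(freqs_bpm = freqs_bpm, power = power),
            class = "spectrum_window")
}

# uniform camera over a flat scene: pixel = clip(gain * exposure)
flat_camera <- function(gain, min_exposure = 1e-4, max_exposure = 1e6,
                        h = 20, w = 20) {
  list(capture = function(exposure_ms) {
    matrix(pmax(pmin(gain * exposure_ms, 255), 0), h, w)
  }, min_exposure = min_exposure, max_exposure = max_exposure)
}

full_bbox <- function(h = 20, w = 20) list(x = 0L, y = 0L, w = w, h = h)

# independent pseudo-inverse for projection oracles
MASS_ginv <- function(X) MASS::ginv(X)
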