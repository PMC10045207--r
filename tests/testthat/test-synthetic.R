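test_that("all generators are deterministic under a fixed seed", {
  cfg <- scene_config(duration = 3, seed = 21)
  expect_identical(simulate_flight_logs(cfg), simulate_flight_logs(cfg))
  s1 <- simulate_roi_signals(cfg); s2 <- simulate_roi_signals(cfg)
  expect_identical(s1$rois, s2$rois)
  expect_identical(simulate_reference_pleth(cfg)$values,
                   simulate_reference_pleth(cfg)$values)
  b1 <- simulate_frames(cfg); b2 <- simulate_frames(cfg)
  expect_identical(b1$frames[[5]]$image, b2$frames[[5]]$image)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_flight_logs(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("flight logs realize the configured motion model", {
  # zero motion: constant logs, zero roll
  cfg0 <- scene_config(duration = 4, roll_std_rad = 0, seed = 2)
  logs0 <- simulate_flight_logs(cfg0)
  expect_true(all(logs0$gimbal$hz == 0))
  expect_true(all(atan2(logs0$gimbal$hz, logs0$gimbal$vz) == 0))
  # roll-angle std tracks the requested sigma within 15% on a long log
  sigma <- 0.12
  cfg <- scene_config(duration = 350, roll_std_rad = sigma, seed = 4)
  logs <- simulate_flight_logs(cfg)
  expect_gt(nrow(logs$gimbal), 1e4)
  roll <- atan2(logs$gimbal$hz, logs$gimbal$vz)
  expect_lt(abs(sd(roll) - sigma) / sigma, 0.15)
  # gimbal vectors are unit length; sensor rate is twice the frame rate
  norms <- with(logs$gimbal, hx^2 + hy^2 + hz^2)
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-9)
  dt <- diff(logs$gimbal$timestamp_s)
  expect_equal(unique(round(dt, 9)), 1 / (2 * cfg$frame_rate))
})

test_that("generated signals decompose exactly as the linear noise model", {
  sim <- sim72()
  cfg <- sim$config
  gt <- sim$ground_truth
  for (lbl in c("forehead_r1c1", "cheek_right_r2c3")) {
    y <- sim$rois[[lbl]]$means
    resid <- y - gt$noise_contribution[[lbl]] - gt$white_noise[[lbl]]
    # what remains is the pure pulse term on the base colour
    base <- cfg$skin_base_color
    amp <- cfg$pulse_direction * cfg$pulse_strength
    for (ch in 1:3)
      expect_equal(resid[, ch], base[ch] * (1 + amp[ch] * gt$pulse_trace),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
  # noise ROIs carry no pulse: spectra flat at the pulse frequency
  nz <- sim$rois[["eye_center"]]$means[, 2]
  sp <- compute_spectrum(nz - mean(nz), 15)
  inb <- abs(sp$freqs_bpm - 72) <= 3
  expect_lt(sum(sp$power[inb]) / sum(sp$power), 0.1)
})

test_that("de-noising with the self-assembled design recovers the pulse", {
  # linear removability: the noise contribution is in the column space of X
  # by construction, so the residual tends to the pure pulse as the segment
  # grows. At finite T, least squares with K ~ 43 regressors absorbs a
  # K/T-order fraction of pulse power by chance correlation, so the
  # guarantee is asymptotic: near-perfect at 60 s, a few percent lost at
  # the study-typical 20 s. The calm scene (motion band 0.35 Hz) keeps the
  # quadratic harmonics of the gimbal trigonometry below the HR band.
  recov <- function(dur) {
    sim <- simulate_roi_signals(scene_config(
      true_hr = 72, seed = 31, white_noise_sd = 0.05,
      motion_bandwidth_hz = 0.35, duration = dur))
    nz <- sim$rois[c("nostril_center", "nostril_right", "eye_center",
                     "eye_right")]
    roi <- sim$rois[["forehead_r2c2"]]
    X <- assemble_noise_matrix(roi, nz, sim$flight, sim$gimbal)
    dn <- glm_denoise(roi$means, X)
    cor(dn$denoised[, 2], sim$ground_truth$pulse_trace)
  }
  expect_gt(recov(60), 0.99)
  expect_gt(recov(20), 0.95)
})

test_that("zero pulse amplitude leaves measurement ROIs pulseless", {
  sim <- simulate_roi_signals(scene_config(pulse_strength = 0, seed = 6,
                                           duration = 10))
  g <- sim$rois[["forehead_r1c1"]]$means[, 2]
  sp <- compute_spectrum(g - mean(g), 15)
  inb <- abs(sp$freqs_bpm - 70) <= 3
  expect_lt(sum(sp$power[inb]) / sum(sp$power), 0.1)
})

test_that("frame renderer obeys the linear camera model and dropouts", {
  cfg <- scene_config(duration = 2, seed = 8, roll_std_rad = 0,
                      bbox_jitter_px = 0, dropout_windows = list(c(5, 9)))
  sc <- scene_radiance(cfg)
  cam <- synthetic_camera(sc$radiance, gain = 0.1)
  img1 <- cam$capture(50); img2 <- cam$capture(100)
  bb <- sc$bbox
  v1 <- face_percentile_value(img1, bb)
  v2 <- face_percentile_value(img2, bb)
  expect_equal(v2 / v1, 2, tolerance = 0.02)  # doubles below clipping
  # dropout frames have no face: visibility ground truth marks them
  b <- simulate_frames(cfg)
  expect_equal(which(!b$ground_truth$visibility), 5:9)
  det <- synthetic_face_detector()
  expect_null(det(b$frames[[6]]$image))
  expect_false(is.null(det(b$frames[[1]]$image)))
})

test_that("frames rendered with known roll derotate to an axis-aligned face", {
  cfg <- scene_config(duration = 4, seed = 12, roll_std_rad = 0.15,
                      bbox_jitter_px = 0)
  b <- simulate_frames(cfg)
  st <- stabilize_sequence(b)
  i <- which.max(abs(b$ground_truth$roll))
  expect_gt(abs(b$ground_truth$roll[i]), 0.05)  # the case is non-trivial
  fill_ratio <- function(img) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    hit <- which(gray > 100, arr.ind = TRUE)
    nrow(hit) / (diff(range(hit[, 1]) + c(0, 1)) *
                   diff(range(hit[, 2]) + c(0, 1)))
  }
  # after derotation the bright region fills its bounding box like an
  # axis-aligned rectangle (minus the dark facial patches); the raw rolled
  # frame fills substantially less
  expect_gt(fill_ratio(st[[i]]$image), 0.85)
  expect_lt(fill_ratio(b$frames[[i]]$image), 0.8)
})

test_that("reference pleth beats at the configured rate", {
  cfg <- scene_config(true_hr = 60, duration = 30, seed = 3)
  pl <- simulate_reference_pleth(cfg)
  expect_equal(length(pl$values), 3000L)
  expect_equal(reference_hr(pl), 60, tolerance = 0.01)
  # drifting rate: mean recovered HR equals the mean of the hr series
  cfg2 <- scene_config(true_hr = 60, hr_drift = 2 / 3, duration = 30,
                       seed = 3)  # 60 -> 80 bpm ramp
  pl2 <- simulate_reference_pleth(cfg2)
  expect_equal(reference_hr(pl2), mean(pl2$hr_series), tolerance = 0.02)
})

test_that("recording bundles round-trip through the directory layout", {
  dir <- withr::local_tempdir()
  b <- simulate_frames(scene_config(duration = 1, seed = 14))
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "frames.csv")))
  back <- read_bundle(dir)
  expect_equal(length(back$frames), length(b$frames))
  expect_identical(back$frames[[7]]$image, b$frames[[7]]$image)
  expect_equal(back$frames[[7]]$t, b$frames[[7]]$t)
  expect_equal(back$gimbal, b$gimbal, tolerance = 1e-15)
  expect_equal(back$flight, b$flight, tolerance = 1e-15)
  expect_equal(back$frame_rate, b$frame_rate)
  expect_equal(back$ground_truth$roll, b$ground_truth$roll,
               tolerance = 1e-15)
  # unsorted sensor log: sorted with a warning on read
  g <- utils::read.csv(file.path(dir, "gimbal.csv"))
  utils::write.csv(g[rev(seq_len(nrow(g))), ], file.path(dir, "gimbal.csv"),
                   row.names = FALSE)
  expect_warning(again <- read_bundle(dir), "sort")
  expect_equal(again$gimbal$timestamp_s, sort(g$timestamp_s))
})
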