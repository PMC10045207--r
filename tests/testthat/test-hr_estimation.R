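test_that("window slicing matches the counting formula and enumeration", {
  expect_length(window_signal(rnorm(45)), 1L)
  w <- window_signal(rnorm(51))
  expect_length(w, 4L)  # starts 0, 2, 4, 6
  expect_true(all(lengths(w) == 45L))
  expect_length(window_signal(rnorm(44)), 0L)
  # exhaustive enumeration oracle for all L up to 500
  for (L in c(1, 44:50, 100, 223, 500)) {
    x <- seq_len(L)
    got <- window_signal(x, 45, 2)
    starts <- if (L < 45) integer(0) else seq(1, L - 45 + 1, by = 2)
    expect_length(got, length(starts))
    expect_equal(length(got), if (L < 45) 0L else floor((L - 45) / 2) + 1L)
    for (i in seq_along(starts))
      expect_identical(got[[i]], x[starts[i]:(starts[i] + 44)])
  }
})

test_that("spectra localize known tones on the bpm grid", {
  fs <- 15
  t <- (0:44) / fs
  sp <- compute_spectrum(sin(2 * pi * 1.2 * t), fs)
  expect_lte(max(diff(sp$freqs_bpm)), 1)          # grid spacing <= 1 bpm
  expect_gte(max(sp$freqs_bpm), 180)              # covers the target band
  expect_true(all(sp$power >= 0))
  expect_equal(sp$freqs_bpm[which.max(sp$power)], 72, tolerance = 1)
  # constant input: all-zero power after mean removal
  expect_true(all(compute_spectrum(rep(7, 45), fs)$power < 1e-20))
  # two equal tones -> two dominant peaks
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 2 * t)
  sp2 <- compute_spectrum(x, fs)
  top <- sort(sp2$freqs_bpm[order(-sp2$power)[1:2]])
  expect_equal(top, c(60, 120), tolerance = 2)
})

test_that("peak SNR equals brute-force band summation", {
  # hand-worked toy spectrum: bins at 1 bpm spacing
  toy <- make_spectrum(0:6, c(0, 0, 1, 8, 1, 0, 10))
  expect_equal(peak_snr(toy, 3, alpha = 1), 1.0)  # (1+8+1)/(0+0+0+10)
  # all power at the peak: +Inf sentinel
  conc <- make_spectrum(0:6, c(0, 0, 0, 5, 0, 0, 0))
  expect_equal(peak_snr(conc, 3, alpha = 1), Inf)
  # flat spectrum: SNR = f/(1-f) for band fraction f
  flat <- make_spectrum(0:99, rep(1, 100))
  expect_equal(peak_snr(flat, 50, alpha = 9.5), 19 / 81)
  # oracle equivalence on random spectra
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    f <- seq(0, 200, length.out = n)
    p <- runif(n)
    pk <- sample(f, 1)
    a <- runif(1, 1, 10)
    inb <- f >= pk - a & f <= pk + a
    oracle <- sum(p[inb]) / (sum(p) - sum(p[inb]))
    expect_equal(peak_snr(make_spectrum(f, p), pk, a), oracle)
  }
  expect_error(peak_snr(toy, 99), "outside")
})

test_that("spectra are gated by the SNR and low-frequency conditions", {
  f <- 0:300
  gauss <- function(mu, sd, amp) amp * exp(-(f - mu)^2 / (2 * sd^2))
  # clean 72 bpm peak: accepted
  expect_true(accept_spectrum(make_spectrum(f, gauss(72, 2, 10))))
  # strong sub-50 bpm drift dominating a weak in-band peak: rejected by the
  # low-frequency condition
  drifty <- gauss(20, 3, 50) + gauss(72, 2, 5)
  expect_false(accept_spectrum(make_spectrum(f, drifty)))
  # flat-ish noise: no in-band peak reaches SNR 0.025
  set.seed(8)
  noise <- 1 + 0.01 * runif(length(f))
  expect_false(accept_spectrum(make_spectrum(f, noise)))
  # drift below the in-band maximum does not reject
  ok <- gauss(40, 3, 4) + gauss(72, 2, 10)
  expect_true(accept_spectrum(make_spectrum(f, ok)))
  # the DC bin is excluded from the low-band check (but would dominate the
  # low band if it were included)
  dc <- gauss(72, 2, 10); dc[1] <- 20
  expect_true(accept_spectrum(make_spectrum(f, dc)))
})

test_that("median spectrum pools per frequency bin", {
  f <- 0:200
  s1 <- make_spectrum(f, rep(1, 201))
  expect_equal(median_spectrum(list(s1))$power, s1$power)
  s2 <- make_spectrum(f, rep(2, 201))
  s9 <- make_spectrum(f, rep(9, 201))
  expect_equal(median_spectrum(list(s1, s2, s9))$power, rep(2, 201))
  # even count: arithmetic mid of the central pair
  expect_equal(median_spectrum(list(s1, s9))$power, rep(5, 201))
  expect_error(median_spectrum(list()), "no accepted")
  expect_error(median_spectrum(list(s1, make_spectrum(0:100, rep(1, 101)))),
               "grids")
})

test_that("HR estimation fuses methods and reports failure statuses", {
  fs <- 15
  t <- (0:199) / fs
  mk <- function(freq_hz, method) {
    structure(list(method = method, roi_label = "r", segment_id = "s",
                   values = sin(2 * pi * freq_hz * t)),
              class = "pulse_signal")
  }
  # POS at 80 bpm, CHROM at 90 bpm -> final = 85
  res <- estimate_hr(list(mk(80 / 60, "POS"), mk(90 / 60, "CHROM")), fs)
  expect_equal(res$status, "ok")
  expect_lte(abs(res$hr_pos - 80), 1)   # within one grid step
  expect_lte(abs(res$hr_chrom - 90), 1)
  expect_equal(res$hr_final, (res$hr_pos + res$hr_chrom) / 2,
               ignore_attr = TRUE)
  # final HR equidistant from the two method values
  expect_equal(res$hr_final - res$hr_pos, res$hr_chrom - res$hr_final,
               ignore_attr = TRUE)
  # no signals at all: declared failed upstream
  expect_equal(estimate_hr(list(), fs)$status, "failed_no_segments")
  # signals present but nothing accepted (sub-band drift only)
  drift <- mk(20 / 60, "POS")
  res2 <- estimate_hr(list(drift), fs)
  expect_equal(res2$status, "failed_no_accepted_spectra")
  expect_true(is.na(res2$hr_final))
})

test_that("recovered HR stays in band and JSON serialization is faithful", {
  sim <- sim72()
  res <- run_estimate_signals(sim$rois, sim$flight, sim$gimbal, 15)
  expect_equal(res$status, "ok")
  expect_true(res$hr_final >= 50 && res$hr_final <= 180)
  expect_equal(res$hr_final, 72, tolerance = 2)
  j <- jsonlite::fromJSON(hr_result_json(res))
  expect_equal(j$hr_final, res$hr_final)
  expect_equal(j$status, "ok")
})
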