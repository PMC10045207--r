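# build a small synthetic roi_signals object from raw matrices
fake_roi <- function(T_, nv = 4, role = "measurement", label = "roi",
                     means = NULL) {
  if (is.null(means)) means <- matrix(100 + rnorm(T_ * 3), T_, 3)
  colnames(means) <- c("R", "G", "B")
  lm <- matrix(rnorm(T_ * 2 * nv, sd = 0.5), T_, 2 * nv) +
    rep(seq_len(2 * nv) * 3, each = T_)
  structure(list(label = label, role = role, means = means,
                 pixel_count = pmax(1, round(50 + rnorm(T_))),
                 landmarks = lm,
                 com = cbind(x = rowMeans(lm[, seq(1, 2 * nv, 2)]),
                             y = rowMeans(lm[, seq(2, 2 * nv, 2)]))),
            class = "roi_signals")
}

fake_inputs <- function(T_, nv = 4) {
  noise_rois <- setNames(lapply(c("nostril_center", "nostril_right",
                                  "eye_center", "eye_right"),
                                function(l) fake_roi(T_, 4, "noise", l)),
                         c("nostril_center", "nostril_right", "eye_center",
                           "eye_right"))
  flight <- data.frame(timestamp_s = seq_len(T_), height_m = 8 + rnorm(T_),
                       longitude_deg = rnorm(T_, 6), latitude_deg = rnorm(T_, 50),
                       vel_u = rnorm(T_), vel_v = rnorm(T_), vel_w = rnorm(T_))
  gimbal <- data.frame(timestamp_s = seq_len(T_), hx = rnorm(T_), hy = rnorm(T_),
                       hz = rnorm(T_), vx = rnorm(T_), vy = rnorm(T_),
                       vz = rnorm(T_))
  list(roi = fake_roi(T_, nv), noise_rois = noise_rois, flight = flight,
       gimbal = gimbal)
}

test_that("first derivative matches the difference-scheme oracle", {
  expect_equal(first_derivative(rep(3, 10)), rep(0, 10))
  expect_equal(first_derivative(5 * (0:9)), rep(5, 10))
  expect_equal(first_derivative(c(0, 1, 4, 9)), c(1, 2, 4, 5))
  expect_error(first_derivative(1), "2 samples")
  # same length, linear in input
  set.seed(2)
  x <- rnorm(31); y <- rnorm(31)
  expect_length(first_derivative(x), 31L)
  expect_equal(first_derivative(2 * x + y),
               2 * first_derivative(x) + first_derivative(y))
})

test_that("noise matrix has the full documented column set in fixed order", {
  set.seed(5)
  for (nv in c(4L, 5L, 6L)) {
    inp <- fake_inputs(100, nv)
    X <- assemble_noise_matrix(inp$roi, inp$noise_rois, inp$flight,
                               inp$gimbal)
    K <- 4 * nv + 27  # all 15 noise sources enumerated
    expect_length(X$column_labels, K)
    expect_equal(dim(X$values$R), c(100L, K))
    # channel-matched: only the 4 noise-region columns differ by channel
    diff_cols <- which(colSums(X$values$R != X$values$G) > 0)
    expect_equal(sort(X$column_labels[diff_cols]),
                 sort(c("nostril_center", "nostril_right", "eye_center",
                        "eye_right")))
    # spot-check content and order
    expect_equal(X$values$G[, "height_m"], inp$flight$height_m)
    expect_equal(X$values$G[, "h_z"], inp$gimbal$hz)
    expect_equal(X$values$B[, "nostril_center"],
                 inp$noise_rois$nostril_center$means[, 3])
    expect_equal(X$values$G[, "d_com_x"],
                 first_derivative(inp$roi$com[, 1]))
    expect_equal(X$values$G[, "pixel_count"], inp$roi$pixel_count)
  }
})

test_that("constant flight log yields flagged degenerate columns, not errors", {
  set.seed(6)
  inp <- fake_inputs(80)
  inp$flight$height_m <- 8
  inp$flight$vel_u <- 0
  X <- assemble_noise_matrix(inp$roi, inp$noise_rois, inp$flight, inp$gimbal)
  expect_true(all(c("height_m", "vel_u") %in% X$degenerate))
  Y <- matrix(100 + rnorm(80 * 3), 80, 3)
  expect_silent(dn <- glm_denoise(Y, X))
  expect_true(all(is.finite(dn$mixing)))
  # misaligned inputs rejected
  bad <- fake_inputs(80)
  bad$flight <- bad$flight[1:79, ]
  expect_error(assemble_noise_matrix(bad$roi, bad$noise_rois, bad$flight,
                                     bad$gimbal), "aligned")
})

test_that("de-noising equals the orthogonal-projection residual oracle", {
  set.seed(17)
  for (rep in 1:30) {
    T_ <- sample(60:200, 1)
    K <- sample(5:min(50, T_ - 5), 1)
    X <- matrix(rnorm(T_ * K), T_, K)
    Y <- matrix(rnorm(T_ * 3), T_, 3)
    dn <- glm_denoise(Y, X, center = FALSE)
    # independent oracle: residual-maker matrix from the pseudo-inverse
    P <- X %*% MASS_ginv(X)
    expect_equal(dn$denoised, (diag(T_) - P) %*% Y, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("pure-noise input is annihilated; orthogonal pulse survives", {
  set.seed(23)
  T_ <- 150; K <- 20
  X <- matrix(rnorm(T_ * K), T_, K)
  M_true <- matrix(rnorm(K * 3), K, 3)
  Y <- X %*% M_true
  dn <- glm_denoise(Y, X, center = FALSE)
  expect_lt(max(dn$residual_norms) / sqrt(max(colSums(Y^2))), 1e-8)
  # pulse orthogonal to the column space passes through untouched
  p_raw <- sin(2 * pi * 1.2 * (0:(T_ - 1)) / 15)
  p <- p_raw - X %*% MASS_ginv(X) %*% p_raw  # project out the columns
  Y2 <- X %*% M_true + matrix(p, T_, 3)
  dn2 <- glm_denoise(Y2, X, center = FALSE)
  for (ch in 1:3)
    expect_gt(cor(dn2$denoised[, ch], p), 0.999)
})

test_that("intercept-only design reduces to per-channel mean removal", {
  set.seed(31)
  Y <- matrix(rnorm(60 * 3, mean = 50), 60, 3)
  X1 <- matrix(1, 60, 1)
  dn <- glm_denoise(Y, X1, center = FALSE)
  expect_equal(dn$denoised, sweep(Y, 2, colMeans(Y)), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("de-noising is idempotent and never increases variance", {
  set.seed(37)
  T_ <- 120
  X <- matrix(rnorm(T_ * 15), T_, 15)
  Y <- matrix(rnorm(T_ * 3), T_, 3) + X %*% matrix(rnorm(45), 15, 3)
  dn1 <- glm_denoise(Y, X)
  dn2 <- glm_denoise(dn1$denoised, X)
  expect_equal(dn2$denoised, dn1$denoised, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(apply(dn1$denoised, 2, var) <= apply(Y, 2, var)))
  # under-determined systems are refused with guidance
  expect_error(glm_denoise(Y[1:10, ], X[1:10, ]), "under-determined")
})

test_that("a noise column equal to the pulse removes the pulse", {
  # the documented failure mode: noise sources correlated with the pulse
  set.seed(41)
  T_ <- 150
  p <- sin(2 * pi * 1.2 * (0:(T_ - 1)) / 15)
  X <- cbind(matrix(rnorm(T_ * 5), T_, 5), p)
  Y <- matrix(p, T_, 3) + matrix(rnorm(T_ * 3, sd = 0.05), T_, 3)
  dn <- glm_denoise(Y, X)
  pulse_power <- function(x) {
    sp <- compute_spectrum(x, 15)
    sum(sp$power[abs(sp$freqs_bpm - 72) <= 3])
  }
  for (ch in 1:3)
    expect_lt(pulse_power(dn$denoised[, ch]) / pulse_power(Y[, ch]), 0.01)
})
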