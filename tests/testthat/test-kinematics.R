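# Signal-processing oracles: closed forms for the posture trigonometry,
# filter magnitude responses, half-stroke counting, the FSR hold rule, the
# ODBA rectified-sine law, and the jiggle speed calibration.

test_that("depth smoothing is a centered running median", {
  expect_equal(smooth_depth(rep(7, 100)), rep(7, 100))
  spike <- rep(10, 100)
  spike[50] <- 15
  expect_equal(smooth_depth(spike)[50], 10)
  ramp <- seq(0, 30, length.out = 301)
  sm <- smooth_depth(ramp)
  expect_equal(sm[3:299], ramp[3:299]) # median of a linear window = center
})

test_that("pitch and roll closed forms hold", {
  mk <- function(v) matrix(rep(v, each = 50), ncol = 3)
  pr <- compute_pitch_roll(mk(c(0, 0, 1)), 50)
  expect_equal(pr$pitch_deg, rep(0, 10), tolerance = 1e-10)
  expect_equal(pr$roll_deg, rep(0, 10), tolerance = 1e-10)
  pr <- compute_pitch_roll(mk(c(0.5, 0, sqrt(3) / 2)), 50)
  expect_equal(pr$pitch_deg, rep(30, 10), tolerance = 1e-6)
  expect_equal(pr$roll_deg, rep(0, 10), tolerance = 1e-6)
  a45 <- sqrt(2) / 2
  pr <- compute_pitch_roll(mk(c(0, a45, a45)), 50)
  expect_equal(pr$roll_deg, rep(45, 10), tolerance = 1e-6)
  expect_equal(pr$pitch_deg, rep(0, 10), tolerance = 1e-6)
})

test_that("free-fall-like records trigger a warning", {
  a <- matrix(0.01, nrow = 500, ncol = 3)
  expect_warning(compute_pitch_roll(a, 50), "0.3 g")
})

test_that("posture low-pass has the specified magnitude response", {
  t <- seq(0, 300, by = 0.1)
  dc <- lowpass_posture(rep(12, length(t)), rep(-7, length(t)))
  expect_equal(dc$pitch_deg, rep(12, length(t)), tolerance = 1e-4)
  expect_equal(dc$roll_deg, rep(-7, length(t)), tolerance = 1e-4)
  amp_out <- function(f) {
    x <- 10 * sin(2 * pi * f * t)
    y <- lowpass_posture(x, x)$pitch_deg
    max(abs(y[1000:2000]))
  }
  expect_gt(amp_out(0.05), 10 * 0.95) # passband: < 5% attenuation
  expect_lt(amp_out(1.0), 10 * 0.10)  # stopband: > 90% attenuation
  expect_error(lowpass_posture(1:10, 1:10), "transient")
})

test_that("stroke band-pass isolates the stroke band", {
  t <- seq(0, 300, by = 0.1)
  expect_lt(max(abs(bandpass_stroke_signal(rep(5, length(t))))), 0.01)
  amp_out <- function(f, a = 8) {
    y <- bandpass_stroke_signal(a * sin(2 * pi * f * t))
    max(abs(y[1000:2000]))
  }
  expect_equal(amp_out(0.5), 8, tolerance = 0.1)  # mid-band gain ~ 1
  expect_lt(amp_out(2), 8 * 0.10)                  # > 90% attenuation
})

test_that("half-strokes count sine transits and alternate polarity", {
  t <- seq(0, 40, by = 0.1)
  hs <- detect_half_strokes(8 * sin(2 * pi * 0.25 * t))
  expect_true(abs(nrow(hs) - floor(40 * 2 * 0.25)) <= 1)
  expect_true(all(abs(diff(hs$polarity)) == 2)) # alternation
  expect_equal(nrow(detect_half_strokes(rep(0, 400))), 0)
  expect_equal(nrow(detect_half_strokes(2.9 * sin(2 * pi * 0.25 * t))), 0)
})

test_that("slow transits beyond the 6.5 s limit are discarded", {
  # 3.2 deg sine at 0.05 Hz: threshold-to-threshold transit takes ~7.7 s
  t <- seq(0, 100, by = 0.1)
  hs <- detect_half_strokes(3.2 * sin(2 * pi * 0.05 * t))
  expect_equal(nrow(hs), 0)
})

test_that("FSR holds 1/(2*delta) between half-strokes", {
  hs <- data.frame(time_s = seq(2, 20, by = 2), polarity = rep(c(1, -1), 5))
  fsr <- compute_fsr(hs, n = 300)
  expect_equal(unique(fsr[ceiling(2 * 10 + 1):floor(20 * 10)]), 0.25)
  expect_true(all(fsr[250:300] == 0))
  expect_equal(compute_fsr(data.frame(time_s = numeric(0),
                                      polarity = integer(0)), 100),
               rep(0, 100))
})

test_that("ODBA follows the rectified-sine law and is linear", {
  n <- 50 * 120
  still <- cbind(rep(0.5, n), rep(0, n), rep(sqrt(3) / 2, n))
  expect_lt(mean(compute_odba(still, 50)), 1e-8)
  tt <- (seq_len(n) - 1) / 50
  osc <- function(A) cbind(A * sin(2 * pi * 2 * tt), 0, 1)
  odba1 <- compute_odba(osc(0.1), 50)
  expect_equal(mean(odba1[100:1100]), 2 * 0.1 / pi * 9.80665, tolerance = 0.03)
  odba2 <- compute_odba(osc(0.2), 50)
  expect_equal(mean(odba2[100:1100]) / mean(odba1[100:1100]), 2,
               tolerance = 0.01)
})

test_that("depth rate is a signed central-difference slope", {
  ramp <- seq(0, 30, length.out = 501) # 0.6 m/s at 10 Hz
  dr <- compute_depth_rate(ramp)
  expect_equal(dr[10:490], rep(0.6, 481), tolerance = 1e-9)
  expect_equal(compute_depth_rate(rep(5, 100)), rep(0, 100))
  expect_true(all(compute_depth_rate(rev(ramp))[10:490] < 0))
})

test_that("roll rate is an unsigned magnitude robust to wrap", {
  expect_equal(compute_roll_rate(rep(45, 100)), rep(0, 100))
  sweep <- seq(0, 90, length.out = 101) # 9 deg/s at 10 Hz
  rr <- compute_roll_rate(sweep)
  expect_equal(rr[10:90], rep(9, 81), tolerance = 1e-9)
  wrap <- c(rep(179, 50), rep(-179, 50)) # a 2 degree step across the wrap
  rr <- compute_roll_rate(wrap)
  expect_lt(max(rr), 50)
  expect_true(all(rr >= 0))
})

test_that("precomputed speed passes through a running mean", {
  out <- estimate_speed(NULL, 10, NULL, NULL,
                        precomputed_speed = rep(1.5, 200))
  expect_equal(out$speed_ms, rep(1.5, 200))
  expect_null(out$fit)
})

test_that("degenerate jiggle calibrations raise errors", {
  n <- 50 * 100
  quiet <- cbind(rep(0, n), 0, 1) # zero jiggle everywhere
  pitch <- rep(35, 1000)
  dr <- rep(0.6, 1000)
  expect_error(estimate_speed(quiet, 50, pitch, dr), "variance|calibration")
  flat_pitch <- rep(0, 1000) # no steep samples at all
  expect_error(estimate_speed(quiet, 50, flat_pitch, dr), "calibration")
  expect_error(estimate_speed(quiet, 15, pitch, dr), "accel_rate_hz >= 20")
})

test_that("jiggle speed recovers the generator's speed and implied slope", {
  cl <- clean_deployment()
  kin <- cl$kin
  dep <- cl$dep
  rmse <- sqrt(mean((kin$speed_ms - dep$truth_speed)^2))
  expect_lt(rmse, 0.3)
  # implied-slope oracle: refit the same log-linear model against the
  # generator's true speed on the calibration samples; the OCDR-based fit
  # must recover it (OCDR is a noisy stand-in for true speed)
  n <- length(kin$depth_m)
  calib <- abs(kin$pitch_post_deg) >= 30 & abs(kin$depth_rate_ms) > 0.3
  sp <- estimate_speed(dep$stream$accel, 50, kin$pitch_post_deg,
                       kin$depth_rate_ms)
  jig <- sp$jiggle_rms_g[seq_len(n)]
  b_implied <- unname(stats::lm.fit(
    cbind(1, jig[calib]), log(dep$truth_speed[seq_len(n)][calib])
  )$coefficients[2])
  expect_equal(kin$speed_fit$b, b_implied, tolerance = 0.2)
  expect_gt(kin$speed_fit$b, 0)
})

test_that("filters are zero-phase: pulse timing preserved", {
  x <- rep(0, 600)
  x[290:310] <- 10 # symmetric pulse centered at sample 300
  lp <- lowpass_posture(x, x)$pitch_deg
  expect_lt(abs(which.max(lp) - 300), 2)
})

test_that("end-to-end channels match truth on a noise-free deployment", {
  cl <- clean_deployment()
  kin <- cl$kin
  dep <- cl$dep
  n <- length(kin$depth_m)
  expect_lt(sqrt(mean((kin$pitch_post_deg - dep$truth_pitch[1:n])^2)), 2)
  expect_lt(sqrt(mean((kin$roll_post_deg - dep$truth_roll[1:n])^2)), 2)
  expect_lt(mean(abs(kin$depth_rate_ms -
                       compute_depth_rate(dep$truth_depth[1:n]))), 0.05)
  # FSR: mean over the stroking interior within 0.05 Hz of the schedule
  expect_lt(abs(mean(kin$fsr_hz[200:(n - 200)]) -
                  mean(dep$truth_fsr[200:(n - 200)])), 0.05)
})

test_that("downsampled high-rate path agrees with a native 10 Hz path", {
  # band-limited posture signal seen by a 400 Hz and a 10 Hz accelerometer
  t_hi <- seq(0, 120, by = 1 / 400)
  pitch_true <- 20 * sin(2 * pi * 0.05 * t_hi)
  a_hi <- cbind(sin(pitch_true * pi / 180), 0, cos(pitch_true * pi / 180))
  pr_hi <- compute_pitch_roll(a_hi, 400)
  idx10 <- seq(20, length(t_hi), by = 40) # native sensor at bin centers
  pr_10 <- compute_pitch_roll(a_hi[idx10, , drop = FALSE], 10)
  n <- min(length(pr_hi$pitch_deg), length(pr_10$pitch_deg))
  expect_equal(pr_hi$pitch_deg[50:(n - 50)], pr_10$pitch_deg[50:(n - 50)],
               tolerance = 0.01)
})
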