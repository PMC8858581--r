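# Derivation of the 10 Hz kinematic channels from raw acceleration + depth.
#
# Frame convention (shared with the synthetic generator): x forward, y right,
# z up; level posture reads (0, 0, +1) g; pitch positive nose-up; roll
# positive right-side-down; depth positive downward, so depth rate is
# positive while descending.

# Zero-phase 4th-order Butterworth filtering. `signal::filtfilt` runs the
# filter forward and backward, so symmetric pulses keep their timing. The
# series is odd-reflection padded at both ends so the filter's start-up
# transient decays inside the padding, not in the data (DC passes exactly).
butter_filtfilt <- function(x, w, type) {
  bf <- signal::butter(4, w, type = type)
  n <- length(x)
  p <- min(n - 1, ceiling(12 / min(w)))
  if (p < 4) return(signal::filtfilt(bf, x))
  front <- 2 * x[1] - x[(p + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(p + 1):(p + n)]
}

#' Smooth a depth trace
#'
#' Centered running median (default 0.5 s, i.e. 5 samples at 10 Hz) with
#' shrinking windows at the edges; removes pressure-sensor spikes without
#' rounding dive transitions.
#'
#' @param depth_m depth series on the 10 Hz clock.
#' @param rate_hz sampling rate (Hz).
#' @param window_s median window width (s).
#' @return Smoothed depth, same length.
#' @export
smooth_depth <- function(depth_m, rate_hz = 10, window_s = 0.5) {
  width <- round(window_s * rate_hz)
  if (width %% 2 == 0) width <- width + 1L
  running_median(depth_m, width)
}

#' Raw pitch and roll from triaxial acceleration
#'
#' Block-averages the high-rate acceleration onto the 10 Hz clock (the
#' static vector `a`), then `pitch = asin(ax / |a|)` and
#' `roll = atan2(ay, az)`, in degrees.
#'
#' @param accel n x 3 acceleration matrix in g.
#' @param accel_rate_hz acceleration sampling rate (Hz).
#' @param out_rate_hz output rate (Hz).
#' @return List with `pitch_deg` and `roll_deg` at `out_rate_hz`.
#' @export
compute_pitch_roll <- function(accel, accel_rate_hz, out_rate_hz = 10) {
  ax <- bin_average(accel[, 1], accel_rate_hz, out_rate_hz)
  ay <- bin_average(accel[, 2], accel_rate_hz, out_rate_hz)
  az <- bin_average(accel[, 3], accel_rate_hz, out_rate_hz)
  nrm <- sqrt(ax^2 + ay^2 + az^2)
  low <- nrm < 0.3
  if (any(low)) {
    r <- rle(low)
    if (any(r$values & r$lengths >= out_rate_hz)) {
      warning("sustained |a| < 0.3 g: free fall or invalid orientation data")
    }
  }
  pitch <- rad2deg(asin(pmin(pmax(ax / nrm, -1), 1)))
  roll <- rad2deg(atan2(ay, az))
  list(pitch_deg = pitch, roll_deg = roll)
}

#' Posture pitch and roll (0.2 Hz low-pass)
#'
#' Removes the fluke-stroke oscillation from raw pitch/roll, leaving body
#' posture. Zero-phase 4th-order Butterworth; roll is filtered on the
#' unwrapped angle and rewrapped to (-180, 180].
#'
#' @param pitch_raw_deg,roll_raw_deg raw angles at `rate_hz`, degrees.
#' @param rate_hz sampling rate (Hz).
#' @param cutoff_hz low-pass cutoff (Hz).
#' @return List with `pitch_deg` and `roll_deg`.
#' @export
lowpass_posture <- function(pitch_raw_deg, roll_raw_deg, rate_hz = 10,
                            cutoff_hz = 0.2) {
  min_len <- ceiling(3 * rate_hz / cutoff_hz)
  if (length(pitch_raw_deg) < min_len) {
    stop("series shorter than 3x the filter transient (", min_len, " samples)")
  }
  w <- cutoff_hz / (rate_hz / 2)
  pitch <- butter_filtfilt(pitch_raw_deg, w, "low")
  roll <- wrap_deg(butter_filtfilt(unwrap_deg(roll_raw_deg), w, "low"))
  list(pitch_deg = pmin(pmax(pitch, -90), 90), roll_deg = roll)
}

#' Fluke-stroke signal (0.2--1 Hz band-pass of raw pitch)
#'
#' @param pitch_raw_deg raw pitch at `rate_hz`, degrees.
#' @param rate_hz sampling rate (Hz).
#' @param band_hz length-2 pass band (Hz).
#' @return Zero-mean band-passed pitch, degrees.
#' @export
bandpass_stroke_signal <- function(pitch_raw_deg, rate_hz = 10,
                                   band_hz = c(0.2, 1)) {
  min_len <- ceiling(3 * rate_hz / band_hz[1])
  if (length(pitch_raw_deg) < min_len) {
    stop("series shorter than 3x the filter transient (", min_len, " samples)")
  }
  out <- butter_filtfilt(pitch_raw_deg, band_hz / (rate_hz / 2), "pass")
  out - mean(out)
}

#' Detect half-strokes from the band-passed pitch
#'
#' A half-stroke is a completed transit: the signal leaves one threshold
#' region (below `-thresh` / above `+thresh`) and reaches the opposite one
#' within `max_transit_s`. Consecutive half-strokes alternate polarity;
#' re-entries into the same region and transits slower than the limit are
#' discarded.
#'
#' @param stroke_signal_deg band-passed pitch, degrees.
#' @param rate_hz sampling rate (Hz).
#' @param thresh_deg threshold, degrees.
#' @param max_transit_s maximum transit time (s).
#' @return `data.frame` with `time_s` (entry into the new region) and
#'   `polarity` (+1 upward, -1 downward); zero rows when none.
#' @export
detect_half_strokes <- function(stroke_signal_deg, rate_hz = 10,
                                thresh_deg = 3, max_transit_s = 6.5) {
  s <- stroke_signal_deg
  region <- integer(length(s))
  region[s >= thresh_deg] <- 1L
  region[s <= -thresh_deg] <- -1L
  times <- numeric(0)
  pol <- integer(0)
  prev_sign <- 0L
  prev_exit_t <- NA_real_
  r <- rle(region)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 0L) next
    t_enter <- (starts[k] - 1) / rate_hz
    if (prev_sign == -v && !is.na(prev_exit_t) &&
        (t_enter - prev_exit_t) <= max_transit_s) {
      times <- c(times, t_enter)
      pol <- c(pol, v)
    }
    prev_sign <- v
    prev_exit_t <- ends[k] / rate_hz
  }
  data.frame(time_s = times, polarity = pol)
}

#' Fluke stroke rate from half-strokes
#'
#' Between consecutive half-strokes separated by `delta <= max_gap_s`, the
#' instantaneous rate is held at `1 / (2 * delta)` full strokes per second;
#' elsewhere the rate is 0.
#'
#' @param half_strokes output of [detect_half_strokes()].
#' @param n length of the output series.
#' @param rate_hz sampling rate (Hz).
#' @param max_gap_s maximum half-stroke spacing still counted as stroking.
#' @return FSR series (Hz), length `n`.
#' @export
compute_fsr <- function(half_strokes, n, rate_hz = 10, max_gap_s = 6.5) {
  fsr <- numeric(n)
  if (nrow(half_strokes) < 2L) return(fsr)
  t <- half_strokes$time_s
  for (i in seq_len(length(t) - 1L)) {
    delta <- t[i + 1L] - t[i]
    if (delta <= max_gap_s && delta > 0) {
      idx <- interval_to_idx(t[i], t[i + 1L], rate_hz, n)
      fsr[idx] <- 1 / (2 * delta)
    }
  }
  fsr
}

#' Overall Dynamic Body Acceleration
#'
#' Static acceleration is the per-axis centered running mean over
#' `window_s`; the dynamic component is the residual. ODBA is the sum of
#' absolute dynamic components over the three axes, block-averaged to the
#' 10 Hz clock and converted to m/s^2.
#'
#' @param accel n x 3 acceleration matrix in g.
#' @param accel_rate_hz acceleration sampling rate (Hz).
#' @param out_rate_hz output rate (Hz).
#' @param window_s static-estimation window (s).
#' @param gravity_ms2 conversion from g to m/s^2.
#' @return ODBA series (m/s^2) at `out_rate_hz`.
#' @export
compute_odba <- function(accel, accel_rate_hz, out_rate_hz = 10,
                         window_s = 3, gravity_ms2 = 9.80665) {
  width <- round(window_s * accel_rate_hz)
  if (width %% 2 == 0) width <- width + 1L
  dyn_sum <- numeric(nrow(accel))
  for (j in 1:3) {
    static <- running_mean(accel[, j], width)
    dyn_sum <- dyn_sum + abs(accel[, j] - static)
  }
  bin_average(dyn_sum, accel_rate_hz, out_rate_hz) * gravity_ms2
}

#' Depth rate
#'
#' Central first difference of (smoothed) depth times the sampling rate,
#' then a 0.5 s running mean. Positive while descending.
#'
#' @param depth_m smoothed depth (m).
#' @param rate_hz sampling rate (Hz).
#' @param smooth_s running-mean width (s).
#' @return Depth rate (m/s), same length.
#' @export
compute_depth_rate <- function(depth_m, rate_hz = 10, smooth_s = 0.5) {
  n <- length(depth_m)
  if (n < 3L) return(numeric(n))
  dr <- numeric(n)
  dr[2:(n - 1)] <- (depth_m[3:n] - depth_m[1:(n - 2)]) / 2 * rate_hz
  dr[1] <- (depth_m[2] - depth_m[1]) * rate_hz
  dr[n] <- (depth_m[n] - depth_m[n - 1]) * rate_hz
  width <- round(smooth_s * rate_hz)
  if (width %% 2 == 0) width <- width + 1L
  running_mean(dr, width)
}

#' Roll rate
#'
#' Absolute first difference of the unwrapped roll times the sampling rate,
#' smoothed over 0.5 s. Reported as an unsigned magnitude, so steady roll
#' gives ~0 and rolling transitions give positive values.
#'
#' @param roll_deg roll series (degrees, wrapped or not).
#' @param rate_hz sampling rate (Hz).
#' @param smooth_s running-mean width (s).
#' @return Roll rate (deg/s), non-negative, same length.
#' @export
compute_roll_rate <- function(roll_deg, rate_hz = 10, smooth_s = 0.5) {
  n <- length(roll_deg)
  if (n < 2L) return(numeric(n))
  u <- unwrap_deg(roll_deg)
  rr <- c(abs(u[2] - u[1]), abs(diff(u))) * rate_hz
  width <- round(smooth_s * rate_hz)
  if (width %% 2 == 0) width <- width + 1L
  running_mean(rr, width)
}

#' Forward speed from tag jiggle
#'
#' When a precomputed speed channel is supplied it is passed through a 0.5 s
#' running mean. Otherwise speed is estimated from the tag-jiggle amplitude:
#' the high-frequency (>= 10 Hz, or 0.4x the sampling rate if lower) content
#' of the acceleration norm is summarized as a windowed RMS `J` on the 10 Hz
#' clock; calibration samples where `|pitch_post| >= 30` deg and
#' `|depth_rate| > 0.3` m/s give the orientation-corrected depth rate
#' `OCDR = |depth_rate / sin(pitch_post)|`, an independent speed estimate;
#' `ln(OCDR) = a + b J` is fit by least squares and applied everywhere.
#'
#' @param accel n x 3 acceleration matrix in g (ignored when
#'   `precomputed_speed` is given).
#' @param accel_rate_hz acceleration sampling rate (Hz); must be >= 20 for
#'   jiggle estimation.
#' @param pitch_post_deg posture pitch at 10 Hz, degrees.
#' @param depth_rate_ms depth rate at 10 Hz, m/s.
#' @param precomputed_speed optional speed channel at 10 Hz (m/s).
#' @param rate_hz kinematic clock rate (Hz).
#' @param smooth_s running-mean width (s) for the output.
#' @param min_calibration minimum number of calibration samples.
#' @return List with `speed_ms` (m/s at 10 Hz) and, for the jiggle path,
#'   `fit` (intercept `a`, slope `b`, number of calibration samples) and
#'   `jiggle_rms_g`.
#' @export
estimate_speed <- function(accel, accel_rate_hz, pitch_post_deg,
                           depth_rate_ms, precomputed_speed = NULL,
                           rate_hz = 10, smooth_s = 0.5,
                           min_calibration = 50) {
  width <- round(smooth_s * rate_hz)
  if (width %% 2 == 0) width <- width + 1L
  if (!is.null(precomputed_speed)) {
    return(list(speed_ms = running_mean(precomputed_speed, width), fit = NULL))
  }
  if (accel_rate_hz < 20) {
    stop("jiggle speed needs accel_rate_hz >= 20; supply a speed channel")
  }
  cutoff <- min(10, 0.4 * accel_rate_hz)
  hp <- apply(accel, 2, butter_filtfilt, w = cutoff / (accel_rate_hz / 2),
              type = "high")
  nrm2 <- rowSums(hp^2)
  ms_bins <- bin_average(nrm2, accel_rate_hz, rate_hz) # mean square per 0.1 s
  jiggle <- sqrt(pmax(running_mean(ms_bins, width), 0)) # RMS over 0.5 s
  # hold the boundary 2 s at the nearest interior value: the zero-phase
  # filter's edge transient otherwise inflates the jiggle there
  guard <- min(2 * rate_hz, length(jiggle))
  if (length(jiggle) > 2 * guard) {
    jiggle[seq_len(guard)] <- jiggle[guard + 1]
    jiggle[length(jiggle) - seq_len(guard) + 1] <- jiggle[length(jiggle) - guard]
  }
  n <- min(length(jiggle), length(pitch_post_deg), length(depth_rate_ms))
  jiggle <- jiggle[seq_len(n)]
  calib <- abs(pitch_post_deg[seq_len(n)]) >= 30 &
    abs(depth_rate_ms[seq_len(n)]) > 0.3
  if (sum(calib) < min_calibration) {
    stop("only ", sum(calib), " calibration samples (steep, moving); ",
         "supply a precomputed speed channel")
  }
  j_cal <- jiggle[calib]
  if (stats::sd(j_cal) < 1e-8) {
    stop("degenerate calibration: jiggle has no variance; ",
         "supply a precomputed speed channel")
  }
  ocdr <- abs(depth_rate_ms[seq_len(n)][calib] /
                sin(deg2rad(pitch_post_deg[seq_len(n)][calib])))
  fit <- stats::lm.fit(cbind(1, j_cal), log(ocdr))
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  speed <- exp(a + b * jiggle)
  list(speed_ms = running_mean(speed, width),
       fit = list(a = unname(a), b = unname(b), n_calibration = sum(calib)),
       jiggle_rms_g = jiggle)
}

#' Derive all kinematic channels from a tag stream
#'
#' Runs the full sensor-processing chain: depth median smoothing, raw and
#' posture pitch/roll, the 0.2--1 Hz stroke signal with half-stroke
#' detection and FSR, ODBA, depth rate, roll rate and (jiggle or
#' precomputed) speed, all index-aligned on the 10 Hz depth clock.
#'
#' @param stream a [tag_stream()].
#' @param config a [pipeline_config()].
#' @param precomputed_speed optional 10 Hz speed channel (m/s).
#' @return An object of class `kinematic_series`: a list of aligned 10 Hz
#'   channels (`depth_m`, `depth_rate_ms`, `speed_ms`, `fsr_hz`,
#'   `pitch_raw_deg`, `roll_raw_deg`, `pitch_post_deg`, `roll_post_deg`,
#'   `roll_rate_dps`, `odba_ms2`, `time_s`) plus `half_strokes` and the
#'   speed calibration `speed_fit`.
#' @export
compute_kinematics <- function(stream, config = pipeline_config(),
                               precomputed_speed = NULL) {
  rate <- config$kin_rate_hz
  depth <- smooth_depth(stream$depth_m, rate, config$depth_median_s)
  pr <- compute_pitch_roll(stream$accel, stream$accel_rate_hz, rate)
  n <- min(length(depth), length(pr$pitch_deg))
  depth <- depth[seq_len(n)]
  pitch_raw <- pr$pitch_deg[seq_len(n)]
  roll_raw <- pr$roll_deg[seq_len(n)]
  post <- lowpass_posture(pitch_raw, roll_raw, rate, config$posture_lowpass_hz)
  stroke <- bandpass_stroke_signal(pitch_raw, rate, config$stroke_band_hz)
  hs <- detect_half_strokes(stroke, rate, config$stroke_thresh_deg,
                            config$stroke_max_transit_s)
  fsr <- compute_fsr(hs, n, rate, config$stroke_max_transit_s)
  odba <- compute_odba(stream$accel, stream$accel_rate_hz, rate,
                       config$odba_window_s, config$gravity_ms2)[seq_len(n)]
  depth_rate <- compute_depth_rate(depth, rate, config$speed_smooth_s)
  roll_rate <- compute_roll_rate(roll_raw, rate, config$speed_smooth_s)
  sp <- estimate_speed(stream$accel, stream$accel_rate_hz, post$pitch_deg,
                       depth_rate, precomputed_speed, rate,
                       config$speed_smooth_s)
  structure(
    list(
      time_s = (seq_len(n) - 1) / rate,
      depth_m = depth,
      depth_rate_ms = depth_rate,
      speed_ms = sp$speed_ms[seq_len(n)],
      fsr_hz = fsr,
      pitch_raw_deg = pitch_raw,
      roll_raw_deg = roll_raw,
      pitch_post_deg = post$pitch_deg,
      roll_post_deg = post$roll_deg,
      roll_rate_dps = roll_rate,
      odba_ms2 = odba,
      stroke_signal_deg = stroke,
      half_strokes = hs,
      speed_fit = sp$fit,
      rate_hz = rate,
      individual_id = stream$individual_id
    ),
    class = "kinematic_series"
  )
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf(
    "<kinematic_series> %s: %d samples @ %g Hz (%.1f min), %d half-strokes\n",
    x$individual_id, length(x$depth_m), x$rate_hz,
    length(x$depth_m) / x$rate_hz / 60, nrow(x$half_strokes)
  ))
  invisible(x)
}

#' Kinematic series as a data frame
#'
#' @param x a `kinematic_series`.
#' @param ... unused.
#' @return A `data.frame` of the aligned 10 Hz channels.
#' @export
as.data.frame.kinematic_series <- function(x, ...) {
  data.frame(
    time_s = x$time_s, depth_m = x$depth_m, depth_rate_ms = x$depth_rate_ms,
    speed_ms = x$speed_ms, fsr_hz = x$fsr_hz, pitch_raw_deg = x$pitch_raw_deg,
    roll_raw_deg = x$roll_raw_deg, pitch_post_deg = x$pitch_post_deg,
    roll_post_deg = x$roll_post_deg, roll_rate_dps = x$roll_rate_dps,
    odba_ms2 = x$odba_ms2
  )
}
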