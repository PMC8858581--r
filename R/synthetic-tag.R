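# Synthetic tag-deployment generator with known ground truth.
#
# Emulates the study conditions: dive cycles with maximal depths of roughly
# 10-33 m, fluke-stroke pitch oscillation whose full-stroke rate sits inside
# the 0.2-1 Hz analysis band, suckling events lasting ~N(18.8, 8.8^2) s
# (truncated > 2 s) in clusters of 2-6 with alternating roll sides,
# sustained absolute roll, near-zero pitch and reduced speed during events,
# slight stroke-rate elevation, and overall rarity of a few percent of the
# record. Simulation is in the animal frame (no tag-to-animal rotation);
# `rotation` provides a fixed-rotation hook for testing the pass-through.

#' Synthetic deployment configuration
#'
#' Defaults are the package's reference study conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param duration_s deployment length (s).
#' @param accel_rate_hz high-rate acceleration sampling rate (Hz); must be a
#'   multiple of `kin_rate_hz`.
#' @param kin_rate_hz depth/kinematic clock (Hz, fixed 10 in the pipeline).
#' @param dive_rate_per_hour mean number of dives per hour (0 = no dives).
#' @param dive_maxdepth_range_m range (m) of maximal dive depths.
#' @param descent_rate_ms,ascent_rate_ms vertical rates (m/s) during the
#'   steep dive phases.
#' @param bottom_fraction fraction of each dive spent in the bottom phase.
#' @param stroke_rate_hz_range full-stroke rate range (Hz); must lie inside
#'   (0.1, 0.5) so the oscillation stays in the analysis band.
#' @param stroke_pitch_amp_deg pitch oscillation amplitude (degrees).
#' @param suckling_per_dive_prob probability that a dive hosts a suckling
#'   cluster.
#' @param suckling_duration_mean_s,suckling_duration_sd_s event duration
#'   distribution (s), truncated above 2 s.
#' @param suckling_roll_deg_range absolute roll plateau range (degrees)
#'   during events.
#' @param suckling_speed_ms speed range (m/s) during events.
#' @param cruise_speed_ms nominal cruising speed (m/s).
#' @param surface_cluster_prob probability that a long surface interval
#'   hosts a shallow suckling cluster.
#' @param cluster_size_probs probabilities of cluster sizes 2..6.
#' @param suckling_fsr_boost_hz stroke-rate elevation (Hz) during events.
#' @param jiggle_gain high-frequency acceleration RMS (g) per m/s of true
#'   speed.
#' @param noise_sd_g per-axis sensor noise SD (g).
#' @param depth_noise_sd_m depth sensor noise SD (m).
#' @param individual_offsets list with `depth_m`, `pitch_deg`, `speed_ms`:
#'   additive per-individual shifts creating inter-individual variability.
#' @param individual_id animal identifier.
#' @param seed RNG seed; identical configs and seeds give bit-identical
#'   deployments.
#'
#' @return Named list of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s = 14400,
                             accel_rate_hz = 50,
                             kin_rate_hz = 10,
                             dive_rate_per_hour = 5,
                             dive_maxdepth_range_m = c(12, 33),
                             descent_rate_ms = 0.9,
                             ascent_rate_ms = 0.9,
                             bottom_fraction = 0.45,
                             stroke_rate_hz_range = c(0.26, 0.36),
                             stroke_pitch_amp_deg = 4.2,
                             suckling_per_dive_prob = 0.3,
                             suckling_duration_mean_s = 18.8,
                             suckling_duration_sd_s = 8.8,
                             suckling_roll_deg_range = c(30, 60),
                             suckling_speed_ms = c(1.0, 1.55),
                             cruise_speed_ms = 1.7,
                             surface_cluster_prob = 0.08,
                             cluster_size_probs = c(0.5, 0.3, 0.1, 0.07, 0.03),
                             suckling_fsr_boost_hz = 0.05,
                             jiggle_gain = 0.006,
                             noise_sd_g = 0.003,
                             depth_noise_sd_m = 0.05,
                             individual_offsets = list(depth_m = 0,
                                                       pitch_deg = 0,
                                                       speed_ms = 0),
                             individual_id = "Calf1",
                             seed = 1) {
  cfg <- as.list(environment())
  if (duration_s <= 0 || accel_rate_hz <= 0 || kin_rate_hz <= 0) {
    stop("durations and rates must be positive")
  }
  if (accel_rate_hz %% kin_rate_hz != 0) {
    stop("accel_rate_hz must be a multiple of kin_rate_hz")
  }
  if (suckling_duration_mean_s <= 2) {
    stop("suckling_duration_mean_s must exceed 2 s")
  }
  if (stroke_rate_hz_range[1] <= 0.1 || stroke_rate_hz_range[2] >= 0.5) {
    stop("stroke_rate_hz_range must lie inside (0.1, 0.5)")
  }
  if (bottom_fraction <= 0 || bottom_fraction >= 1) {
    stop("bottom_fraction must lie in (0, 1)")
  }
  if (descent_rate_ms <= 0 || ascent_rate_ms <= 0) {
    stop("vertical rates must be positive")
  }
  structure(cfg, class = "synthetic_config")
}

# Truncated-normal event duration (s), capped to a window.
draw_event_duration <- function(cfg, cap = Inf) {
  for (i in 1:50) {
    d <- stats::rnorm(1, cfg$suckling_duration_mean_s,
                      cfg$suckling_duration_sd_s)
    if (d > 2) break
  }
  min(max(d, 2.5), 45, cap)
}

draw_cluster_size <- function(cfg, max_size = 6L) {
  k <- sample(2:6, 1, prob = cfg$cluster_size_probs)
  min(k, max_size)
}

#' Generate a synthetic deployment
#'
#' Builds the 10 Hz schedules (depth, posture pitch, roll, speed, stroke
#' rate) from a dive/surface timeline with embedded suckling clusters, then
#' synthesizes the high-rate acceleration as gravity projected through the
#' scheduled posture plus the stroke oscillation, speed-proportional jiggle
#' noise and sensor noise. Suckling events are scheduled only during
#' descent, bottom and (shallow-submergence) surface phases, never during
#' ascent, and always at depth >= 1.5 m and speed <= 2 m/s so the pipeline's
#' exclusion filter provably removes none of them.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_deployment`: `stream` (a
#'   [tag_stream()]), `truth_events` (behavior event table),
#'   `truth_phases` (a `phase_annotation` on the noise-free depth),
#'   `truth_speed`, `truth_fsr`, `truth_depth` (clean 10 Hz schedules) and
#'   `config`.
#' @export
generate_deployment <- function(config) {
  cfg <- config
  rate <- cfg$kin_rate_hz
  n_total <- round(cfg$duration_s * rate)
  off <- cfg$individual_offsets
  surface_depth <- 0.4

  if (cfg$dive_rate_per_hour > 0) {
    mind <- cfg$dive_maxdepth_range_m[1] + off$depth_m
    t_steep <- (mind - surface_depth) *
      (1 / cfg$descent_rate_ms + 1 / cfg$ascent_rate_ms)
    min_cycle <- t_steep / (1 - cfg$bottom_fraction) + 30
    if (cfg$duration_s < min_cycle) {
      stop("duration too short to fit one dive (need >= ",
           ceiling(min_cycle), " s)")
    }
  }

  set.seed(cfg$seed)
  depth <- numeric(0)
  pitch <- numeric(0)
  speed <- numeric(0)
  stroke <- numeric(0)
  events <- list() # list(start_s, stop_s, side, roll, speed, pitch)
  cursor <- function() length(depth) / rate

  base_speed <- function() {
    max(0.5, min(1.95,
                 cfg$cruise_speed_ms * stats::runif(1, 0.85, 1.15) +
                   off$speed_ms))
  }
  steep_speed <- function(vrate) {
    # speed consistent with the vertical rate and a >= 30 deg pitch
    v <- cfg$cruise_speed_ms * stats::runif(1, 0.8, 1.15) + off$speed_ms
    min(max(v, vrate / 0.78), vrate / 0.52, 1.95)
  }
  nsmp <- function(dur_s) max(1L, round(dur_s * rate))

  add_event <- function(t0, dur, side) {
    ev <- list(
      start_s = t0, stop_s = t0 + dur, side = side,
      roll = side_sign(side) * stats::runif(1, cfg$suckling_roll_deg_range[1],
                                            cfg$suckling_roll_deg_range[2]),
      speed = min(max(stats::runif(1, cfg$suckling_speed_ms[1],
                                   min(cfg$suckling_speed_ms[2], 1.9)) +
                        off$speed_ms, 0.5), 1.9),
      pitch = stats::runif(1, -5, 10),
      # slow roll jostling around the plateau while holding contact
      osc_amp = stats::runif(1, 8, 16),
      osc_phase = stats::runif(1, 0, 2 * pi)
    )
    events[[length(events) + 1L]] <<- ev
  }
  side_sign <- function(side) if (side == "right") 1 else -1
  flip <- function(side) if (side == "right") "left" else "right"

  # --- chunk builders (append to the schedule vectors) ----------------------
  emit <- function(d, p, v, s) {
    depth <<- c(depth, d)
    pitch <<- c(pitch, p)
    speed <<- c(speed, v)
    stroke <<- c(stroke, s)
  }
  ramp_depth <- function(from, to, vrate, p, v, s) {
    k <- nsmp(abs(to - from) / vrate)
    emit(seq(from, to, length.out = k), rep(p, k), rep(v, k), rep(s, k))
  }
  hold <- function(dur, d_fun, p, v, s) {
    k <- nsmp(dur)
    tt <- (seq_len(k) - 1) / rate
    emit(d_fun(tt), rep(p, k), rep(v, k), rep(s, k))
  }

  surface_chunk <- function(dur, allow_cluster = TRUE) {
    t_end <- cursor() + dur
    cluster_at <- NA_real_
    if (allow_cluster && dur >= 180 &&
        stats::runif(1) < cfg$surface_cluster_prob) {
      cluster_at <- cursor() + stats::runif(1, 40, dur / 2)
    }
    while (cursor() < t_end - 1 / rate) {
      left <- t_end - cursor()
      if (!is.na(cluster_at) && cursor() >= cluster_at) {
        # shallow suckling dip: submerge to a few meters, suckle, resurface
        k_ev <- min(draw_cluster_size(cfg, 3L), 3L)
        d_s <- stats::runif(1, 4, 8.5)
        s_rate <- stats::runif(1, cfg$stroke_rate_hz_range[1],
                               cfg$stroke_rate_hz_range[2])
        v <- base_speed()
        ramp_depth(surface_depth, d_s, 0.5, 0, v, s_rate)
        side <- sample(c("right", "left"), 1)
        for (e in seq_len(k_ev)) {
          dur_e <- draw_event_duration(cfg, cap = 30)
          if (cursor() + dur_e + 8 > t_end) break
          add_event(cursor(), dur_e, side)
          hold(dur_e + stats::runif(1, 4, 12),
               function(tt) rep(d_s, length(tt)), 0, v, s_rate)
          side <- flip(side)
        }
        ramp_depth(d_s, surface_depth, 0.5, 0, v, s_rate)
        cluster_at <- NA_real_
        next
      }
      s_rate <- stats::runif(1, cfg$stroke_rate_hz_range[1],
                             cfg$stroke_rate_hz_range[2])
      v <- base_speed()
      p0 <- stats::rnorm(1, 0, 1.5)
      if (stats::runif(1) < 0.5) {
        # logging / resting right at the surface
        hold(min(left, stats::runif(1, 20, 60)),
             function(tt) rep(surface_depth, length(tt)), p0, v, s_rate)
      } else {
        # shallow swimming excursion (< 10 m, still surface phase)
        d_s <- stats::runif(1, 2, 6)
        seg <- stats::runif(1, 30, 90)
        if (left < seg + 2 * (d_s / 0.4)) {
          hold(left, function(tt) rep(surface_depth, length(tt)), p0, v,
               s_rate)
        } else {
          ramp_depth(surface_depth, d_s, 0.4, p0, v, s_rate)
          hold(seg, function(tt) rep(d_s, length(tt)), p0, v, s_rate)
          ramp_depth(d_s, surface_depth, 0.4, p0, v, s_rate)
        }
      }
    }
  }

  dive_chunk <- function() {
    maxd <- stats::runif(1, cfg$dive_maxdepth_range_m[1],
                         cfg$dive_maxdepth_range_m[2]) + off$depth_m
    maxd <- max(maxd, cfg$dive_maxdepth_range_m[1])
    s_rate <- stats::runif(1, cfg$stroke_rate_hz_range[1],
                           cfg$stroke_rate_hz_range[2])
    has_cluster <- stats::runif(1) < cfg$suckling_per_dive_prob
    where <- if (has_cluster && stats::runif(1) < 0.3) "descent" else "bottom"

    v_desc <- steep_speed(cfg$descent_rate_ms)
    p_desc <- -rad2deg(asin(min(cfg$descent_rate_ms / v_desc, 0.95)))
    # descent, optionally interrupted by suckling events (slowed sink)
    d_cur <- surface_depth
    if (has_cluster && where == "descent") {
      d_trig <- max(3.5, 0.4 * maxd)
      ramp_depth(d_cur, d_trig, cfg$descent_rate_ms, p_desc, v_desc, s_rate)
      d_cur <- d_trig
      side <- sample(c("right", "left"), 1)
      k_ev <- draw_cluster_size(cfg)
      for (e in seq_len(k_ev)) {
        dur_e <- draw_event_duration(cfg)
        if (d_cur + dur_e * 0.15 > 0.8 * maxd) break
        add_event(cursor(), dur_e, side)
        d_next <- d_cur + dur_e * 0.15
        # base posture stays at descent pitch; the event override blends
        # toward the near-horizontal suckling posture inside the event
        ramp_depth(d_cur, d_next, 0.15, p_desc, v_desc, s_rate)
        d_cur <- d_next
        gap <- stats::runif(1, 5, 20)
        d_next <- min(d_cur + gap * cfg$descent_rate_ms, 0.82 * maxd)
        ramp_depth(d_cur, d_next, cfg$descent_rate_ms, p_desc, v_desc, s_rate)
        d_cur <- d_next
        side <- flip(side)
        if (d_cur >= 0.8 * maxd) break
      }
    }
    ramp_depth(d_cur, maxd, cfg$descent_rate_ms, p_desc, v_desc, s_rate)

    # bottom phase: depth wobbles within 93-100% of max depth
    t_steep <- (maxd - surface_depth) *
      (1 / cfg$descent_rate_ms + 1 / cfg$ascent_rate_ms)
    bottom_dur <- cfg$bottom_fraction / (1 - cfg$bottom_fraction) * t_steep
    bot_events <- list()
    if (has_cluster && where == "bottom") {
      side <- sample(c("right", "left"), 1)
      k_ev <- draw_cluster_size(cfg)
      t_rel <- stats::runif(1, 2, 8)
      for (e in seq_len(k_ev)) {
        dur_e <- draw_event_duration(cfg)
        bot_events[[e]] <- list(t_rel = t_rel, dur = dur_e, side = side)
        t_rel <- t_rel + dur_e + stats::runif(1, 5, 25)
        side <- flip(side)
      }
      bottom_dur <- max(bottom_dur, t_rel + 5)
    }
    t_b0 <- cursor()
    v_bot <- base_speed()
    hold(bottom_dur, # absolute 0.8 m wobble, always above the 85% line
         function(tt) maxd - 0.4 * (1 - cos(2 * pi * tt / 25)),
         stats::rnorm(1, 0, 1.5), v_bot, s_rate)
    for (be in bot_events) {
      if (t_b0 + be$t_rel + be$dur < cursor()) {
        add_event(t_b0 + be$t_rel, be$dur, be$side)
      }
    }

    v_asc <- steep_speed(cfg$ascent_rate_ms)
    p_asc <- rad2deg(asin(min(cfg$ascent_rate_ms / v_asc, 0.95)))
    ramp_depth(depth[length(depth)], surface_depth, cfg$ascent_rate_ms,
               p_asc, v_asc, s_rate)
  }

  # --- timeline --------------------------------------------------------------
  if (cfg$dive_rate_per_hour > 0) {
    mean_dive <- (mean(cfg$dive_maxdepth_range_m) + off$depth_m) *
      (1 / cfg$descent_rate_ms + 1 / cfg$ascent_rate_ms) /
      (1 - cfg$bottom_fraction)
    gap_mean <- max(60, 3600 / cfg$dive_rate_per_hour - mean_dive)
    while (cursor() < cfg$duration_s) {
      surf <- max(30, stats::rexp(1, 1 / gap_mean))
      surf <- min(surf, cfg$duration_s - cursor())
      surface_chunk(surf)
      left <- cfg$duration_s - cursor()
      maxd_worst <- cfg$dive_maxdepth_range_m[2] + off$depth_m
      dive_worst <- maxd_worst *
        (1 / cfg$descent_rate_ms + 1 / cfg$ascent_rate_ms) /
        (1 - cfg$bottom_fraction) + 180
      if (left < dive_worst) break
      dive_chunk()
    }
  }
  if (cursor() < cfg$duration_s) {
    surface_chunk(cfg$duration_s - cursor(), allow_cluster = FALSE)
  }
  if (length(depth) < n_total) { # rounding shortfall: hold the last state
    k <- n_total - length(depth)
    emit(rep(depth[length(depth)], k), rep(pitch[length(pitch)], k),
         rep(speed[length(speed)], k), rep(stroke[length(stroke)], k))
  }
  depth <- depth[seq_len(n_total)]
  pitch <- pitch[seq_len(n_total)]
  speed <- speed[seq_len(n_total)]
  stroke <- stroke[seq_len(n_total)]

  # --- apply event overrides and build the roll schedule ---------------------
  wander <- running_mean(stats::rnorm(n_total), 51)
  roll <- wander / max(stats::sd(wander), 1e-12) * 2.5
  # non-suckling rolling episodes (banking turns): brief smooth excursions
  # to 10-40 deg, so high absolute roll alone does not give suckling away
  n_bank <- stats::rpois(1, cfg$duration_s / 180)
  for (b in seq_len(n_bank)) {
    dur_b <- stats::runif(1, 3, 10)
    t0_b <- stats::runif(1, 0, cfg$duration_s - dur_b)
    idx_b <- interval_to_idx(t0_b, t0_b + dur_b, rate, n_total)
    amp_b <- sample(c(-1, 1), 1) * stats::runif(1, 10, 40)
    bump <- 0.5 * (1 - cos(2 * pi * seq_along(idx_b) / length(idx_b)))
    roll[idx_b] <- roll[idx_b] + amp_b * bump
  }
  # sustained non-suckling lateral rolls (side resting / play): held
  # excursions kinematically close to the suckling roll plateau, so the
  # detector cannot rely on absolute roll alone
  n_slow <- stats::rpois(1, cfg$duration_s / 300)
  for (b in seq_len(n_slow)) {
    dur_b <- stats::runif(1, 8, 30)
    t0_b <- stats::runif(1, 0, cfg$duration_s - dur_b)
    idx_b <- interval_to_idx(t0_b, t0_b + dur_b, rate, n_total)
    amp_b <- sample(c(-1, 1), 1) *
      stats::runif(1, cfg$suckling_roll_deg_range[1],
                   cfg$suckling_roll_deg_range[2])
    k_b <- length(idx_b)
    ramp_b <- max(2L, min(20L, k_b %/% 3))
    shape <- rep(1, k_b)
    shape[seq_len(ramp_b)] <- 0.5 * (1 - cos(pi * seq_len(ramp_b) / ramp_b))
    shape[k_b + 1 - seq_len(ramp_b)] <- shape[seq_len(ramp_b)]
    tt_b <- (seq_len(k_b) - 1) / rate
    jostle <- stats::runif(1, 8, 16) *
      sin(2 * pi * 0.08 * tt_b + stats::runif(1, 0, 2 * pi))
    roll[idx_b] <- roll[idx_b] + (amp_b + jostle) * shape
    if (stats::runif(1) < 0.35) { # active play: stroking picks up as well
      stroke[idx_b] <- min(0.40,
                           stats::runif(1, cfg$stroke_rate_hz_range[1],
                                        cfg$stroke_rate_hz_range[2]) +
                             cfg$suckling_fsr_boost_hz)
    }
  }
  for (ev in events) {
    idx <- interval_to_idx(ev$start_s, ev$stop_s, rate, n_total)
    if (!length(idx)) next
    # per-event stroke-rate draw: the mild FSR elevation is shared across
    # individuals and does not memorize the cluster's background rate
    stroke[idx] <- min(0.40, stats::runif(1, cfg$stroke_rate_hz_range[1],
                                          cfg$stroke_rate_hz_range[2]) +
                         cfg$suckling_fsr_boost_hz)
    # The labeled event starts at snout contact, i.e. after the calf has
    # already rolled into the suckling posture: the posture/speed ramps
    # (~5 s, cosine-eased) sit just outside the event interval, and the
    # plateau is held across the whole event.
    pad <- 50L
    lo <- max(1L, idx[1] - pad)
    hi <- min(n_total, idx[length(idx)] + pad)
    ext <- lo:hi
    n_up <- idx[1] - lo
    n_dn <- hi - idx[length(idx)]
    blend <- rep(1, length(ext))
    if (n_up > 0) {
      blend[seq_len(n_up)] <- 0.5 * (1 - cos(pi * seq_len(n_up) / (n_up + 1)))
    }
    if (n_dn > 0) {
      blend[length(ext) + 1 - seq_len(n_dn)] <-
        0.5 * (1 - cos(pi * seq_len(n_dn) / (n_dn + 1)))
    }
    tt <- (ext - ext[1]) / rate
    roll_target <- ev$roll + ev$osc_amp * sin(2 * pi * 0.08 * tt + ev$osc_phase)
    roll[ext] <- (1 - blend) * roll[ext] + blend * roll_target
    pitch[ext] <- (1 - blend) * pitch[ext] + blend * ev$pitch
    speed[ext] <- (1 - blend) * speed[ext] + blend * ev$speed
  }
  pitch <- running_mean(pitch, 11) + off$pitch_deg
  speed <- pmin(running_mean(speed, 11), 1.98)

  # --- ground truth -----------------------------------------------------------
  truth_events <- if (length(events)) {
    behavior_events(
      start_s = vapply(events, `[[`, numeric(1), "start_s"),
      stop_s = vapply(events, `[[`, numeric(1), "stop_s"),
      label = "suckling",
      roll_side = vapply(events, `[[`, character(1), "side")
    )
  } else {
    behavior_events(numeric(0), numeric(0))
  }
  truth_phases <- annotate_phases(depth, find_dives(depth, rate), rate)

  for (i in seq_len(nrow(truth_events))) {
    idx <- interval_to_idx(truth_events$start_s[i], truth_events$stop_s[i],
                           rate, n_total)
    stopifnot(min(depth[idx]) >= 1.5, max(speed[idx]) <= 2)
  }

  # --- high-rate synthesis ----------------------------------------------------
  up <- cfg$accel_rate_hz / rate
  n_hi <- n_total * up
  t10 <- (seq_len(n_total) - 1) / rate
  t_hi <- (seq_len(n_hi) - 1) / cfg$accel_rate_hz
  lin <- function(x) stats::approx(t10, x, xout = t_hi, rule = 2)$y
  pitch_hi <- lin(pitch)
  roll_hi <- lin(roll)
  speed_hi <- lin(speed)
  stroke_hi <- lin(stroke)
  phase <- cumsum(2 * pi * stroke_hi / cfg$accel_rate_hz)
  p_rad <- deg2rad(pitch_hi + cfg$stroke_pitch_amp_deg * sin(phase))
  r_rad <- deg2rad(roll_hi)
  accel <- cbind(
    sin(p_rad),
    cos(p_rad) * sin(r_rad),
    cos(p_rad) * cos(r_rad)
  )
  jig_sd <- cfg$jiggle_gain * speed_hi / sqrt(3)
  for (j in 1:3) {
    accel[, j] <- accel[, j] + stats::rnorm(n_hi, 0, jig_sd) +
      stats::rnorm(n_hi, 0, cfg$noise_sd_g)
  }
  depth_obs <- pmax(depth + stats::rnorm(n_total, 0, cfg$depth_noise_sd_m), 0)

  stream <- tag_stream(
    time_s = t_hi, accel = accel, accel_rate_hz = cfg$accel_rate_hz,
    depth_m = depth_obs, kin_rate_hz = rate,
    individual_id = cfg$individual_id,
    metadata = list(synthetic = TRUE, seed = cfg$seed)
  )
  structure(
    list(stream = stream, truth_events = truth_events,
         truth_phases = truth_phases, truth_speed = speed,
         truth_fsr = stroke, truth_depth = depth, truth_roll = roll,
         truth_pitch = pitch, config = cfg),
    class = "synthetic_deployment"
  )
}

#' @export
print.synthetic_deployment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_deployment> %s: %.1f h, %d dives, %d suckling events (%.2f%% of time)\n",
    x$config$individual_id, x$config$duration_s / 3600,
    nrow(x$truth_phases$dives), nrow(x$truth_events),
    suckling_budget(x$truth_events, x$config$duration_s)
  ))
  invisible(x)
}

#' Generate a cohort of synthetic deployments
#'
#' One deployment per configuration. `individual_offsets` in each config
#' shift depth, pitch and speed so summary features differ between
#' individuals while the roll/FSR suckling signature stays shared.
#'
#' @param configs list of [synthetic_config()] objects with distinct
#'   `individual_id`s (at least 2).
#' @return List of `synthetic_deployment` objects, named by individual.
#' @export
generate_cohort <- function(configs) {
  if (length(configs) < 2L) stop("a cohort needs at least 2 configurations")
  ids <- vapply(configs, `[[`, character(1), "individual_id")
  if (anyDuplicated(ids)) stop("duplicate individual ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  out <- lapply(configs, generate_deployment)
  names(out) <- ids
  out
}

#' Apply a fixed tag-to-animal rotation to a stream's acceleration
#'
#' Testing hook for the (out-of-pipeline) tag-orientation correction: left
#' multiplies each acceleration sample by a fixed rotation matrix. Applying
#' a rotation and then its transpose restores the original stream.
#'
#' @param stream a [tag_stream()].
#' @param rotation 3 x 3 rotation matrix.
#' @return The rotated `tag_stream`.
#' @export
rotate_stream <- function(stream, rotation) {
  stopifnot(all(dim(rotation) == c(3, 3)))
  stream$accel <- stream$accel %*% t(rotation)
  stream
}

#' Write a synthetic deployment to disk
#'
#' Writes the CATS-style sensor CSV, the BORIS-style truth annotation CSV
#' and the truth phases as a BED-like interval CSV.
#'
#' @param dep a `synthetic_deployment`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_deployment <- function(dep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- dep$config$individual_id
  paths <- c(
    sensors = file.path(dir, paste0(id, "_sensors.csv")),
    events = file.path(dir, paste0(id, "_events.csv")),
    phases = file.path(dir, paste0(id, "_phases.csv"))
  )
  write_tag_csv(dep$stream, paths[["sensors"]])
  write_events_csv(dep$truth_events, paths[["events"]], observation_id = id)
  write_phases_csv(dep$truth_phases, paths[["phases"]],
                   rate_hz = dep$config$kin_rate_hz)
  invisible(paths)
}
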