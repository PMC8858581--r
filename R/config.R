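#' Pipeline configuration
#'
#' Collects every numeric constant used by the processing pipeline, with
#' reference defaults: 0.5 s median smoothing of depth,
#' 0.2 Hz posture low-pass, 0.2--1 Hz stroke band, +-3 deg stroke thresholds
#' with a 6.5 s maximum transit, 10 m dive criterion, bottom phase above 85%
#' of maximal dive depth, 20 s comparison segments with 10 random
#' non-suckling draws per phase, 2 s classification blocks labelled suckling
#' when at least 3/5 of the block overlaps a suckling event, and the
#' exclusion filter at < 1.5 m depth or > 2 m/s speed.
#'
#' @param depth_median_s width (s) of the running median applied to depth.
#' @param posture_lowpass_hz low-pass cutoff (Hz) for posture pitch/roll.
#' @param stroke_band_hz length-2 band (Hz) isolating the fluke-stroke
#'   oscillation in raw pitch.
#' @param stroke_thresh_deg half-stroke detection threshold (degrees).
#' @param stroke_max_transit_s maximum time (s) allowed for a transit
#'   between the opposite stroke thresholds.
#' @param dive_depth_m minimum maximal depth (m) for a submergence to count
#'   as a dive.
#' @param surface_threshold_m depth (m) delimiting dive start/end crossings.
#' @param bottom_frac fraction of maximal dive depth defining the bottom
#'   phase.
#' @param segment_len_s length (s) of non-suckling comparison segments.
#' @param nonsuckling_per_phase segments drawn per activity phase.
#' @param block_len_s length (s) of classification blocks.
#' @param block_label_frac minimum fraction of a block inside a suckling
#'   event for the block to be labelled suckling.
#' @param excl_depth_m blocks with mean depth below this (m) are excluded.
#' @param excl_speed_ms blocks with mean speed above this (m/s) are excluded.
#' @param speed_smooth_s running-mean width (s) for speed smoothing.
#' @param odba_window_s running-mean width (s) separating static from
#'   dynamic acceleration in the ODBA computation.
#' @param gravity_ms2 standard gravity, converts g to m/s^2.
#' @param kin_rate_hz canonical kinematic sampling rate (Hz).
#'
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(depth_median_s = 0.5,
                            posture_lowpass_hz = 0.2,
                            stroke_band_hz = c(0.2, 1.0),
                            stroke_thresh_deg = 3,
                            stroke_max_transit_s = 6.5,
                            dive_depth_m = 10,
                            surface_threshold_m = 1,
                            bottom_frac = 0.85,
                            segment_len_s = 20,
                            nonsuckling_per_phase = 10,
                            block_len_s = 2,
                            block_label_frac = 0.6,
                            excl_depth_m = 1.5,
                            excl_speed_ms = 2.0,
                            speed_smooth_s = 0.5,
                            odba_window_s = 3.0,
                            gravity_ms2 = 9.80665,
                            kin_rate_hz = 10) {
  cfg <- list(
    depth_median_s = depth_median_s, posture_lowpass_hz = posture_lowpass_hz,
    stroke_band_hz = stroke_band_hz, stroke_thresh_deg = stroke_thresh_deg,
    stroke_max_transit_s = stroke_max_transit_s, dive_depth_m = dive_depth_m,
    surface_threshold_m = surface_threshold_m, bottom_frac = bottom_frac,
    segment_len_s = segment_len_s,
    nonsuckling_per_phase = nonsuckling_per_phase,
    block_len_s = block_len_s, block_label_frac = block_label_frac,
    excl_depth_m = excl_depth_m, excl_speed_ms = excl_speed_ms,
    speed_smooth_s = speed_smooth_s, odba_window_s = odba_window_s,
    gravity_ms2 = gravity_ms2, kin_rate_hz = kin_rate_hz
  )
  num <- unlist(cfg)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all pipeline_config values must be positive and finite")
  }
  if (block_label_frac > 1) stop("block_label_frac must lie in (0, 1]")
  if (stroke_band_hz[1] >= stroke_band_hz[2]) {
    stop("stroke_band_hz lower edge must be below the upper edge")
  }
  if (bottom_frac >= 1) stop("bottom_frac must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}
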