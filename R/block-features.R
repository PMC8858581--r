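# 2-s block featurization for classification: 43 features per block,
# 3/5-overlap labeling, and the depth/speed exclusion filter with its
# validity report.

.block_channels <- c("depth", "depth_rate", "speed", "odba", "pitch",
                     "abs_roll", "roll_rate")
.block_stats <- c("mean", "min", "max", "var", "skew", "kurt")

#' Names of the 43 block features
#'
#' Mean, min, max, variance, skewness and kurtosis for depth, depth rate,
#' speed, ODBA, pitch, absolute roll and roll rate (42 features), plus the
#' mean FSR.
#'
#' @return Character vector of length 43.
#' @export
block_feature_names <- function() {
  c(as.vector(t(outer(.block_channels, .block_stats, paste, sep = "_"))),
    "fsr_mean")
}

# Moment conventions shared with the original analysis environment:
# variance with n - 1; skewness m3 / m2^1.5 and kurtosis m4 / m2^2 computed
# from biased central moments (kurtosis non-excess, i.e. 3 for a normal).
# Constant windows get skewness and kurtosis 0 (degenerate moments).
moment_stats <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 < 1e-24) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  c(mean = m, min = min(x), max = max(x), var = stats::var(x),
    skew = skew, kurt = kurt)
}

#' 43 features for one block window
#'
#' @param window `data.frame` (or list) with the per-sample channels
#'   `depth_m`, `depth_rate_ms`, `speed_ms`, `odba_ms2`, `pitch_post_deg`,
#'   `roll_post_deg`, `roll_rate_dps`, `fsr_hz` over one block. Roll enters
#'   the features as its absolute value.
#' @return Named numeric vector of length 43 (see [block_feature_names()]).
#' @export
compute_block_features <- function(window) {
  chans <- list(
    depth = window$depth_m,
    depth_rate = window$depth_rate_ms,
    speed = window$speed_ms,
    odba = window$odba_ms2,
    pitch = window$pitch_post_deg,
    abs_roll = abs(window$roll_post_deg),
    roll_rate = window$roll_rate_dps
  )
  out <- numeric(0)
  for (nm in .block_channels) {
    s <- moment_stats(chans[[nm]])
    names(s) <- paste(nm, .block_stats, sep = "_")
    out <- c(out, s)
  }
  c(out, fsr_mean = mean(window$fsr_hz))
}

#' Label rule for one block
#'
#' A block is `"suckling"` iff at least `label_frac` (default 3/5) of its
#' duration overlaps suckling events -- at 10 Hz and 2 s blocks, at least 12
#' of the 20 samples (inclusive boundary).
#'
#' @param start_s,stop_s block boundaries (s).
#' @param events behavior event `data.frame`.
#' @param rate_hz sampling rate (Hz).
#' @param n record length in samples.
#' @param suckling_mask optional precomputed per-sample logical mask.
#' @param label_frac required overlap fraction.
#' @return `"suckling"` or `"non-suckling"`.
#' @export
label_block <- function(start_s, stop_s, events = NULL, rate_hz = 10,
                        n = NULL, suckling_mask = NULL, label_frac = 0.6) {
  if (is.null(suckling_mask)) {
    n <- n %||% ceiling(stop_s * rate_hz)
    suckling_mask <- suckling_sample_mask(events, n, rate_hz)
  }
  idx <- interval_to_idx(start_s, stop_s, rate_hz, length(suckling_mask))
  need <- label_frac * length(idx)
  if (sum(suckling_mask[idx]) >= need - 1e-9) "suckling" else "non-suckling"
}

# Per-sample indicator of lying inside any suckling event.
suckling_sample_mask <- function(events, n, rate_hz) {
  mask <- logical(n)
  suck <- events[events$label == "suckling", , drop = FALSE]
  for (i in seq_len(nrow(suck))) {
    mask[interval_to_idx(suck$start_s[i], suck$stop_s[i], rate_hz, n)] <- TRUE
  }
  mask
}

#' Build the 2-s block table
#'
#' Splits the deployment into non-overlapping blocks of `block_len_s`
#' anchored at t = 0 (a trailing partial block is dropped), computes the 43
#' features per block, applies the 3/5 labeling rule, and records each
#' block's majority phase. Blocks start with `retained = TRUE`; run
#' [filter_blocks()] to apply the exclusion filter.
#'
#' @param kin a `kinematic_series`.
#' @param events behavior event `data.frame`.
#' @param phases a `phase_annotation`.
#' @param config a [pipeline_config()].
#' @return `data.frame`: `individual`, `start_s`, `phase`, `label`,
#'   `retained` plus the 43 feature columns.
#' @export
make_blocks <- function(kin, events, phases, config = pipeline_config()) {
  rate <- kin$rate_hz
  len <- round(config$block_len_s * rate)
  n <- length(kin$depth_m)
  n_blocks <- floor(n / len)
  if (n_blocks < 1L) stop("record shorter than one block")
  mask <- suckling_sample_mask(events, n, rate)
  chan <- as.data.frame(kin)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * len + 1L):(b * len)
    feats <- compute_block_features(chan[idx, , drop = FALSE])
    start_s <- (b - 1L) * config$block_len_s
    lab <- if (sum(mask[idx]) >= config$block_label_frac * len - 1e-9)
      "suckling" else "non-suckling"
    rows[[b]] <- c(list(individual = kin$individual_id, start_s = start_s,
                        phase = majority_phase(phases$labels, idx),
                        label = lab, retained = TRUE),
                   as.list(feats))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Exclusion filter for blocks
#'
#' Excludes blocks too close to the surface (mean depth below
#' `excl_depth_m`) or of high-speed activity (mean speed above
#' `excl_speed_ms`), and reports whether the assumption that no suckling
#' block is lost holds on this data set.
#'
#' @param blocks block table from [make_blocks()].
#' @param excl_depth_m depth threshold (m).
#' @param excl_speed_ms speed threshold (m/s).
#' @return List: `blocks` (all rows, `retained` updated), `retained` (the
#'   surviving rows) and `report` (`n_before`, `n_after`,
#'   `n_suckling_removed`, `pass`).
#' @export
filter_blocks <- function(blocks, excl_depth_m = 1.5, excl_speed_ms = 2.0) {
  drop <- blocks$depth_mean < excl_depth_m | blocks$speed_mean > excl_speed_ms
  blocks$retained <- !drop
  report <- list(
    n_before = nrow(blocks),
    n_after = sum(!drop),
    n_suckling_removed = sum(drop & blocks$label == "suckling"),
    pass = sum(drop & blocks$label == "suckling") == 0L
  )
  list(blocks = blocks, retained = blocks[!drop, , drop = FALSE],
       report = report)
}
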