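# Dive detection and surface/descent/bottom/ascent annotation.

#' Find dives in a depth trace
#'
#' A dive is a maximal submergence between a downward crossing of the
#' surface-proximity threshold (default 1 m) and the next upward crossing,
#' retained only if its maximal depth exceeds `dive_depth_m` (default 10 m).
#' Shallower submergences are treated as surface time.
#'
#' @param depth_m smoothed depth at `rate_hz` (m).
#' @param rate_hz sampling rate (Hz).
#' @param dive_depth_m minimum maximal depth for a dive (m).
#' @param surface_threshold_m submergence threshold bounding a dive (m).
#' @return `data.frame` with one row per dive: `start_s`, `end_s`,
#'   `max_depth_m` (bottom columns are filled by [annotate_phases()]).
#' @export
find_dives <- function(depth_m, rate_hz = 10, dive_depth_m = 10,
                       surface_threshold_m = 1) {
  sub <- depth_m > surface_threshold_m
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  rows <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    maxd <- max(depth_m[idx])
    if (maxd > dive_depth_m) {
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = (starts[k] - 1) / rate_hz,
        end_s = ends[k] / rate_hz,
        max_depth_m = maxd,
        bottom_start_s = NA_real_,
        bottom_end_s = NA_real_
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      max_depth_m = numeric(0), bottom_start_s = numeric(0),
                      bottom_end_s = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Annotate activity phases
#'
#' Within each dive the bottom phase spans the first-to-last sample deeper
#' than `bottom_frac` times the dive's maximal depth (a single contiguous
#' bottom, so stops at intermediate depths between two deep lobes stay in
#' the bottom phase); descent runs from the dive start to the bottom start
#' and ascent from the bottom end to the dive end. Everything outside dives
#' is surface -- including submergences that never exceed the dive
#' criterion.
#'
#' @param depth_m smoothed depth at `rate_hz` (m).
#' @param dives output of [find_dives()].
#' @param rate_hz sampling rate (Hz).
#' @param bottom_frac fraction of maximal dive depth defining the bottom.
#' @return List of class `phase_annotation`: `labels` (per-sample factor
#'   levels surface/descent/bottom/ascent) and `dives` (the dive table with
#'   `bottom_start_s`/`bottom_end_s` filled).
#' @export
annotate_phases <- function(depth_m, dives, rate_hz = 10, bottom_frac = 0.85) {
  n <- length(depth_m)
  labels <- rep("surface", n)
  if (nrow(dives)) {
    for (i in seq_len(nrow(dives))) {
      idx <- interval_to_idx(dives$start_s[i], dives$end_s[i], rate_hz, n)
      line <- bottom_frac * dives$max_depth_m[i]
      deep <- idx[depth_m[idx] > line]
      b1 <- deep[1]
      b2 <- deep[length(deep)]
      labels[idx] <- "ascent"
      labels[idx[idx < b1]] <- "descent"
      labels[b1:b2] <- "bottom"
      dives$bottom_start_s[i] <- (b1 - 1) / rate_hz
      dives$bottom_end_s[i] <- b2 / rate_hz
    }
  }
  structure(list(labels = labels, dives = dives), class = "phase_annotation")
}

#' Detect dives and annotate phases in one call
#'
#' @param kin a `kinematic_series` (or any list with `depth_m`).
#' @param config a [pipeline_config()].
#' @return A `phase_annotation` (see [annotate_phases()]).
#' @export
segment_phases <- function(kin, config = pipeline_config()) {
  dives <- find_dives(kin$depth_m, config$kin_rate_hz, config$dive_depth_m,
                      config$surface_threshold_m)
  annotate_phases(kin$depth_m, dives, config$kin_rate_hz, config$bottom_frac)
}

#' @export
print.phase_annotation <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("surface", "descent", "bottom", "ascent")))
  cat(sprintf("<phase_annotation> %d dives; samples: %s\n",
              nrow(x$dives),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
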