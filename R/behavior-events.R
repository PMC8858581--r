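# Event-level products: per-event feature records, suckling budget, event
# clusters, non-suckling comparison segments, dive-type counts and the
# per-individual/phase summary table.

# Majority phase over an index range; ties resolved by the phase at the
# range start.
majority_phase <- function(labels, idx) {
  tab <- table(labels[idx])
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1L) labels[idx[1]] else winners
}

#' Per-event kinematic feature record
#'
#' Averages each kinematic channel over `[start_s, end_s)`. Roll is
#' summarized as the mean absolute posture roll (emphasizing deviation from
#' zero regardless of side); pitch uses the posture channel. The activity
#' phase is the majority phase over the event (ties broken by the phase at
#' the event start).
#'
#' @param kin a `kinematic_series`.
#' @param phases a `phase_annotation`.
#' @param event one-row `data.frame` with `label`, `start_s`, `stop_s` (see
#'   [behavior_events()]).
#' @param id record identifier.
#' @return One-row `data.frame`: `id`, `individual`, `phase`, `is_suckling`,
#'   `duration_s`, `avg_depth_m`, `avg_depth_rate_ms`, `avg_speed_ms`,
#'   `avg_fsr_hz`, `avg_pitch_deg`, `avg_abs_roll_deg`, `avg_roll_rate_dps`,
#'   `avg_odba_ms2`.
#' @export
event_features <- function(kin, phases, event, id = NA_character_) {
  n <- length(kin$depth_m)
  idx <- interval_to_idx(event$start_s, event$stop_s, kin$rate_hz, n)
  if (!length(idx) || event$start_s < 0 || event$stop_s > n / kin$rate_hz) {
    stop("event [", event$start_s, ", ", event$stop_s,
         ") lies outside the record")
  }
  data.frame(
    id = id,
    individual = kin$individual_id,
    phase = majority_phase(phases$labels, idx),
    is_suckling = identical(as.character(event$label), "suckling"),
    duration_s = event$stop_s - event$start_s,
    avg_depth_m = mean(kin$depth_m[idx]),
    avg_depth_rate_ms = mean(kin$depth_rate_ms[idx]),
    avg_speed_ms = mean(kin$speed_ms[idx]),
    avg_fsr_hz = mean(kin$fsr_hz[idx]),
    avg_pitch_deg = mean(kin$pitch_post_deg[idx]),
    avg_abs_roll_deg = mean(abs(kin$roll_post_deg[idx])),
    avg_roll_rate_dps = mean(kin$roll_rate_dps[idx]),
    avg_odba_ms2 = mean(kin$odba_ms2[idx]),
    stringsAsFactors = FALSE
  )
}

#' Feature records for a set of events
#'
#' @param kin a `kinematic_series`.
#' @param phases a `phase_annotation`.
#' @param events behavior event `data.frame`.
#' @return `data.frame` with one [event_features()] row per event.
#' @export
events_feature_table <- function(kin, phases, events) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    event_features(kin, phases, events[i, , drop = FALSE],
                   id = sprintf("%s_ev%03d", kin$individual_id, i))
  })
  do.call(rbind, rows)
}

#' Random non-suckling comparison segments
#'
#' Divides the deployment into consecutive non-overlapping segments of
#' `segment_len_s` anchored at t = 0, keeps those with zero overlap with any
#' suckling event, assigns each its majority phase, and draws
#' `n_per_phase` uniformly without replacement for every activity phase in
#' which suckling occurred in this deployment. When a phase has fewer
#' candidates than requested, all are returned with a warning.
#'
#' @param kin a `kinematic_series`.
#' @param phases a `phase_annotation`.
#' @param events behavior event `data.frame` (suckling rows are used).
#' @param seed RNG seed for the draw.
#' @param segment_len_s segment length (s).
#' @param n_per_phase segments drawn per phase.
#' @return `data.frame` of [event_features()] records (`is_suckling` FALSE).
#' @export
sample_nonsuckling_segments <- function(kin, phases, events, seed,
                                        segment_len_s = 20, n_per_phase = 10) {
  n <- length(kin$depth_m)
  total_s <- n / kin$rate_hz
  n_seg <- floor(total_s / segment_len_s)
  if (n_seg < 1L) stop("deployment shorter than one segment")
  suck <- events[events$label == "suckling", , drop = FALSE]
  seg_start <- (seq_len(n_seg) - 1) * segment_len_s
  seg_stop <- seg_start + segment_len_s
  overlaps <- vapply(seq_len(n_seg), function(i) {
    any(suck$start_s < seg_stop[i] & suck$stop_s > seg_start[i])
  }, logical(1))
  seg_phase <- vapply(seq_len(n_seg), function(i) {
    majority_phase(phases$labels,
                   interval_to_idx(seg_start[i], seg_stop[i], kin$rate_hz, n))
  }, character(1))
  suck_phases <- unique(vapply(seq_len(nrow(suck)), function(i) {
    majority_phase(phases$labels,
                   interval_to_idx(suck$start_s[i], suck$stop_s[i],
                                   kin$rate_hz, n))
  }, character(1)))
  set.seed(seed)
  picked <- integer(0)
  for (ph in sort(suck_phases)) {
    cand <- which(!overlaps & seg_phase == ph)
    if (!length(cand)) {
      warning("no non-suckling candidate segments in phase '", ph, "'")
      next
    }
    if (length(cand) < n_per_phase) {
      warning("only ", length(cand), " candidate segments in phase '", ph,
              "'; returning all")
      picked <- c(picked, cand)
    } else {
      picked <- c(picked, sample(cand, n_per_phase))
    }
  }
  picked <- sort(picked)
  rows <- lapply(picked, function(i) {
    ev <- data.frame(label = "non-suckling", start_s = seg_start[i],
                     stop_s = seg_stop[i])
    event_features(kin, phases, ev,
                   id = sprintf("%s_seg%04d", kin$individual_id, i))
  })
  do.call(rbind, rows)
}

#' Suckling time budget
#'
#' Percentage of the recording time occupied by the events.
#'
#' @param events behavior event `data.frame` (or any frame with
#'   `duration_s`).
#' @param total_duration_s total recording duration (s).
#' @return Budget in percent.
#' @export
suckling_budget <- function(events, total_duration_s) {
  if (total_duration_s <= 0) stop("total_duration_s must be positive")
  100 * sum(events$duration_s) / total_duration_s
}

#' Cluster events by temporal proximity
#'
#' Single-linkage chaining: consecutive events whose inter-event gap (next
#' start minus previous end) is below `gap_s` share a cluster.
#'
#' @param events behavior event `data.frame`, any order.
#' @param gap_s chaining gap (s).
#' @return The events with a `cluster` column added, sorted by start;
#'   cluster sizes are in `attr(, "cluster_sizes")`.
#' @export
cluster_events <- function(events, gap_s = 60) {
  ev <- events[order(events$start_s), , drop = FALSE]
  ncl <- 0L
  cl <- integer(nrow(ev))
  last_stop <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$start_s[i] - last_stop >= gap_s) ncl <- ncl + 1L
    cl[i] <- ncl
    last_stop <- max(last_stop, ev$stop_s[i])
  }
  ev$cluster <- cl
  attr(ev, "cluster_sizes") <- as.integer(table(cl))
  ev
}

#' Count suckling and non-suckling dives
#'
#' A dive is a suckling dive iff at least one suckling event overlaps it.
#'
#' @param dives dive table from [find_dives()].
#' @param events behavior event `data.frame`.
#' @return Named integer vector `c(n_suckling_dives, n_other_dives)`.
#' @export
count_dive_types <- function(dives, events) {
  suck <- events[events$label == "suckling", , drop = FALSE]
  is_suck <- vapply(seq_len(nrow(dives)), function(i) {
    any(suck$start_s < dives$end_s[i] & suck$stop_s > dives$start_s[i])
  }, logical(1))
  c(n_suckling_dives = sum(is_suck), n_other_dives = sum(!is_suck))
}

#' Summary table by individual and phase
#'
#' Per (individual, phase): N and, for every `avg_*` feature plus duration,
#' the mean, SD (n - 1; reported as NA when N = 1), min and max -- the
#' layout of a per-calf event characteristics table. A `budget_pct` column
#' gives the share of `total_duration_s` when supplied.
#'
#' @param records [event_features()] rows.
#' @param total_duration_s optional named vector of deployment durations (s)
#'   per individual, enabling the budget column.
#' @return Long-format `data.frame`: `individual`, `phase`, `n`, `feature`,
#'   `mean`, `sd`, `min`, `max` (+ `budget_pct`).
#' @export
summarize_by_individual_phase <- function(records, total_duration_s = NULL) {
  if (!nrow(records)) stop("no records to summarize")
  feats <- c("duration_s", grep("^avg_", names(records), value = TRUE))
  out <- list()
  for (ind in unique(records$individual)) {
    for (ph in unique(records$phase[records$individual == ind])) {
      sub <- records[records$individual == ind & records$phase == ph, ,
                     drop = FALSE]
      budget <- if (!is.null(total_duration_s) && ind %in% names(total_duration_s))
        100 * sum(sub$duration_s) / total_duration_s[[ind]] else NA_real_
      for (f in feats) {
        x <- sub[[f]]
        out[[length(out) + 1L]] <- data.frame(
          individual = ind, phase = ph, n = nrow(sub), feature = f,
          mean = mean(x),
          sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
          min = min(x), max = max(x),
          budget_pct = budget,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
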