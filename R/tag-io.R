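# Readers and writers for the sensor, annotation, event-feature and
# block-table exchange formats.

#' Construct a tag stream
#'
#' Container for one deployment's raw sensor record: high-rate triaxial
#' acceleration (in g) plus a 10 Hz depth trace, with deployment metadata.
#'
#' @param time_s acceleration sample times, seconds from deployment start,
#'   strictly increasing.
#' @param accel n x 3 matrix of acceleration in g (columns x, y, z; x forward,
#'   y right, z up; level posture reads (0, 0, +1) g).
#' @param accel_rate_hz acceleration sampling rate.
#' @param depth_m depth in meters, positive downward, on the 10 Hz clock.
#' @param kin_rate_hz depth/kinematic clock rate (Hz).
#' @param individual_id identifier of the tagged animal.
#' @param metadata free-form list (tag id, start datetime, ...).
#'
#' @return An object of class `tag_stream`.
#' @export
tag_stream <- function(time_s, accel, accel_rate_hz, depth_m,
                       kin_rate_hz = 10, individual_id = "unknown",
                       metadata = list()) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L) stop("accel must have three columns (x, y, z)")
  if (length(time_s) != nrow(accel)) stop("time_s and accel lengths differ")
  if (any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop("time_s is not strictly increasing (first offending row: ", bad, ")")
  }
  if (anyNA(accel) || anyNA(depth_m)) stop("NA values in sensor channels")
  if (any(depth_m < -0.5)) stop("depth below -0.5 m: wrong units or sign?")
  depth_m <- pmax(depth_m, 0)
  structure(
    list(time_s = time_s, accel = accel, accel_rate_hz = accel_rate_hz,
         depth_m = depth_m, kin_rate_hz = kin_rate_hz,
         individual_id = individual_id, metadata = metadata),
    class = "tag_stream"
  )
}

#' @export
print.tag_stream <- function(x, ...) {
  cat(sprintf(
    "<tag_stream> %s: %.1f min, accel %d Hz (%d samples), depth %d Hz (%d samples)\n",
    x$individual_id, length(x$depth_m) / x$kin_rate_hz / 60,
    round(x$accel_rate_hz), nrow(x$accel), round(x$kin_rate_hz),
    length(x$depth_m)
  ))
  invisible(x)
}

# Canonical column names and the default aliases the dialect mapper accepts.
.tag_csv_canonical <- c("time_s", "ax_g", "ay_g", "az_g", "depth_m")

#' Read a CATS-style sensor CSV
#'
#' Expects one row per acceleration sample with columns for time, the three
#' acceleration axes (g) and depth (m). Column names can be mapped through
#' `dialect`, a named character vector `c(canonical = "file column")`, so
#' vendor exports with decorated headers (e.g. `"Depth (100bar) 1 [m]"`)
#' ingest without editing the file. Depth is averaged down to the 10 Hz
#' kinematic clock when logged at the acceleration rate. Gaps shorter than
#' 1 s are linearly interpolated; longer gaps raise an error asking for the
#' record to be split.
#'
#' @param path CSV file path.
#' @param dialect optional named character vector mapping canonical names
#'   (`time_s`, `ax_g`, `ay_g`, `az_g`, `depth_m`) to the file's columns.
#' @param individual_id animal identifier attached to the stream.
#' @param kin_rate_hz output depth clock rate (Hz).
#'
#' @return A [tag_stream()].
#' @export
read_tag_csv <- function(path, dialect = NULL, individual_id = "unknown",
                         kin_rate_hz = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(df)) {
        stop("dialect column not in file: ", dialect[[canon]])
      }
      names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  # tolerate a 'datetime' column written by write_tag_csv
  if (!"time_s" %in% names(df) && "datetime" %in% names(df)) {
    names(df)[names(df) == "datetime"] <- "time_s"
  }
  missing <- setdiff(.tag_csv_canonical, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  t <- as.numeric(df$time_s)
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop("non-monotonic time at row ", bad)
  }
  dt <- stats::median(diff(t))
  accel_rate <- round(1 / dt)
  big_gap <- which(diff(t) >= 1)
  if (length(big_gap)) {
    warning("gap of >= 1 s at ", round(t[big_gap[1]], 2),
            " s; keeping the record up to the gap")
    keep <- seq_len(big_gap[1])
    t <- t[keep]
    df <- df[keep, , drop = FALSE]
  }
  # regularize small (< 1 s) gaps by linear interpolation onto a uniform clock
  n_reg <- floor((t[length(t)] - t[1]) / dt) + 1L
  t_reg <- t[1] + (seq_len(n_reg) - 1L) * dt
  interp <- function(y) stats::approx(t, y, xout = t_reg, rule = 2)$y
  accel <- cbind(interp(df$ax_g), interp(df$ay_g), interp(df$az_g))
  depth_hi <- interp(df$depth_m)
  depth <- if (accel_rate > kin_rate_hz) {
    bin_average(depth_hi, accel_rate, kin_rate_hz)
  } else {
    depth_hi
  }
  tag_stream(
    time_s = t_reg - t_reg[1], accel = accel, accel_rate_hz = accel_rate,
    depth_m = depth, kin_rate_hz = kin_rate_hz, individual_id = individual_id,
    metadata = list(source = path, t0_s = t[1])
  )
}

#' Write a tag stream as a CATS-style sensor CSV
#'
#' One row per acceleration sample: `datetime` (seconds from start), the
#' three acceleration axes in g, depth in m (linearly interpolated onto the
#' acceleration clock) and a constant placeholder temperature.
#'
#' @param stream a [tag_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tag_csv <- function(stream, path) {
  t_depth <- (seq_along(stream$depth_m) - 1) / stream$kin_rate_hz
  depth_hi <- stats::approx(t_depth, stream$depth_m, xout = stream$time_s,
                            rule = 2)$y
  df <- data.frame(
    datetime = stream$time_s,
    ax_g = stream$accel[, 1], ay_g = stream$accel[, 2],
    az_g = stream$accel[, 3],
    depth_m = depth_hi, temp_c = 25
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a behavior event table
#'
#' @param start_s,stop_s event boundaries in seconds from deployment start.
#' @param label behavior label (default `"suckling"`).
#' @param roll_side rolling side observed on video: `"right"`, `"left"` or
#'   `"unknown"`.
#' @return A `data.frame` with columns `label`, `start_s`, `stop_s`,
#'   `duration_s`, `roll_side`, sorted by start time.
#' @export
behavior_events <- function(start_s, stop_s, label = "suckling",
                            roll_side = "unknown") {
  if (any(stop_s <= start_s)) {
    stop("event with stop_s <= start_s (first at index ",
         which(stop_s <= start_s)[1], ")")
  }
  df <- data.frame(
    label = rep_len(label, length(start_s)),
    start_s = start_s, stop_s = stop_s,
    duration_s = stop_s - start_s,
    roll_side = rep_len(roll_side, length(start_s)),
    stringsAsFactors = FALSE
  )
  df[order(df$start_s), , drop = FALSE]
}

#' Read a BORIS-style annotation CSV
#'
#' Expects columns `behavior`, `start_s`, `stop_s` and optionally
#' `modifier` (rolling side). Events are sorted by start time; overlapping
#' or abutting events with the same label are merged with a warning.
#'
#' @param path CSV file path.
#' @return A behavior event `data.frame` (see [behavior_events()]).
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("behavior", "start_s", "stop_s")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  side <- if ("modifier" %in% names(df)) as.character(df$modifier) else "unknown"
  ev <- behavior_events(df$start_s, df$stop_s, label = as.character(df$behavior),
                        roll_side = side)
  merge_events(ev)
}

# Merge overlapping or abutting events sharing a label.
merge_events <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  out <- ev[0, ]
  for (lab in unique(ev$label)) {
    sub <- ev[ev$label == lab, , drop = FALSE]
    merged_any <- FALSE
    rows <- sub[1, , drop = FALSE]
    for (j in seq_len(nrow(sub))[-1]) {
      last <- nrow(rows)
      if (sub$start_s[j] <= rows$stop_s[last]) {
        rows$stop_s[last] <- max(rows$stop_s[last], sub$stop_s[j])
        merged_any <- TRUE
      } else {
        rows <- rbind(rows, sub[j, , drop = FALSE])
      }
    }
    if (merged_any) {
      warning("merged overlapping/abutting '", lab, "' events")
    }
    out <- rbind(out, rows)
  }
  out$duration_s <- out$stop_s - out$start_s
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a BORIS-style annotation CSV
#'
#' @param events behavior event `data.frame`.
#' @param path output CSV path.
#' @param observation_id observation identifier written per row.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, observation_id = "obs1") {
  df <- data.frame(
    observation_id = observation_id,
    behavior = events$label,
    start_s = events$start_s,
    stop_s = events$stop_s,
    modifier = events$roll_side
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read phase annotation intervals
#'
#' Serializes per-sample phase labels as a BED-like interval CSV with
#' columns `start_s`, `end_s`, `phase`.
#'
#' @param phases a phase annotation (see [annotate_phases()]).
#' @param path output CSV path.
#' @param rate_hz sampling rate of the label vector.
#' @return `path`, invisibly.
#' @export
write_phases_csv <- function(phases, path, rate_hz = 10) {
  lab <- phases$labels
  r <- rle(lab)
  end_i <- cumsum(r$lengths)
  start_i <- c(1L, utils::head(end_i, -1) + 1L)
  df <- data.frame(
    start_s = (start_i - 1) / rate_hz,
    end_s = end_i / rate_hz,
    phase = r$values
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phases_csv
#' @return For `read_phases_csv`, the per-sample label vector.
#' @export
read_phases_csv <- function(path, rate_hz = 10) {
  df <- utils::read.csv(path)
  n <- round(max(df$end_s) * rate_hz)
  lab <- character(n)
  for (i in seq_len(nrow(df))) {
    idx <- interval_to_idx(df$start_s[i], df$end_s[i], rate_hz, n)
    lab[idx] <- df$phase[i]
  }
  lab
}

#' Write / read the event feature table
#'
#' Per-event (or per-segment) feature records with a stable column order,
#' in a stable per-event exchange schema.
#'
#' @param records event feature `data.frame` (see [event_features()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  if (nrow(records) == 0L) warning("writing header-only feature table")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the 2-s block table
#'
#' The block table is the machine-learning exchange format: exactly the 43
#' feature columns plus `individual`, `start_s`, `phase`, `label` and
#' `retained`.
#'
#' @param blocks block `data.frame` (see [make_blocks()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  if (nrow(blocks) == 0L) warning("writing header-only block table")
  meta <- c("individual", "start_s", "phase", "label", "retained")
  feats <- block_feature_names()
  missing <- setdiff(c(meta, feats), names(blocks))
  if (length(missing)) {
    stop("block table missing column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(blocks[, c(meta, feats)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_table
#' @export
read_block_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(block_feature_names(), names(df))
  if (length(missing)) {
    stop("block table missing feature column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}
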