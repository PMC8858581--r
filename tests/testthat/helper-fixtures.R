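# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A 20-minute deployment with sensor noise, plus its derived kinematics and
# phases -- the workhorse for pipeline-level tests.
tiny_deployment <- function() {
  memo("tiny_dep", {
    dep <- generate_deployment(synthetic_config(duration_s = 1200, seed = 42))
    kin <- compute_kinematics(dep$stream)
    phases <- segment_phases(kin)
    list(dep = dep, kin = kin, phases = phases)
  })
}

# The same deployment without sensor/depth noise, for recovery oracles.
clean_deployment <- function() {
  memo("clean_dep", {
    dep <- generate_deployment(synthetic_config(
      duration_s = 1200, seed = 42, noise_sd_g = 0, depth_noise_sd_m = 0
    ))
    kin <- compute_kinematics(dep$stream)
    phases <- segment_phases(kin)
    list(dep = dep, kin = kin, phases = phases)
  })
}

# The reference 3-individual cohort (4 h each) used by the end-to-end
# detection experiments; building it once keeps the suite fast.
cohort_configs <- function(seeds = c(101, 202, 303)) {
  offs <- list(list(depth_m = 0, pitch_deg = 0, speed_ms = 0),
               list(depth_m = 15, pitch_deg = 8, speed_ms = 0.25),
               list(depth_m = -5, pitch_deg = -6, speed_ms = -0.2))
  lapply(1:3, function(i) synthetic_config(
    duration_s = 14400, seed = seeds[i],
    individual_id = paste0("Calf", i), individual_offsets = offs[[i]]
  ))
}

cohort_blocks <- function() {
  memo("cohort_blocks", {
    cohort <- generate_cohort(cohort_configs())
    blocks <- do.call(rbind, lapply(cohort, function(dep) {
      kin <- compute_kinematics(dep$stream)
      make_blocks(kin, dep$truth_events, segment_phases(kin))
    }))
    rownames(blocks) <- NULL
    blocks
  })
}

# Small labelled block table with a planted signal: cheap stand-in for
# classifier unit tests that do not need the full pipeline.
fake_blocks <- function(n = 400, n_features = 6, signal = 2, seed = 1,
                        individuals = c("A", "B")) {
  set.seed(seed)
  label <- rep(c("suckling", "non-suckling"), length.out = n)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  x[label == "suckling", 1] <- x[label == "suckling", 1] + signal
  data.frame(individual = rep(individuals, each = ceiling(n / length(individuals)))[1:n],
             label = label, x, stringsAsFactors = FALSE)
}

# A hand-built kinematic series with fully controlled channels.
manual_kin <- function(n, rate = 10, depth = 0, depth_rate = 0, speed = 1,
                       fsr = 0, pitch = 0, roll = 0, roll_rate = 0, odba = 0,
                       individual = "test") {
  rep_n <- function(x) rep_len(x, n)
  structure(list(
    time_s = (seq_len(n) - 1) / rate,
    depth_m = rep_n(depth), depth_rate_ms = rep_n(depth_rate),
    speed_ms = rep_n(speed), fsr_hz = rep_n(fsr),
    pitch_raw_deg = rep_n(pitch), roll_raw_deg = rep_n(roll),
    pitch_post_deg = rep_n(pitch), roll_post_deg = rep_n(roll),
    roll_rate_dps = rep_n(roll_rate), odba_ms2 = rep_n(odba),
    half_strokes = data.frame(time_s = numeric(0), polarity = integer(0)),
    rate_hz = rate, individual_id = individual
  ), class = "kinematic_series")
}
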