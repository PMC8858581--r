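# Event-level characterization: per-event kinematic records, the random
# non-suckling comparison segments (10 per activity phase with suckling),
# and the per-individual/phase summary in the style of a per-calf event
# characteristics table. Writes results/event_features.csv and
# results/event_summary_by_phase.csv.

source("analysis/00_common.R")

processed <- get_processed_cohort()

records <- do.call(rbind, lapply(processed, function(p) {
  ev <- events_feature_table(p$kin, p$phases, p$dep$truth_events)
  seg <- suppressWarnings(sample_nonsuckling_segments(
    p$kin, p$phases, p$dep$truth_events, seed = p$dep$config$seed
  ))
  rbind(ev, seg)
}))
rownames(records) <- NULL
write_feature_table(records, "results/event_features.csv")

suck <- records[records$is_suckling, ]
durations <- vapply(processed,
                    function(p) p$dep$config$duration_s, numeric(1))
names(durations) <- vapply(processed,
                           function(p) p$dep$config$individual_id,
                           character(1))
summary_tab <- summarize_by_individual_phase(suck, durations)
write.csv(summary_tab, "results/event_summary_by_phase.csv",
          row.names = FALSE)

cat("Suckling events by phase:\n")
print(table(suck$individual, suck$phase))
cat("\nMean feature values, suckling vs non-suckling segments:\n")
for (f in c("avg_abs_roll_deg", "avg_fsr_hz", "avg_speed_ms",
            "avg_pitch_deg", "avg_odba_ms2", "avg_roll_rate_dps")) {
  cat(sprintf("  %-18s suckling %6.2f   non-suckling %6.2f\n", f,
              mean(suck[[f]]), mean(records[[f]][!records$is_suckling])))
}
cat("\nThe suckling signature: sustained high |roll| with mildly elevated\n",
    "FSR and reduced speed, at near-zero pitch -- the non-suckling segments\n",
    "overlap it in every single channel, which is why classification uses\n",
    "all 43 block features.\n")
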