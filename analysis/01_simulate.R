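#!/usr/bin/env Rscript
# Generate the two synthetic experimental days (SWR blockade and delayed
# control) and export their raw inputs in the pipeline's file formats:
# spike-time text files, position CSVs, flat-binary LFP with YAML sidecars,
# and ground-truth / pulse event CSVs.

source(file.path("analysis", "00_config.R"))

out <- results_dir("data")
for (cond in names(DAY_SEEDS)) {
  day <- get_day(cond)
  prefix <- file.path(out, cond)
  write.csv(day$manifest, paste0(prefix, "_manifest.csv"), row.names = FALSE)
  write_spike_file(day$spikes$expl1, paste0(prefix, "_expl1_spikes.txt"))
  write_spike_file(day$spikes$expl2, paste0(prefix, "_expl2_spikes.txt"))
  write_positions(day$trajectories$expl1, paste0(prefix, "_expl1_pos.csv"))
  write_positions(day$trajectories$expl2, paste0(prefix, "_expl2_pos.csv"))
  write_lfp(day$sleep[[1]]$lfp, paste0(prefix, "_sleep1.dat"))
  write_events(day$sleep[[1]]$truth, paste0(prefix, "_sleep1_truth.csv"))
  write_events(day$sleep[[1]]$ttl, paste0(prefix, "_sleep1_ttl.csv"))
  write_events(day$control_pulses, paste0(prefix, "_control_pulses.csv"))
  cat(sprintf("%s day: %d cells, %d ground-truth ripples in sleep block 1, %d TTLs\n",
              cond, day$config$n_cells, nrow(day$sleep[[1]]$truth),
              nrow(day$sleep[[1]]$ttl)))
}
cat("raw inputs written under", out, "\n")
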