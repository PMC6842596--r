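#!/usr/bin/env Rscript
# Junction-state classification and opening/closing event statistics.
#
# Reads the production trajectories of 02_simulate_unzipping.R, assigns
# per-frame junction states (CLOSED / FLIP5 / FLIP3 / OPEN), extracts
# complete opening and closing events with their 5'/3' pathway labels, and
# tests the detailed-balance expectation that opening and closing use each
# pathway with statistically identical frequencies.

library(unwindr)

traj_dir <- "results/trajectories"
out <- "results/junction"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

metas <- list.files(traj_dir, pattern = "_meta\\.json$", full.names = TRUE)
if (length(metas) == 0) stop("run analysis/02_simulate_unzipping.R first")

for (meta_file in metas) {
  base <- sub("_meta\\.json$", "", meta_file)
  name <- basename(base)
  parts <- strsplit(name, "_")[[1]]
  chan <- as.matrix(utils::read.csv(paste0(base, "_channels.csv"),
                                    check.names = FALSE))
  seqstr <- parts[2]
  attr(chan, "seq1") <- seqstr
  attr(chan, "nucleic_type") <- parts[1]
  ser <- assign_states(chan, window = 15)  # 15 saved frames = 300 steps
  write_states_tsv(ser, file.path(out, paste0(name, "_states.tsv")))
  ev <- extract_events(ser, min_dwell = 15)
  utils::write.table(ev, file.path(out, paste0(name, "_events.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d frames, state occupancies:\n", name, nrow(ser)))
  print(round(table(ser$state) / nrow(ser), 3))
  cat(sprintf("  %d complete opening/closing events\n", nrow(ev)))
  db <- detailed_balance_report(ev)
  print(db)
}
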