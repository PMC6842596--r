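#!/usr/bin/env Rscript
# h-unwind predictions for the homopurine/homopyrimidine benchmark
# constructs, from (i) the closed-form reference table in which purine
# flipping is uniformly disfavoured by 1 kT, and (ii) the nearest-neighbour
# tables estimated from the DNA unzipping simulations (pooled).

library(unwindr)

tab_dir <- "results/nn_tables"
out <- "results/hunwind"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

constructs <- design_constructs()

score_all <- function(tab, label) {
  scores <- lapply(constructs, hunwind, table = tab)
  rk <- rank_predictions(scores)
  cat(sprintf("\n-- %s --\n", label))
  print(rk)
  utils::write.csv(rk, file.path(out, paste0(label, "_ranking.csv")),
                   row.names = FALSE)
  rk
}

score_all(toy_dg_table(1), "toy_1kT")

files <- list.files(tab_dir, pattern = "^DNA_.*_dg\\.csv$", full.names = TRUE)
if (length(files)) {
  tabs <- lapply(files, utils::read.csv)
  pooled <- do.call(rbind, tabs)
  # pool by context: weighted-population sums across runs
  agg <- do.call(rbind, lapply(split(pooled, pooled$context), function(d) {
    data.frame(context = d$context[1],
               g = log(sum(d$w5) / sum(d$w3)),
               se = sqrt(sum(d$se^2, na.rm = TRUE)) / max(1, sum(!is.na(d$se))),
               n5 = sum(d$n5), n3 = sum(d$n3),
               w5 = sum(d$w5), w3 = sum(d$w3))
  }))
  class(agg) <- c("nn_dg_table", "data.frame")
  write_dg_csv(agg, file.path(out, "DNA_pooled_dg.csv"))
  needed <- unique(hunwind(constructs[[1]], toy_dg_table(1))$steps$context)
  have <- agg$context[is.finite(agg$g)]
  if (all(needed %in% have)) {
    score_all(agg, "simulated_DNA")
  } else {
    cat("simulated DNA table misses contexts:",
        setdiff(needed, have), "- skipping simulated ranking\n")
  }
}
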