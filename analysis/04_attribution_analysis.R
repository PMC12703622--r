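#!/usr/bin/env Rscript
# Attribution analyses over the planned cohort: policy decomposition into
# baseline / DVH / memory components, leading actions per input source,
# organ-segmented DVH heatmaps, and the baseline-offset sensitivity of the
# heatmaps (offsets 0.005 and 0.01 on the OAR baseline entries, PTV kept
# zero). Reads results/cohort written by 03_plan_cohort.R.

suppressMessages(library(planxai))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

ck <- load_checkpoints("results/checkpoints")
man <- read.csv("results/cohort_manifest.csv", stringsAsFactors = FALSE)
acts <- action_table()

lead_rows <- seg_rows <- dec_rows <- list()
for (ci in seq_along(ck$checkpoints)) {
  params <- ck$checkpoints[[ci]]$params
  files <- man$trace[man$checkpoint == ci & man$steps > 0][1:4]
  files <- files[!is.na(files)]
  for (f in files) {
    tr <- read_trace(f)
    for (si in seq_along(tr$steps)) {
      st <- tr$steps[[si]]
      recs <- attribute_all_actions(params, st$dvh_input, st$memory_in,
                                    baseline_spec(0), path_steps = 64L)
      la <- leading_action(recs)
      lead_rows[[length(lead_rows) + 1L]] <- data.frame(
        checkpoint = ci, trace = basename(f), step = si,
        lead_dvh = acts$label[la[["dvh"]]],
        lead_c = acts$label[la[["c"]]],
        lead_h = acts$label[la[["h"]]],
        chosen = acts$label[st$action]
      )
      seg <- heatmap_segments(recs[[la[["dvh"]]]]$ig_dvh)
      seg_rows[[length(seg_rows) + 1L]] <- cbind(
        data.frame(checkpoint = ci, trace = basename(f), step = si), seg)
      dec <- decompose_policy(recs)
      dec_rows[[length(dec_rows) + 1L]] <- data.frame(
        checkpoint = ci, trace = basename(f), step = si,
        action = seq_len(nrow(dec)), dec)
    }
  }
}
write.csv(do.call(rbind, lead_rows), "results/leading_actions.csv",
          row.names = FALSE)
write.csv(do.call(rbind, seg_rows), "results/heatmap_segments.csv",
          row.names = FALSE)
write.csv(do.call(rbind, dec_rows), "results/policy_decomposition.csv",
          row.names = FALSE)

lead <- do.call(rbind, lead_rows)
cat("most frequent leading actions (DVH input):\n")
print(sort(table(lead$lead_dvh), decreasing = TRUE)[1:5])

# baseline sensitivity on a couple of traces of the best checkpoint
best <- which.max(tapply(man$final_score, man$checkpoint, mean))
fs <- man$trace[man$checkpoint == best & man$steps > 0][1:2]
traces <- lapply(fs[!is.na(fs)], read_trace)
sens <- baseline_sensitivity(ck$checkpoints[[best]]$params, traces,
                             offsets = c(0.005, 0.01), path_steps = 32L)
write.csv(sens, "results/baseline_sensitivity.csv", row.names = FALSE)
cat("\nbaseline-offset sensitivity of DVH heatmaps (cosine vs zero baseline):\n")
print(sens, digits = 3)
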