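#!/usr/bin/env Rscript
# The quantitative interpretation suite over the planned cohort:
# attribution-reward similarity (both reward definitions), normalized
# policy entropy, actual vs ideal planning steps, the final-TPP-space
# summary, the similarity-vs-steps correlation across checkpoints, and the
# LSTM memory probe with a classical-MDS embedding and silhouette readout.

suppressMessages(library(planxai))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

ck <- load_checkpoints("results/checkpoints")
man <- read.csv("results/cohort_manifest.csv", stringsAsFactors = FALSE)
cases <- new.env()
get_case <- function(k) {
  key <- as.character(k)
  if (is.null(cases[[key]])) {
    cases[[key]] <- generate_case(derive_seed(seed, "cohort-case", k),
                                  overlap_level = 0.25)
  }
  cases[[key]]
}

traces_by_ckpt <- list()
sims_by_ckpt <- list()
for (ci in seq_along(ck$checkpoints)) {
  rows <- man[man$checkpoint == ci, ]
  traces <- lapply(rows$trace, read_trace)
  traces_by_ckpt[[sprintf("ckpt%02d", ci)]] <- traces
  # similarity is expensive (18 counterfactual re-optimizations per step):
  # compute it on the first few non-trivial plans per checkpoint
  idx <- which(rows$steps > 0)[1:3]
  idx <- idx[!is.na(idx)]
  sims <- rep(NA_real_, nrow(rows))
  for (i in idx) {
    sims[i] <- trace_similarity(traces[[i]], get_case(rows$case[i]),
                                ck$checkpoints[[ci]]$params, mode = 2,
                                path_steps = 32L)$similarity
  }
  sims_by_ckpt[[sprintf("ckpt%02d", ci)]] <- as.list(sims)
}

rep <- cohort_report(traces_by_ckpt, similarities = sims_by_ckpt)
write.csv(rep$plans, "results/plans.csv", row.names = FALSE)
write.csv(rep$summary, "results/checkpoint_summary.csv", row.names = FALSE)
if (!is.null(rep$tpp_space)) {
  write.csv(rep$tpp_space, "results/tpp_space.csv", row.names = FALSE)
}
jsonlite::write_json(rep$correlation, "results/similarity_steps_correlation.json",
                     auto_unbox = TRUE, digits = NA)
print(rep)

# memory probe on the best checkpoint: do the LSTM states cluster by
# violation scenario?
best <- which.max(rep$summary$final_mean)
probe <- memory_probe(ck$checkpoints[[best]]$params)
sep_c <- probe_separation(probe$c, probe$labels)
sep_h <- probe_separation(probe$h, probe$labels)
cat(sprintf(
  "memory probe: c separation %.3f, h separation %.3f (between - within cosine distance)\n",
  sep_c$separation, sep_h$separation
))
emb <- stats::cmdscale(as.dist(1 - tcrossprod(probe$c)), k = 2)
probe_df <- data.frame(label = probe$labels, mds1 = emb[, 1], mds2 = emb[, 2])
if (requireNamespace("cluster", quietly = TRUE)) {
  sil <- cluster::silhouette(as.integer(factor(probe$labels)),
                             as.dist(1 - tcrossprod(probe$c)))
  cat(sprintf("mean silhouette width (c states): %.3f\n",
              mean(sil[, "sil_width"])))
}
write.csv(probe_df, "results/memory_probe_embedding.csv", row.names = FALSE)
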