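#!/usr/bin/env Rscript
# Train checkpoint agents on one phantom case with the on-policy
# actor-critic trainer and snapshot parameters at regular intervals,
# emulating (at desk scale) the progression of checkpoint agents whose
# interpretation the rest of the pipeline studies. Saves the checkpoint
# archive under results/checkpoints/ and a greedy learning-curve table.

suppressMessages(library(planxai))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
steps <- 5000L
ckpt_every <- 1250L
dir.create("results", showWarnings = FALSE)

train_case <- generate_case(derive_seed(seed, "cohort-case", 1L),
                            overlap_level = 0.25)
cat(sprintf("training on %s for %d steps (checkpoint every %d)...\n",
            train_case$case_id, steps, ckpt_every))
ck <- train_checkpoints(train_case, steps = steps,
                        checkpoint_every = ckpt_every,
                        seed = derive_seed(seed, "train"))
save_checkpoints(ck, "results/checkpoints")

# greedy evaluation on 20 held-out cases per checkpoint
panel <- lapply(1:20, function(k) {
  generate_case(derive_seed(seed, "eval-case", k), overlap_level = 0.25)
})
curve <- do.call(rbind, lapply(seq_along(ck$checkpoints), function(i) {
  sc <- vapply(panel, function(cs) {
    run_episode(cs, ck$checkpoints[[i]]$params, max_steps = 20L,
                mode = "greedy")$final_score
  }, numeric(1))
  data.frame(checkpoint = i, step = ck$checkpoints[[i]]$step,
             mean_score = mean(sc), sd_score = sd(sc),
             n_full = sum(sc >= 9))
}))
write.csv(curve, "results/learning_curve.csv", row.names = FALSE)
print(curve, digits = 3)
cat(sprintf("greedy panel score moved %.2f -> %.2f over training\n",
            curve$mean_score[1], curve$mean_score[nrow(curve)]))
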