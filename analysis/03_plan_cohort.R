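#!/usr/bin/env Rscript
# Plan the cohort with every checkpoint agent: repeated stochastic episodes
# per case, full trace + per-step attribution archives (JSON-lines), and a
# manifest. The full-scale study plans 39 cases 5 times each (195 plans per
# agent); this driver defaults to a desk-scale 8 cases x 2 repeats.

suppressMessages(library(planxai))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
n_cases <- 8L
repeats <- 2L

ck <- load_checkpoints("results/checkpoints")
cfg <- default_config()
cfg$seed <- seed
cfg$attribution$path_steps <- 32L

man <- simulate_cohort(cfg, ck, "results/cohort", n_cases = n_cases,
                       repeats = repeats, max_steps = 20L)
write.csv(man, "results/cohort_manifest.csv", row.names = FALSE)

bad <- sum(vapply(man$trace, function(f) nrow(validate_archive(f, cfg)),
                  numeric(1)))
cat(sprintf(
  "planned %d episodes (%d checkpoints x %d cases x %d repeats); %d archive violations\n",
  nrow(man), length(ck$checkpoints), n_cases, repeats, bad
))
agg <- aggregate(cbind(final_score, steps) ~ checkpoint, man, mean)
print(agg, digits = 3)
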