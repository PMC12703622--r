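# Shared fixtures. Expensive artifacts (trained checkpoint sets) are built
# once per test run and cached in a session environment.

.px_cache <- new.env(parent = emptyenv())

px_cached <- function(key, expr) {
  if (!exists(key, envir = .px_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .px_cache)
  }
  get(key, envir = .px_cache, inherits = FALSE)
}

# tiny network for gradient / IG micro-tests
tiny_config <- function() net_config(input = 6L, dense = 5L, hidden = 4L,
                                     actions = 3L)

tiny_baseline <- function(offset = 0) {
  baseline_spec(offset, n_dvh = 6L, n_mem = 4L)
}

# a minimal hand-built case: identity dose matrix, PTV over all voxels.
# Bladder/rectum masks are empty: only the PTV terms are active.
identity_ptv_case <- function(n = 5L, d_p = 10) {
  phantom_case(
    case_id = "identity-ptv", voxel_count = n,
    structure_masks = list(PTV = seq_len(n), BLA = integer(0),
                           REC = integer(0)),
    dose_matrix = diag(n), prescription_dose = d_p
  )
}

# small planning case reused across tests
small_case <- function(seed = 1, overlap = 0.25) {
  px_cached(sprintf("case-%s-%s", seed, overlap),
            generate_case(seed, overlap_level = overlap, size = "small"))
}

# one trained checkpoint set per seed (the scaled-down study conditions:
# one small case, 5000 environment steps, checkpoints every 1250 steps)
toy_checkpoints <- function(seed = 11) {
  px_cached(sprintf("ckpts-%d", seed), {
    train_checkpoints(small_case(1), steps = 5000L, checkpoint_every = 1250L,
                      seed = seed)
  })
}

toy_trained_agent <- function(seed = 11) {
  ck <- toy_checkpoints(seed)
  ck$checkpoints[[length(ck$checkpoints)]]$params
}

# greedy evaluation over a panel of generated cases; returns final scores
greedy_panel_scores <- function(params, n_cases = 20L, max_steps = 20L) {
  vapply(seq_len(n_cases), function(k) {
    cs <- small_case(100 + k)
    run_episode(cs, params, max_steps = max_steps, mode = "greedy")$final_score
  }, numeric(1))
}
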