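#' @title Quantitative interpretation metrics
#' @description Connects attributions to planning behaviour: organ-wise
#'   attribution/reward vectors and their probability-weighted cosine
#'   similarity, normalized policy entropy, the ideal number of planning
#'   steps, an LSTM memory probe, and cohort-level reporting.
#' @name exai_metrics
NULL

#' Organ-wise attribution vector
#'
#' Sums a record's 300 DVH attributions per organ block (PTV entries
#' 1..100, bladder 101..200, rectum 201..300).
#'
#' @param record an `attribution_record`.
#' @return named numeric 3-vector `(PTV, BLA, REC)`.
#' @export
organ_attribution <- function(record) {
  v <- record$ig_dvh
  stopifnot(length(v) == 300L)
  c(PTV = sum(v[1:100]), BLA = sum(v[101:200]), REC = sum(v[201:300]))
}

#' Counterfactual organ-wise reward vectors for all actions at one step
#'
#' For each of the 18 actions, applies it to the step's pre-action TPPs,
#' re-optimizes the plan (warm-started from the step's pre-action plan) and
#' scores it. Reward mode 1 is the per-organ score change (after minus
#' before); mode 2 is the per-organ dose-violation *reduction* (before
#' minus after), so mitigating a violation is positive. Actions clipped at
#' a bound leave the TPPs unchanged and get a zero vector.
#'
#' @param trace an `episode_trace`.
#' @param step step index.
#' @param case the [phantom_case()] the trace was planned on.
#' @param criteria scoring criteria table.
#' @param mode 1 (score difference) or 2 (dose-violation difference).
#' @param warm_start use the recorded pre-action fluence as solver seed
#'   (set FALSE for a cold-start cross-check).
#' @param control optimizer control.
#' @return matrix `18 x 3` (columns PTV, BLA, REC).
#' @export
reward_vectors <- function(trace, step, case, criteria = default_criteria(),
                           mode = 2, warm_start = TRUE, control = list()) {
  stopifnot(mode %in% c(1, 2))
  st <- trace$steps[[step]]
  pre_tpps <- tpps_before_step(trace, step)
  pre_plan <- if (warm_start) {
    structure(list(fluence = st$fluence_pre), class = "plan_state")
  } else NULL
  before <- if (step == 1L) {
    trace$initial_score
  } else {
    list(organ_scores = trace$steps[[step - 1L]]$organ_scores_after,
         organ_violations = trace$steps[[step - 1L]]$organ_violations_after)
  }
  n_act <- nrow(action_table(attr(pre_tpps, "grid")))
  out <- matrix(0, n_act, 3, dimnames = list(NULL, c("PTV", "BLA", "REC")))
  for (j in seq_len(n_act)) {
    tp_j <- apply_action(pre_tpps, j)
    if (isTRUE(all.equal(as.numeric(tp_j), as.numeric(pre_tpps)))) {
      next  # clipped at a bound: identical re-optimization, zero reward
    }
    plan_j <- optimize_fluence(case, tp_j, warm_start = pre_plan,
                               control = control)
    sc_j <- evaluate_plan(plan_j, case, criteria)$score
    out[j, ] <- if (mode == 1) {
      sc_j$organ_scores - before$organ_scores
    } else {
      before$organ_violations - sc_j$organ_violations
    }
  }
  out
}

#' Probability-weighted attribution-reward similarity of a plan
#'
#' Computes
#' \deqn{\mathrm{Similarity} = \frac{1}{N} \sum_{i=1}^{N} \sum_{j=1}^{18}
#'   p_{ij} \cos(A_{ij}, R_{ij}),}
#' where `N` is the number of tuning steps, `p_ij` the recorded policy
#' probability, and `A_ij`, `R_ij` the organ-wise attribution and reward
#' vectors. The cosine of a zero vector is defined as 0 (neutral
#' contribution). Since each probability row sums to 1, the value lies in
#' \[-1, 1\]; normalizing by N makes plans of different lengths comparable.
#'
#' @param probs `N x 18` matrix of per-step policy probabilities.
#' @param A list of N `18 x 3` organ-attribution matrices (rows = actions),
#'   or an `N x 18 x 3` array.
#' @param R same layout for the reward vectors.
#' @return list with `similarity`, `n_steps`.
#' @export
similarity_index <- function(probs, A, R) {
  if (is.array(A) && length(dim(A)) == 3L) {
    A <- lapply(seq_len(dim(A)[1]), function(i) A[i, , ])
  }
  if (is.array(R) && length(dim(R)) == 3L) {
    R <- lapply(seq_len(dim(R)[1]), function(i) R[i, , ])
  }
  probs <- rbind(probs)
  n <- nrow(probs)
  if (length(A) != n || length(R) != n) stop("step count mismatch")
  total <- 0
  for (i in seq_len(n)) {
    if (nrow(A[[i]]) != ncol(probs) || nrow(R[[i]]) != ncol(probs)) {
      stop("action count mismatch")
    }
    cs <- vapply(seq_len(ncol(probs)),
                 function(j) .cosine(A[[i]][j, ], R[[i]][j, ]), numeric(1))
    total <- total + sum(probs[i, ] * cs)
  }
  list(similarity = total / n, n_steps = n)
}

#' Attribution-reward similarity of an episode trace
#'
#' End-to-end wrapper: attributes all actions at every step (zero
#' baseline), computes counterfactual reward vectors, and evaluates
#' [similarity_index()].
#'
#' @param trace an `episode_trace`.
#' @param case its [phantom_case()].
#' @param params the agent that produced the trace.
#' @param mode reward mode (1 = score difference, 2 = violation
#'   difference).
#' @param path_steps IG quadrature nodes.
#' @param criteria scoring criteria.
#' @param control optimizer control.
#' @return list with `similarity`, `n_steps`, `mode`.
#' @export
trace_similarity <- function(trace, case, params, mode = 2, path_steps = 64L,
                             criteria = default_criteria(), control = list()) {
  n <- length(trace$steps)
  if (n == 0L) stop("trace has no tuning steps")
  probs <- t(vapply(trace$steps, `[[`, numeric(18L), "probs"))
  A <- vector("list", n)
  R <- vector("list", n)
  for (i in seq_len(n)) {
    st <- trace$steps[[i]]
    recs <- attribute_all_actions(params, st$dvh_input, st$memory_in,
                                  baseline_spec(0), path_steps)
    A[[i]] <- t(vapply(recs, organ_attribution, numeric(3)))
    R[[i]] <- reward_vectors(trace, i, case, criteria, mode = mode,
                             control = control)
  }
  res <- similarity_index(probs, A, R)
  res$mode <- mode
  res
}

#' Normalized policy entropy of a plan
#'
#' Computes
#' \deqn{\mathrm{Entropy} = -\frac{1}{N} \sum_{i=1}^{N} \sum_{j=1}^{18}
#'   p_{ij} \ln p_{ij},}
#' with `0 ln 0 = 0`. The value lies in \[0, ln 18\]; lower entropy means
#' more concentrated (decisive) policies.
#'
#' @param probs `N x 18` matrix of per-step policy probabilities (or an
#'   `episode_trace`, from which the rows are pulled).
#' @param tol row-sum consistency tolerance.
#' @return list with `entropy`, `n_steps`.
#' @export
policy_entropy <- function(probs, tol = 1e-6) {
  if (inherits(probs, "episode_trace")) {
    probs <- t(vapply(probs$steps, `[[`, numeric(18L), "probs"))
  }
  probs <- rbind(probs)
  if (nrow(probs) == 0L) stop("no probability rows")
  if (any(abs(rowSums(probs) - 1) > tol)) {
    stop("probability row does not sum to 1")
  }
  terms <- ifelse(probs > 0, probs * log(probs), 0)
  list(entropy = -sum(terms) / nrow(probs), n_steps = nrow(probs))
}

#' Ideal number of planning steps between two TPP configurations
#'
#' The minimal count of monotonic one-directional fixed-step adjustments
#' transforming the initial TPP vector into the final one: the sum over
#' parameters of `round(|final - initial| / delta)`. Errors if a final
#' value is off the step lattice beyond `tol` (in step units).
#'
#' @param initial,final [tpp_vector()]s (or plain numeric vectors on the
#'   default grid).
#' @param grid the TPP grid.
#' @param tol lattice tolerance in units of the per-parameter step.
#' @return integer step count.
#' @export
ideal_steps <- function(initial, final, grid = tpp_grid(), tol = 1e-6) {
  ini <- as.numeric(initial); fin <- as.numeric(final)
  stopifnot(length(ini) == nrow(grid), length(fin) == nrow(grid))
  r <- abs(fin - ini) / grid$delta
  k <- round(r)
  if (any(abs(r - k) > tol)) {
    stop("final TPP value off the step lattice")
  }
  as.integer(sum(k))
}

#' Probe the LSTM memory with synthetic violation scenarios
#'
#' Builds eight scenario DVH inputs in which each organ's 100-value block
#' is either all ones ("violation") or all zeros ("conserved"): none, PTV,
#' BLA, REC, PTV+BLA, PTV+REC, BLA+REC, all. For each scenario the memory
#' is reset and the same input is processed `repeats` times so the memory
#' evolves; the c and h vectors after every application are collected
#' (8 x 10 = 80 of each by default) and L2-normalized. Suitable embedding
#' defaults for downstream visualization (perplexity 8, cosine metric, PCA
#' initialization, learning rate 50) are recorded as metadata.
#'
#' @param params agent parameters.
#' @param repeats applications per scenario (default 10).
#' @return list with matrices `c`, `h` (rows = probe states), character
#'   `labels` (scenario per row), `scenarios`, and `embedding_defaults`.
#' @export
memory_probe <- function(params, repeats = 10L) {
  cfg <- attr(params, "config")
  block <- cfg$input %/% 3L
  combos <- expand.grid(PTV = c(FALSE, TRUE), BLA = c(FALSE, TRUE),
                        REC = c(FALSE, TRUE))
  combos <- combos[order(combos$PTV + combos$BLA + combos$REC,
                         -combos$PTV, -combos$BLA), ]
  label_of <- function(row) {
    on <- c("PTV", "BLA", "REC")[unlist(row)]
    if (length(on) == 0) "none" else if (length(on) == 3) "all"
    else paste(on, collapse = "+")
  }
  labels_scn <- apply(combos, 1, function(r) label_of(as.list(as.logical(r))))
  cs <- hs <- NULL
  labels <- character(0)
  for (s in seq_len(nrow(combos))) {
    x <- numeric(cfg$input)
    if (combos$PTV[s]) x[1:block] <- 1
    if (combos$BLA[s]) x[(block + 1):(2 * block)] <- 1
    if (combos$REC[s]) x[(2 * block + 1):(3 * block)] <- 1
    mem <- zero_memory(cfg)
    for (r in seq_len(repeats)) {
      mem <- agent_forward(params, x, mem)$memory
      cs <- rbind(cs, mem$c)
      hs <- rbind(hs, mem$h)
      labels <- c(labels, labels_scn[s])
    }
  }
  l2norm <- function(m) {
    n <- sqrt(rowSums(m^2))
    n[n == 0] <- 1
    m / n
  }
  list(
    c = l2norm(cs), h = l2norm(hs), labels = labels,
    scenarios = labels_scn, repeats = as.integer(repeats),
    embedding_defaults = list(perplexity = 8, metric = "cosine",
                              init = "pca", learning_rate = 50)
  )
}

#' Within- versus between-scenario cosine distances of probe vectors
#'
#' @param vectors matrix of probe states (rows) from [memory_probe()].
#' @param labels scenario label per row.
#' @return list with `within`, `between` (mean cosine distances) and
#'   `separation` (between minus within; positive = clustered).
#' @export
probe_separation <- function(vectors, labels) {
  n <- nrow(vectors)
  sims <- tcrossprod(vectors)  # rows are unit-normalized
  d <- 1 - sims
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  within <- mean(d[same & upper.tri(d)], na.rm = TRUE)
  between <- mean(d[!same & upper.tri(d)], na.rm = TRUE)
  list(within = within, between = between, separation = between - within)
}

#' Cohort-level analysis report
#'
#' Summarizes a set of episode traces per checkpoint: initial/final score
#' mean and sd, count of full-score plans, actual steps (over full-score
#' plans), ideal steps, entropy, optional per-plan similarity values, the
#' final-TPP-space table over full-score plans, and the across-checkpoint
#' Pearson and Spearman correlations between mean similarity and mean
#' steps.
#'
#' @param traces_by_ckpt named list: one list of `episode_trace`s per
#'   checkpoint.
#' @param similarities optional named list of per-plan similarity values
#'   (same shape), e.g. from [trace_similarity()] mode 2.
#' @param max_total the full score (default 9).
#' @param grid the TPP grid.
#' @return object of class `analysis_report`: list with `plans` (one row
#'   per plan), `summary` (one row per checkpoint), `tpp_space` (final-TPP
#'   multiplicities over full-score plans) and `correlation`
#'   (`pearson`, `spearman` between checkpoint mean similarity and mean
#'   steps; NA when similarities are absent or fewer than 3 checkpoints).
#' @export
cohort_report <- function(traces_by_ckpt, similarities = NULL, max_total = 9,
                          grid = tpp_grid()) {
  if (length(traces_by_ckpt) == 0L) stop("empty cohort")
  if (is.null(names(traces_by_ckpt))) {
    names(traces_by_ckpt) <- sprintf("ckpt%02d", seq_along(traces_by_ckpt))
  }
  plan_rows <- list()
  tpp_rows <- list()
  for (ck in names(traces_by_ckpt)) {
    trs <- traces_by_ckpt[[ck]]
    if (length(trs) == 0L) stop("empty cohort for checkpoint ", ck)
    for (k in seq_along(trs)) {
      tr <- trs[[k]]
      n_steps <- length(tr$steps)
      full <- tr$final_score >= max_total
      ent <- if (n_steps > 0) policy_entropy(tr)$entropy else NA_real_
      final_tpps <- if (n_steps > 0) tr$steps[[n_steps]]$tpps_after
                    else tr$initial_tpps
      ideal <- ideal_steps(tr$initial_tpps, final_tpps, grid)
      sim <- if (!is.null(similarities)) similarities[[ck]][[k]] else NA_real_
      plan_rows[[length(plan_rows) + 1L]] <- data.frame(
        checkpoint = ck, case_id = tr$case_id, plan = k,
        initial_score = tr$initial_score$total,
        final_score = tr$final_score, full_score = full,
        steps = n_steps, ideal_steps = ideal, entropy = ent,
        similarity = sim, stringsAsFactors = FALSE
      )
      if (full) {
        tpp_rows[[length(tpp_rows) + 1L]] <- data.frame(
          checkpoint = ck, param = grid$name, value = final_tpps,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  plans <- do.call(rbind, plan_rows)
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  summ <- do.call(rbind, lapply(names(traces_by_ckpt), function(ck) {
    d <- plans[plans$checkpoint == ck, ]
    df <- d[d$full_score, ]
    data.frame(
      checkpoint = ck, n_plans = nrow(d),
      initial_mean = mean(d$initial_score), initial_sd = stats::sd(d$initial_score),
      final_mean = mean(d$final_score), final_sd = stats::sd(d$final_score),
      n_full = sum(d$full_score),
      steps_mean = if (nrow(df)) mean(df$steps) else NA_real_,
      steps_sd = if (nrow(df) > 1) stats::sd(df$steps) else NA_real_,
      ideal_mean = if (nrow(df)) mean(df$ideal_steps) else NA_real_,
      ideal_sd = if (nrow(df) > 1) stats::sd(df$ideal_steps) else NA_real_,
      entropy_mean = mean(d$entropy, na.rm = TRUE),
      similarity_mean = if (all(is.na(d$similarity))) NA_real_
                        else mean(d$similarity, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  tpp_space <- if (length(tpp_rows)) {
    tp <- do.call(rbind, tpp_rows)
    agg <- stats::aggregate(list(count = tp$value),
                            by = list(checkpoint = tp$checkpoint,
                                      param = tp$param, value = tp$value),
                            FUN = length)
    agg[order(agg$checkpoint, match(agg$param, grid$name), agg$value), ]
  } else NULL
  correlation <- list(pearson = NA_real_, spearman = NA_real_)
  ok <- !is.na(summ$similarity_mean) & !is.na(summ$steps_mean)
  if (sum(ok) >= 2) {
    correlation$pearson <- stats::cor(summ$similarity_mean[ok],
                                      summ$steps_mean[ok])
    correlation$spearman <- stats::cor(summ$similarity_mean[ok],
                                       summ$steps_mean[ok],
                                       method = "spearman")
  }
  structure(
    list(plans = plans, summary = summ, tpp_space = tpp_space,
         correlation = correlation),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$summary, digits = 3)
  if (!is.na(x$correlation$pearson)) {
    cat(sprintf("similarity vs steps: Pearson %.3f, Spearman %.3f\n",
                x$correlation$pearson, x$correlation$spearman))
  }
  invisible(x)
}

#' Mixed-model comparison of planning steps between checkpoints
#'
#' Optional statistical hook: fits `steps ~ checkpoint + (1 | case_id)`
#' with lme4/lmerTest (off-the-shelf routines) on the full-score plans of
#' an [cohort_report()] and returns the fixed-effect table. Requires the
#' suggested packages; errors informatively otherwise.
#'
#' @param report an `analysis_report`.
#' @return coefficient table from the fitted mixed model.
#' @export
step_comparison_test <- function(report) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    stop("step_comparison_test needs the suggested package 'lmerTest'")
  }
  d <- report$plans[report$plans$full_score, ]
  if (length(unique(d$checkpoint)) < 2L) stop("need at least two checkpoints")
  fit <- lmerTest::lmer(steps ~ checkpoint + (1 | case_id), data = d)
  summary(fit)$coefficients
}
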