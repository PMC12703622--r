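#' @title Episode runner: agent-driven TPP tuning on a phantom case
#' @name episode
NULL

#' Run one TPP-tuning planning episode
#'
#' Implements the plan-observe-tune loop: optimize the fluence map for the
#' current TPPs (warm-started from the previous plan), extract the DVH
#' observation, query the network, pick an action (sampled from the policy
#' in `stochastic` mode with a dedicated per-episode random stream, argmax
#' in `greedy` mode with ties broken by lowest index), apply it, repeat.
#' The episode terminates when the plan reaches the maximum score or after
#' `max_steps` tuning steps.
#'
#' @param case a [phantom_case()].
#' @param params agent parameters ([agent_init()] or a trained checkpoint),
#'   or NULL when `policy_fn` is given.
#' @param initial_tpps starting [tpp_vector()] (default: grid initial
#'   values).
#' @param max_steps maximum number of tuning steps (default 30).
#' @param mode `"stochastic"` or `"greedy"`.
#' @param seed integer seed for the per-episode action-sampling stream
#'   (ignored in greedy mode).
#' @param criteria scoring criteria table.
#' @param policy_fn optional scripted policy: `function(dvh_input, step)`
#'   returning an action index (used for environment diagnostics; bypasses
#'   the network, probabilities are recorded as one-hot).
#' @param control optimizer control passed to [optimize_fluence()].
#' @return object of class `episode_trace`: list with `case_id`, `seed`,
#'   `mode`, `initial_tpps`, `initial_score` (a `score_card`), `steps`
#'   (list; each step holds `dvh_input`, `memory_in`, `probs`, `q_values`,
#'   `action`, `tpps_after`, `score_after`, `organ_violations_after`,
#'   `fluence_pre`, `fluence_post`) and `termination`
#'   (`"max_score"`/`"max_steps"`).
#' @export
run_episode <- function(case, params, initial_tpps = tpp_vector(),
                        max_steps = 30L, mode = c("stochastic", "greedy"),
                        seed = 0L, criteria = default_criteria(),
                        policy_fn = NULL, control = list()) {
  mode <- match.arg(mode)
  cfg <- if (!is.null(params)) attr(params, "config") else net_config()
  max_total <- sum(criteria$points)
  tpps <- initial_tpps
  plan <- optimize_fluence(case, tpps, control = control)
  ev <- evaluate_plan(plan, case, criteria)
  initial_score <- ev$score
  memory <- zero_memory(cfg)
  steps <- list()
  termination <- "max_steps"
  rng_seed <- derive_seed(seed, "episode-actions")
  if (initial_score$total >= max_total) {
    termination <- "max_score"
    max_steps <- 0L
  }
  step_i <- 0L
  with_seed(rng_seed, {
    while (step_i < max_steps) {
      step_i <- step_i + 1L
      dvh_in <- ev$dvh_input
      mem_in <- memory
      if (is.null(policy_fn)) {
        fw <- agent_forward(params, dvh_in, memory)
        probs <- fw$probs
        q <- fw$q
        memory <- fw$memory
        action <- if (mode == "greedy") {
          which.max(probs)  # lowest index on exact ties
        } else {
          sample.int(length(probs), 1L, prob = probs)
        }
      } else {
        action <- policy_fn(dvh_in, step_i)
        probs <- numeric(2L * 9L); probs[action] <- 1
        q <- numeric(length(probs))
      }
      tpps <- apply_action(tpps, action)
      fluence_pre <- plan$fluence
      plan <- optimize_fluence(case, tpps, warm_start = plan,
                               control = control)
      ev <- evaluate_plan(plan, case, criteria)
      steps[[step_i]] <- list(
        dvh_input = dvh_in,
        memory_in = mem_in,
        probs = probs,
        q_values = q,
        action = action,
        tpps_after = as.numeric(tpps),
        score_after = ev$score$total,
        organ_scores_after = ev$score$organ_scores,
        organ_violations_after = ev$score$organ_violations,
        fluence_pre = fluence_pre,
        fluence_post = plan$fluence
      )
      if (ev$score$total >= max_total) {
        termination <- "max_score"
        break
      }
    }
  })
  structure(
    list(
      case_id = case$case_id,
      seed = as.integer(seed),
      mode = mode,
      initial_tpps = as.numeric(initial_tpps),
      initial_score = initial_score,
      final_score = if (length(steps)) steps[[length(steps)]]$score_after
                    else initial_score$total,
      steps = steps,
      termination = termination
    ),
    class = "episode_trace"
  )
}

#' @export
print.episode_trace <- function(x, ...) {
  cat(sprintf(
    "<episode_trace %s> %s, %d steps, score %.0f -> %.0f (%s)\n",
    x$case_id, x$mode, length(x$steps), x$initial_score$total,
    x$final_score, x$termination
  ))
  invisible(x)
}

#' TPP vector at the start of a given step
#'
#' @param trace an [run_episode()] trace.
#' @param step step index (1-based).
#' @return a [tpp_vector()] holding the parameters *before* the step's
#'   action was applied.
#' @export
tpps_before_step <- function(trace, step, grid = tpp_grid()) {
  stopifnot(step >= 1L, step <= length(trace$steps))
  v <- if (step == 1L) trace$initial_tpps else trace$steps[[step - 1L]]$tpps_after
  tpp_vector(stats::setNames(v, grid$name), grid)
}
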