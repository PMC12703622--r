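#' @title Small-scale actor-critic training with checkpointing
#' @description The full-scale agent this analysis suite targets was trained
#'   with actor-critic with experience replay (ACER) for hundreds of
#'   thousands of steps. For a desk-scale testbed that only needs a graded
#'   progression of checkpoint agents, this trainer uses plain on-policy
#'   advantage actor-critic with entropy regularization — a deliberate
#'   simplification (no trust region, no off-policy correction). Backprop is
#'   truncated to single steps: the LSTM memory entering a step is treated
#'   as a constant input, matching how the attribution engine later treats
#'   (c, h) as standalone inputs.
#' @name training
NULL

#' Default training hyperparameters
#'
#' @return named list: discount `gamma`, learning rate `lr`, entropy bonus
#'   `entropy_beta`, critic loss weight `critic_coef`, per-step penalty
#'   `step_penalty`, terminal bonus `terminal_bonus`, violation-reduction
#'   shaping weight `violation_coef`, episode cap `max_steps`, Adam moments
#'   `beta1`/`beta2`/`eps`.
#' @export
train_defaults <- function() {
  list(
    gamma = 0.90, lr = 3e-3, entropy_beta = 0.003, critic_coef = 0.5,
    step_penalty = 0.05, terminal_bonus = 1, violation_coef = 2,
    max_steps = 30L,
    beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
}

.adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

.adam_update <- function(params, grads, state, hp) {
  state$t <- state$t + 1L
  corr1 <- 1 - hp$beta1^state$t
  corr2 <- 1 - hp$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- hp$beta1 * state$m[[nm]] + (1 - hp$beta1) * g
    state$v[[nm]] <- hp$beta2 * state$v[[nm]] + (1 - hp$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      hp$lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + hp$eps)
  }
  list(params = params, state = state)
}

#' Train checkpoint agents on phantom cases
#'
#' Runs on-policy advantage actor-critic over TPP-tuning episodes with
#' episodic Monte-Carlo returns: the immediate reward for a step is the
#' change in total plan score plus `violation_coef` times the reduction in
#' total dose violation (the dense component of criterion-based scoring,
#' without which sparse score deltas reward degenerate ratchet strategies),
#' minus a per-step penalty (plus a terminal bonus at the maximum score);
#' at each episode end the discounted returns
#' `G_t` are computed, the policy head is updated with the advantage
#' `A_t = G_t - V_t` (`V_t = sum(pi_t * q_t)`, treated as a constant
#' baseline) plus an entropy bonus, and the Q head regresses `q[a_t]` onto
#' `G_t`. All steps of an episode form one batched gradient and one Adam
#' update. Parameters are snapshotted every `checkpoint_every` environment
#' steps.
#'
#' @param cases a [phantom_case()] or list of them; episodes cycle through
#'   the list.
#' @param steps total environment steps (each step = one TPP adjustment +
#'   re-optimization).
#' @param checkpoint_every snapshot interval in environment steps.
#' @param seed integer root seed for initialization, episode streams and
#'   case cycling.
#' @param config a [net_config()].
#' @param hp hyperparameters, see [train_defaults()].
#' @param criteria scoring criteria table.
#' @param control optimizer control for [optimize_fluence()].
#' @param verbose print a progress line per checkpoint.
#' @return object of class `checkpoint_set`: list with `checkpoints` (each:
#'   `params`, `step`, `episodes_seen`, `mean_recent_score`), `seed`,
#'   `config`, `hp`.
#' @export
train_checkpoints <- function(cases, steps, checkpoint_every, seed = 1L,
                              config = net_config(), hp = train_defaults(),
                              criteria = default_criteria(), control = list(),
                              verbose = FALSE) {
  if (inherits(cases, "phantom_case")) cases <- list(cases)
  stopifnot(length(cases) >= 1L, steps >= checkpoint_every)
  params <- agent_init(config, seed = derive_seed(seed, "train-init"))
  adam <- .adam_state(params)
  max_total <- sum(criteria$points)

  # initial plan/score per case is fixed by the initial TPPs: cache it
  init_tpps <- tpp_vector()
  init_cache <- lapply(cases, function(cs) {
    plan <- optimize_fluence(cs, init_tpps, control = control)
    ev <- evaluate_plan(plan, cs, criteria)
    list(plan = plan, ev = ev)
  })

  if (all(vapply(init_cache, function(ic) ic$ev$score$total, numeric(1)) >=
            max_total)) {
    stop("all training cases already score the maximum at the initial TPPs")
  }

  checkpoints <- list()
  recent_scores <- numeric(0)
  episodes_seen <- 0L
  env_step <- 0L
  with_seed(derive_seed(seed, "train-actions"), {
    while (env_step < steps) {
      episodes_seen <- episodes_seen + 1L
      ci <- ((episodes_seen - 1L) %% length(cases)) + 1L
      case <- cases[[ci]]
      tpps <- init_tpps
      plan <- init_cache[[ci]]$plan
      ev <- init_cache[[ci]]$ev
      memory <- zero_memory(config)
      prev_total <- ev$score$total
      prev_viol <- ev$score$organ_violations
      done <- prev_total >= max_total
      ep_len <- 0L
      ep <- list(caches = list(), probs = list(), q = list(),
                 actions = integer(0), rewards = numeric(0))
      while (!done && ep_len < hp$max_steps && env_step < steps) {
        ep_len <- ep_len + 1L
        env_step <- env_step + 1L
        fw <- agent_forward(params, ev$dvh_input, memory, keep_cache = TRUE)
        probs <- fw$probs
        action <- sample.int(length(probs), 1L, prob = probs)
        tpps <- apply_action(tpps, action)
        plan <- optimize_fluence(case, tpps, warm_start = plan,
                                 control = control)
        ev_next <- evaluate_plan(plan, case, criteria)
        total <- ev_next$score$total
        dviol <- sum(prev_viol) - sum(ev_next$score$organ_violations)
        reward <- (total - prev_total) + hp$violation_coef * dviol -
          hp$step_penalty
        done <- total >= max_total
        if (done) reward <- reward + hp$terminal_bonus
        ep$caches[[ep_len]] <- fw$cache
        ep$probs[[ep_len]] <- probs
        ep$q[[ep_len]] <- fw$q
        ep$actions[ep_len] <- action
        ep$rewards[ep_len] <- reward
        memory <- fw$memory
        ev <- ev_next
        prev_total <- total
        prev_viol <- ev_next$score$organ_violations
        if (env_step %% checkpoint_every == 0L) {
          ck <- structure(params, config = config, class = "agent_params")
          checkpoints[[length(checkpoints) + 1L]] <- list(
            params = ck, step = env_step, episodes_seen = episodes_seen,
            mean_recent_score = if (length(recent_scores))
              mean(utils::tail(recent_scores, 20)) else NA_real_
          )
          if (verbose) {
            message(sprintf("checkpoint %d at step %d (%d episodes)",
                            length(checkpoints), env_step, episodes_seen))
          }
        }
      }
      if (ep_len > 0L) {
        # discounted Monte-Carlo returns (episode is complete or truncated;
        # truncation treats the remaining return as zero)
        G <- numeric(ep_len)
        acc <- 0
        for (t in rev(seq_len(ep_len))) {
          acc <- ep$rewards[t] + hp$gamma * acc
          G[t] <- acc
        }
        P <- do.call(cbind, ep$probs)
        Q <- do.call(cbind, ep$q)
        V <- colSums(P * Q)
        adv <- G - V
        # policy gradient: d(-log pi_a * adv)/dlogits = adv * (pi - e_a)
        dlogits <- sweep(P, 2, adv, "*")
        dlogits[cbind(ep$actions, seq_len(ep_len))] <-
          dlogits[cbind(ep$actions, seq_len(ep_len))] - adv
        # entropy bonus: loss -beta*H, d(-H)/dl_k = p_k (log p_k + H)
        logP <- log(pmax(P, 1e-12))
        ent <- -colSums(P * logP)
        dlogits <- dlogits + hp$entropy_beta * P * sweep(logP, 2, ent, "+")
        # critic: 0.5 * coef * (q_a - G)^2
        dq <- matrix(0, nrow(Q), ep_len)
        dq[cbind(ep$actions, seq_len(ep_len))] <-
          hp$critic_coef * (Q[cbind(ep$actions, seq_len(ep_len))] - G)
        # one batched backward over the episode: concatenate step caches
        cache <- ep$caches[[1]]
        if (ep_len > 1L) {
          for (nm in setdiff(names(cache), "K")) {
            cache[[nm]] <- do.call(cbind, lapply(ep$caches, `[[`, nm))
          }
        }
        cache$K <- ep_len
        bw <- agent_backward(params, cache, dlogits = dlogits, dq = dq)
        grads <- lapply(bw$grads, function(g2) g2 / ep_len)
        upd <- .adam_update(params, grads, adam, hp)
        params <- upd$params
        adam <- upd$state
        if (!all(vapply(params, function(p2) all(is.finite(p2)), logical(1)))) {
          stop("training diverged: non-finite parameters")
        }
      }
      recent_scores <- c(recent_scores, prev_total)
    }
  })
  structure(
    list(checkpoints = checkpoints, seed = as.integer(seed), config = config,
         hp = hp),
    class = "checkpoint_set"
  )
}

#' @export
print.checkpoint_set <- function(x, ...) {
  cat(sprintf("<checkpoint_set> %d checkpoints (seed %d) at steps: %s\n",
              length(x$checkpoints), x$seed,
              paste(vapply(x$checkpoints, `[[`, numeric(1), "step"),
                    collapse = ", ")))
  invisible(x)
}

#' Save / load checkpoint parameters as a flat text archive
#'
#' One directory per checkpoint set: a JSON manifest (shapes, steps, seed)
#' plus one whitespace-separated text matrix file per parameter tensor per
#' checkpoint. Plain text keeps archives diff-able and portable.
#'
#' @param ckpts a `checkpoint_set`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoints <- function(ckpts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = ckpts$seed,
    config = ckpts$config,
    steps = vapply(ckpts$checkpoints, `[[`, numeric(1), "step"),
    n_checkpoints = length(ckpts$checkpoints),
    param_names = names(ckpts$checkpoints[[1]]$params)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(ckpts$checkpoints)) {
    pk <- ckpts$checkpoints[[k]]$params
    for (nm in names(pk)) {
      f <- file.path(dir, sprintf("ckpt%02d_%s.txt", k, nm))
      utils::write.table(as.matrix(pk[[nm]]), f, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname save_checkpoints
#' @param dir directory written by [save_checkpoints()].
#' @export
load_checkpoints <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(net_config, manifest$config)
  cks <- lapply(seq_len(manifest$n_checkpoints), function(k) {
    p <- lapply(stats::setNames(nm = manifest$param_names), function(nm) {
      m <- as.matrix(utils::read.table(
        file.path(dir, sprintf("ckpt%02d_%s.txt", k, nm))
      ))
      dimnames(m) <- NULL
      if (ncol(m) == 1L && nm %in% c("bd", "bf", "bi", "bg", "bo", "bp", "bq")) {
        as.numeric(m)
      } else m
    })
    list(params = structure(p, config = cfg, class = "agent_params"),
         step = manifest$steps[k])
  })
  structure(list(checkpoints = cks, seed = manifest$seed, config = cfg,
                 hp = train_defaults()),
            class = "checkpoint_set")
}
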