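#' @title Configuration, archives and the cohort driver
#' @description Traces and attributions are stored as JSON-lines (one
#'   object per line: streamable and diff-able); tabular reports as CSV;
#'   configuration as a single YAML file. A run is reproducible from the
#'   config plus its root seed alone: no archive payload contains
#'   timestamps or machine state.
#' @name cli_io
NULL

#' Default run configuration
#'
#' Nested list covering every tunable of the pipeline, namespaced per
#' module: `phantom.*` (grid size, overlap, prescription dose),
#' `scoring.criteria`, `tpp` grid, `network` sizes, `training`
#' hyperparameters, `attribution` (baseline offset, path steps, residual
#' tolerance) and `analysis` (reward mode, sensitivity offsets), plus the
#' root `seed`.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phantom = list(size = "small", overlap_level = 0.25,
                   prescription_dose = 78),
    scoring = list(criteria = default_criteria()),
    tpp = tpp_grid(),
    network = net_config(),
    training = train_defaults(),
    attribution = list(offset = 0, path_steps = 64L, tolerance = 1e-3),
    analysis = list(reward_mode = 2, offsets = c(0.005, 0.01))
  )
}

#' Read / write a run configuration
#'
#' @param config a configuration list.
#' @param path YAML file path.
#' @return `read_config` returns the configuration list (data.frame blocks
#'   restored); `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$scoring$criteria <- as.list(cfg$scoring$criteria)
  cfg$tpp <- as.list(cfg$tpp)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$scoring$criteria <- as.data.frame(cfg$scoring$criteria,
                                        stringsAsFactors = FALSE)
  cfg$tpp <- as.data.frame(cfg$tpp, stringsAsFactors = FALSE)
  cfg
}

.jsonl_line <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write an episode trace as JSON-lines
#'
#' Line 1 is a header object (case id, seed, mode, initial TPPs and score,
#' termination reason); each following line is one tuning step with its
#' DVH input, incoming memory, policy row, Q-values, action, post-action
#' TPPs, score, violations and fluence vectors.
#'
#' @param trace an `episode_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  header <- list(
    record = "trace_header",
    case_id = trace$case_id, seed = trace$seed, mode = trace$mode,
    initial_tpps = trace$initial_tpps,
    initial_score = trace$initial_score$total,
    initial_organ_scores = as.list(trace$initial_score$organ_scores),
    initial_organ_violations = as.list(trace$initial_score$organ_violations),
    final_score = trace$final_score,
    termination = trace$termination,
    n_steps = length(trace$steps)
  )
  lines <- c(.jsonl_line(header), vapply(trace$steps, function(st) {
    .jsonl_line(list(
      record = "step",
      dvh_input = st$dvh_input,
      memory_c = st$memory_in$c, memory_h = st$memory_in$h,
      probs = st$probs, q_values = st$q_values,
      action = st$action, tpps_after = st$tpps_after,
      score_after = st$score_after,
      organ_scores_after = as.list(st$organ_scores_after),
      organ_violations_after = as.list(st$organ_violations_after),
      fluence_pre = st$fluence_pre, fluence_post = st$fluence_post
    ))
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an episode trace written by [write_trace()]
#'
#' @param path JSON-lines trace file.
#' @return an `episode_trace` (score cards reduced to the serialized
#'   totals/organ summaries).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  steps <- lapply(lines[-1], function(ln) {
    s <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    list(
      dvh_input = s$dvh_input,
      memory_in = list(c = s$memory_c, h = s$memory_h),
      probs = s$probs, q_values = s$q_values,
      action = s$action, tpps_after = s$tpps_after,
      score_after = s$score_after,
      organ_scores_after = unlist(s$organ_scores_after),
      organ_violations_after = unlist(s$organ_violations_after),
      fluence_pre = s$fluence_pre, fluence_post = s$fluence_post
    )
  })
  structure(
    list(
      case_id = header$case_id, seed = header$seed, mode = header$mode,
      initial_tpps = header$initial_tpps,
      initial_score = list(
        total = header$initial_score,
        organ_scores = unlist(header$initial_organ_scores),
        organ_violations = unlist(header$initial_organ_violations)
      ),
      final_score = header$final_score,
      steps = steps,
      termination = header$termination
    ),
    class = "episode_trace"
  )
}

#' Write attribution records for a trace as JSON-lines
#'
#' One line per (step, action): the three attribution arrays, the
#' baseline offset, outputs and completeness residual.
#'
#' @param records_by_step list over steps of 18-record lists
#'   ([attribute_all_actions()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(records_by_step, path) {
  lines <- unlist(lapply(seq_along(records_by_step), function(i) {
    vapply(records_by_step[[i]], function(r) {
      .jsonl_line(list(
        record = "attribution", step = i, action = r$action,
        offset = r$offset, path_steps = r$path_steps,
        ig_dvh = r$ig_dvh, ig_c = r$ig_c, ig_h = r$ig_h,
        baseline_output = r$baseline_output,
        actual_output = r$actual_output,
        completeness_residual = r$completeness_residual
      ))
    }, character(1))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an attribution archive written by [write_attributions()]
#'
#' @param path JSON-lines attribution file.
#' @return list over steps of lists of `attribution_record`s.
#' @export
read_attributions <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  steps <- sort(unique(vapply(recs, `[[`, numeric(1), "step")))
  lapply(steps, function(i) {
    lapply(Filter(function(r) r$step == i, recs), function(r) {
      structure(
        list(action = as.integer(r$action), ig_dvh = r$ig_dvh,
             ig_c = r$ig_c, ig_h = r$ig_h,
             baseline_output = r$baseline_output,
             actual_output = r$actual_output,
             completeness_residual = r$completeness_residual,
             path_steps = as.integer(r$path_steps), offset = r$offset),
        class = "attribution_record"
      )
    })
  })
}

#' Validate a trace or attribution archive
#'
#' Re-checks the declared invariants on every line: probability rows sum
#' to 1 (tolerance 1e-6) with entries in \[0,1\], input/memory lengths
#' match the network configuration, scores lie in \[0, max\], TPPs lie
#' within bounds and on the step lattice, and attribution residuals stay
#' below the configured tolerance.
#'
#' @param path archive file.
#' @param config run configuration (for sizes, bounds, tolerance).
#' @return data.frame of violations (zero rows when the archive is clean)
#'   with columns `line`, `field`, `problem`.
#' @export
validate_archive <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("archive not found: ", path)
  lines <- readLines(path)
  grid <- if (is.data.frame(config$tpp)) config$tpp else as.data.frame(config$tpp)
  max_total <- sum(config$scoring$criteria$points)
  probs_n <- config$network$actions
  bad <- list()
  note <- function(line, field, problem) {
    bad[[length(bad) + 1L]] <<- data.frame(line = line, field = field,
                                           problem = problem,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj)) { note(i, "json", "unparseable line"); next }
    kind <- obj$record
    if (identical(kind, "step")) {
      p <- obj$probs
      if (length(p) != probs_n) note(i, "probs", "wrong length")
      if (abs(sum(p) - 1) > 1e-6) note(i, "probs", "row does not sum to 1")
      if (any(p < 0 | p > 1)) note(i, "probs", "entry outside [0,1]")
      if (length(obj$dvh_input) != config$network$input) {
        note(i, "dvh_input", "wrong length")
      }
      if (obj$score_after < 0 || obj$score_after > max_total) {
        note(i, "score_after", "outside [0, max]")
      }
      tp <- obj$tpps_after
      if (any(tp < grid$lo - 1e-9) || any(tp > grid$hi + 1e-9)) {
        note(i, "tpps_after", "outside bounds")
      } else {
        k <- abs(tp - grid$init) / grid$delta
        if (any(abs(k - round(k)) > 1e-6)) {
          note(i, "tpps_after", "off the step lattice")
        }
      }
    } else if (identical(kind, "attribution")) {
      if (length(obj$ig_dvh) != config$network$input) {
        note(i, "ig_dvh", "wrong length")
      }
      if (obj$completeness_residual > config$attribution$tolerance) {
        note(i, "completeness_residual", "exceeds tolerance")
      }
    } else if (identical(kind, "trace_header")) {
      if (obj$final_score < 0 || obj$final_score > max_total) {
        note(i, "final_score", "outside [0, max]")
      }
    } else {
      note(i, "record", "unknown record type")
    }
  }
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(line = integer(0), field = character(0),
               problem = character(0), stringsAsFactors = FALSE)
  }
}

#' Plan a cohort of cases with checkpoint agents and archive everything
#'
#' Generates `n_cases` phantom cases from the root seed, runs `repeats`
#' stochastic planning episodes per case and checkpoint, attributes every
#' step of every episode against the configured baseline, and writes one
#' trace file and one attribution file per (checkpoint, case, repeat).
#' Rerunning with the same config and seed reproduces byte-identical
#' archives.
#'
#' @param config run configuration, see [default_config()].
#' @param checkpoints a `checkpoint_set` (or list of `agent_params`).
#' @param out_dir output directory (created).
#' @param n_cases number of phantom cases (the full study uses 39).
#' @param repeats stochastic plans per case (the full study uses 5).
#' @param max_steps episode cap.
#' @return data.frame manifest: one row per trace with checkpoint, case,
#'   repeat, file paths, final score and steps.
#' @export
simulate_cohort <- function(config, checkpoints, out_dir, n_cases = 39L,
                            repeats = 5L, max_steps = 30L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cks <- if (inherits(checkpoints, "checkpoint_set")) {
    lapply(checkpoints$checkpoints, `[[`, "params")
  } else checkpoints
  seed <- config$seed
  cases <- lapply(seq_len(n_cases), function(k) {
    generate_case(derive_seed(seed, "cohort-case", k),
                  overlap_level = config$phantom$overlap_level,
                  size = config$phantom$size,
                  prescription_dose = config$phantom$prescription_dose)
  })
  rows <- list()
  for (ci in seq_along(cks)) {
    for (k in seq_len(n_cases)) {
      for (r in seq_len(repeats)) {
        ep_seed <- derive_seed(seed, "cohort-episode",
                               ci * 1000003L %% 2147483647L + k * 1009L + r)
        tr <- run_episode(cases[[k]], cks[[ci]], max_steps = max_steps,
                          mode = "stochastic", seed = ep_seed,
                          criteria = config$scoring$criteria)
        stem <- sprintf("ckpt%02d_case%03d_rep%d", ci, k, r)
        trace_path <- file.path(out_dir, paste0(stem, ".trace.jsonl"))
        write_trace(tr, trace_path)
        attr_path <- NA_character_
        if (length(tr$steps) > 0) {
          recs <- lapply(tr$steps, function(st) {
            attribute_all_actions(
              cks[[ci]], st$dvh_input, st$memory_in,
              baseline_spec(config$attribution$offset),
              config$attribution$path_steps
            )
          })
          attr_path <- file.path(out_dir, paste0(stem, ".attr.jsonl"))
          write_attributions(recs, attr_path)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          checkpoint = ci, case = k, rep = r,
          trace = trace_path, attributions = attr_path,
          final_score = tr$final_score, steps = length(tr$steps),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
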