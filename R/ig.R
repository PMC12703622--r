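#' @title Integrated-gradients attribution engine
#' @description Attributes an action's post-softmax policy probability to
#'   the three network inputs — the 300-value DVH observation and the LSTM
#'   memory vectors c and h — via integrated gradients:
#'   \deqn{IG_i(x, x') = (x_i - x'_i) \int_0^1
#'     \frac{\partial F_j(x' + \alpha(x - x'))}{\partial x_i}\, d\alpha.}
#'   A single straight path scales all three inputs jointly from their
#'   baselines, so the completeness identity
#'   \eqn{\sum_i IG_i = F_j(x) - F_j(x')} holds for the concatenated input
#'   and is audited on every record. The path integral is approximated by
#'   trapezoid quadrature; the residual is logged so quadrature adequacy is
#'   observable rather than assumed.
#' @name ig_engine
NULL

#' Baseline specification for attribution
#'
#' The default baseline is all-zero DVH, c and h — the complete absence of
#' a planning signal. For sensitivity analysis the OAR part of the DVH
#' baseline (entries 101..300: bladder and rectum) can be offset by a small
#' constant while the PTV entries (1..100) are kept at zero, so the
#' baseline never violates a target-coverage criterion.
#'
#' @param offset scalar applied to the OAR DVH baseline entries.
#' @param n_dvh length of the DVH input (default 300).
#' @param n_mem LSTM width (default 32).
#' @return object of class `baseline_spec` with `dvh`, `c`, `h`, `offset`.
#' @export
baseline_spec <- function(offset = 0, n_dvh = 300L, n_mem = 32L) {
  dvh <- numeric(n_dvh)
  ptv_len <- n_dvh %/% 3L
  if (offset != 0) dvh[(ptv_len + 1L):n_dvh] <- offset
  structure(list(dvh = dvh, c = numeric(n_mem), h = numeric(n_mem),
                 offset = offset),
            class = "baseline_spec")
}

#' Path-integral attribution of a scalar function (generic quadrature core)
#'
#' Approximates \eqn{(x - x') \cdot \int_0^1 \nabla F(x' + \alpha(x - x'))
#' d\alpha} by trapezoid quadrature with `path_steps` nodes. `fn_grad`
#' must map a matrix whose columns are input points to
#' `list(value = <vector>, grad = <matrix>)`. The trapezoid rule is exact
#' for linear F at any `path_steps >= 2` (the integrand is constant).
#'
#' @param fn_grad batched value-and-gradient closure.
#' @param x input point (numeric vector).
#' @param baseline baseline point, same length.
#' @param path_steps number of quadrature nodes (>= 2).
#' @return list with `ig` (attribution vector), `value_x`, `value_baseline`,
#'   `completeness_residual`, `path_steps`.
#' @export
ig_attribute <- function(fn_grad, x, baseline, path_steps = 256L) {
  stopifnot(length(x) == length(baseline), path_steps >= 2L)
  alpha <- seq(0, 1, length.out = path_steps)
  w <- rep(1, path_steps); w[c(1, path_steps)] <- 0.5
  w <- w / (path_steps - 1)
  diff <- x - baseline
  Z <- baseline + outer(diff, alpha)   # columns are path points
  fg <- fn_grad(Z)
  if (any(!is.finite(fg$grad))) stop("non-finite gradient along the IG path")
  avg_grad <- as.numeric(fg$grad %*% w)
  ig <- diff * avg_grad
  v0 <- fg$value[1]
  v1 <- fg$value[path_steps]
  list(
    ig = ig,
    value_x = v1,
    value_baseline = v0,
    completeness_residual = abs(sum(ig) - (v1 - v0)),
    path_steps = as.integer(path_steps)
  )
}

#' Integrated gradients for one tuning action of the agent
#'
#' Attributes the post-softmax probability of action `action` at the given
#' (DVH, c, h) input to all 364 input coordinates, against `baseline`,
#' along the joint straight path.
#'
#' @param params agent parameters.
#' @param dvh 300-value DVH observation.
#' @param memory list with `c` and `h` memory vectors.
#' @param action integer action index.
#' @param baseline a [baseline_spec()].
#' @param path_steps trapezoid nodes (default 256).
#' @return object of class `attribution_record`: list with `action`,
#'   `ig_dvh` (300), `ig_c`, `ig_h` (32 each), `baseline_output`,
#'   `actual_output`, `completeness_residual`, `path_steps`, `offset`.
#' @export
integrated_gradients <- function(params, dvh, memory, action,
                                 baseline = baseline_spec(),
                                 path_steps = 256L) {
  cfg <- attr(params, "config")
  n_dvh <- cfg$input
  n_mem <- cfg$hidden
  stopifnot(length(dvh) == n_dvh, length(baseline$dvh) == n_dvh,
            length(memory$c) == n_mem, length(memory$h) == n_mem)
  x <- c(dvh, memory$c, memory$h)
  x0 <- c(baseline$dvh, baseline$c, baseline$h)
  fn_grad <- function(Z) {
    D <- Z[seq_len(n_dvh), , drop = FALSE]
    C <- Z[n_dvh + seq_len(n_mem), , drop = FALSE]
    H <- Z[n_dvh + n_mem + seq_len(n_mem), , drop = FALSE]
    pg <- policy_input_grad(params, D, list(c = C, h = H), action)
    list(value = pg$value, grad = rbind(pg$d_dvh, pg$d_c, pg$d_h))
  }
  res <- ig_attribute(fn_grad, x, x0, path_steps)
  structure(
    list(
      action = as.integer(action),
      ig_dvh = res$ig[seq_len(n_dvh)],
      ig_c = res$ig[n_dvh + seq_len(n_mem)],
      ig_h = res$ig[n_dvh + n_mem + seq_len(n_mem)],
      baseline_output = res$value_baseline,
      actual_output = res$value_x,
      completeness_residual = res$completeness_residual,
      path_steps = res$path_steps,
      offset = baseline$offset
    ),
    class = "attribution_record"
  )
}

#' Attribute all 18 actions at one planning step
#'
#' Runs the forward/backward path cache once per action but shares the
#' path points; convenience wrapper used by the archive writer and the
#' policy decomposition.
#'
#' @inheritParams integrated_gradients
#' @return list of 18 `attribution_record`s.
#' @export
attribute_all_actions <- function(params, dvh, memory,
                                  baseline = baseline_spec(),
                                  path_steps = 256L) {
  n_act <- attr(params, "config")$actions
  lapply(seq_len(n_act), function(j) {
    integrated_gradients(params, dvh, memory, j, baseline, path_steps)
  })
}

#' Audit the completeness identity of an attribution record
#'
#' @param record an `attribution_record`.
#' @param tol absolute tolerance.
#' @return TRUE iff
#'   `|sum(all IG) - (F_j(x) - F_j(x'))| <= tol`.
#' @export
completeness_check <- function(record, tol = 1e-4) {
  record$completeness_residual <= tol
}

#' Decompose the policy distribution into baseline / DVH / c / h parts
#'
#' By completeness, each action's probability splits as
#' `F_j(x) = F_j(x') + sum(ig_dvh) + sum(ig_c) + sum(ig_h)`; stacking the
#' four parts over all 18 actions shows where the policy mass comes from.
#'
#' @param records list of 18 `attribution_record`s against a common
#'   baseline.
#' @return matrix `18 x 4` with columns `baseline`, `dvh`, `c`, `h`; row
#'   sums equal the actual action probabilities up to the records'
#'   completeness residuals.
#' @export
decompose_policy <- function(records) {
  offs <- vapply(records, `[[`, numeric(1), "offset")
  if (length(unique(offs)) != 1L) {
    stop("records were computed against mixed baselines")
  }
  out <- t(vapply(records, function(r) {
    c(baseline = r$baseline_output, dvh = sum(r$ig_dvh),
      c = sum(r$ig_c), h = sum(r$ig_h))
  }, numeric(4)))
  rownames(out) <- vapply(records, `[[`, integer(1), "action")
  out
}

#' Leading action per input source
#'
#' For each input type the leading action is the one receiving the highest
#' total attribution from that input; exact ties resolve to the lowest
#' action index.
#'
#' @param records list of 18 `attribution_record`s for one planning step.
#' @return named integer vector with elements `dvh`, `c`, `h`.
#' @export
leading_action <- function(records) {
  totals <- vapply(records, function(r) {
    c(dvh = sum(r$ig_dvh), c = sum(r$ig_c), h = sum(r$ig_h))
  }, numeric(3))
  acts <- vapply(records, `[[`, integer(1), "action")
  out <- apply(totals, 1, function(v) acts[which.max(v)])
  stats::setNames(as.integer(out), c("dvh", "c", "h"))
}

#' Group a DVH attribution heatmap into 30 organ-labelled segments
#'
#' The 300 DVH attribution values are summed in 30 consecutive blocks of
#' 10; segments 1-10 cover the PTV curve, 11-20 the bladder, 21-30 the
#' rectum. Segment sums conserve the total DVH attribution exactly.
#'
#' @param ig_dvh numeric vector of 300 DVH attributions.
#' @return data.frame with `segment` (1..30), `organ`, `value`.
#' @export
heatmap_segments <- function(ig_dvh) {
  stopifnot(length(ig_dvh) == 300L)
  seg <- rep(seq_len(30L), each = 10L)
  data.frame(
    segment = seq_len(30L),
    organ = rep(c("PTV", "BLA", "REC"), each = 10L),
    value = as.numeric(tapply(ig_dvh, seg, sum))
  )
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)  # zero-norm heatmap: similarity 0
  if (identical(a, b)) return(1)     # exact by construction, not up to ulp
  sum(a * b) / (na * nb)
}

#' Baseline-offset sensitivity of DVH attribution heatmaps
#'
#' For every planning step of the supplied traces, finds the leading action
#' under the zero baseline (by total DVH attribution), recomputes that
#' action's DVH heatmap under each offset baseline (OAR entries offset, PTV
#' entries kept zero), and reports the cosine similarity between the
#' 300-value offset and zero-baseline heatmaps, grouped by leading action.
#'
#' @param params agent parameters.
#' @param traces list of `episode_trace`s.
#' @param offsets numeric vector of baseline offsets (e.g. `c(0.005, 0.01)`).
#' @param path_steps trapezoid nodes per attribution.
#' @return data.frame with one row per (offset, action group):
#'   `offset`, `action`, `label`, `n`, `mean_similarity`, `sd_similarity`;
#'   attribute `per_step` holds the unaggregated values.
#' @export
baseline_sensitivity <- function(params, traces, offsets = c(0.005, 0.01),
                                 path_steps = 64L) {
  acts <- action_table()
  rows <- list()
  for (tr in traces) {
    for (st in tr$steps) {
      recs0 <- attribute_all_actions(params, st$dvh_input, st$memory_in,
                                     baseline_spec(0), path_steps)
      lead <- leading_action(recs0)[["dvh"]]
      h0 <- recs0[[lead]]$ig_dvh
      for (off in offsets) {
        rec <- integrated_gradients(params, st$dvh_input, st$memory_in,
                                    lead, baseline_spec(off), path_steps)
        rows[[length(rows) + 1L]] <- data.frame(
          offset = off, action = lead,
          similarity = .cosine(rec$ig_dvh, h0)
        )
      }
    }
  }
  per_step <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_step, list(per_step$offset,
                                                    per_step$action),
                                     drop = TRUE), function(d) {
    data.frame(offset = d$offset[1], action = d$action[1],
               label = acts$label[acts$action == d$action[1]],
               n = nrow(d), mean_similarity = mean(d$similarity),
               sd_similarity = stats::sd(d$similarity))
  }))
  rownames(agg) <- NULL
  attr(agg, "per_step") <- per_step
  agg
}
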