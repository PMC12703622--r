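#' @title DVH extraction and ProKnow-style plan scoring
#' @name plan_eval
NULL

#' The relative-dose grid for DVH sampling
#'
#' 100 points uniformly spaced on \[0, 1.2\] in units of the prescription
#' dose; the same grid is used for all three structures and for the
#' network's 300-value input.
#'
#' @param n number of points (default 100).
#' @param max_rel upper end of the relative-dose axis (default 1.2).
#' @return numeric vector of length `n`.
#' @export
dvh_grid <- function(n = 100L, max_rel = 1.2) seq(0, max_rel, length.out = n)

#' Compute a cumulative DVH curve
#'
#' @param dose numeric dose vector over all voxels, Gy.
#' @param mask integer voxel indices of the structure; must be non-empty.
#' @param d_p prescription dose, Gy.
#' @param grid relative-dose sample points, see [dvh_grid()].
#' @param structure optional structure label carried in the result.
#' @return object of class `dvh_curve`: list with `structure`,
#'   `rel_dose_grid` and `volume_fraction`, where `volume_fraction[k]` is the
#'   fraction of the structure's voxels receiving at least
#'   `grid[k] * d_p` Gy.
#' @export
compute_dvh <- function(dose, mask, d_p, grid = dvh_grid(), structure = NA_character_) {
  if (length(mask) == 0L) stop("empty structure mask")
  d <- dose[mask]
  thr <- grid * d_p
  # counts via the sorted-dose rank: |{d >= t}| = n - (# strictly below t)
  ds <- sort(d)
  vf <- (length(d) - findInterval(thr, ds, left.open = TRUE)) / length(d)
  structure(
    list(structure = structure, rel_dose_grid = grid, volume_fraction = vf),
    class = "dvh_curve"
  )
}

#' Assemble the 300-value DVH network input
#'
#' Concatenates the PTV, bladder and rectum volume-fraction curves (100
#' points each, in that order) into the vector the tuning agent observes.
#'
#' @param curves named list of three [compute_dvh()] curves with names
#'   `PTV`, `BLA`, `REC`.
#' @return numeric vector of length 300 with values in \[0, 1\].
#' @export
dvh_input_vector <- function(curves) {
  need <- c("PTV", "BLA", "REC")
  if (!all(need %in% names(curves))) stop("missing structure curve")
  unlist(lapply(curves[need], function(cv) cv$volume_fraction),
         use.names = FALSE)
}

#' Split a 300-value DVH input back into per-organ curves
#'
#' @param x numeric vector of length 300.
#' @return named list of three numeric 100-vectors (`PTV`, `BLA`, `REC`).
#' @export
split_dvh_input <- function(x) {
  stopifnot(length(x) == 300L)
  list(PTV = x[1:100], BLA = x[101:200], REC = x[201:300])
}

#' Default plan-scoring criteria table
#'
#' A ProKnow-style criterion list with a maximum total score of 9:
#' PTV coverage V(0.95 d_p) >= 95% (2 points) and hot-spot control
#' V(1.07 d_p) <= 10% (1 point); bladder V(0.6) <= 50%, V(0.8) <= 30%,
#' V(0.9) <= 15% (1 point each); rectum V(0.6) <= 45%, V(0.8) <= 25%,
#' V(0.9) <= 10% (1 point each). Dose levels are fractions of the
#' prescription dose; limits are volume fractions. Fully overridable — any
#' data.frame with the same columns works.
#'
#' @return data.frame with columns `structure`, `rel_dose`, `bound_type`
#'   (`"at_most"`/`"at_least"`), `volume_limit`, `points`.
#' @export
default_criteria <- function() {
  data.frame(
    structure = c("PTV", "PTV", "BLA", "BLA", "BLA", "REC", "REC", "REC"),
    rel_dose = c(0.95, 1.07, 0.60, 0.80, 0.90, 0.60, 0.80, 0.90),
    bound_type = c("at_least", rep("at_most", 7)),
    volume_limit = c(0.95, 0.10, 0.50, 0.30, 0.15, 0.45, 0.25, 0.10),
    points = c(2, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Score a plan against a criteria table
#'
#' Each criterion compares the DVH volume fraction at its relative-dose
#' level (linear interpolation on the DVH grid) against its limit. A
#' satisfied criterion awards its points and has violation 0; a failed
#' `at_most` criterion has violation `observed - limit`, a failed
#' `at_least` criterion `limit - observed` (dimensionless volume-fraction
#' excess).
#'
#' @param curves named list of [compute_dvh()] curves (`PTV`, `BLA`, `REC`).
#' @param criteria a criteria table, see [default_criteria()].
#' @return object of class `score_card`: list with `table` (per-criterion
#'   observed value, pass flag, awarded points, violation), `organ_scores`,
#'   `organ_violations` (named numeric over PTV/BLA/REC) and `total`.
#' @export
score_plan <- function(curves, criteria = default_criteria()) {
  stopifnot(all(c("structure", "rel_dose", "bound_type", "volume_limit",
                  "points") %in% names(criteria)))
  obs <- vapply(seq_len(nrow(criteria)), function(i) {
    cv <- curves[[criteria$structure[i]]]
    if (is.null(cv)) stop("criteria reference a missing structure")
    rng <- range(cv$rel_dose_grid)
    xd <- min(max(criteria$rel_dose[i], rng[1]), rng[2])
    stats::approx(cv$rel_dose_grid, cv$volume_fraction, xout = xd,
                  ties = "ordered")$y
  }, numeric(1))
  viol <- ifelse(
    criteria$bound_type == "at_most",
    pmax(0, obs - criteria$volume_limit),
    pmax(0, criteria$volume_limit - obs)
  )
  passed <- viol <= 0
  awarded <- ifelse(passed, criteria$points, 0)
  tab <- cbind(criteria,
               observed = obs, passed = passed,
               awarded = awarded, violation = viol)
  organs <- c("PTV", "BLA", "REC")
  organ_scores <- vapply(organs,
                         function(o) sum(awarded[criteria$structure == o]),
                         numeric(1))
  organ_viol <- vapply(organs,
                       function(o) sum(viol[criteria$structure == o]),
                       numeric(1))
  structure(
    list(table = tab, organ_scores = organ_scores,
         organ_violations = organ_viol, total = sum(awarded)),
    class = "score_card"
  )
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> total %.0f / %.0f\n",
              x$total, sum(x$table$points)))
  cat(sprintf("  organ scores: PTV %.0f  BLA %.0f  REC %.0f\n",
              x$organ_scores["PTV"], x$organ_scores["BLA"],
              x$organ_scores["REC"]))
  cat(sprintf("  organ violations: PTV %.3f  BLA %.3f  REC %.3f\n",
              x$organ_violations["PTV"], x$organ_violations["BLA"],
              x$organ_violations["REC"]))
  invisible(x)
}

#' Evaluate a plan state end-to-end (DVH curves, input vector, score)
#'
#' @param plan a `plan_state` from [optimize_fluence()].
#' @param case the corresponding [phantom_case()].
#' @param criteria criteria table, see [default_criteria()].
#' @param grid DVH relative-dose grid.
#' @return list with `curves`, `dvh_input` (300-vector) and `score`
#'   (a `score_card`).
#' @export
evaluate_plan <- function(plan, case, criteria = default_criteria(),
                          grid = dvh_grid()) {
  curves <- lapply(
    stats::setNames(nm = c("PTV", "BLA", "REC")),
    function(org) compute_dvh(plan$dose, case$structure_masks[[org]],
                              case$prescription_dose, grid, structure = org)
  )
  list(
    curves = curves,
    dvh_input = dvh_input_vector(curves),
    score = score_plan(curves, criteria)
  )
}
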