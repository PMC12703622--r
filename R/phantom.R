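#' @title Synthetic planning phantom
#' @description A 2-D stand-in for a clinical treatment planning system:
#'   each case is a voxel grid holding one planning target volume (PTV) and
#'   two organs at risk (bladder, rectum), plus a pencil-beam dose-deposition
#'   matrix. Only DVH-level behaviour needs to be realistic — the geometry is
#'   deliberately simple.
#' @name phantom
NULL

#' Construct a phantom case
#'
#' Low-level constructor with validation; most users call [generate_case()].
#'
#' @param case_id character identifier.
#' @param voxel_count positive integer number of voxels.
#' @param structure_masks named list with integer voxel index vectors for
#'   `PTV`, `BLA`, `REC`; must be pairwise disjoint (PTV has priority during
#'   generation).
#' @param dose_matrix non-negative matrix, `voxel_count` rows, one column per
#'   beamlet, in Gy per unit fluence.
#' @param prescription_dose prescription dose in Gy, > 0.
#' @param seed integer seed the case was generated from (metadata).
#' @param meta optional list of extra metadata (grid shape, achieved overlap).
#' @return an object of class `phantom_case`.
#' @export
phantom_case <- function(case_id, voxel_count, structure_masks, dose_matrix,
                         prescription_dose, seed = NA_integer_, meta = list()) {
  stopifnot(
    voxel_count > 0,
    is.matrix(dose_matrix), nrow(dose_matrix) == voxel_count,
    all(dose_matrix >= 0), prescription_dose > 0,
    all(c("PTV", "BLA", "REC") %in% names(structure_masks))
  )
  all_idx <- unlist(structure_masks, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    stop("structure masks overlap after PTV-priority resolution")
  }
  if (any(all_idx < 1 | all_idx > voxel_count)) stop("mask index out of range")
  ptv_rowsum <- rowSums(dose_matrix[structure_masks$PTV, , drop = FALSE])
  if (any(ptv_rowsum <= 0)) stop("PTV contains an unirradiable voxel")
  structure(
    list(
      case_id = case_id,
      voxel_count = as.integer(voxel_count),
      structure_masks = lapply(structure_masks, as.integer),
      dose_matrix = dose_matrix,
      prescription_dose = prescription_dose,
      seed = seed,
      meta = meta
    ),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(
    sprintf(
      "<phantom_case %s>: %d voxels, %d beamlets, d_p = %.1f Gy; PTV %d / BLA %d / REC %d voxels\n",
      x$case_id, x$voxel_count, ncol(x$dose_matrix), x$prescription_dose,
      length(x$structure_masks$PTV), length(x$structure_masks$BLA),
      length(x$structure_masks$REC)
    )
  )
  invisible(x)
}

# squared-grid helpers: voxel v <-> (row, col), column-major
.grid_coords <- function(n_side) {
  idx <- seq_len(n_side * n_side)
  cbind(row = ((idx - 1L) %% n_side) + 1L, col = ((idx - 1L) %/% n_side) + 1L)
}

#' Generate a synthetic planning case
#'
#' Builds a square 2-D voxel grid with a roughly circular PTV at the centre,
#' a bladder-like OAR above and a rectum-like OAR below, and a pencil-beam
#' dose-deposition matrix (three beam directions, Gaussian lateral profiles,
#' exponential depth attenuation). `overlap_level` sets the target fraction
#' of each OAR's voxels lying within one voxel (8-neighbourhood) of the PTV;
#' the OAR is assembled constructively from the PTV's adjacency ring plus a
#' compact distal blob, so the achieved fraction tracks the request closely
#' (it saturates when the ring is exhausted; the achieved value is stored in
#' `meta$achieved_overlap`).
#'
#' @param seed integer; cases are bit-identical for identical seeds.
#' @param overlap_level fraction in \[0, 1\] of OAR voxels adjacent to the
#'   PTV.
#' @param size `"small"` (20 x 20 grid = 400 voxels, 30 beamlets) or
#'   `"medium"` (30 x 30, 45 beamlets).
#' @param prescription_dose prescription dose in Gy.
#' @return a [phantom_case()].
#' @export
generate_case <- function(seed, overlap_level = 0.25, size = c("small", "medium"),
                          prescription_dose = 78) {
  size <- match.arg(size)
  if (!is.numeric(overlap_level) || length(overlap_level) != 1L ||
      is.na(overlap_level) || overlap_level < 0 || overlap_level > 1) {
    stop("overlap_level must be a single value in [0, 1]")
  }
  n_side <- if (size == "small") 20L else 30L
  beamlets_per_beam <- if (size == "small") 10L else 15L
  with_seed(derive_seed(seed, "case-geometry"), {
    coords <- .grid_coords(n_side)
    centre <- c(n_side / 2 + 0.5, n_side / 2 + 0.5) +
      stats::runif(2, -0.8, 0.8)
    r_ptv <- (n_side / 5) * stats::runif(1, 0.95, 1.05)
    d_centre <- sqrt((coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2)
    ptv <- which(d_centre <= r_ptv)

    # 8-neighbourhood adjacency ring around the PTV
    cheb <- matrix(Inf, n_side, n_side)
    for (v in ptv) {
      r <- coords[v, 1]; cc <- coords[v, 2]
      rr <- max(1, r - 1):min(n_side, r + 1)
      cs <- max(1, cc - 1):min(n_side, cc + 1)
      cheb[rr, cs] <- 0
    }
    ring <- setdiff(which(cheb == 0), ptv)

    make_oar <- function(side, n_target) {
      # side = -1: above the PTV (smaller row), +1: below
      sel <- if (side < 0) coords[, 1] < centre[1] else coords[, 1] > centre[1]
      ring_side <- ring[sel[ring]]
      n_adj <- min(round(overlap_level * n_target), length(ring_side))
      adj <- if (n_adj > 0) sample(ring_side, n_adj) else integer(0)
      # distal pool: outside PTV and its adjacency ring, correct side
      pool <- setdiff(which(sel), c(ptv, ring))
      blob_centre <- centre + c(side * (r_ptv + 3.5 + stats::runif(1, -0.5, 0.5)),
                                stats::runif(1, -1.5, 1.5))
      dist_blob <- sqrt((coords[pool, 1] - blob_centre[1])^2 +
                          (coords[pool, 2] - blob_centre[2])^2)
      distal <- pool[order(dist_blob)][seq_len(min(n_target - n_adj, length(pool)))]
      sort(c(adj, distal))
    }
    n_oar <- round(0.065 * n_side * n_side)  # ~26 voxels on the small grid
    bla <- make_oar(-1, n_oar)
    rec <- make_oar(+1, n_oar)

    achieved <- function(oar) mean(cheb[oar] == 0)

    dose_matrix <- .pencil_beam_matrix(coords, n_side, centre,
                                       beamlets_per_beam)
    phantom_case(
      case_id = sprintf("case-%d-%s-%03d", seed, size,
                        round(100 * overlap_level)),
      voxel_count = n_side * n_side,
      structure_masks = list(PTV = ptv, BLA = bla, REC = rec),
      dose_matrix = dose_matrix,
      prescription_dose = prescription_dose,
      seed = as.integer(seed),
      meta = list(
        n_side = n_side,
        overlap_level = overlap_level,
        achieved_overlap = c(BLA = achieved(bla), REC = achieved(rec))
      )
    )
  })
}

# Pencil-beam dose-deposition matrix: three beams (top, left, diagonal),
# parallel rays 1 voxel apart centred on the PTV, Gaussian lateral falloff
# (sigma = 0.6 voxel) and exponential depth attenuation (mu = 0.04 / voxel).
.pencil_beam_matrix <- function(coords, n_side, centre, beamlets_per_beam) {
  sigma <- 0.6
  mu <- 0.04
  dirs <- list(c(1, 0), c(0, 1), c(sqrt(0.5), sqrt(0.5)))
  offsets <- seq(-(beamlets_per_beam - 1) / 2, (beamlets_per_beam - 1) / 2)
  xy <- cbind(coords[, 1], coords[, 2])
  cols <- vector("list", length(dirs) * beamlets_per_beam)
  k <- 0L
  for (u in dirs) {
    perp <- c(-u[2], u[1])
    # depth measured from the entry edge along u
    proj_along <- (xy[, 1] - centre[1]) * u[1] + (xy[, 2] - centre[2]) * u[2]
    depth <- proj_along - min(proj_along)
    for (off in offsets) {
      k <- k + 1L
      origin <- centre + off * perp
      lateral <- (xy[, 1] - origin[1]) * perp[1] + (xy[, 2] - origin[2]) * perp[2]
      cols[[k]] <- exp(-lateral^2 / (2 * sigma^2)) * exp(-mu * depth)
    }
  }
  m <- do.call(cbind, cols)
  m[m < 1e-6] <- 0
  m
}

#' DVH-constraint voxel selection
#'
#' Standard inverse-planning heuristic for turning a dose-volume constraint
#' "at most a fraction V of the structure may exceed threshold `thr`" into a
#' quadratic penalty: among the voxels currently above `thr`, the
#' `floor(V * n)` highest-dose voxels are tolerated (they occupy the allowed
#' volume) and the remaining, lowest-dose excess violators are selected for
#' penalisation. Re-run at every outer optimizer iteration.
#'
#' @param dose_struct numeric dose vector over the structure's voxels.
#' @param thr absolute dose threshold in Gy.
#' @param V allowed volume fraction in \[0, 1\].
#' @return integer indices (into `dose_struct`) of the penalised voxels.
#' @export
select_dvh_voxels <- function(dose_struct, thr, V) {
  viol <- which(dose_struct > thr)
  n_allow <- floor(V * length(dose_struct))
  if (length(viol) <= n_allow) return(integer(0))
  ord <- viol[order(dose_struct[viol], decreasing = TRUE)]
  if (n_allow == 0) return(sort(ord))
  sort(ord[-seq_len(n_allow)])
}

# objective and dose-space gradient with frozen voxel selections
.fmo_objective <- function(dose, case, tpps, sel) {
  dp <- case$prescription_dose
  m <- case$structure_masks
  under <- pmin(dose[m$PTV] - dp, 0)
  val <- tpps[["lambda_PTV"]] * sum(under^2)
  over_p <- pmax(dose[m$PTV][sel$PTV] - tpps[["t_PTV"]] * dp, 0)
  val <- val + tpps[["lambda_PTV"]] * sum(over_p^2)
  for (org in c("BLA", "REC")) {
    lam <- tpps[[paste0("lambda_", org)]]
    thr <- tpps[[paste0("t_", org)]] * dp
    over <- pmax(dose[m[[org]]][sel[[org]]] - thr, 0)
    val <- val + lam * sum(over^2)
  }
  val
}

.fmo_grad_dose <- function(dose, case, tpps, sel) {
  dp <- case$prescription_dose
  m <- case$structure_masks
  g <- numeric(length(dose))
  g[m$PTV] <- 2 * tpps[["lambda_PTV"]] * pmin(dose[m$PTV] - dp, 0)
  idx <- m$PTV[sel$PTV]
  g[idx] <- g[idx] +
    2 * tpps[["lambda_PTV"]] * pmax(dose[idx] - tpps[["t_PTV"]] * dp, 0)
  for (org in c("BLA", "REC")) {
    idx <- m[[org]][sel[[org]]]
    thr <- tpps[[paste0("t_", org)]] * dp
    g[idx] <- g[idx] +
      2 * tpps[[paste0("lambda_", org)]] * pmax(dose[idx] - thr, 0)
  }
  g
}

.fmo_select <- function(dose, case, tpps) {
  dp <- case$prescription_dose
  m <- case$structure_masks
  list(
    PTV = select_dvh_voxels(dose[m$PTV], tpps[["t_PTV"]] * dp, tpps[["V_PTV"]]),
    BLA = select_dvh_voxels(dose[m$BLA], tpps[["t_BLA"]] * dp, tpps[["V_BLA"]]),
    REC = select_dvh_voxels(dose[m$REC], tpps[["t_REC"]] * dp, tpps[["V_REC"]])
  )
}

#' Solve the fluence-map optimization for given TPPs
#'
#' Minimizes the DVH-constrained quadratic-penalty objective
#' \deqn{F(x) = \lambda_{PTV}\big[\sum_{v \in PTV}(d_v - d_p)_-^2 +
#'   \sum_{v \in S_{PTV}}(d_v - t_{PTV} d_p)_+^2\big] +
#'   \sum_{i \in \{BLA, REC\}} \lambda_i \sum_{v \in S_i}
#'   (d_v - t_i d_p)_+^2,\quad d = Mx,\ x \ge 0,}
#' where \eqn{(a)_- = \min(a, 0)}, \eqn{(a)_+ = \max(a, 0)} and the
#' penalised sets \eqn{S_i} come from [select_dvh_voxels()]. The solver is
#' projected gradient descent with backtracking line search; voxel
#' selections are re-computed every outer round and frozen during inner
#' steps, so the inner objective decreases monotonically.
#'
#' @param case a [phantom_case()].
#' @param tpps a [tpp_vector()].
#' @param warm_start optional previous `plan_state` whose fluence seeds the
#'   solver.
#' @param control list: `outer` re-selection rounds (default 20), `inner`
#'   gradient steps per round (default 50), `tol` relative objective-change
#'   stopping tolerance (default 1e-6), `pg_tol` projected-gradient
#'   convergence tolerance relative to `1 + objective` (default 1e-4).
#' @return an object of class `plan_state`: list with `fluence`, `dose`,
#'   `objective_value`, `converged` (TRUE iff the final projected-gradient
#'   sup-norm is below `pg_tol * (1 + objective)`), `pg_norm`, `iterations`.
#' @export
optimize_fluence <- function(case, tpps, warm_start = NULL,
                             control = list()) {
  ctl <- utils::modifyList(list(outer = 20L, inner = 50L, tol = 1e-6,
                                pg_tol = 1e-4), control)
  M <- case$dose_matrix
  Mt <- t(M)
  dp <- case$prescription_dose
  if (!is.null(warm_start)) {
    x <- warm_start$fluence
    if (length(x) != ncol(M)) stop("warm_start fluence has wrong length")
  } else {
    # scale a flat field so the mean PTV dose equals the prescription
    flat <- rowSums(M[case$structure_masks$PTV, , drop = FALSE])
    x <- rep(dp / mean(flat), ncol(M))
  }
  dose <- as.numeric(M %*% x)
  step <- 1 / max(colSums(M^2))   # conservative initial step, then adaptive
  f_prev_outer <- Inf
  total_it <- 0L
  for (outer in seq_len(ctl$outer)) {
    sel <- .fmo_select(dose, case, tpps)
    f <- .fmo_objective(dose, case, tpps, sel)
    if (!is.finite(f)) stop("non-finite objective in fluence optimization")
    for (inner in seq_len(ctl$inner)) {
      g <- as.numeric(Mt %*% .fmo_grad_dose(dose, case, tpps, sel))
      repeat {
        x_new <- pmax(x - step * g, 0)
        dose_new <- as.numeric(M %*% x_new)
        f_new <- .fmo_objective(dose_new, case, tpps, sel)
        if (f_new <= f || step < 1e-14) break
        step <- step / 2
      }
      total_it <- total_it + 1L
      moved <- sum(abs(x_new - x))
      x <- x_new; dose <- dose_new
      rel <- (f - f_new) / max(f, 1e-12)
      f <- f_new
      step <- step * 1.25
      if (rel < ctl$tol || moved == 0) break
    }
    if (abs(f_prev_outer - f) / max(f_prev_outer, 1e-12) < ctl$tol &&
        outer > 1L) {
      f_prev_outer <- f
      break
    }
    f_prev_outer <- f
  }
  # projected-gradient sup-norm under the final voxel selection: at an
  # active bound (x = 0) only a negative gradient counts as unconverged
  sel <- .fmo_select(dose, case, tpps)
  g <- as.numeric(Mt %*% .fmo_grad_dose(dose, case, tpps, sel))
  g[x <= 0 & g > 0] <- 0
  pg_norm <- max(abs(g))
  structure(
    list(
      fluence = x,
      dose = dose,
      objective_value = f_prev_outer,
      converged = pg_norm <= ctl$pg_tol * (1 + f_prev_outer),
      pg_norm = pg_norm,
      iterations = total_it
    ),
    class = "plan_state"
  )
}
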