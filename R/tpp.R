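#' @title Treatment planning parameters and the tuning action space
#' @description The inverse-planning objective exposes nine tunable treatment
#'   planning parameters (TPPs): three importance weights (lambda) for PTV,
#'   bladder and rectum, three upper dose thresholds (t, as fractions of the
#'   prescription dose) and three allowed volume fractions (V) for the
#'   DVH-type constraints. The tuning agent moves one parameter at a time by
#'   a fixed step, up or down, giving an 18-action discrete policy space.
#' @name tpp
NULL

TPP_NAMES <- c(
  "lambda_PTV", "lambda_BLA", "lambda_REC",
  "t_PTV", "t_BLA", "t_REC",
  "V_PTV", "V_BLA", "V_REC"
)

#' Default TPP grid: bounds, step sizes and initial values
#'
#' Weights lambda live on \[0.05, 5\] with step 0.15; dose thresholds t on
#' \[0.5, 1.2\] (fraction of prescription dose) with step 0.05; volume
#' fractions V on \[0.05, 0.95\] with step 0.05. Initial values sit near
#' mid-range and are lattice-aligned: every bound is reachable from the
#' initial value by a whole number of steps, so clipping at a bound never
#' moves a parameter off the step lattice.
#'
#' @return a data.frame with one row per parameter and columns
#'   `name`, `lo`, `hi`, `delta`, `init`.
#' @export
tpp_grid <- function() {
  data.frame(
    name  = TPP_NAMES,
    lo    = c(0.05, 0.05, 0.05, 0.50, 0.50, 0.50, 0.05, 0.05, 0.05),
    hi    = c(5.00, 5.00, 5.00, 1.20, 1.20, 1.20, 0.95, 0.95, 0.95),
    delta = c(0.15, 0.15, 0.15, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    init  = c(2.45, 2.45, 2.45, 0.85, 0.85, 0.85, 0.50, 0.50, 0.50),
    stringsAsFactors = FALSE
  )
}

#' Construct a TPP vector
#'
#' @param values named numeric vector of length 9 (names as in
#'   `tpp_grid()$name`), or NULL for the grid's initial values.
#' @param grid a TPP grid as returned by [tpp_grid()].
#' @return an object of class `tpp_vector`: a named numeric vector with the
#'   grid attached as attribute `grid`.
#' @export
tpp_vector <- function(values = NULL, grid = tpp_grid()) {
  if (is.null(values)) {
    values <- stats::setNames(grid$init, grid$name)
  }
  if (is.null(names(values))) names(values) <- grid$name
  stopifnot(length(values) == 9L, identical(names(values), grid$name))
  if (any(values < grid$lo - 1e-12) || any(values > grid$hi + 1e-12)) {
    stop("TPP values outside bounds")
  }
  if (any(values[4:6] <= 0)) stop("dose thresholds must be positive")
  structure(as.numeric(values), names = grid$name, grid = grid,
            class = "tpp_vector")
}

#' The 18-action TPP-tuning table
#'
#' Action `2p - 1` increases parameter `p` by its step size, action `2p`
#' decreases it; moves are clipped to the parameter bounds.
#'
#' @param grid a TPP grid as returned by [tpp_grid()].
#' @return data.frame with columns `action` (1..18), `param`, `direction`
#'   (+1/-1), `delta` and a human-readable `label`.
#' @export
action_table <- function(grid = tpp_grid()) {
  idx <- rep(seq_len(nrow(grid)), each = 2L)
  dir <- rep(c(1, -1), times = nrow(grid))
  data.frame(
    action = seq_len(2L * nrow(grid)),
    param = grid$name[idx],
    direction = dir,
    delta = grid$delta[idx],
    label = paste0(ifelse(dir > 0, "increase ", "decrease "), grid$name[idx]),
    stringsAsFactors = FALSE
  )
}

#' Apply a tuning action to a TPP vector
#'
#' @param tpps a [tpp_vector()].
#' @param action integer action index in 1..18.
#' @return the updated `tpp_vector`; the targeted parameter is moved by
#'   plus/minus its step and clipped to its bounds, all others unchanged.
#' @export
apply_action <- function(tpps, action) {
  grid <- attr(tpps, "grid")
  acts <- action_table(grid)
  if (!(length(action) == 1L && action %in% acts$action)) {
    stop("invalid action index")
  }
  a <- acts[acts$action == action, ]
  p <- match(a$param, grid$name)
  out <- unclass(tpps)
  out[p] <- min(max(out[p] + a$direction * a$delta, grid$lo[p]), grid$hi[p])
  structure(out, grid = grid, class = "tpp_vector")
}
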