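test_that("case generation is deterministic per seed and seed-sensitive", {
  a <- generate_case(1, overlap_level = 0, size = "small")
  b <- generate_case(1, overlap_level = 0, size = "small")
  expect_identical(a$structure_masks, b$structure_masks)
  expect_identical(a$dose_matrix, b$dose_matrix)
  d <- generate_case(2, overlap_level = 0, size = "small")
  expect_false(identical(a$structure_masks, d$structure_masks))
})

test_that("overlap_level controls the OAR-PTV adjacency fraction", {
  cs <- generate_case(7, overlap_level = 0.5, size = "small")
  # recount adjacency independently of the generator's bookkeeping
  n_side <- cs$meta$n_side
  coord <- function(v) c(((v - 1) %% n_side) + 1, ((v - 1) %/% n_side) + 1)
  ptv_xy <- t(vapply(cs$structure_masks$PTV, coord, numeric(2)))
  adj_frac <- function(mask) {
    mean(vapply(mask, function(v) {
      xy <- coord(v)
      any(abs(ptv_xy[, 1] - xy[1]) <= 1 & abs(ptv_xy[, 2] - xy[2]) <= 1)
    }, logical(1)))
  }
  expect_lt(abs(adj_frac(cs$structure_masks$BLA) - 0.5), 0.1)
  expect_lt(abs(adj_frac(cs$structure_masks$REC) - 0.5), 0.1)
  expect_error(generate_case(1, overlap_level = 1.5), "overlap_level")
})

test_that("case invariants hold: disjoint masks, irradiable PTV", {
  for (seed in c(3, 9)) {
    cs <- generate_case(seed, overlap_level = 0.4)
    all_idx <- unlist(cs$structure_masks)
    expect_equal(anyDuplicated(all_idx), 0L)
    expect_true(all(rowSums(cs$dose_matrix[cs$structure_masks$PTV, ]) > 0))
    expect_true(all(cs$dose_matrix >= 0))
  }
})

test_that("PTV-only identity case reaches the analytic optimum d = d_p", {
  cs <- identity_ptv_case(n = 5, d_p = 10)
  tp <- tpp_vector()  # t_PTV used only above threshold; underdose drives to d_p
  tp_vals <- as.numeric(tp)
  names(tp_vals) <- names(tp)
  tp_vals[c("lambda_BLA", "lambda_REC")] <- 0.05
  tp_vals["t_PTV"] <- 1.2  # overdose threshold above d_p: inactive at optimum
  tp <- tpp_vector(tp_vals)
  pl <- optimize_fluence(cs, tp, control = list(outer = 30, inner = 200))
  expect_lt(pl$objective_value, 1e-6)
  expect_equal(pl$dose, rep(10, 5), tolerance = 1e-3)
})

test_that("re-optimizing from an optimum with unchanged TPPs is idempotent", {
  cs <- small_case(3)
  tp <- tpp_vector()
  ctl <- list(outer = 60, inner = 400, tol = 1e-10)
  pl <- optimize_fluence(cs, tp, control = ctl)
  pl2 <- optimize_fluence(cs, tp, warm_start = pl, control = ctl)
  expect_equal(pl2$dose, pl$dose, tolerance = 1e-3)
  expect_lte(pl2$objective_value, pl$objective_value * (1 + 1e-6))
})

test_that("solver matches an independent projected-quadratic oracle on a fixed-selection instance", {
  # 5 voxels / 3 beamlets; V = 0.05 with 5-voxel structures floors to zero
  # tolerated violators, so every violator is penalised and the objective is
  # selection-independent: a plain convex problem an off-the-shelf bound-
  # constrained solver can check.
  set.seed(42)
  M <- matrix(runif(15, 0.2, 1), 5, 3)
  cs <- phantom_case("oracle", 5L,
                     list(PTV = 1:2, BLA = 3:4, REC = 5L),
                     M, prescription_dose = 10)
  g <- tpp_grid()
  v <- setNames(c(2.0, 0.8, 0.5, 1.0, 0.6, 0.6, 0.05, 0.05, 0.05), g$name)
  tp <- tpp_vector(v)
  dp <- 10
  obj <- function(x) {   # written independently of the package internals
    d <- as.numeric(M %*% x)
    2.0 * (sum(pmin(d[1:2] - dp, 0)^2) + sum(pmax(d[1:2] - 1.0 * dp, 0)^2)) +
      0.8 * sum(pmax(d[3:4] - 0.6 * dp, 0)^2) +
      0.5 * sum(pmax(d[5] - 0.6 * dp, 0)^2)
  }
  ora <- optim(rep(1, 3), obj, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 500, factr = 1e3))
  pl <- optimize_fluence(cs, tp, control = list(outer = 40, inner = 400,
                                                tol = 1e-12))
  expect_lt(abs(pl$objective_value - ora$value), 1e-4)
})

test_that("objective is non-increasing across iterations with frozen selections", {
  cs <- small_case(2)
  tp <- tpp_vector()
  # instrument: replay the solver's inner loop manually on frozen selections
  pl0 <- optimize_fluence(cs, tp, control = list(outer = 1, inner = 1))
  sel <- planxai:::.fmo_select(pl0$dose, cs, tp)
  M <- cs$dose_matrix; Mt <- t(M)
  x <- pl0$fluence
  d <- as.numeric(M %*% x)
  f <- planxai:::.fmo_objective(d, cs, tp, sel)
  step <- 1 / max(colSums(M^2))
  objs <- f
  for (it in 1:40) {
    gr <- as.numeric(Mt %*% planxai:::.fmo_grad_dose(d, cs, tp, sel))
    repeat {
      x_new <- pmax(x - step * gr, 0)
      d_new <- as.numeric(M %*% x_new)
      f_new <- planxai:::.fmo_objective(d_new, cs, tp, sel)
      if (f_new <= f || step < 1e-14) break
      step <- step / 2
    }
    x <- x_new; d <- d_new; f <- f_new
    step <- step * 1.25
    objs <- c(objs, f)
  }
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("converged plans have a small projected gradient", {
  cs <- small_case(4)
  tp <- tpp_vector()
  pl <- optimize_fluence(cs, tp, control = list(outer = 60, inner = 300))
  if (pl$converged) {
    expect_lte(pl$pg_norm, 1e-4 * (1 + pl$objective_value))
  }
  expect_true(all(pl$fluence >= 0))
  expect_equal(pl$dose, as.numeric(cs$dose_matrix %*% pl$fluence),
               tolerance = 1e-10)
})

test_that("rescaling all lambda weights leaves the optimal dose unchanged", {
  cs <- small_case(5)
  g <- tpp_grid()
  v1 <- setNames(g$init, g$name)
  v2 <- v1
  v2[1:3] <- v1[1:3] * 2          # common positive rescaling of the weights
  ctl <- list(outer = 40, inner = 200, tol = 1e-10)
  pl1 <- optimize_fluence(cs, tpp_vector(v1), control = ctl)
  pl2 <- optimize_fluence(cs, tpp_vector(v2), control = ctl)
  expect_equal(pl1$dose, pl2$dose, tolerance = 0.05 * cs$prescription_dose)
})
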