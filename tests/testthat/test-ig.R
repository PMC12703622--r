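test_that("attribution at the baseline itself is exactly zero", {
  cfg <- tiny_config()
  p <- agent_init(cfg, seed = 1)
  bl <- tiny_baseline()
  rec <- integrated_gradients(p, bl$dvh, list(c = bl$c, h = bl$h), 1, bl,
                              path_steps = 8)
  expect_equal(rec$ig_dvh, rep(0, cfg$input))
  expect_equal(rec$ig_c, rep(0, cfg$hidden))
  expect_equal(rec$ig_h, rep(0, cfg$hidden))
  expect_equal(rec$completeness_residual, 0)
})

test_that("trapezoid IG is exact for linear functions at any path_steps >= 2", {
  set.seed(31)
  n <- 12
  w <- rnorm(n)
  fn_grad <- function(Z) list(value = as.numeric(crossprod(w, Z)),
                              grad = matrix(w, n, ncol(Z)))
  x <- rnorm(n); x0 <- rnorm(n)
  for (ps in c(2L, 3L, 17L)) {
    res <- ig_attribute(fn_grad, x, x0, path_steps = ps)
    expect_equal(res$ig, w * (x - x0), tolerance = 1e-14)
    expect_lt(res$completeness_residual, 1e-12)
  }
})

test_that("256-step trapezoid matches a dense Riemann oracle on a tiny network", {
  cfg <- tiny_config()
  p <- agent_init(cfg, seed = 5)
  set.seed(77)
  dvh <- runif(cfg$input)
  mem <- list(c = runif(cfg$hidden, -1, 1), h = runif(cfg$hidden, -1, 1))
  bl <- tiny_baseline()
  rec <- integrated_gradients(p, dvh, mem, 2, bl, path_steps = 256)
  # independent quadrature: midpoint Riemann sum with 1e5 nodes
  K <- 1e5
  alpha <- (seq_len(K) - 0.5) / K
  x <- c(dvh, mem$c, mem$h)
  Z <- outer(x, alpha)  # baseline is zero
  D <- Z[seq_len(cfg$input), ]
  C <- Z[cfg$input + seq_len(cfg$hidden), ]
  H <- Z[cfg$input + cfg$hidden + seq_len(cfg$hidden), ]
  pg <- policy_input_grad(p, D, list(c = C, h = H), 2)
  ig_oracle <- x * rowMeans(rbind(pg$d_dvh, pg$d_c, pg$d_h))
  got <- c(rec$ig_dvh, rec$ig_c, rec$ig_h)
  rel_err <- abs(got - ig_oracle) / pmax(abs(ig_oracle), 1e-8)
  expect_lt(max(rel_err), 1e-3)
})

test_that("completeness holds at fine quadrature and may fail at coarse", {
  cfg <- tiny_config()
  set.seed(13)
  for (trial in 1:20) {
    p <- agent_init(cfg, seed = 1000 + trial)
    dvh <- runif(cfg$input)
    mem <- list(c = runif(cfg$hidden, -2, 2), h = runif(cfg$hidden, -1, 1))
    j <- sample.int(cfg$actions, 1)
    rec <- integrated_gradients(p, dvh, mem, j, tiny_baseline(),
                                path_steps = 1024)
    expect_true(completeness_check(rec, tol = 1e-4))
    expect_equal(sum(rec$ig_dvh) + sum(rec$ig_c) + sum(rec$ig_h),
                 rec$actual_output - rec$baseline_output,
                 tolerance = 1e-4)
  }
  # a 2-step rule on a strongly nonlinear path need not satisfy 1e-6
  p <- agent_init(cfg, seed = 3)
  p$Wp <- p$Wp * 30  # exaggerate curvature of the softmax
  rec2 <- integrated_gradients(p, runif(cfg$input),
                               list(c = runif(cfg$hidden, -2, 2),
                                    h = runif(cfg$hidden, -1, 1)),
                               1, tiny_baseline(), path_steps = 2)
  expect_gt(rec2$completeness_residual, 1e-6)
})

test_that("policy decomposition stacks to the actual probabilities", {
  cfg <- tiny_config()
  p <- agent_init(cfg, seed = 8)
  dvh <- runif(cfg$input)
  mem <- list(c = runif(cfg$hidden), h = runif(cfg$hidden))
  recs <- attribute_all_actions(p, dvh, mem, tiny_baseline(),
                                path_steps = 512)
  dec <- decompose_policy(recs)
  fw <- agent_forward(p, dvh, mem)
  expect_equal(unname(rowSums(dec)), unname(fw$probs), tolerance = 1e-4)
  # stacked totals over all actions sum to 1 (softmax + completeness)
  expect_equal(sum(dec), 1, tolerance = cfg$actions * 1e-4)
  # zero-weight network: baseline component is uniform, others vanish
  p0 <- agent_init(cfg, zero = TRUE)
  recs0 <- attribute_all_actions(p0, dvh, mem, tiny_baseline(), 16)
  dec0 <- decompose_policy(recs0)
  expect_equal(unname(dec0[, "baseline"]), rep(1 / cfg$actions, cfg$actions),
               tolerance = 1e-12)
  expect_equal(sum(abs(dec0[, c("dvh", "c", "h")])), 0, tolerance = 1e-12)
  # mixed baselines are rejected
  recs_mixed <- recs
  recs_mixed[[2]] <- integrated_gradients(p, dvh, mem, 2, tiny_baseline(0.01),
                                          16)
  expect_error(decompose_policy(recs_mixed), "mixed")
})

test_that("leading action selection matches a brute-force scan with tie rule", {
  mk_rec <- function(j, dvh_total, c_total, h_total) {
    structure(list(action = j, ig_dvh = c(dvh_total, rep(0, 299)),
                   ig_c = c(c_total, rep(0, 31)),
                   ig_h = c(h_total, rep(0, 31)), offset = 0),
              class = "attribution_record")
  }
  recs <- lapply(1:18, function(j) mk_rec(j, dvh_total = as.numeric(j == 5),
                                          c_total = 0, h_total = -j))
  la <- leading_action(recs)
  expect_equal(la[["dvh"]], 5L)
  expect_equal(la[["c"]], 1L)   # exact 18-way tie at 0: lowest index
  expect_equal(la[["h"]], 1L)   # -1 is the largest of -j
  # randomised cross-check against an explicit scan
  set.seed(6)
  for (trial in 1:10) {
    vals <- matrix(rnorm(18 * 3), 18, 3)
    recs2 <- lapply(1:18, function(j) mk_rec(j, vals[j, 1], vals[j, 2],
                                             vals[j, 3]))
    la2 <- leading_action(recs2)
    expect_equal(unname(la2), apply(vals, 2, which.max))
  }
})

test_that("heatmap segments conserve the total DVH attribution", {
  set.seed(12)
  v <- rnorm(300)
  seg <- heatmap_segments(v)
  expect_equal(nrow(seg), 30L)
  expect_equal(sum(seg$value), sum(v), tolerance = 1e-12)
  expect_equal(seg$organ, rep(c("PTV", "BLA", "REC"), each = 10))
  expect_equal(seg$value[1], sum(v[1:10]), tolerance = 1e-12)
  expect_equal(seg$value[30], sum(v[291:300]), tolerance = 1e-12)
})

test_that("offset baselines keep the PTV block at zero", {
  bl <- baseline_spec(0.01)
  expect_equal(bl$dvh[1:100], rep(0, 100))
  expect_equal(bl$dvh[101:300], rep(0.01, 200))
  expect_equal(baseline_spec(0)$dvh, rep(0, 300))
})

test_that("baseline sensitivity returns similarity 1 at offset zero", {
  p <- agent_init(seed = 2)
  cs <- small_case(1)
  tr <- run_episode(cs, p, max_steps = 2, mode = "stochastic", seed = 9)
  out <- baseline_sensitivity(p, list(tr), offsets = c(0, 0.005),
                              path_steps = 16)
  zero_rows <- out[out$offset == 0, ]
  expect_true(all(zero_rows$mean_similarity == 1))
  ps <- attr(out, "per_step")
  expect_true(all(ps$similarity[ps$offset == 0] == 1))
  expect_true(all(abs(ps$similarity) <= 1 + 1e-12))
})

test_that("implementation invariance: permuted hidden units give identical attributions", {
  cfg <- tiny_config()
  p <- agent_init(cfg, seed = 10)
  perm <- c(3L, 1L, 4L, 2L)
  p2 <- p
  for (nm in c("Wf", "Wi", "Wg", "Wo")) p2[[nm]] <- p[[nm]][perm, ]
  for (nm in c("Uf", "Ui", "Ug", "Uo")) p2[[nm]] <- p[[nm]][perm, perm]
  for (nm in c("bf", "bi", "bg", "bo")) p2[[nm]] <- p[[nm]][perm]
  p2$Wp <- p$Wp[, perm]; p2$Wq <- p$Wq[, perm]
  set.seed(3)
  dvh <- runif(cfg$input)
  # memory is a network-internal input: permute it consistently
  mem <- list(c = runif(cfg$hidden), h = runif(cfg$hidden))
  mem2 <- list(c = mem$c[perm], h = mem$h[perm])
  r1 <- integrated_gradients(p, dvh, mem, 2, tiny_baseline(), 128)
  r2 <- integrated_gradients(p2, dvh, mem2, 2, tiny_baseline(), 128)
  expect_equal(r1$ig_dvh, r2$ig_dvh, tolerance = 1e-8)
  expect_equal(r1$ig_c[perm], r2$ig_c, tolerance = 1e-8)
  expect_equal(r1$ig_h[perm], r2$ig_h, tolerance = 1e-8)
})

test_that("sensitivity axiom smoke test: differing influential input gets nonzero attribution", {
  cfg <- tiny_config()
  p <- agent_init(cfg, seed = 14)
  bl <- tiny_baseline()
  dvh <- bl$dvh
  dvh[3] <- 0.9   # only coordinate 3 differs from the baseline
  mem <- list(c = bl$c, h = bl$h)
  f_x <- agent_forward(p, dvh, mem)$probs[1]
  f_b <- agent_forward(p, bl$dvh, list(c = bl$c, h = bl$h))$probs[1]
  expect_false(isTRUE(all.equal(f_x, f_b)))
  rec <- integrated_gradients(p, dvh, mem, 1, bl, 64)
  expect_gt(abs(sum(rec$ig_dvh)), 0)
  expect_equal(sum(rec$ig_dvh[-3]), 0)  # non-differing coords get zero
})
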