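# Variance-based indices: closed forms, MC oracle agreement, main
# effects, uncertainty propagation, restitution surfaces.

test_that("linear emulators recover the analytic variance shares", {
  X <- with_seed_local(20, lhs::randomLHS(20, 2))
  colnames(X) <- c("x1", "x2")
  em <- gp_train(X, 3 * X[, 1] - X[, 2], restarts = 3, seed = 21)
  u <- uncertain_inputs(c("x1", "x2"), variance = c(0.02, 0.04))
  si <- sobol_indices(em, u)
  exact <- c(9 * 0.02, 1 * 0.04) / (9 * 0.02 + 0.04)
  expect_equal(si$S, exact, tolerance = 1e-4)
  expect_equal(si$S_T, exact, tolerance = 1e-4)
  expect_equal(si$sign, c(1, -1))
  # single active input
  em1 <- gp_train(X, X[, 1], restarts = 3, seed = 22)
  si1 <- sobol_indices(em1, uncertain_inputs(c("x1", "x2"),
                                             variance = 0.02))
  expect_equal(si1$S, c(1, 0), tolerance = 1e-5)
})

test_that("a pure interaction has zero first-order and unit total effect", {
  X <- with_seed_local(23, lhs::randomLHS(36, 2))
  colnames(X) <- c("x1", "x2")
  y <- (X[, 1] - 0.5) * (X[, 2] - 0.5)
  em <- gp_train(X, y, restarts = 5, seed = 24)
  u <- uncertain_inputs(c("x1", "x2"), variance = 0.02)
  si <- sobol_indices(em, u)
  expect_lt(max(si$S), 0.02)
  expect_gt(min(si$S_T), 0.9)
  expect_gt(min(si$interaction), 0.85)
})

test_that("additive emulators have equal first-order and total indices", {
  X <- with_seed_local(25, lhs::randomLHS(30, 3))
  colnames(X) <- c("x1", "x2", "x3")
  y <- sin(2 * X[, 1]) + X[, 2]^2 + 0.5 * X[, 3]
  em <- gp_train(X, y, restarts = 5, seed = 26)
  u <- uncertain_inputs(c("x1", "x2", "x3"), variance = 0.03)
  si <- sobol_indices(em, u)
  expect_equal(si$S_T, si$S, tolerance = 0.02)
  expect_lte(sum(si$S), 1 + 0.02)
  expect_gte(sum(si$S_T), sum(si$S) - 0.02)
})

test_that("closed-form indices match the MC oracle on random emulators", {
  # randomized GP fixtures; agreement within 3 MC standard errors
  n_fix <- 20
  fails <- 0
  for (k in seq_len(n_fix)) {
    P <- 2 + (k %% 2)
    X <- with_seed_local(100 + k, lhs::randomLHS(25, P))
    colnames(X) <- paste0("x", seq_len(P))
    coef <- with_seed_local(200 + k, runif(P, -2, 2))
    y <- drop(X %*% coef) + sin(3 * X[, 1]) * X[, 2]
    em <- gp_train(X, y, restarts = 3, seed = 300 + k)
    u <- uncertain_inputs(colnames(X), variance = 0.02)
    si <- sobol_indices(em, u)
    mc <- mc_oracle(em_mean_fun(em), u, n = 8000, seed = 400 + k)
    ok_S <- abs(si$S - mc$S) <= 3 * pmax(mc$S_se, 1e-4)
    ok_T <- abs(si$S_T - mc$S_T) <= 3 * pmax(mc$S_T_se, 1e-4)
    fails <- fails + sum(!ok_S) + sum(!ok_T)
  }
  # a 3-sigma criterion over ~100 comparisons admits a few marginal cases
  expect_lte(fails, 3)
})

test_that("the MC oracle is deterministic under a fixed seed", {
  af <- make_linear_function(c(1, 1))
  u <- uncertain_inputs(c("x1", "x2"), variance = c(0.02, 0.04))
  m1 <- mc_oracle(af$f, u, n = 2000, seed = 5)
  m2 <- mc_oracle(af$f, u, n = 2000, seed = 5)
  expect_identical(m1, m2)
  expect_error(mc_oracle(af$f, u, n = 10), "at least 1000")
})

test_that("indices are invariant to affine output rescaling", {
  X <- with_seed_local(27, lhs::randomLHS(24, 2))
  colnames(X) <- c("x1", "x2")
  y <- exp(X[, 1]) + 0.5 * X[, 2]
  em1 <- gp_train(X, y, restarts = 3, seed = 28)
  em2 <- gp_train(X, -5 * y + 100, restarts = 3, seed = 28)
  u <- uncertain_inputs(c("x1", "x2"), variance = 0.02)
  s1 <- sobol_indices(em1, u)
  s2 <- sobol_indices(em2, u)
  expect_equal(s1$S, s2$S, tolerance = 1e-3)
  expect_equal(s1$S_T, s2$S_T, tolerance = 1e-3)
  expect_equal(s1$sign, -s2$sign)
})

test_that("main effects are exact for linear emulators and signed", {
  X <- with_seed_local(29, lhs::randomLHS(15, 2))
  colnames(X) <- c("x1", "x2")
  em <- gp_train(X, 2 * X[, 1] + 1, restarts = 3, seed = 30)
  u <- uncertain_inputs(c("x1", "x2"), variance = 0.02)
  me <- main_effect(em, u, inputs = "x1")
  expect_equal(me$value, 2 * me$grid + 1, tolerance = 1e-5)
  em2 <- gp_train(X, -3 * X[, 2] + 0.1 * X[, 1], restarts = 3, seed = 31)
  si <- sobol_indices(em2, u)
  expect_equal(si$sign[si$input == "x2"], -1)
  expect_error(main_effect(em, u, grid = c(-0.5, 2)), "within")
})

test_that("requesting an index for a fixed input errors", {
  X <- with_seed_local(32, lhs::randomLHS(15, 2))
  colnames(X) <- c("x1", "x2")
  em <- gp_train(X, X[, 1] + X[, 2], restarts = 3, seed = 33)
  u <- uncertain_inputs(c("x1", "x2"), variance = 0.02, fixed = "x2")
  expect_error(sobol_indices(em, u, inputs = c("x1", "x2")), "fixed")
  si <- sobol_indices(em, u)
  expect_equal(si$input, "x1")
})

test_that("uncertainty propagation matches linear closed forms", {
  X <- with_seed_local(34, lhs::randomLHS(20, 2))
  colnames(X) <- c("x1", "x2")
  a <- c(2, -1)
  em <- gp_train(X, drop(X %*% a) + 5, restarts = 3, seed = 35)
  u <- uncertain_inputs(c("x1", "x2"), variance = c(0.02, 0.05))
  ou <- output_uncertainty(em, u)
  expect_equal(ou$mean, sum(a * 0.5) + 5, tolerance = 1e-4)
  expect_equal(ou$var, sum(a^2 * c(0.02, 0.05)), tolerance = 1e-3)
  # doubling every input variance doubles the output variance
  u2 <- uncertain_inputs(c("x1", "x2"), variance = 2 * c(0.02, 0.05))
  expect_equal(output_uncertainty(em, u2)$var, 2 * ou$var,
               tolerance = 1e-3)
  # all inputs fixed: no input-driven variance, emulator variance remains
  uf <- uncertain_inputs(c("x1", "x2"), variance = 0.02,
                         fixed = c("x1", "x2"))
  ouf <- output_uncertainty(em, uf)
  expect_equal(ouf$var, 0, tolerance = 1e-10)
  expect_gte(ouf$emulator_var, 0)
  sweep <- uncertainty_sweep(em, sds = c(0.1, 0.2), means = c(0.4, 0.6))
  expect_equal(nrow(sweep), 4)
  expect_true(all(diff(sweep$var[sweep$mean_in == 0.4]) > 0))
})

test_that("restitution surfaces from a toy Stage-2 emulator behave", {
  sp <- build_input_space("toy", 2)
  dd <- generate_toy_design_data(sp, n = 60, seed = 40,
                                 protocol = pacing_protocol(cl = 900,
                                                            n_beats = 3))
  X <- as.matrix(dd$design)[dd$kept, ]
  y <- dd$biomarkers$APD_90[dd$kept]
  em <- gp_train(X, y, restarts = 4, seed = 41)
  surf <- restitution_surface(em, "apd_scale",
                              di_grid = seq(0, 1, length.out = 12),
                              second_grid = c(0.25, 0.75))
  expect_true(all(surf$upper >= surf$lower))
  # positive restitution slope: mean APD90 non-decreasing in DI
  for (g in unique(surf$apd_scale)) {
    s <- surf[surf$apd_scale == g, ]
    expect_true(all(diff(s$mean[order(s$DI)]) > -1))
  }
  # design points have near-zero band width relative to far points
  expect_error(restitution_surface(em, "nope"), "unknown input")
})
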