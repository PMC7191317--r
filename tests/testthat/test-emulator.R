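# Gaussian-process emulator: kernel, training, prediction, validation.

test_that("RBF correlation has the stated analytic values", {
  expect_equal(rbf_covariance(c(0.3, 0.7), c(0.3, 0.7), c(1, 1)), 1)
  expect_equal(rbf_covariance(0.2, 0.2 + 0.5, 0.5), exp(-1))
  expect_equal(rbf_covariance(c(0.1, 0.9), c(0.4, 0.2), c(2, 3)),
               rbf_covariance(c(0.4, 0.2), c(0.1, 0.9), c(2, 3)))
  expect_error(rbf_covariance(0.1, 0.2, -1))
})

test_that("a linear target is reproduced exactly by the linear mean", {
  X <- with_seed_local(1, lhs::randomLHS(12, 2))
  colnames(X) <- c("x1", "x2")
  y <- 2 * X[, 1] + 1
  em <- gp_train(X, y, restarts = 4, seed = 2)
  Xnew <- with_seed_local(2, lhs::randomLHS(20, 2))
  colnames(Xnew) <- c("x1", "x2")
  pr <- predict(em, Xnew)
  expect_lt(max(abs(pr$.pred - (2 * Xnew[, 1] + 1))), 1e-6)
})

test_that("the emulator interpolates its design data", {
  f <- function(X) X[, 1]^2 + 0.5 * X[, 2]
  # at fixed, well-conditioned length scales interpolation holds to
  # nugget precision
  X <- with_seed_local(3, lhs::randomLHS(20, 2))
  colnames(X) <- c("x1", "x2")
  emf <- apsens:::gp_refit(X, f(X), delta = c(0.7, 0.7), nugget = 1e-7)
  prf <- predict(emf, X)
  expect_lt(max(abs(prf$.pred - emf$y)) / sd(emf$y), 1e-4)
  expect_true(all(prf$.pred_var <=
                    10 * emf$nugget * emf$sigma2 * emf$y_sd^2 + 1e-12))
  # a trained emulator stays within the nugget-scale bound set by the
  # magnitude of its interpolation weights
  em <- gp_fixture(f, P = 2, n = 20, seed = 3)
  pr <- predict(em, em$X)
  err <- max(abs(pr$.pred - em$y))
  expect_lt(err, 10 * em$nugget * max(abs(em$alpha)) * em$y_sd + 1e-12)
  expect_lt(err / sd(em$y), 1e-3)
})

test_that("the GP beats the linear-mean-only fit on a nonlinear target", {
  f <- function(X) sin(2 * pi * X[, 1])
  X <- with_seed_local(4, lhs::randomLHS(20, 1))
  colnames(X) <- "x1"
  y <- f(X)
  em <- gp_train(X, y, restarts = 5, seed = 5)
  Xv <- matrix(seq(0.025, 0.975, length.out = 40), ncol = 1,
               dimnames = list(NULL, "x1"))
  yv <- f(Xv)
  rmse_gp <- sqrt(mean((predict(em, Xv)$.pred - yv)^2))
  ols <- lm(y ~ X)
  rmse_ols <- sqrt(mean((cbind(1, Xv) %*% coef(ols) - yv)^2))
  expect_lt(rmse_gp, 0.05 * sd(yv))
  expect_lt(rmse_gp, rmse_ols / 10)
})

test_that("the kept fit is at least as good as every restart", {
  f <- function(X) exp(X[, 1]) * cos(3 * X[, 2])
  em <- gp_fixture(f, P = 2, n = 20, seed = 6)
  expect_true(all(em$loglik >= em$training_log$loglik - 1e-6))
})

test_that("prediction variance grows away from the design and batches agree", {
  f <- function(X) X[, 1] + 0.3 * sin(5 * X[, 2])
  em <- gp_fixture(f, P = 2, n = 15, seed = 7)
  far <- matrix(c(5, 5), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_warning(pv <- predict(em, far), "extrapolat")
  expect_gte(pv$.pred_var, em$sigma2 * em$y_sd^2)
  near <- em$X[3, , drop = FALSE]
  expect_lt(predict(em, near)$.pred_var, pv$.pred_var)
  # batch equals pointwise
  pts <- rbind(c(0.2, 0.4), c(0.8, 0.1), c(0.5, 0.5))
  colnames(pts) <- c("x1", "x2")
  batch <- predict(em, pts)
  for (i in 1:3) {
    one <- predict(em, pts[i, , drop = FALSE])
    expect_equal(one$.pred, batch$.pred[i])
    expect_equal(one$.pred_var, batch$.pred_var[i])
  }
})

test_that("posterior mean is equivariant under affine output rescaling", {
  f <- function(X) sin(3 * X[, 1]) + X[, 2]
  X <- with_seed_local(8, lhs::randomLHS(18, 2))
  colnames(X) <- c("x1", "x2")
  em1 <- gp_train(X, f(X), restarts = 4, seed = 9)
  em2 <- gp_train(X, 10 * f(X) + 3, restarts = 4, seed = 9)
  pts <- with_seed_local(9, lhs::randomLHS(10, 2))
  colnames(pts) <- c("x1", "x2")
  p1 <- predict(em1, pts)
  p2 <- predict(em2, pts)
  expect_equal(p2$.pred, 10 * p1$.pred + 3, tolerance = 1e-5)
  expect_equal(p2$.pred_var, 100 * p1$.pred_var, tolerance = 1e-4)
})

test_that("a very large nugget shrinks predictions toward the linear fit", {
  f <- function(X) sin(2 * pi * X[, 1])
  X <- with_seed_local(10, lhs::randomLHS(25, 1))
  colnames(X) <- "x1"
  y <- f(X)
  em <- apsens:::gp_refit(X, y, delta = 1, nugget = 1e6)
  ols <- lm(y ~ X)
  Xv <- matrix(seq(0, 1, 0.05), ncol = 1, dimnames = list(NULL, "x1"))
  pr <- predict(em, Xv)
  expect_equal(pr$.pred, drop(cbind(1, Xv) %*% coef(ols)),
               tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("MAPE and ISE follow their defining formulas", {
  # emulator of y = 100 + 10 x, trained exactly, validated at points
  # where its predictions are known: y_e = (105, 110)
  X <- matrix(seq(0, 1, length.out = 12), ncol = 1,
              dimnames = list(NULL, "x1"))
  em <- gp_train(X, 100 + 10 * X[, 1], restarts = 3, seed = 11)
  Xv <- matrix(c(0.5, 1.0), ncol = 1, dimnames = list(NULL, "x1"))
  vr <- gp_validate(em, Xv, c(100, 110))
  expect_equal(vr$mape, 100 / 2 * 5 / 105, tolerance = 1e-4)
  # ISE convention: error standardized by the posterior sd
  expect_equal(vr$runs$ise,
               vr$runs$abs_err / sqrt(vr$runs$pred_var))
  vr2 <- gp_validate(em, Xv, c(100, 110), ise_form = "variance")
  expect_equal(vr2$runs$ise, vr2$runs$abs_err / vr2$runs$pred_var)
  # perfect emulator
  vr3 <- gp_validate(em, Xv, predict(em, Xv)$.pred)
  expect_equal(vr3$mape, 0, tolerance = 1e-10)
  expect_equal(vr3$median_ise, 0, tolerance = 1e-6)
})

test_that("training guards reject degenerate designs", {
  X <- matrix(runif(10), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(gp_train(X, rnorm(5)), "N > P")
  X2 <- with_seed_local(12, lhs::randomLHS(12, 1))
  colnames(X2) <- "a"
  X2[2, ] <- X2[1, ]
  expect_error(gp_train(X2, rnorm(12)), "duplicate")
  expect_error(gp_train(with_seed_local(1, lhs::randomLHS(12, 1)),
                        rep(1, 12)), "constant")
})

test_that("emulator state round-trips through the JSON archive", {
  f <- function(X) cos(2 * X[, 1]) + X[, 2]
  em <- gp_fixture(f, P = 2, n = 16, seed = 13)
  path <- tempfile(fileext = ".json")
  write_gp(em, path)
  em2 <- read_gp(path)
  pts <- with_seed_local(14, lhs::randomLHS(8, 2))
  colnames(pts) <- c("x1", "x2")
  expect_equal(predict(em2, pts)$.pred, predict(em, pts)$.pred,
               tolerance = 1e-10)
  unlink(path)
})
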