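# Standardized multivariate regression indices and the S ~ B^2 link.

test_that("standardize z-scores columns with the sample sd", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(m)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(standardize(z), z, ignore_attr = TRUE)
  expect_error(standardize(cbind(a = c(1, 1, 1))), "constant")
})

test_that("OLS regression indices recover exact linear structure", {
  X <- with_seed_local(50, lhs::randomLHS(60, 3))
  colnames(X) <- c("x1", "x2", "x3")
  y <- X[, 1]
  r <- regression_indices(X, cbind(out = y))
  expect_equal(unname(r$B["x1", "out"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(r$B[c("x2", "x3"), "out"])), 1e-6)

  # two-input weighted sum: B_w proportional to a_w sd(x_w) / sd(y)
  a <- c(2, -3, 0)
  y2 <- drop(X %*% a)
  r2 <- regression_indices(X, cbind(out = y2))
  expect_equal(unname(r2$B[, "out"]),
               a * apply(X, 2, sd) / sd(y2), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("pure-interaction data yield near-zero linear coefficients", {
  X <- with_seed_local(51, lhs::randomLHS(2000, 2))
  colnames(X) <- c("x1", "x2")
  y <- (X[, 1] - mean(X[, 1])) * (X[, 2] - mean(X[, 2]))
  r <- regression_indices(X, cbind(out = y))
  expect_lt(max(abs(r$B)), 0.1)
})

test_that("collinear designs are rejected with the offending columns", {
  X <- cbind(x1 = runif(20), x2 = runif(20))
  X <- cbind(X, x3 = X[, 1] * 2)
  expect_error(regression_indices(X, cbind(out = rnorm(20))), "collinear")
})

test_that("PLS mode with full components approaches the OLS solution", {
  X <- with_seed_local(52, lhs::randomLHS(80, 3))
  colnames(X) <- c("x1", "x2", "x3")
  Y <- cbind(o1 = X[, 1] + 0.5 * X[, 2], o2 = X[, 3] - X[, 1])
  r_ols <- regression_indices(X, Y)
  r_pls <- regression_indices(X, Y, method = "pls", ncomp = 3)
  expect_equal(r_pls$B, r_ols$B, tolerance = 1e-6)
})

test_that("S approximately equals B^2 on linear additive data", {
  X <- with_seed_local(53, lhs::randomLHS(600, 2))
  colnames(X) <- c("x1", "x2")
  y <- 2 * X[, 1] + X[, 2]
  em <- gp_train(X, y, restarts = 3, seed = 54)
  # equal normalized variances make S the variance share
  u <- uncertain_inputs(c("x1", "x2"), variance = 1 / 12)
  si <- sobol_indices(em, u)
  si$output <- "y"
  reg <- regression_indices(X, cbind(y = y))
  cmp <- compare_indices(si[, c("output", "input", "S")], reg)
  expect_equal(cmp$table$S, cmp$table$B2, tolerance = 0.05)
  expect_equal(cmp$rank_cor$rank_cor, 1)
})

test_that("toy-pipeline S and B^2 rank together per output", {
  sp <- build_input_space("toy", 1)
  dd <- generate_toy_design_data(sp, n = 120, seed = 55)
  X <- as.matrix(dd$design)[dd$kept, ]
  outs <- c("APD_90", "V_40", "V_60")
  u <- uncertain_inputs(sp, variance = 1 / 12)
  sens <- dplyr::bind_rows(lapply(outs, function(o) {
    em <- gp_train(X, dd$biomarkers[[o]][dd$kept], restarts = 3,
                   seed = 56)
    si <- sobol_indices(em, u)
    si$output <- o
    tibble::as_tibble(si)
  }))
  reg <- regression_indices(X, as.matrix(dd$biomarkers[dd$kept, outs]))
  cmp <- compare_indices(sens[, c("output", "input", "S")], reg,
                         min_index = 0.005)
  # outputs with a single meaningful input yield NA rank correlations;
  # for those, agreement means the same top input under both methods
  expect_true(all(cmp$rank_cor$rank_cor > 0.8, na.rm = TRUE))
  tops <- cmp$table |>
    dplyr::group_by(output) |>
    dplyr::summarise(same_top = input[which.max(S)] == input[which.max(B2)])
  expect_true(all(tops$same_top))
})
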