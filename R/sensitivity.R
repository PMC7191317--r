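#' Uncertain-input measure for sensitivity and uncertainty analysis
#'
#' Independent (untruncated) Gaussian measures on the normalized input
#' scale. By default every input gets mean 0.5 and the variance recorded
#' in the input space (0.02 for +-50% inputs, 0.04 for G_K1 and C_m, 0.1
#' for extracellular concentrations). Inputs listed in `fixed` are held
#' at their mean with zero variance.
#'
#' @param space An `input_space`, or a character vector of input names.
#' @param mean Mean(s) in normalized units (recycled).
#' @param variance Optional variance(s) overriding the space defaults.
#' @param fixed Character vector of inputs to fix at their mean.
#' @return A tibble with columns `name`, `mean`, `var`.
#' @export
uncertain_inputs <- function(space, mean = 0.5, variance = NULL,
                             fixed = NULL) {
  if (is.character(space)) {
    nm <- space
    v <- rep(variance %||% 0.02, length.out = length(nm))
  } else {
    nm <- space$name
    v <- if (is.null(variance)) space$sa_variance else {
      rep(variance, length.out = length(nm))
    }
  }
  out <- tibble::tibble(name = nm,
                        mean = rep(mean, length.out = length(nm)),
                        var = v)
  if (!is.null(fixed)) {
    bad <- setdiff(fixed, nm)
    if (length(bad) > 0) stop("unknown fixed input(s): ",
                              paste(bad, collapse = ", "))
    out$var[out$name %in% fixed] <- 0
  }
  out
}

# One-dimensional Gaussian integrals of the squared-exponential kernel
# factor k(x) = exp(-(x - a)^2 / delta^2) under x ~ N(mu, v):
#   J  = E[k(x)]          (log scale)
#   mstar = E[x k(x)] / E[k(x)]
#   logD(a, b) = log E[k_a(x) k_b(x)]
log_j_gauss <- function(a, delta, mu, v) {
  s2 <- delta^2 + 2 * v
  0.5 * (log(delta^2) - log(s2)) - (a - mu)^2 / s2
}
mstar_gauss <- function(a, delta, mu, v) {
  (2 * a * v + mu * delta^2) / (2 * v + delta^2)
}
log_d_gauss <- function(a, b, delta, mu, v) {
  s2 <- delta^2 + 4 * v
  mbar <- (a + b) / 2
  -(a - b)^2 / (2 * delta^2) + 0.5 * (log(delta^2) - log(s2)) -
    2 * (mbar - mu)^2 / s2
}

# Shared precomputation for the closed-form sensitivity integrals, all on
# the standardized output scale of the emulator.
sobol_prep <- function(em, u) {
  X <- em$X
  P <- ncol(X)
  n <- nrow(X)
  u <- u[match(em$input_names, u$name), , drop = FALSE]
  if (any(is.na(u$name))) {
    stop("uncertain-input table does not cover all emulator inputs")
  }
  delta <- em$delta
  mu <- u$mean
  v <- u$var
  beta0 <- em$beta[1]
  beta <- em$beta[-1]
  alpha <- em$alpha

  logJ <- vapply(seq_len(P), function(p) {
    log_j_gauss(X[, p], delta[p], mu[p], v[p])
  }, numeric(n))
  logJ <- matrix(logJ, nrow = n)
  mst <- vapply(seq_len(P), function(p) {
    mstar_gauss(X[, p], delta[p], mu[p], v[p])
  }, numeric(n))
  mst <- matrix(mst, nrow = n)
  rowlogJ <- rowSums(logJ)
  wvec <- alpha * exp(rowlogJ)
  kerE <- sum(wvec)
  Sc <- colSums(wvec * (mst - matrix(mu, n, P, byrow = TRUE)))

  logD <- array(0, dim = c(n, n, P))
  for (p in seq_len(P)) {
    logD[, , p] <- outer(X[, p], X[, p],
                         function(a, b) log_d_gauss(a, b, delta[p],
                                                    mu[p], v[p]))
  }
  logDsum <- rowSums(logD, dims = 2)
  Eker2 <- drop(alpha %*% exp(logDsum) %*% alpha)
  var_total <- sum(beta^2 * v) + 2 * sum(beta * Sc) + (Eker2 - kerE^2)

  list(X = X, P = P, n = n, mu = mu, v = v, beta0 = beta0, beta = beta,
       alpha = alpha, delta = delta, logJ = logJ, mst = mst,
       rowlogJ = rowlogJ, kerE = kerE, Sc = Sc, logD = logD,
       logDsum = logDsum, var_total = var_total, names = em$input_names)
}

#' First-order and total-effect sensitivity indices from an emulator
#'
#' Variance-based Sobol indices of the emulator posterior mean under
#' independent Gaussian input measures, computed from the closed-form
#' Gaussian integrals of the squared-exponential kernel (no sampling).
#' The first-order index of input w is
#' `S_w = Var[E(f(x) | x_w)] / Var[f(x)]`: the fraction of output
#' variance removed by fixing `x_w`. The total-effect index is
#' `S_Tw = (Var[f(x)] - Var[E(f(x) | x_{~w})]) / Var[f(x)]`, which adds
#' all interaction contributions of `x_w`. Each index is given a sign
#' from the gradient of the main effect at the central value.
#'
#' @param em A `gp_emulator`.
#' @param u An [uncertain_inputs()] table covering the emulator inputs.
#' @param inputs Inputs to report (default: all uncertain inputs).
#' @return A tibble of class `sensitivity_result` with columns `input`,
#'   `S`, `S_T`, `sign`, `S_signed`, `interaction` (= `S_T - |S|`), and
#'   attributes `var_total`, `sum_abs_S`, `sum_interaction`.
#' @export
sobol_indices <- function(em, u, inputs = NULL) {
  pr <- sobol_prep(em, u)
  uncertain <- pr$names[pr$v > 0]
  inputs <- inputs %||% uncertain
  fixed_req <- setdiff(inputs, uncertain)
  if (length(fixed_req) > 0) {
    stop("sensitivity index requested for fixed input(s): ",
         paste(fixed_req, collapse = ", "))
  }
  res <- lapply(inputs, function(nm) {
    w <- match(nm, pr$names)
    Jw <- exp(pr$logJ[, w])
    uu <- exp(pr$rowlogJ - pr$logJ[, w])
    a <- pr$alpha * uu
    Dw <- exp(pr$logD[, , w])
    var_first <- pr$beta[w]^2 * pr$v[w] + 2 * pr$beta[w] * pr$Sc[w] +
      (drop(a %*% Dw %*% a) - pr$kerE^2)
    at <- pr$alpha * Jw
    Dnw <- exp(pr$logDsum - pr$logD[, , w])
    var_rest <- sum(pr$beta[-w]^2 * pr$v[-w]) +
      2 * sum(pr$beta[-w] * pr$Sc[-w]) +
      (drop(at %*% Dnw %*% at) - pr$kerE^2)
    tibble::tibble(
      input = nm,
      S = max(var_first / pr$var_total, 0),
      S_T = max(1 - var_rest / pr$var_total, 0)
    )
  })
  out <- dplyr::bind_rows(res)
  me <- main_effect(em, u, inputs = inputs, grid = c(0.49, 0.51))
  slopes <- vapply(split(me, factor(me$input, levels = inputs)),
                   function(d) diff(d$value) / diff(d$grid), numeric(1))
  out$sign <- unname(sign(slopes))
  out$S_signed <- out$sign * out$S
  out$interaction <- out$S_T - abs(out$S)
  attr(out, "var_total") <- pr$var_total * em$y_sd^2
  attr(out, "sum_abs_S") <- sum(abs(out$S))
  attr(out, "sum_interaction") <- sum(out$interaction)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Main-effect curves
#'
#' The expected emulator output as one input is fixed at each grid value
#' and all other inputs are integrated over their Gaussian measures:
#' `E[f(x) | x_w = g]`. The gradient of this curve near the central value
#' provides the sign of the sensitivity indices.
#'
#' @inheritParams sobol_indices
#' @param grid Values of the fixed input (default 0, 0.01, ..., 1).
#' @return A tibble with columns `input`, `grid`, `value` (original
#'   output scale).
#' @export
main_effect <- function(em, u, inputs = NULL, grid = seq(0, 1, by = 0.01)) {
  if (any(grid < 0 | grid > 1)) stop("grid values must be within [0, 1]")
  pr <- sobol_prep(em, u)
  inputs <- inputs %||% pr$names[pr$v > 0]
  res <- lapply(inputs, function(nm) {
    w <- match(nm, pr$names)
    a <- pr$alpha * exp(pr$rowlogJ - pr$logJ[, w])
    const <- pr$beta0 + sum(pr$beta[-w] * pr$mu[-w])
    kw <- exp(-outer(grid, pr$X[, w], "-")^2 / pr$delta[w]^2)
    val_std <- const + pr$beta[w] * grid + drop(kw %*% a)
    tibble::tibble(input = nm, grid = grid,
                   value = em$y_mean + em$y_sd * val_std)
  })
  dplyr::bind_rows(res)
}

#' Uncertainty propagation through an emulator
#'
#' Mean and variance of the emulator posterior-mean output under the
#' uncertain-input measure (closed form), with the emulator's own
#' code uncertainty (mean posterior variance under the measure) reported
#' separately.
#'
#' @inheritParams sobol_indices
#' @param n_mc Monte-Carlo sample size for the emulator-variance term.
#' @param mc_seed Seed for that sample.
#' @return One-row tibble: `mean`, `var`, `sd`, `cov` (coefficient of
#'   variation), `emulator_var`.
#' @export
output_uncertainty <- function(em, u, n_mc = 256, mc_seed = 1L) {
  pr <- sobol_prep(em, u)
  mean_std <- pr$beta0 + sum(pr$beta * pr$mu) + pr$kerE
  m <- em$y_mean + em$y_sd * mean_std
  v <- em$y_sd^2 * max(pr$var_total, 0)
  Xs <- with_seed(mc_seed, {
    vapply(seq_len(pr$P), function(p) {
      if (pr$v[p] > 0) rnorm(n_mc, pr$mu[p], sqrt(pr$v[p]))
      else rep(pr$mu[p], n_mc)
    }, numeric(n_mc))
  })
  emu_var <- suppressWarnings(mean(predict(em, Xs)$.pred_var))
  tibble::tibble(mean = m, var = v, sd = sqrt(v), cov = sqrt(v) / m,
                 emulator_var = emu_var)
}

#' Sweep of output uncertainty against input uncertainty
#'
#' Recomputes [output_uncertainty()] over a grid of common input standard
#' deviations and input means, to show how output uncertainty grows with
#' input uncertainty.
#'
#' @param em A `gp_emulator`.
#' @param sds Common standard deviation applied to every input.
#' @param means Normalized input means to sweep.
#' @return Tibble with columns `mean_in`, `sd_in`, `mean`, `var`, `sd`,
#'   `cov`.
#' @export
uncertainty_sweep <- function(em, sds = seq(0.02, 0.3, by = 0.04),
                              means = c(0.4, 0.5, 0.6)) {
  grid <- tidyr::expand_grid(mean_in = means, sd_in = sds)
  res <- purrr::pmap(grid, function(mean_in, sd_in) {
    u <- uncertain_inputs(em$input_names, mean = mean_in,
                          variance = sd_in^2)
    output_uncertainty(em, u)[, c("mean", "var", "sd", "cov")]
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Monte-Carlo oracle for Sobol indices
#'
#' Brute-force pick-freeze estimates of first-order (Saltelli) and
#' total-effect (Jansen) indices with standard errors, for any evaluable
#' function under independent Gaussian input measures. Used to verify
#' the closed-form indices.
#'
#' @param f Function taking a numeric matrix (rows = points, columns in
#'   the order of `u$name`) and returning a numeric vector.
#' @param u An [uncertain_inputs()] table.
#' @param n Base sample size (>= 1000).
#' @param seed Integer seed.
#' @return Tibble with columns `input`, `S`, `S_se`, `S_T`, `S_T_se`.
#' @export
mc_oracle <- function(f, u, n = 1e4, seed = 1L) {
  if (n < 1e3) stop("n must be at least 1000 for stable estimates")
  P <- nrow(u)
  draw <- function() {
    vapply(seq_len(P), function(p) {
      if (u$var[p] > 0) rnorm(n, u$mean[p], sqrt(u$var[p]))
      else rep(u$mean[p], n)
    }, numeric(n))
  }
  with_seed(seed, {
    A <- draw()
    B <- draw()
    fA <- f(A)
    fB <- f(B)
    V <- var(c(fA, fB))
    res <- lapply(which(u$var > 0), function(w) {
      AB <- A
      AB[, w] <- B[, w]
      fAB <- f(AB)
      tS <- fB * (fAB - fA)
      tT <- (fA - fAB)^2 / 2
      tibble::tibble(
        input = u$name[w],
        S = mean(tS) / V, S_se = sd(tS) / sqrt(n) / V,
        S_T = mean(tT) / V, S_T_se = sd(tT) / sqrt(n) / V
      )
    })
    dplyr::bind_rows(res)
  })
}

#' APD restitution surface from a Stage-2 emulator
#'
#' Posterior mean of the emulated output over a (DI x second input) grid
#' with every other input fixed (default 0.5, no input uncertainty), and
#' a 95% credible band reflecting only emulator prediction uncertainty.
#'
#' @param em A `gp_emulator` trained on a Stage-2 space including `DI`.
#' @param second_input Name of the second swept input.
#' @param di_grid,second_grid Normalized grid values in `[0, 1]`.
#' @param fixed_value Value assigned to all non-swept inputs.
#' @return Tibble with `DI`, the second input, `mean`, `sd`, `lower`,
#'   `upper` (mean +- 1.96 sd).
#' @export
restitution_surface <- function(em, second_input,
                                di_grid = seq(0, 1, length.out = 25),
                                second_grid = seq(0, 1, length.out = 5),
                                fixed_value = 0.5) {
  nm <- em$input_names
  if (!"DI" %in% nm) stop("emulator inputs do not include DI")
  if (!second_input %in% nm) stop("unknown input: ", second_input)
  grid <- tidyr::expand_grid(DI = di_grid, x2 = second_grid)
  X <- matrix(fixed_value, nrow(grid), length(nm),
              dimnames = list(NULL, nm))
  X[, "DI"] <- grid$DI
  X[, second_input] <- grid$x2
  pr <- predict(em, X)
  out <- tibble::tibble(
    DI = grid$DI, x2 = grid$x2,
    mean = pr$.pred, sd = sqrt(pr$.pred_var),
    lower = pr$.pred - 1.96 * sqrt(pr$.pred_var),
    upper = pr$.pred + 1.96 * sqrt(pr$.pred_var)
  )
  names(out)[2] <- second_input
  out
}
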