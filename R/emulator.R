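#' Squared-exponential correlation between input points
#'
#' `c(x, x') = exp(-sum_p (x_p - x'_p)^2 / delta_p^2)`, the radial basis
#' correlation used by the emulator; value in (0, 1], symmetric, and 1
#' exactly when `x == x'`.
#'
#' @param x,xp Numeric vectors of equal length P.
#' @param delta Positive correlation length scales, length P.
#' @return Scalar correlation.
#' @export
rbf_covariance <- function(x, xp, delta) {
  stopifnot(length(x) == length(xp), length(delta) == length(x),
            all(delta > 0))
  exp(-sum((x - xp)^2 / delta^2))
}

# Correlation matrix between rows of X1 and X2 (matrices, columns = inputs)
rbf_cross <- function(X1, X2, delta) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (p in seq_along(delta)) {
    K <- K + outer(X1[, p], X2[, p], "-")^2 / delta[p]^2
  }
  exp(-K)
}

# Negative restricted (weak-prior) log-likelihood of the length scales,
# with analytic gradient in log(delta). beta has a flat prior and
# sigma^2 a weak noninformative prior, both handled analytically.
# Returns a closure pair (fn, gr) sharing cached decompositions, so the
# line searches of the optimizer do not redo the gradient work.
make_gp_objective <- function(X, y, H, nugget, sqdist) {
  n <- nrow(X)
  q <- ncol(H)
  P <- length(sqdist)
  cache <- new.env(parent = emptyenv())
  cache$ld <- NULL

  base <- function(ldelta) {
    if (identical(cache$ld, ldelta)) return(TRUE)
    delta2 <- exp(2 * ldelta)
    A <- exp(-Reduce(`+`, Map(function(S, d2) S / d2, sqdist,
                              as.list(delta2))))
    diag(A) <- diag(A) + nugget
    L <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(L)) {
      cache$ld <- ldelta; cache$bad <- TRUE
      return(FALSE)
    }
    Ainv_y <- backsolve(L, forwardsolve(t(L), y))
    Ainv_H <- backsolve(L, forwardsolve(t(L), H))
    G <- crossprod(H, Ainv_H)
    LG <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(LG)) {
      cache$ld <- ldelta; cache$bad <- TRUE
      return(FALSE)
    }
    beta <- backsolve(LG, forwardsolve(t(LG), crossprod(H, Ainv_y)))
    Py <- Ainv_y - Ainv_H %*% beta  # P y, P = A^-1 - A^-1 H G^-1 H'A^-1
    quad <- sum(y * Py)
    if (!is.finite(quad)) {
      cache$ld <- ldelta; cache$bad <- TRUE
      return(FALSE)
    }
    # outputs captured exactly by the linear mean leave a residual
    # quadratic form at rounding level; floor it so the restricted
    # likelihood stays finite instead of failing
    quad <- max(quad, n * .Machine$double.eps)
    cache$ld <- ldelta; cache$bad <- FALSE
    cache$delta2 <- delta2; cache$A <- A; cache$L <- L; cache$LG <- LG
    cache$Ainv_H <- Ainv_H; cache$Py <- Py; cache$quad <- quad
    cache$value <- 0.5 * ((n - q) * log(quad) + 2 * sum(log(diag(L))) +
                            2 * sum(log(diag(LG))))
    cache$grad <- NULL
    TRUE
  }

  fn <- function(ldelta) {
    if (!base(ldelta) || cache$bad) return(1e10)
    cache$value
  }
  gr <- function(ldelta) {
    if (!base(ldelta) || cache$bad) return(rep(0, P))
    if (!is.null(cache$grad)) return(cache$grad)
    Ainv <- chol2inv(cache$L)
    Pm <- Ainv - cache$Ainv_H %*%
      backsolve(cache$LG, forwardsolve(t(cache$LG), t(cache$Ainv_H)))
    Acorr <- cache$A
    diag(Acorr) <- diag(Acorr) - nugget
    Py <- cache$Py
    grad <- vapply(seq_len(P), function(p) {
      Adot <- Acorr * (2 * sqdist[[p]] / cache$delta2[p])
      tr_PA <- sum(Pm * Adot)
      qdot <- -crossprod(Py, Adot %*% Py)[1]
      0.5 * ((n - q) * qdot / cache$quad + tr_PA)
    }, numeric(1))
    cache$grad <- grad
    grad
  }
  list(fn = fn, gr = gr)
}

#' Train a Gaussian-process emulator
#'
#' Fits a GP with linear mean `h(x) = (1, x_1, ..., x_P)` and
#' squared-exponential covariance to one simulator output. The mean
#' coefficients and process variance are handled analytically under weak
#' prior information (flat prior on the mean coefficients, Jeffreys-type
#' prior on the variance), leaving the correlation length scales to be
#' found by maximizing the restricted marginal log-likelihood. The
#' optimization is restarted `restarts` times from length scales drawn
#' log-uniformly on `[0.1, 10]` (normalized input units), and the best
#' fit is kept. Outputs are standardized internally and predictions are
#' returned on the original scale. A fixed nugget (default 1e-7) is added
#' to the correlation diagonal for numerical stability.
#'
#' Length scales are constrained to `[0.01, delta_max]` input ranges: on
#' a unit hypercube the likelihood is flat in any length scale beyond a
#' few input ranges (the kernel factor is indistinguishable from
#' constant there), while such values push the correlation matrix toward
#' singularity and destabilize the closed-form sensitivity integrals, so
#' the bounded optimum is the statistically equivalent, well-posed
#' representative.
#'
#' @param X Design inputs: matrix/data frame of normalized values (rows =
#'   runs). `N` must exceed `P + 3` and rows must be distinct.
#' @param y Design output, length N.
#' @param nugget Fixed nugget added to the correlation diagonal.
#' @param restarts Number of random restarts of the optimizer.
#' @param seed Integer seed for the restart initializations.
#' @param delta_max Upper bound on the correlation length scales, in
#'   units of the input range.
#' @return An object of class `gp_emulator`.
#' @export
gp_train <- function(X, y, nugget = 1e-7, restarts = 10, seed = 1L,
                     delta_max = 5) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  P <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= P + 3) {
    stop("need N > P + 3 design runs for the weak-prior likelihood ",
         "(N = ", n, ", P = ", P, ")")
  }
  if (anyDuplicated(X) > 0) {
    stop("duplicate design rows; the correlation matrix would be singular")
  }
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd == 0) {
    stop("design output is constant; nothing to emulate")
  }
  ys <- (y - y_mean) / y_sd
  H <- cbind(1, X)
  sqdist <- lapply(seq_len(P), function(p) outer(X[, p], X[, p], "-")^2)

  obj <- make_gp_objective(X, ys, H, nugget, sqdist)
  fits <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      init <- pmin(runif(P, log(0.1), log(10)), log(delta_max))
      res <- tryCatch(
        optim(init, fn = obj$fn, gr = obj$gr,
              method = "L-BFGS-B", lower = rep(log(1e-2), P),
              upper = rep(log(delta_max), P),
              control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      list(par = res$par, nll = res$value, init = init,
           convergence = res$convergence)
    })
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  nlls <- vapply(fits, function(f) f$nll, numeric(1))
  if (length(fits) == 0 || all(nlls >= 1e10)) {
    stop("emulator training failed on all restarts; check for duplicate ",
         "or near-duplicate design rows, or increase the nugget")
  }
  best <- fits[[which.min(nlls)]]
  delta <- exp(best$par)

  # cache decompositions at the optimum
  A <- exp(-Reduce(`+`, Map(function(S, d2) S / d2, sqdist,
                            as.list(delta^2))))
  diag(A) <- diag(A) + nugget
  L <- chol(A)
  Ainv_y <- backsolve(L, forwardsolve(t(L), ys))
  Ainv_H <- backsolve(L, forwardsolve(t(L), H))
  G <- crossprod(H, Ainv_H)
  LG <- chol(G)
  beta <- drop(backsolve(LG, forwardsolve(t(LG), crossprod(H, Ainv_y))))
  resid <- ys - drop(H %*% beta)
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  sigma2 <- max(sum(resid * alpha), n * .Machine$double.eps) / (n - ncol(H) - 2)

  structure(list(
    X = X, y = y, y_mean = y_mean, y_sd = y_sd,
    delta = delta, beta = beta, sigma2 = sigma2, nugget = nugget,
    alpha = drop(alpha), chol_A = L, chol_G = LG, Ainv_H = Ainv_H,
    input_names = colnames(X) %||% paste0("x", seq_len(P)),
    loglik = -best$nll,
    training_log = tibble::tibble(
      restart = seq_along(fits),
      loglik = -nlls,
      converged = vapply(fits, function(f) f$convergence == 0, logical(1)))
  ), class = "gp_emulator")
}

#' @export
print.gp_emulator <- function(x, ...) {
  cat("<gp_emulator> N =", nrow(x$X), " P =", ncol(x$X),
      " loglik =", signif(x$loglik, 6), "\n")
  cat("  delta:", paste(signif(x$delta, 3), collapse = " "), "\n")
  invisible(x)
}

#' Posterior prediction from a trained emulator
#'
#' Returns the posterior mean and variance of the emulator at new
#' normalized input points. Values outside `[0, 1]` are allowed
#' (extrapolation) and flagged with a warning.
#'
#' @param object A `gp_emulator`.
#' @param newdata Matrix/data frame of normalized inputs (rows = points).
#' @param ... Unused.
#' @return A tibble with columns `.pred` (posterior mean) and `.pred_var`
#'   (non-negative posterior variance), on the original output scale.
#' @export
predict.gp_emulator <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = 1)
  storage.mode(Xs) <- "double"
  if (ncol(Xs) != ncol(object$X)) stop("newdata has wrong number of inputs")
  if (any(Xs < -1e-9 | Xs > 1 + 1e-9)) {
    warning("prediction points outside [0, 1]: extrapolating")
  }
  Tm <- rbf_cross(Xs, object$X, object$delta)     # n* x N
  h <- cbind(1, Xs)                               # n* x (P+1)
  mean_s <- drop(h %*% object$beta) + drop(Tm %*% object$alpha)
  # variance: sigma2 * (1 + nugget - t' A^-1 t + r G^-1 r'), r = h - t' A^-1 H
  TL <- forwardsolve(t(object$chol_A), t(Tm))     # N x n*
  quad1 <- colSums(TL^2)
  R <- h - Tm %*% object$Ainv_H                   # n* x (P+1)
  RG <- forwardsolve(t(object$chol_G), t(R))
  quad2 <- colSums(RG^2)
  var_s <- object$sigma2 * pmax(1 + object$nugget - quad1 + quad2, 0)
  tibble::tibble(
    .pred = unname(object$y_mean + object$y_sd * mean_s),
    .pred_var = unname(object$y_sd^2 * var_s)
  )
}

#' Validate an emulator on held-out simulator runs
#'
#' Computes the mean average predicted error (MAPE), in percent of the
#' validation-set mean,
#' `MAPE = 100 / (N * mean(y_s)) * sum |y_s - y_e|`,
#' and the individual standard error of each run,
#' `ISE = |y_s - y_e| / sd_e`, where `sd_e` is the posterior predictive
#' standard deviation (set `ise_form = "variance"` to divide by the
#' posterior variance instead).
#'
#' @param em A `gp_emulator`.
#' @param X_val Normalized validation inputs (disjoint from the design).
#' @param y_val Simulator outputs of the validation runs.
#' @param ise_form `"sd"` (default) or `"variance"`.
#' @return An object of class `gp_validation`: list with `mape`,
#'   `median_ise`, `n`, and a per-run tibble `runs`.
#' @export
gp_validate <- function(em, X_val, y_val, ise_form = c("sd", "variance")) {
  ise_form <- match.arg(ise_form)
  pr <- predict(em, X_val)
  ybar <- mean(y_val)
  if (abs(ybar) < .Machine$double.eps) {
    stop("validation-set mean is zero; MAPE denominator degenerate")
  }
  abs_err <- abs(y_val - pr$.pred)
  mape <- 100 / length(y_val) * sum(abs_err) / abs(ybar)
  denom <- if (ise_form == "sd") sqrt(pr$.pred_var) else pr$.pred_var
  ise <- abs_err / denom
  structure(list(
    mape = mape, median_ise = median(ise), n = length(y_val),
    ise_form = ise_form,
    runs = tibble::tibble(y_sim = y_val, y_emu = pr$.pred,
                          pred_var = pr$.pred_var, abs_err = abs_err,
                          ise = ise)
  ), class = "gp_validation")
}

#' @export
print.gp_validation <- function(x, ...) {
  cat(sprintf("<gp_validation> N = %d  MAPE = %.3f%%  median ISE = %.3f\n",
              x$n, x$mape, x$median_ise))
  invisible(x)
}

#' @rdname gp_tidiers
#' @export
glance.gp_validation <- function(x, ...) {
  tibble::tibble(mape = x$mape, median_ise = x$median_ise, n = x$n)
}

#' Tidiers for emulator objects
#'
#' `tidy()` on a `gp_emulator` returns the per-input hyperparameters;
#' `glance()` returns one-row fit summaries.
#'
#' @param x A `gp_emulator` or `gp_validation`.
#' @param ... Unused.
#' @name gp_tidiers
#' @export
tidy.gp_emulator <- function(x, ...) {
  tibble::tibble(
    input = x$input_names,
    delta = x$delta,
    beta = x$beta[-1]
  )
}

#' @rdname gp_tidiers
#' @export
glance.gp_emulator <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X), p = ncol(x$X), loglik = x$loglik,
    sigma2 = x$sigma2, nugget = x$nugget,
    beta0 = x$beta[1]
  )
}

#' Serialize / restore an emulator as plain text
#'
#' Writes the complete emulator state (design data, hyperparameters,
#' nugget, standardization constants, version tag) to a JSON archive from
#' which [read_gp()] rebuilds a working emulator.
#'
#' @param em A `gp_emulator`.
#' @param path File path.
#' @export
write_gp <- function(em, path) {
  obj <- list(
    version = "apsens-gp-1",
    X = unname(apply(em$X, 1, function(r) as.numeric(r), simplify = FALSE)),
    input_names = em$input_names,
    y = as.numeric(em$y),
    delta = as.numeric(em$delta), beta = as.numeric(em$beta),
    sigma2 = em$sigma2, nugget = em$nugget,
    y_mean = em$y_mean, y_sd = em$y_sd
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp
#' @export
read_gp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- if (is.list(obj$X)) do.call(rbind, obj$X) else as.matrix(obj$X)
  colnames(X) <- obj$input_names
  em <- gp_refit(X, obj$y, obj$delta, obj$nugget)
  em
}

# Rebuild the cached decompositions for given length scales (no
# optimization); used by read_gp and by tests that need a GP with known
# hyperparameters.
gp_refit <- function(X, y, delta, nugget = 1e-7) {
  X <- as.matrix(X)
  n <- nrow(X)
  y_mean <- mean(y)
  y_sd <- sd(y)
  ys <- (y - y_mean) / y_sd
  H <- cbind(1, X)
  A <- rbf_cross(X, X, delta)
  diag(A) <- diag(A) + nugget
  L <- chol(A)
  Ainv_y <- backsolve(L, forwardsolve(t(L), ys))
  Ainv_H <- backsolve(L, forwardsolve(t(L), H))
  G <- crossprod(H, Ainv_H)
  LG <- chol(G)
  beta <- drop(backsolve(LG, forwardsolve(t(LG), crossprod(H, Ainv_y))))
  resid <- ys - drop(H %*% beta)
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  sigma2 <- max(sum(resid * alpha), n * .Machine$double.eps) / (n - ncol(H) - 2)
  structure(list(
    X = X, y = y, y_mean = y_mean, y_sd = y_sd, delta = delta,
    beta = beta, sigma2 = sigma2, nugget = nugget, alpha = drop(alpha),
    chol_A = L, chol_G = LG, Ainv_H = Ainv_H,
    input_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    loglik = NA_real_, training_log = NULL
  ), class = "gp_emulator")
}

#' Turn a fitted object into a tidy tibble
#'
#' Minimal broom-style generics for the fitted objects in this package.
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
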