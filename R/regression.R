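#' Z-score the columns of a matrix
#'
#' Subtracts the column mean and divides by the column standard deviation
#' (sample convention, N-1 denominator). Errors on constant columns.
#'
#' @param m Numeric matrix or data frame.
#' @return Matrix with columns of mean 0 and sd 1; attributes `center`
#'   and `scale`.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(!is.finite(scl) | scl == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[scl == 0 | !is.finite(scl)], collapse = ", "))
  }
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Standardized multivariate linear-regression sensitivity indices
#'
#' Regresses each standardized output on all standardized inputs,
#' `Y = X B`, giving a P x M matrix of standardized regression
#' coefficients `B`. Each coefficient says how many output standard
#' deviations the output moves per input standard deviation, so under an
#' approximately additive simulator `B^2` is comparable to the
#' first-order variance-based index. The default estimator is ordinary
#' multivariate least squares; a latent-component partial-least-squares
#' mode (NIPALS, `method = "pls"`) is available for comparison.
#'
#' @param X Design inputs (rows = kept runs).
#' @param Y Design outputs (same rows).
#' @param method `"ols"` (default) or `"pls"`.
#' @param ncomp Number of latent components for `"pls"`.
#' @return Object of class `regression_indices`: list with the `B`
#'   matrix, a tidy tibble `coefs` (`input`, `output`, `B`), and the
#'   standardization constants.
#' @export
regression_indices <- function(X, Y, method = c("ols", "pls"),
                               ncomp = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) <= ncol(X)) stop("need more runs than inputs (N > P)")
  Xs <- standardize(X)
  Ys <- standardize(Y)
  if (method == "ols") {
    qx <- qr(Xs)
    if (qx$rank < ncol(Xs)) {
      dropped <- colnames(Xs)[qx$pivot[-seq_len(qx$rank)]]
      stop("design inputs are collinear: ", paste(dropped, collapse = ", "))
    }
    B <- qr.coef(qx, Ys)
  } else {
    nc <- ncomp %||% min(ncol(Xs), 10L)
    B <- pls_nipals(Xs, Ys, nc)
  }
  rownames(B) <- colnames(Xs) %||% paste0("x", seq_len(ncol(Xs)))
  colnames(B) <- colnames(Ys) %||% paste0("y", seq_len(ncol(Ys)))
  coefs <- tibble::as_tibble(as.data.frame.table(B,
                                                 responseName = "B"))
  names(coefs)[1:2] <- c("input", "output")
  coefs$input <- as.character(coefs$input)
  coefs$output <- as.character(coefs$output)
  structure(list(B = B, coefs = coefs, method = method,
                 x_center = attr(Xs, "center"), x_scale = attr(Xs, "scale"),
                 y_center = attr(Ys, "center"), y_scale = attr(Ys, "scale")),
            class = "regression_indices")
}

# NIPALS PLS2 regression coefficients on standardized data.
pls_nipals <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  E <- X
  Fm <- Y
  W <- P <- NULL
  Q <- NULL
  for (k in seq_len(ncomp)) {
    u <- Fm[, which.max(apply(Fm, 2, var)), drop = TRUE]
    w_old <- rep(Inf, ncol(E))
    for (it in seq_len(maxit)) {
      w <- drop(crossprod(E, u))
      w <- w / sqrt(sum(w^2))
      tsc <- drop(E %*% w)
      q <- drop(crossprod(Fm, tsc)) / sum(tsc^2)
      u <- drop(Fm %*% q) / sum(q^2)
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    p <- drop(crossprod(E, tsc)) / sum(tsc^2)
    E <- E - tcrossprod(tsc, p)
    Fm <- Fm - tcrossprod(tsc, q)
    W <- cbind(W, w)
    P <- cbind(P, p)
    Q <- cbind(Q, q)
  }
  Wstar <- W %*% solve(crossprod(P, W))
  Wstar %*% t(Q)
}

#' @export
print.regression_indices <- function(x, ...) {
  cat("<regression_indices>", x$method, "fit:",
      nrow(x$B), "inputs x", ncol(x$B), "outputs\n")
  invisible(x)
}

#' @export
tidy.regression_indices <- function(x, ...) x$coefs

#' Compare variance-based and regression-based indices
#'
#' Joins first-order Sobol indices with standardized regression
#' coefficients for the same inputs and outputs, reporting `S`, `B`,
#' `B^2`, and the per-output Spearman rank correlation between `S` and
#' `B^2` (under an additive simulator `S ~ B^2`).
#'
#' @param sens Tibble with columns `output`, `input`, `S` (e.g. the bound
#'   sensitivity tables of a stage run).
#' @param reg A `regression_indices` object.
#' @param min_index Indices where both `S` and `B^2` fall below this
#'   threshold are dropped from the rank correlation (ranking noise-level
#'   indices is uninformative); the full table is always returned.
#' @return List with `table` (input x output rows) and `rank_cor`
#'   (per-output Spearman correlation of S with B^2).
#' @export
compare_indices <- function(sens, reg, min_index = 0) {
  tb <- dplyr::inner_join(sens, reg$coefs, by = c("input", "output"))
  tb$B2 <- tb$B^2
  keep <- tb$S >= min_index | tb$B2 >= min_index
  rc <- tb[keep, ] |>
    dplyr::group_by(.data$output) |>
    dplyr::summarise(rank_cor = suppressWarnings(
      cor(.data$S, .data$B2, method = "spearman")), .groups = "drop")
  list(table = tb[, c("input", "output", "S", "B", "B2")], rank_cor = rc)
}
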