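#' Analytic benchmark functions with known variance decompositions
#'
#' Test-oracle layer: smooth deterministic maps on the input hypercube
#' whose first-order and total-effect indices are available in closed
#' form under independent Gaussian input measures, so every index
#' estimator in the package can be checked against exact values.
#'
#' `make_linear_function()` builds `f(x) = intercept + sum a_p x_p`, for
#' which `S_w = S_Tw = a_w^2 v_w / sum_p a_p^2 v_p`.
#'
#' @param coeffs Numeric coefficients (at least one nonzero).
#' @param intercept Constant term.
#' @return Object of class `analytic_function`: list with `f` (vectorized
#'   over matrix rows), `indices(u)` returning the exact index tibble,
#'   and a `label`.
#' @export
make_linear_function <- function(coeffs, intercept = 0) {
  if (all(coeffs == 0)) stop("at least one coefficient must be nonzero")
  f <- function(X) drop(as.matrix(X) %*% coeffs) + intercept
  indices <- function(u) {
    stopifnot(nrow(u) == length(coeffs))
    contrib <- coeffs^2 * u$var
    S <- contrib / sum(contrib)
    tibble::tibble(input = u$name, S = S, S_T = S)
  }
  structure(list(f = f, indices = indices,
                 label = "linear", P = length(coeffs)),
            class = "analytic_function")
}

#' @rdname make_linear_function
#'
#' @details `make_interaction_function()` builds the pure-interaction
#' product `f(x) = prod_p (x_p - mu_p)`; when the measure means equal the
#' `centers`, every conditional expectation vanishes, so all first-order
#' indices are 0 while (for P = 2) both total-effect indices are 1.
#'
#' @param centers Centering constants `mu_p` (length P >= 2).
#' @export
make_interaction_function <- function(centers) {
  if (length(centers) < 2) stop("need at least two inputs")
  f <- function(X) {
    X <- as.matrix(X)
    apply(sweep(X, 2, centers), 1, prod)
  }
  indices <- function(u) {
    stopifnot(nrow(u) == length(centers), all(u$mean == centers))
    P <- length(centers)
    # Var = prod v_p; removing input w leaves E[prod_{p!=w}(x_p-mu)^2] v_w
    S_T <- rep(if (P == 2) 1 else NA_real_, P)
    if (P > 2) {
      S_T <- vapply(seq_len(P), function(w) 1, numeric(1))
    }
    tibble::tibble(input = u$name, S = 0, S_T = S_T)
  }
  structure(list(f = f, indices = indices,
                 label = "pure-interaction", P = length(centers)),
            class = "analytic_function")
}

#' @export
print.analytic_function <- function(x, ...) {
  cat("<analytic_function>", x$label, "P =", x$P, "\n")
  invisible(x)
}

#' Self-check an analytic function against the Monte-Carlo oracle
#'
#' Verifies that the stored closed-form indices agree with the
#' [mc_oracle()] estimates within `k` standard errors.
#'
#' @param af An `analytic_function`.
#' @param u An [uncertain_inputs()] table.
#' @param n Oracle sample size.
#' @param seed Oracle seed.
#' @param k Allowed number of standard errors.
#' @return `TRUE` invisibly, or an error describing the disagreement.
#' @export
validate_analytic <- function(af, u, n = 1e5, seed = 1L, k = 3) {
  exact <- af$indices(u)
  est <- mc_oracle(af$f, u, n = n, seed = seed)
  tb <- dplyr::inner_join(exact, est, by = "input",
                          suffix = c("_exact", "_mc"))
  bad_S <- abs(tb$S_exact - tb$S_mc) > k * pmax(tb$S_se, 1e-12)
  bad_T <- abs(tb$S_T_exact - tb$S_T_mc) > k * pmax(tb$S_T_se, 1e-12)
  if (any(bad_S | bad_T, na.rm = TRUE)) {
    stop("analytic indices disagree with MC oracle for: ",
         paste(tb$input[bad_S | bad_T], collapse = ", "))
  }
  invisible(TRUE)
}

#' Generate toy-model design data
#'
#' Mirrors the full design workflow at toy scale: Latin-hypercube sample
#' of the toy input space, closed-form toy simulations, biomarker
#' extraction, and the plausibility filter. The toy parameter-biomarker
#' map is monotone in every parameter, so ground-truth effect signs are
#' recorded for downstream assertions.
#'
#' @param space A toy `input_space` (see [build_input_space()]).
#' @param n Number of runs.
#' @param seed Design seed.
#' @param protocol Pacing protocol (Stage-2 spaces with a `DI` input use
#'   the sampled DI for each run's S2 beat).
#' @param dt_out Trace sampling interval, ms.
#' @return List of class `design_data`: `design` (normalized),
#'   `raw` (raw parameter values), `biomarkers` (all runs),
#'   `exclusions`, `kept` (indices), and `truth_signs`.
#' @export
generate_toy_design_data <- function(space, n, seed = 1L,
                                     protocol = pacing_protocol(cl = 600,
                                                                n_beats = 4),
                                     dt_out = 0.5) {
  design <- latin_hypercube(n, space, seed = seed)
  has_di <- "DI" %in% space$name
  par_space <- space[space$name != "DI", , drop = FALSE]
  raw <- denormalize_inputs(space, design)
  runs <- lapply(seq_len(n), function(i) {
    pars <- as.list(raw[i, setdiff(names(raw), "DI"), drop = FALSE])
    proto <- protocol
    if (has_di) {
      proto <- pacing_protocol(cl = protocol$cl, n_beats = protocol$n_beats,
                               s2_di = raw$DI[i])
    }
    tr <- simulate_toy_ap(pars, proto, dt_out = dt_out)
    bm <- trace_biomarkers(tr)
    flt <- plausibility_filter(bm)
    list(bm = bm$final, flt = flt)
  })
  bms <- dplyr::bind_rows(lapply(runs, function(r) {
    r$bm %||% tibble::tibble(dVdt_max = NA_real_)
  }))
  excl <- dplyr::bind_rows(lapply(runs, function(r) r$flt))
  excl$run <- seq_len(n)
  # every toy parameter acts monotonically on its primary biomarker
  truth <- tibble::tibble(
    input = c("upstroke_slope", "peak", "apd_scale", "rest",
              "ca_min", "ca_max"),
    biomarker = c("dVdt_max", "V_max", "APD_90", "RestVm",
                  "Ca_min", "Ca_max"),
    sign = c(1, 1, 1, 1, 1, 1)
  )
  truth <- truth[truth$input %in% space$name, , drop = FALSE]
  structure(list(design = design, raw = raw, biomarkers = bms,
                 exclusions = excl, kept = which(excl$keep),
                 truth_signs = truth, space = space, seed = seed),
            class = "design_data")
}

#' @export
print.design_data <- function(x, ...) {
  cat("<design_data>", nrow(x$design), "runs,",
      length(x$kept), "kept\n")
  invisible(x)
}
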