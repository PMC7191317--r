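#' Input-space definition for a model and analysis stage
#'
#' Builds the ordered table of tunable inputs: name, central (default)
#' value, half-range fraction, bounds, units, and the variance assigned to
#' each input (in normalized units) for the sensitivity analysis. Ranges
#' are `central * (1 +- fraction)`: 50% for most inputs, 25% for G_K1 and
#' C_m, and 10% for the extracellular concentrations. Stage 2 restricts
#' to the inputs that dominate action-potential shape and duration and
#' adds the diastolic interval (DI, 50-450 ms) as a protocol input.
#'
#' Sensitivity-analysis variances (normalized scale): 0.02 for the +-50%
#' inputs, 0.04 for G_K1 and C_m, and 0.1 for the extracellular
#' concentrations.
#'
#' @param model `"courtemanche"`, `"maleckar"`, or `"toy"`.
#' @param stage 1 (full input set, S1 pacing) or 2 (reduced set + DI,
#'   S1-S2 pacing).
#' @return A tibble of class `input_space` with columns `name`, `central`,
#'   `fraction`, `low`, `high`, `units`, `sa_variance`, and attributes
#'   `model` and `stage`.
#' @export
build_input_space <- function(model = c("courtemanche", "maleckar", "toy"),
                              stage = 1) {
  model <- match.arg(model)
  if (!stage %in% c(1, 2)) stop("stage must be 1 or 2")
  defaults <- model_defaults(model)

  units <- switch(model,
    courtemanche = c(
      G_Na = "nS/pF", G_K1 = "nS/pF", G_to = "nS/pF", fG_Kur = "1",
      G_Kr = "nS/pF", G_Ks = "nS/pF", G_CaL = "nS/pF", G_bNa = "nS/pF",
      G_bCa = "nS/pF", i_NaK_max = "pA/pF", i_NaCa_max = "pA/pF",
      i_pCa_max = "pA/pF", K_rel = "1/ms", tau_tr = "ms",
      i_up_max = "mM/ms", K_up = "mM", C_m = "pF", Na_o = "mM",
      K_o = "mM", Ca_o = "mM"),
    maleckar = c(
      P_Na = "nL/s", G_K1 = "nS", G_t = "nS", G_Kur = "nS", G_Kr = "nS",
      G_Ks = "nS", G_CaL = "nS", G_bNa = "nS", G_bCa = "nS",
      i_NaK_max = "pA", K_NaCa = "pA/mM^4", i_pCa_max = "pA",
      alpha_rel = "pA/mM", tau_tr = "s", i_up_max = "pA", K_cyca = "mM",
      K_srca = "mM", K_xcs = "1", C_m = "pF", Na_o = "mM", K_o = "mM",
      Ca_o = "mM"),
    toy = c(
      upstroke_slope = "mV/ms", peak = "mV", plateau = "mV",
      apd_scale = "ms", rest = "mV", ca_min = "mM", ca_max = "mM",
      rest_coef = "1")
  )
  nm <- names(units)
  central <- unlist(defaults[nm])
  frac <- rep(0.50, length(nm))
  names(frac) <- nm
  if (model != "toy") {
    frac[c("G_K1", "C_m")] <- 0.25
    frac[c("Na_o", "K_o", "Ca_o")] <- 0.10
  } else {
    frac["rest"] <- 0.10
    frac["plateau"] <- 0.50
  }
  sa_var <- ifelse(frac == 0.50, 0.02, ifelse(frac == 0.25, 0.04, 0.1))
  if (model == "toy") sa_var <- rep(0.02, length(nm))

  tb <- tibble::tibble(
    name = nm, central = unname(central), fraction = unname(frac),
    low = unname(pmin(central * (1 - frac), central * (1 + frac))),
    high = unname(pmax(central * (1 - frac), central * (1 + frac))),
    units = unname(units), sa_variance = unname(sa_var)
  )

  if (stage == 2) {
    keep <- switch(model,
      courtemanche = c("G_K1", "G_to", "fG_Kur", "G_CaL", "G_bCa",
                       "i_NaK_max", "i_NaCa_max", "i_pCa_max"),
      maleckar = c("G_K1", "G_t", "G_Kur", "G_CaL", "G_bCa",
                   "i_NaK_max", "C_m"),
      toy = c("apd_scale", "rest_coef", "peak"))
    fixed <- tb[!tb$name %in% keep, , drop = FALSE]
    tb <- tb[match(keep, tb$name), , drop = FALSE]
    tb <- dplyr::bind_rows(tb, tibble::tibble(
      name = "DI", central = 250, fraction = NA_real_, low = 50,
      high = 450, units = "ms", sa_variance = 0.02))
    attr(tb, "fixed_at_central") <- fixed$name
  }
  attr(tb, "model") <- model
  attr(tb, "stage") <- stage
  class(tb) <- c("input_space", class(tb))
  tb
}

#' Normalize raw parameter values to the unit hypercube
#'
#' Affine map of each input from its `[low, high]` design range to
#' `[0, 1]`. Values outside the range are clamped with a warning.
#'
#' @param space An `input_space`.
#' @param raw A data frame / tibble (rows = runs) or a named list of raw
#'   values; names must match `space$name`.
#' @return A tibble of normalized values with one column per input.
#' @export
normalize_inputs <- function(space, raw) {
  if (!is.data.frame(raw)) raw <- tibble::as_tibble(raw[space$name])
  missing <- setdiff(space$name, names(raw))
  if (length(missing) > 0) {
    stop("missing input(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(space)), function(i) {
    x <- raw[[space$name[i]]]
    z <- (x - space$low[i]) / (space$high[i] - space$low[i])
    if (any(z < -1e-9 | z > 1 + 1e-9)) {
      warning("values of ", space$name[i],
              " outside the design range were clamped to [0, 1]")
    }
    pmin(pmax(z, 0), 1)
  })
  names(out) <- space$name
  tibble::as_tibble(out)
}

#' @rdname normalize_inputs
#' @param normalized Tibble/matrix of values in `[0, 1]`, columns matching
#'   `space$name`.
#' @return `denormalize_inputs()`: a tibble of raw values.
#' @export
denormalize_inputs <- function(space, normalized) {
  normalized <- tibble::as_tibble(as.data.frame(normalized))
  out <- lapply(seq_len(nrow(space)), function(i) {
    z <- normalized[[space$name[i]]]
    space$low[i] + z * (space$high[i] - space$low[i])
  })
  names(out) <- space$name
  tibble::as_tibble(out)
}

#' Maximin-optimized Latin hypercube design
#'
#' Draws `optimize_iters` candidate Latin hypercube samples of size `n`
#' over the normalized input space and returns the candidate maximizing
#' the minimum pairwise Euclidean distance. Each column of the result has
#' exactly one point per stratum `[k/n, (k+1)/n)`.
#'
#' @param n Number of design points (>= 2).
#' @param space An `input_space` (or an integer number of columns).
#' @param seed Integer seed; the same seed reproduces the same design.
#' @param optimize_iters Number of candidate hypercubes to compare.
#' @return A tibble of class `design_matrix` with one `[0, 1]` column per
#'   input and attributes `seed`, `optimize_iters`, `min_distance`.
#' @export
latin_hypercube <- function(n, space, seed = 1L, optimize_iters = 50L) {
  if (n < 2) stop("n must be at least 2")
  nm <- if (is.numeric(space)) paste0("x", seq_len(space)) else space$name
  P <- length(nm)
  best <- NULL
  best_d <- -Inf
  with_seed(seed, {
    for (i in seq_len(max(1L, optimize_iters))) {
      cand <- lhs::randomLHS(n, P)
      d <- min(dist(cand))
      if (d > best_d) {
        best_d <- d
        best <- cand
      }
    }
  })
  colnames(best) <- nm
  out <- tibble::as_tibble(best)
  attr(out, "seed") <- seed
  attr(out, "optimize_iters") <- optimize_iters
  attr(out, "min_distance") <- best_d
  if (!is.numeric(space)) attr(out, "space") <- space
  class(out) <- c("design_matrix", class(out))
  out
}
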