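biomarker_names <- c("dVdt_max", "V_max", "V_20", "V_40", "V_60", "V_80",
                     "APD_50", "APD_90", "RestVm", "Ca_min", "Ca_max")

#' Stage configuration
#'
#' Defaults follow the study design: 300 design and 150 validation runs
#' for Stage 1 (40 beats at a cycle length of 1000 ms), 200 and 100 for
#' Stage 2 (39 S1 beats plus an S2 whose diastolic interval is a design
#' input).
#'
#' @param model `"courtemanche"`, `"maleckar"`, or `"toy"`.
#' @param stage 1 or 2.
#' @param n_design,n_validation Number of design / validation runs.
#' @param cl Cycle length (ms).
#' @param n_beats Number of S1 beats.
#' @param seed Master seed; all child seeds derive from it.
#' @param dt_out Trace sampling interval (ms).
#' @param solver [solver_settings()].
#' @param restarts Emulator-training restarts.
#' @param outputs Biomarkers to emulate (default all 11).
#' @return A `stage_config` list.
#' @export
stage_config <- function(model, stage = 1,
                         n_design = if (stage == 1) 300 else 200,
                         n_validation = if (stage == 1) 150 else 100,
                         cl = 1000, n_beats = if (stage == 1) 40 else 39,
                         seed = 1L, dt_out = 0.5,
                         solver = solver_settings(), restarts = 10,
                         outputs = biomarker_names) {
  space <- build_input_space(model, stage)
  if (n_design <= nrow(space) + 3) {
    stop("n_design must exceed the input dimension + 3")
  }
  structure(list(model = model, stage = stage, n_design = n_design,
                 n_validation = n_validation, cl = cl, n_beats = n_beats,
                 seed = as.integer(seed), dt_out = dt_out, solver = solver,
                 restarts = restarts, outputs = outputs, space = space),
            class = "stage_config")
}

# Simulate every row of a normalized design and collect biomarkers and
# exclusion decisions. Rows that error (solver failure / no capture) are
# excluded with the corresponding reason.
simulate_design_runs <- function(config, design, progress = FALSE) {
  space <- config$space
  raw <- denormalize_inputs(space, design)
  has_di <- "DI" %in% space$name
  n <- nrow(design)
  rows <- vector("list", n)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- as.list(raw[i, setdiff(names(raw), "DI"), drop = FALSE])
    proto <- pacing_protocol(cl = config$cl, n_beats = config$n_beats,
                             s2_di = if (has_di) raw$DI[i] else NULL)
    res <- tryCatch({
      tr <- if (config$model == "toy") {
        simulate_toy_ap(pars, proto, dt_out = config$dt_out)
      } else {
        simulate_ap(config$model, pars, proto, config$solver,
                    dt_out = config$dt_out)
      }
      bm <- trace_biomarkers(tr)
      list(bm = bm, flt = plausibility_filter(bm))
    }, error = function(e) {
      list(bm = NULL,
           flt = tibble::tibble(keep = FALSE,
                                reasons = paste0("no_capture")))
    })
    rows[[i]] <- if (!is.null(res$bm$final)) res$bm$final else {
      tibble::as_tibble(setNames(as.list(rep(NA_real_,
                                             length(biomarker_names))),
                                 biomarker_names))
    }
    excl[[i]] <- res$flt
    if (progress && i %% 25 == 0) message("  run ", i, "/", n)
  }
  bms <- dplyr::bind_rows(rows)[, biomarker_names]
  ex <- dplyr::bind_rows(excl)
  ex$run <- seq_len(n)
  list(biomarkers = bms, exclusions = ex[, c("run", "keep", "reasons")])
}

#' Run a full analysis stage
#'
#' End-to-end orchestration: Latin-hypercube design, simulator runs,
#' plausibility filtering, one emulator per output, held-out validation
#' (MAPE and median ISE), signed first-order and total-effect indices,
#' main-effect curves, and standardized regression indices. Fully
#' reproducible from `(config, seed)`.
#'
#' @param config A [stage_config()].
#' @param progress Print progress messages.
#' @return An object of class `stage_result`.
#' @export
run_stage <- function(config, progress = FALSE) {
  space <- config$space
  seed <- config$seed
  design <- latin_hypercube(config$n_design, space, seed = seed)
  if (progress) message("simulating ", config$n_design, " design runs")
  des <- simulate_design_runs(config, design, progress = progress)
  kept <- which(des$exclusions$keep)
  if (length(kept) <= nrow(space) + 3) {
    stop("too few kept design runs (", length(kept), ")")
  }
  X <- as.matrix(design)[kept, , drop = FALSE]
  Y <- as.matrix(des$biomarkers)[kept, , drop = FALSE]

  val_design <- latin_hypercube(config$n_validation, space,
                                seed = child_seed(seed, 777001L))
  if (progress) message("simulating ", config$n_validation,
                        " validation runs")
  val <- simulate_design_runs(config, val_design, progress = progress)
  vkept <- which(val$exclusions$keep)
  Xv <- as.matrix(val_design)[vkept, , drop = FALSE]
  Yv <- as.matrix(val$biomarkers)[vkept, , drop = FALSE]

  u <- uncertain_inputs(space)
  emulators <- list()
  validation <- list()
  sens <- list()
  meffs <- list()
  for (k in seq_along(config$outputs)) {
    out_nm <- config$outputs[k]
    if (progress) message("emulating ", out_nm)
    em <- gp_train(X, Y[, out_nm], restarts = config$restarts,
                   seed = child_seed(seed, k))
    emulators[[out_nm]] <- em
    vr <- gp_validate(em, Xv, Yv[, out_nm])
    validation[[out_nm]] <- tibble::tibble(
      output = out_nm, mape = vr$mape, median_ise = vr$median_ise,
      n_validation = vr$n)
    si <- sobol_indices(em, u)
    si$output <- out_nm
    sens[[out_nm]] <- si
    me <- main_effect(em, u)
    me$output <- out_nm
    meffs[[out_nm]] <- me
  }
  sens_tb <- dplyr::bind_rows(lapply(sens, tibble::as_tibble))
  reg <- regression_indices(X, Y[, config$outputs, drop = FALSE])

  structure(list(
    config = config, design = design, val_design = val_design,
    biomarkers = des$biomarkers, exclusions = des$exclusions,
    val_biomarkers = val$biomarkers, val_exclusions = val$exclusions,
    emulators = emulators,
    validation = dplyr::bind_rows(validation),
    sensitivity = sens_tb,
    main_effects = dplyr::bind_rows(meffs),
    regression = reg,
    kept = kept, val_kept = vkept
  ), class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat("<stage_result>", x$config$model, "stage", x$config$stage, "\n")
  cat("  design runs:", x$config$n_design, "(", length(x$kept), "kept )\n")
  cat("  emulated outputs:", length(x$emulators), "\n")
  invisible(x)
}

#' @export
glance.stage_result <- function(x, ...) {
  tibble::tibble(
    model = x$config$model, stage = x$config$stage,
    n_design = x$config$n_design, n_kept = length(x$kept),
    n_excluded = x$config$n_design - length(x$kept),
    worst_mape = max(x$validation$mape),
    worst_median_ise = max(x$validation$median_ise)
  )
}

#' @export
tidy.stage_result <- function(x, ...) x$sensitivity

#' Write the artifact bundle of a stage run
#'
#' CSV tables (design, biomarkers, exclusions, validation, signed
#' first-order and total-effect indices, interaction differences,
#' main-effect curves, regression coefficients), JSON-serialized
#' emulators, and the configuration.
#'
#' @param result A `stage_result`.
#' @param dir Output directory (created if needed).
#' @export
write_stage_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, nm) utils::write.csv(as.data.frame(x),
                                           file.path(dir, nm),
                                           row.names = FALSE)
  wcsv(result$design, "design_normalized.csv")
  wcsv(denormalize_inputs(result$config$space, result$design),
       "design_raw.csv")
  wcsv(result$biomarkers, "biomarkers.csv")
  wcsv(result$exclusions, "exclusions.csv")
  wcsv(result$validation, "validation.csv")
  sens <- result$sensitivity
  wide <- function(col) {
    tidyr::pivot_wider(sens[, c("output", "input", col)],
                       names_from = "input",
                       values_from = dplyr::all_of(col))
  }
  wcsv(wide("S_signed"), "first_order_indices.csv")
  wcsv(wide("S_T"), "total_effect_indices.csv")
  wcsv(wide("interaction"), "interaction_differences.csv")
  wcsv(result$main_effects, "main_effects.csv")
  wcsv(result$regression$coefs, "regression_indices.csv")
  emdir <- file.path(dir, "emulators")
  dir.create(emdir, showWarnings = FALSE)
  for (nm in names(result$emulators)) {
    write_gp(result$emulators[[nm]], file.path(emdir, paste0(nm, ".json")))
  }
  cfg <- result$config
  cfg$space <- NULL
  cfg$solver <- unclass(cfg$solver)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Targeted G_Kur verification simulations
#'
#' Runs each cell model for 40 beats at a cycle length of 1000 ms with
#' the ultra-rapid K+ conductance at 50%, 100%, and 150% of its default,
#' reporting the final-beat APD90 and the I_Kur, I_CaL and I_Kr current
#' traces of the final beat. Used to confirm the emulator main-effect
#' prediction that decreasing G_Kur lengthens the action potential in
#' the Maleckar model but slightly shortens it in the Courtemanche
#' model.
#'
#' @param model `"courtemanche"` or `"maleckar"`.
#' @param levels Multipliers applied to the default conductance.
#' @param protocol Pacing protocol.
#' @param solver Solver settings.
#' @return List with `apd` (tibble `level`, `APD_90`) and `currents`
#'   (final-beat traces per level).
#' @export
gkur_experiment <- function(model = c("courtemanche", "maleckar"),
                            levels = c(0.5, 1.0, 1.5),
                            protocol = pacing_protocol(cl = 1000,
                                                       n_beats = 40),
                            solver = solver_settings()) {
  model <- match.arg(model)
  par_name <- if (model == "courtemanche") "fG_Kur" else "G_Kur"
  central <- model_defaults(model)[[par_name]]
  res <- lapply(levels, function(lv) {
    pars <- setNames(list(central * lv), par_name)
    tr <- simulate_ap(model, pars, protocol, solver, keep_currents = TRUE)
    bm <- extract_biomarkers(tr)
    stim <- attr(tr, "stim_times")
    fin <- tr[tr$time_ms >= stim[length(stim)], , drop = FALSE]
    fin <- tibble::as_tibble(fin)
    fin$level <- lv
    list(apd = tibble::tibble(level = lv, APD_90 = bm$APD_90),
         currents = fin[, c("level", "time_ms", "V_mV",
                            "I_Kur", "I_CaL", "I_Kr")])
  })
  list(model = model,
       apd = dplyr::bind_rows(lapply(res, `[[`, "apd")),
       currents = dplyr::bind_rows(lapply(res, `[[`, "currents")))
}

#' Principal-component summary of the output matrix
#'
#' Eigen-decomposition of the correlation matrix of the (kept-run)
#' biomarker matrix, with cumulative explained-variance fractions and
#' the number of components needed to reach a target fraction.
#'
#' @param Y Output matrix / data frame (rows = kept runs).
#' @param target Cumulative variance fraction of interest.
#' @return Tibble with `component`, `eigenvalue`, `prop_var`, `cum_var`;
#'   attribute `n_target` gives the first component count reaching
#'   `target`.
#' @export
pca_outputs <- function(Y, target = 0.95) {
  Ys <- standardize(Y)
  ev <- eigen(cor(as.matrix(Y)), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  prop <- ev / sum(ev)
  out <- tibble::tibble(component = seq_along(ev), eigenvalue = ev,
                        prop_var = prop, cum_var = cumsum(prop))
  attr(out, "n_target") <- which(out$cum_var >= target)[1]
  out
}
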