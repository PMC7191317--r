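#' Default parameter assignments for a cell model
#'
#' Returns the central (default) values of the tunable inputs for the
#' Courtemanche, Maleckar, or toy action-potential model. These are the
#' values around which the design ranges are defined, and any subset of
#' them can be overridden when simulating.
#'
#' @param model `"courtemanche"`, `"maleckar"`, or `"toy"`.
#' @return Named list of default input values (raw units).
#' @export
model_defaults <- function(model = c("courtemanche", "maleckar", "toy")) {
  model <- match.arg(model)
  switch(model,
    courtemanche = list(
      G_Na = 7.8, G_K1 = 0.09, G_to = 0.165, fG_Kur = 1.0, G_Kr = 0.0294,
      G_Ks = 0.1294, G_CaL = 0.1237, G_bNa = 0.0006, G_bCa = 0.0011,
      i_NaK_max = 0.5993, i_NaCa_max = 1600.0, i_pCa_max = 0.275,
      K_rel = 30.0, tau_tr = 180.0, i_up_max = 0.005, K_up = 0.00092,
      C_m = 100.0, Na_o = 140.0, K_o = 5.4, Ca_o = 1.8
    ),
    maleckar = list(
      P_Na = 0.0018, G_K1 = 3.1, G_t = 8.25, G_Kur = 2.25, G_Kr = 0.5,
      G_Ks = 1.0, G_CaL = 6.75, G_bNa = 0.0605, G_bCa = 0.0590,
      i_NaK_max = 68.55, K_NaCa = 0.0750, i_pCa_max = 4.0,
      alpha_rel = 200000, tau_tr = 0.01, i_up_max = 2800,
      K_cyca = 0.0003, K_srca = 0.5, K_xcs = 0.4,
      C_m = 50.0, Na_o = 140.0, K_o = 5.4, Ca_o = 1.8
    ),
    toy = list(
      upstroke_slope = 100, peak = 20, plateau = -5, apd_scale = 300,
      rest = -80, ca_min = 1e-4, ca_max = 7e-4, rest_coef = 0.2,
      rest_tau = 100
    )
  )
}

#' Pacing protocol description
#'
#' S1 pacing at a fixed cycle length, optionally followed by a single S2
#' stimulus. The S2 stimulus is delivered at the last S1 onset plus the
#' APD90 of that final S1 beat, plus a 10 ms offset, plus the diastolic
#' interval `s2_di`.
#'
#' @param cl Cycle length in ms.
#' @param n_beats Number of S1 beats.
#' @param s2_di Diastolic interval of the S2 beat in ms, or `NULL` for
#'   plain S1 pacing.
#' @param s2_offset Offset in ms added between APD90 of the final S1 beat
#'   and the start of the diastolic interval.
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cl = 1000, n_beats = 40, s2_di = NULL,
                            s2_offset = 10) {
  stopifnot(cl > 0, n_beats >= 1)
  if (!is.null(s2_di) && (s2_di < 0 || !is.finite(s2_di))) {
    stop("s2_di must be a non-negative finite diastolic interval (ms)")
  }
  structure(
    list(cl = cl, n_beats = as.integer(n_beats), s2_di = s2_di,
         s2_offset = s2_offset),
    class = "pacing_protocol"
  )
}

#' Stiff-solver settings
#'
#' @param rtol,atol Relative and absolute tolerances.
#' @param max_step Maximum time step in ms.
#' @param method deSolve integration method tag (adaptive, stiff-capable).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-6, max_step = 0.5,
                            method = "lsoda") {
  stopifnot(rtol > 0, atol > 0, max_step > 0)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 method = method),
            class = "solver_settings")
}

# Published initial conditions
crn_initial_state <- function() {
  c(V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775,
    oa = 0.03043, oi = 0.9992, ua = 0.004966, ui = 0.9986,
    xr = 3.296e-5, xs = 0.01869, d = 1.367e-4, f = 0.9996,
    fCa = 0.7755, u = 0.0, v = 1.0, w = 0.9992,
    Nai = 11.17, Ki = 139.0, Cai = 1.013e-4,
    Caup = 1.488, Carel = 1.488)
}

mal_initial_state <- function() {
  c(V = -74.031982, m = 0.0032017, h1 = 0.8814, h2 = 0.8742,
    dL = 1.3005e-5, fL1 = 0.9986, fL2 = 0.9986,
    r = 0.0010678, s = 0.949, a_ur = 0.000367, i_ur = 0.9673,
    n = 0.0046, pa = 5.3e-5,
    Nac = 130.022096, Kc = 5.560224, Cac = 1.8147,
    Nai = 8.5547, Ki = 129.435, Cai = 6.5e-5, Cad = 7.1e-5,
    O_C = 0.0275, O_TC = 0.0133, O_TMgC = 0.1961, O_TMgMg = 0.7094,
    O_Calse = 0.43686, Carel = 0.6465, Caup = 0.6646,
    F1 = 0.4284, F2 = 0.0028)
}

# Order of the compiled-model parameter vectors
crn_par_order <- c("G_Na", "G_K1", "G_to", "fG_Kur", "G_Kr", "G_Ks", "G_CaL",
                   "G_bNa", "G_bCa", "i_NaK_max", "i_NaCa_max", "i_pCa_max",
                   "K_rel", "tau_tr", "i_up_max", "K_up", "C_m",
                   "Na_o", "K_o", "Ca_o")
mal_par_order <- c("P_Na", "G_K1", "G_t", "G_Kur", "G_Kr", "G_Ks", "G_CaL",
                   "G_bNa", "G_bCa", "i_NaK_max", "K_NaCa", "i_pCa_max",
                   "alpha_rel", "tau_tr", "i_up_max", "K_cyca", "K_srca",
                   "K_xcs", "C_m", "Na_o", "K_o", "Ca_o")

check_params <- function(model, params) {
  defaults <- model_defaults(model)
  if (is.null(params)) return(defaults)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad) > 0) {
    stop("unknown parameter name(s) for model '", model, "': ",
         paste(bad, collapse = ", "))
  }
  out <- modifyList(defaults, as.list(params))
  if (model != "toy") {
    pos <- vapply(defaults, function(x) is.numeric(x) && x > 0, logical(1))
    neg_given <- names(out)[pos & unlist(out) <= 0]
    if (length(neg_given) > 0) {
      stop("parameter(s) must be strictly positive: ",
           paste(neg_given, collapse = ", "))
    }
  }
  out
}

new_ap_trace <- function(df, model, params, protocol, solver, stim_times) {
  out <- tibble::as_tibble(df)
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  attr(out, "solver") <- solver
  attr(out, "stim_times") <- unname(stim_times)
  class(out) <- c("ap_trace", class(out))
  out
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace> model:", attr(x, "model"),
      " beats:", length(attr(x, "stim_times")),
      " span:", round(max(x$time_ms)), "ms\n")
  NextMethod()
}

# Integrate one model segment with the stimulus flag set on or off.
# `state` is the full state vector; returns the deSolve output matrix.
ode_segment <- function(state, t0, t1, parms_vec, stim_on, funcs, solver,
                        dt_out, time_scale, keep_currents) {
  # time_scale: 1 for ms-based models, 1000 for s-based (inputs are ms)
  times <- unique(c(seq(t0, t1, by = dt_out), t1)) / time_scale
  pv <- c(parms_vec, stim_on)
  out <- deSolve::ode(
    y = state, times = times, func = funcs$derivs, parms = pv,
    dllname = "apsens", initfunc = funcs$init,
    nout = 3, outnames = c("I_Kur", "I_CaL", "I_Kr"),
    rtol = solver$rtol, atol = solver$atol,
    hmax = solver$max_step / time_scale, method = solver$method
  )
  if (any(!is.finite(out))) {
    bad_t <- min(out[!stats::complete.cases(out), 1], na.rm = TRUE)
    stop(sprintf("solver produced non-finite state near t = %.1f ms",
                 bad_t * time_scale))
  }
  out
}

#' Simulate an atrial myocyte action potential train
#'
#' Runs the Courtemanche or Maleckar cell model under an S1 (or S1-S2)
#' pacing protocol with a stiff adaptive solver. In the Courtemanche model
#' the intracellular Na+ and K+ concentrations are held at 11.17 and
#' 139.00 mM; in the Maleckar model the acetylcholine-activated K+ current
#' is zero. Stimuli are square pulses of inward current: 2000 pA for 2 ms
#' (Courtemanche) and 750 pA, i.e. 750/Cm pA/pF, for 6 ms (Maleckar).
#'
#' @param model `"courtemanche"` or `"maleckar"`.
#' @param params Named list/vector overriding any subset of
#'   [model_defaults()] (raw units).
#' @param protocol A [pacing_protocol()].
#' @param solver A [solver_settings()].
#' @param dt_out Output sampling interval in ms.
#' @param keep_currents If `TRUE`, include I_Kur, I_CaL and I_Kr
#'   (pA/pF) as trace columns.
#' @return An `ap_trace` tibble with columns `time_ms`, `V_mV`, `Ca_mM`
#'   and attributes `stim_times`, `model`, `params`, `protocol`, `solver`.
#' @export
simulate_ap <- function(model = c("courtemanche", "maleckar"), params = NULL,
                        protocol = pacing_protocol(),
                        solver = solver_settings(), dt_out = 0.5,
                        keep_currents = FALSE) {
  model <- match.arg(model)
  p <- check_params(model, params)
  if (model == "courtemanche") {
    funcs <- list(derivs = "crn_derivs", init = "crn_init")
    order <- crn_par_order
    pvec <- unlist(p[order])
    pvec <- c(pvec, stim_amp = 2000)
    stim_dur <- 2
    time_scale <- 1
    state <- crn_initial_state()
    state["Nai"] <- 11.17
    state["Ki"] <- 139.0
    ca_name <- "Cai"
  } else {
    funcs <- list(derivs = "mal_derivs", init = "mal_init")
    order <- mal_par_order
    pl <- p
    pl$C_m <- pl$C_m / 1000 # pF -> nF
    pvec <- unlist(pl[order])
    pvec <- c(pvec, stim_amp = 750)
    stim_dur <- 6
    time_scale <- 1000
    state <- mal_initial_state()
    ca_name <- "Cai"
  }

  cl <- protocol$cl
  nb <- protocol$n_beats
  stim_times <- (seq_len(nb) - 1) * cl
  pieces <- list()
  # the upstroke lasts ~1 ms; sample it densely so the maximum dV/dt is
  # resolved (mirrors the dense steps an adaptive solver takes there),
  # and coarsely elsewhere
  dt_fine <- min(dt_out, 0.02)
  fine_until <- stim_dur + 10
  run_segment <- function(state, t0, t1, on, dt) {
    ode_segment(state, t0, t1, pvec, on, funcs, solver, dt,
                time_scale, keep_currents)
  }
  step_state <- function(seg) {
    s <- seg[nrow(seg), 1 + seq_along(state)]
    names(s) <- names(crn_or_mal_state_names(model))
    s
  }
  for (b in seq_len(nb)) {
    t0 <- stim_times[b]
    seg1 <- run_segment(state, t0, t0 + stim_dur, 1, dt_fine)
    state <- step_state(seg1)
    seg1b <- run_segment(state, t0 + stim_dur, t0 + fine_until, 0, dt_fine)
    state <- step_state(seg1b)
    seg2 <- run_segment(state, t0 + fine_until, t0 + cl, 0, dt_out)
    state <- step_state(seg2)
    pieces[[length(pieces) + 1]] <- seg1[-nrow(seg1), , drop = FALSE]
    pieces[[length(pieces) + 1]] <- seg1b[-nrow(seg1b), , drop = FALSE]
    pieces[[length(pieces) + 1]] <- seg2[-nrow(seg2), , drop = FALSE]
    last_row <- seg2[nrow(seg2), , drop = FALSE]
  }
  pieces[[length(pieces) + 1]] <- last_row
  out <- do.call(rbind, pieces)

  if (!is.null(protocol$s2_di)) {
    # anchor APD90 of the final S1 beat at its activation, then add the
    # guard offset and the requested diastolic interval
    tr_tmp <- assemble_trace(out, model, p, protocol, solver, stim_times,
                             time_scale, keep_currents, ca_name)
    act <- detect_activations(tr_tmp)
    bm <- extract_biomarkers(tr_tmp, beat = nb)
    if (!is.finite(bm$APD_90)) {
      stop("final S1 beat did not repolarize; S2 timing undefined")
    }
    s2_time <- stim_times[nb] + bm$APD_90 + protocol$s2_offset +
      protocol$s2_di
    s2_time <- round(s2_time / dt_out) * dt_out
    # restart from the stored state at s2_time
    keep <- out[, 1] * time_scale <= s2_time + 1e-9
    out <- out[keep, , drop = FALSE]
    state <- out[nrow(out), 1 + seq_len(ncol(out) - 4)]
    names(state) <- names(crn_or_mal_state_names(model))
    seg1 <- run_segment(state, s2_time, s2_time + stim_dur, 1, dt_fine)
    state <- step_state(seg1)
    seg1b <- run_segment(state, s2_time + stim_dur,
                         s2_time + fine_until, 0, dt_fine)
    state <- step_state(seg1b)
    seg2 <- run_segment(state, s2_time + fine_until, s2_time + cl, 0,
                        dt_out)
    out <- rbind(out[-nrow(out), , drop = FALSE],
                 seg1[-nrow(seg1), , drop = FALSE],
                 seg1b[-nrow(seg1b), , drop = FALSE], seg2)
    stim_times <- c(stim_times, s2_time)
  }

  assemble_trace(out, model, p, protocol, solver, stim_times,
                 time_scale, keep_currents, ca_name)
}

crn_or_mal_state_names <- function(model) {
  if (model == "courtemanche") crn_initial_state() else mal_initial_state()
}

assemble_trace <- function(out, model, p, protocol, solver, stim_times,
                           time_scale, keep_currents, ca_name) {
  df <- tibble::tibble(
    time_ms = out[, 1] * time_scale,
    V_mV = out[, "V"],
    Ca_mM = out[, ca_name]
  )
  if (keep_currents) {
    df$I_Kur <- out[, "I_Kur"]
    df$I_CaL <- out[, "I_CaL"]
    df$I_Kr <- out[, "I_Kr"]
  }
  new_ap_trace(df, model, p, protocol, solver, stim_times)
}

#' Export a trace and its metadata
#'
#' Writes `time_ms, V_mV, Ca_mM` columns as CSV with a JSON sidecar
#' holding parameters, protocol and solver settings.
#'
#' @param trace An `ap_trace`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(
    model = attr(trace, "model"),
    params = attr(trace, "params"),
    protocol = unclass(attr(trace, "protocol")),
    solver = unclass(attr(trace, "solver")),
    stim_times = attr(trace, "stim_times")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
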