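#' Detect action-potential activations in a trace
#'
#' An activation is a sustained fast upstroke: a contiguous run of samples
#' with dV/dt above `slope_thresh` whose total voltage excursion exceeds
#' `min_amp`. Each upstroke occurring within `window` ms of a stimulus is
#' attributed to that stimulus; any other upstroke is reported as
#' spontaneous (pacemaking-like) activity.
#'
#' @param trace An `ap_trace`.
#' @param window Capture window after each stimulus onset, ms.
#' @param slope_thresh Minimum dV/dt (mV/ms) counting as upstroke.
#' @param min_amp Minimum voltage excursion (mV) of an upstroke event.
#' @return A tibble with columns `time` (ms, moment of maximum dV/dt),
#'   `stimulus` (index of the triggering stimulus or `NA`), and
#'   `spontaneous` (logical).
#' @export
detect_activations <- function(trace, window = 50, slope_thresh = 5,
                               min_amp = 10) {
  t <- trace$time_ms
  v <- trace$V_mV
  stim <- attr(trace, "stim_times")
  dv <- diff(v) / diff(t)
  fast <- dv >= slope_thresh
  if (!any(fast)) {
    return(tibble::tibble(time = numeric(0), stimulus = integer(0),
                          spontaneous = logical(0)))
  }
  # group contiguous fast samples into events (gaps > 20 ms split events)
  idx <- which(fast)
  brk <- c(TRUE, diff(t[idx]) > 20)
  grp <- cumsum(brk)
  ev <- lapply(split(idx, grp), function(ii) {
    amp <- v[max(ii) + 1L] - v[min(ii)]
    if (amp < min_amp) return(NULL)
    peak <- ii[which.max(dv[ii])]
    t[peak]
  })
  times <- unname(unlist(ev))
  if (is.null(times)) times <- numeric(0)
  stim_idx <- vapply(times, function(tt) {
    k <- which(tt >= stim & tt <= stim + window)
    if (length(k) == 0) NA_integer_ else k[1L]
  }, integer(1))
  tibble::tibble(time = times, stimulus = stim_idx,
                 spontaneous = is.na(stim_idx))
}

#' Extract action-potential and calcium biomarkers for one beat
#'
#' Computes the eleven outputs characterizing the action potential and
#' calcium transient of the beat triggered by stimulus `beat`:
#' maximum upstroke slope, peak voltage, voltages at 20/40/60/80% of
#' APD90, APD50 and APD90, resting potential, and the minimum and maximum
#' intracellular calcium over the beat's cycle. APDx is measured from the
#' activation time to the first crossing of the level
#' `V_max - x% * (V_max - RestVm)`, with linear interpolation. RestVm is
#' the mean voltage over a 10 ms window ending 100 ms before the upstroke.
#'
#' @param trace An `ap_trace`.
#' @param beat Stimulus index of the beat to analyze (default: final).
#' @param activations Optional result of [detect_activations()] (computed
#'   if missing).
#' @return A one-row tibble with the 11 biomarker columns plus a
#'   `repolarized` flag; APDs are `NA` when the repolarization level is
#'   never reached before the next beat.
#' @export
extract_biomarkers <- function(trace, beat = NULL, activations = NULL) {
  t <- trace$time_ms
  v <- trace$V_mV
  ca <- trace$Ca_mM
  stim <- attr(trace, "stim_times")
  if (is.null(beat)) beat <- length(stim)
  if (beat < 1 || beat > length(stim)) stop("beat index out of range")
  if (is.null(activations)) activations <- detect_activations(trace)
  act_row <- activations[!activations$spontaneous &
                           activations$stimulus == beat, , drop = FALSE]
  if (nrow(act_row) == 0) {
    stop("no capture: stimulus ", beat, " did not elicit an upstroke")
  }
  act <- act_row$time[1L]

  cyc_end <- if (beat < length(stim)) stim[beat + 1L] else max(t)
  in_cyc <- t >= act & t <= cyc_end
  v_max <- max(v[in_cyc])
  t_peak <- t[in_cyc][which.max(v[in_cyc])]

  rest_win <- t >= act - 110 & t <= act - 100
  rest_vm <- if (any(rest_win)) mean(v[rest_win]) else v[which.min(abs(t - act))[1]]

  amp <- v_max - rest_vm
  apd_at <- function(frac) {
    level <- v_max - frac * amp
    i_peak <- which(t >= t_peak)[1L]
    i_end <- max(which(t <= cyc_end))
    tc <- first_down_crossing(t[i_peak:i_end], v[i_peak:i_end], level)
    if (is.na(tc)) NA_real_ else tc - act
  }
  apd50 <- apd_at(0.50)
  apd90 <- apd_at(0.90)

  # upstroke slope within the capture window of this stimulus
  up_win <- t >= stim[beat] & t <= act + 20
  dv <- diff(v) / diff(t)
  dvdt_max <- max(dv[up_win[-length(up_win)]], na.rm = TRUE)

  vp <- function(frac) {
    if (is.na(apd90)) return(NA_real_)
    lin_interp(t, v, act + frac * apd90)
  }

  tibble::tibble(
    dVdt_max = dvdt_max,
    V_max = v_max,
    V_20 = vp(0.2), V_40 = vp(0.4), V_60 = vp(0.6), V_80 = vp(0.8),
    APD_50 = apd50, APD_90 = apd90,
    RestVm = rest_vm,
    Ca_min = min(ca[in_cyc]), Ca_max = max(ca[in_cyc]),
    repolarized = is.finite(apd90)
  )
}

#' Biomarkers of the eleven-output panel for a whole run
#'
#' Convenience wrapper: extracts biomarkers for the final (analysis) beat
#' and for the final pair of S1 beats needed by the plausibility filter.
#'
#' @param trace An `ap_trace`.
#' @return A list with `final` (one-row biomarker tibble of the analysis
#'   beat), `pair` (biomarkers of the final two S1 beats), and
#'   `activations`.
#' @export
trace_biomarkers <- function(trace) {
  stim <- attr(trace, "stim_times")
  proto <- attr(trace, "protocol")
  has_s2 <- !is.null(proto$s2_di)
  act <- detect_activations(trace)
  n_s1 <- if (has_s2) length(stim) - 1L else length(stim)
  final_beat <- length(stim)
  pair_idx <- c(n_s1 - 1L, n_s1)
  pair <- lapply(pair_idx, function(b) {
    tryCatch(extract_biomarkers(trace, b, act), error = function(e) NULL)
  })
  final <- tryCatch(extract_biomarkers(trace, final_beat, act),
                    error = function(e) NULL)
  list(final = final, pair = pair, activations = act,
       pair_beats = pair_idx)
}

#' Plausibility filter for simulator runs
#'
#' A run is excluded from design data if it shows unphysiological
#' behavior: spontaneous (pacemaking) activity, a resting potential above
#' -60 mV, APD90 above 600 ms (including failure to repolarize), or APD
#' alternans, defined as the APD90 of the final pair of S1 beats
#' differing by more than 5% (relative to the later beat). The resting
#' potential and APD criteria are judged on the final S1 beat: for a
#' plain S1 run that is the analysis beat itself, while for an S1-S2 run
#' it keeps the criteria about the model's paced behavior rather than
#' about the deliberately premature S2 beat (whose pre-upstroke window
#' can overlap the previous repolarization at short diastolic
#' intervals). Runs whose required beats cannot be measured are excluded
#' as `incomplete` or `no_capture`.
#'
#' @param bm Result of [trace_biomarkers()] for one run.
#' @return A one-row tibble with `keep` (logical) and `reasons`
#'   (comma-separated reason codes, empty when kept).
#' @export
plausibility_filter <- function(bm) {
  reasons <- character(0)
  if (any(bm$activations$spontaneous)) reasons <- c(reasons, "pacemaking")
  # reference beat for the rest/APD criteria: the final S1 beat
  ref <- if (!is.null(bm$pair) && !is.null(bm$pair[[2]])) {
    bm$pair[[2]]
  } else {
    bm$final
  }
  if (is.null(bm$final)) {
    reasons <- c(reasons, "no_capture")
  } else if (!is.null(ref)) {
    if (ref$RestVm > -60) reasons <- c(reasons, "depolarized_rest")
    if (!is.finite(ref$APD_90) || ref$APD_90 > 600) {
      reasons <- c(reasons, "long_apd")
    }
  }
  p <- bm$pair
  if (any(vapply(p, is.null, logical(1)))) {
    if (!"no_capture" %in% reasons) reasons <- c(reasons, "incomplete")
  } else {
    a39 <- p[[1]]$APD_90
    a40 <- p[[2]]$APD_90
    if (!is.finite(a39) || !is.finite(a40)) {
      if (!"long_apd" %in% reasons) reasons <- c(reasons, "long_apd")
    } else if (abs(a39 - a40) / a40 > 0.05) {
      reasons <- c(reasons, "alternans")
    }
  }
  tibble::tibble(keep = length(reasons) == 0,
                 reasons = paste(reasons, collapse = ","))
}
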