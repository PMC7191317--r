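#' Closed-form toy action-potential generator
#'
#' A fast, fully analytic stand-in for a myocyte simulator, so that the
#' design/biomarker/emulator/sensitivity pipeline can be exercised in
#' milliseconds. Each beat is a piecewise-linear waveform: a linear
#' upstroke from `rest` to `peak` at `upstroke_slope` mV/ms, a fast early
#' repolarization from `peak` to `plateau` over the first 20% of the
#' repolarization time, and a slow phase from `plateau` back to `rest`.
#' The repolarization time is set so that the 90% repolarization level is
#' crossed exactly `apd` ms after the end of the upstroke, where
#' `apd = apd_scale * (1 - rest_coef * exp(-DI / rest_tau))` gives a
#' monotone APD restitution when `rest_coef > 0`. The calcium transient
#' rises linearly from `ca_min` to `ca_max` during the upstroke and
#' relaxes linearly back to `ca_min` at the end of repolarization.
#'
#' Every biomarker of the eleven-output panel is an analytic function of
#' the parameters (see [toy_biomarkers()]), and each parameter acts
#' monotonically, so downstream sign assignments have unambiguous ground
#' truth.
#'
#' @param params Named list overriding [model_defaults("toy")][model_defaults].
#' @param protocol A [pacing_protocol()].
#' @param dt_out Sampling interval in ms.
#' @return An `ap_trace` tibble.
#' @export
simulate_toy_ap <- function(params = NULL, protocol = pacing_protocol(),
                            dt_out = 0.5) {
  p <- check_params("toy", params)
  if (p$apd_scale <= 0) stop("apd_scale must be positive")
  if (p$peak <= p$rest) stop("peak must exceed rest")

  geom <- toy_geometry(p, protocol)
  stim_times <- geom$stim_times
  t_end <- max(stim_times) + protocol$cl
  t <- seq(0, t_end, by = dt_out)
  v <- rep(p$rest, length(t))
  ca <- rep(p$ca_min, length(t))
  for (k in seq_len(nrow(geom$beats))) {
    b <- geom$beats[k, ]
    rel <- t - b$onset
    up <- rel >= 0 & rel < b$t_up
    v[up] <- p$rest + p$upstroke_slope * rel[up]
    phase_a <- rel >= b$t_up & rel < b$t_up + 0.2 * b$t_fall
    fa <- (rel[phase_a] - b$t_up) / (0.2 * b$t_fall)
    v[phase_a] <- p$peak + fa * (p$plateau - p$peak)
    phase_b <- rel >= b$t_up + 0.2 * b$t_fall & rel < b$t_up + b$t_fall
    fb <- (rel[phase_b] - b$t_up - 0.2 * b$t_fall) / (0.8 * b$t_fall)
    v[phase_b] <- p$plateau + fb * (p$rest - p$plateau)
    ca_up <- up
    ca[ca_up] <- p$ca_min + (p$ca_max - p$ca_min) * rel[ca_up] / b$t_up
    ca_rel <- rel >= b$t_up & rel < b$t_up + b$t_fall
    ca[ca_rel] <- p$ca_max - (p$ca_max - p$ca_min) *
      (rel[ca_rel] - b$t_up) / b$t_fall
  }
  df <- tibble::tibble(time_ms = t, V_mV = v, Ca_mM = ca)
  new_ap_trace(df, "toy", p, protocol, NULL, stim_times)
}

# Beat-by-beat geometry: onsets, upstroke and repolarization durations,
# following the APD restitution recursion.
toy_geometry <- function(p, protocol) {
  cl <- protocol$cl
  nb <- protocol$n_beats
  amp <- p$peak - p$rest
  t_up <- amp / p$upstroke_slope
  # fraction of t_fall at which the 90% repolarization level is crossed
  l90 <- p$rest + 0.1 * amp
  f90 <- rep90_fraction(p, 0.9)
  apd_eff <- function(di) {
    p$apd_scale * (1 - p$rest_coef * exp(-di / p$rest_tau))
  }
  onsets <- (seq_len(nb) - 1) * cl
  di <- cl - p$apd_scale # nominal first-beat recovery time
  beats <- vector("list", nb)
  for (k in seq_len(nb)) {
    apd <- apd_eff(max(di, 1))
    t_fall <- apd / f90
    beats[[k]] <- tibble::tibble(onset = onsets[k], t_up = t_up,
                                 t_fall = t_fall, apd = apd, di = di)
    if (k < nb) di <- onsets[k + 1] - (onsets[k] + t_up + apd)
  }
  stim_times <- onsets
  if (!is.null(protocol$s2_di)) {
    last <- beats[[nb]]
    apd90_last <- last$apd + last$t_up # APD measured from activation
    s2 <- onsets[nb] + apd90_last + protocol$s2_offset + protocol$s2_di
    apd <- apd_eff(protocol$s2_di)
    beats[[nb + 1]] <- tibble::tibble(onset = s2, t_up = t_up,
                                      t_fall = apd / f90, apd = apd,
                                      di = protocol$s2_di)
    stim_times <- c(onsets, s2)
  }
  list(beats = do.call(rbind, beats), stim_times = stim_times)
}

# Fraction of the repolarization time at which x% repolarization from
# peak (toward rest) is crossed, given the two-segment fall.
rep90_fraction <- function(p, frac) {
  amp <- p$peak - p$rest
  level <- p$peak - frac * amp
  if (level >= p$plateau) {
    0.2 * (p$peak - level) / (p$peak - p$plateau)
  } else {
    0.2 + 0.8 * (p$plateau - level) / (p$plateau - p$rest)
  }
}

#' Analytic biomarkers of the toy action potential
#'
#' Closed-form values of the eleven-output biomarker panel for the final
#' beat of a toy-model run; the oracle counterpart of running
#' [simulate_toy_ap()] through [extract_biomarkers()].
#'
#' @inheritParams simulate_toy_ap
#' @return One-row tibble matching [extract_biomarkers()] columns.
#' @export
toy_biomarkers <- function(params = NULL, protocol = pacing_protocol()) {
  p <- check_params("toy", params)
  geom <- toy_geometry(p, protocol)
  b <- geom$beats[nrow(geom$beats), ]
  amp <- p$peak - p$rest
  # activation time detected at maximum dV/dt, i.e. on the upstroke;
  # the first sample of the rise is taken, so APDs include the upstroke
  apd_x <- function(frac) b$t_up + rep90_fraction(p, frac) * b$t_fall
  apd90 <- apd_x(0.9)
  v_at <- function(tau) {
    # voltage tau ms after activation
    if (tau < b$t_up) return(p$rest + p$upstroke_slope * tau)
    rel <- tau - b$t_up
    if (rel < 0.2 * b$t_fall) {
      p$peak + (rel / (0.2 * b$t_fall)) * (p$plateau - p$peak)
    } else if (rel < b$t_fall) {
      p$plateau + ((rel - 0.2 * b$t_fall) / (0.8 * b$t_fall)) *
        (p$rest - p$plateau)
    } else p$rest
  }
  tibble::tibble(
    dVdt_max = p$upstroke_slope,
    V_max = p$peak,
    V_20 = v_at(0.2 * apd90), V_40 = v_at(0.4 * apd90),
    V_60 = v_at(0.6 * apd90), V_80 = v_at(0.8 * apd90),
    APD_50 = apd_x(0.5), APD_90 = apd90,
    RestVm = p$rest,
    Ca_min = p$ca_min, Ca_max = p$ca_max,
    repolarized = TRUE
  )
}
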