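# Small shared fixtures built in code.

# A triangular action potential: rest at -80 mV, effectively instant
# rise to +20 mV at t = 0, linear fall back to -80 mV at t = 500 ms.
# Closed forms: amplitude 100 mV, APD90 = 450 ms, APD50 = 250 ms,
# V at 20% of APD90 (t = 90 ms) = +2 mV.
triangle_trace <- function(dt = 0.1) {
  t <- seq(-200, 600, by = dt)
  v <- ifelse(t <= 0, -80, pmax(20 - 0.2 * t, -80))
  ca <- ifelse(t > 0 & t <= 500, 7e-4, 1e-4)
  df <- tibble::tibble(time_ms = t, V_mV = v, Ca_mM = ca)
  apsens:::new_ap_trace(df, "toy", list(), pacing_protocol(cl = 800, n_beats = 1),
                        NULL, stim_times = 0)
}

# GP fixture on a named smooth function of a few inputs.
gp_fixture <- function(f, P, n = 30, seed = 1, names = paste0("x", seq_len(P))) {
  X <- with_seed_local(seed, lhs::randomLHS(n, P))
  colnames(X) <- names
  gp_train(X, f(X), restarts = 4, seed = seed + 1)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Emulator posterior mean as a plain function of a matrix, for the MC
# oracle.
em_mean_fun <- function(em) {
  function(M) {
    colnames(M) <- em$input_names
    suppressWarnings(predict(em, M)$.pred)
  }
}
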