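# Cell-model simulators: protocol bookkeeping, published-value checks,
# and agreement of the compiled derivatives with an independent R
# transcription of each model.

test_that("compiled Courtemanche derivatives match the R transcription", {
  p <- model_defaults("courtemanche")
  y0 <- apsens:::crn_initial_state()
  states <- list(
    y0,
    replace(y0, "V", -20),          # plateau-ish depolarized state
    replace(y0, c("V", "Cai"), c(10, 5e-4)),
    replace(y0, c("V", "m", "h"), c(-50, 0.5, 0.5))
  )
  for (y in states) {
    d_c <- compiled_rhs("courtemanche", y, NULL)
    d_r <- crn_rhs_R(y, p)
    expect_equal(d_c, unname(d_r), tolerance = 1e-4)
  }
  # intracellular Na+/K+ are clamped: zero derivative exactly
  expect_identical(compiled_rhs("courtemanche", y0, NULL)[17:18], c(0, 0))
})

test_that("compiled Maleckar derivatives match the R transcription", {
  p <- model_defaults("maleckar")
  y0 <- apsens:::mal_initial_state()
  states <- list(
    y0,
    replace(y0, "V", -10),
    replace(y0, c("V", "Cai", "Cad"), c(20, 2e-4, 5e-4))
  )
  for (y in states) {
    d_c <- compiled_rhs("maleckar", y, NULL)
    d_r <- mal_rhs_R(y, p)
    expect_equal(d_c, unname(d_r), tolerance = 1e-5)
  }
})

test_that("S1 pacing delivers one stimulus per cycle and captures", {
  tr <- simulate_ap("courtemanche",
                    protocol = pacing_protocol(cl = 1000, n_beats = 5))
  expect_equal(attr(tr, "stim_times"), seq(0, 4000, by = 1000))
  act <- detect_activations(tr)
  expect_equal(nrow(act), 5)
  expect_false(any(act$spontaneous))
  expect_true(all(abs(act$time - attr(tr, "stim_times")) < 10))
})

test_that("default Courtemanche beats match published model behavior", {
  tr <- simulate_ap("courtemanche",
                    protocol = pacing_protocol(cl = 1000, n_beats = 10))
  bm <- extract_biomarkers(tr)
  # published resting potential ~ -81 mV, APD90 ~ 300 ms at CL 1000 ms
  expect_lt(abs(bm$RestVm - -81.2), 1.5)
  expect_lt(abs(bm$APD_90 - 300), 25)
  expect_gt(bm$V_max, 15)
  expect_lt(bm$V_max, 35)
  expect_true(bm$Ca_max > 4e-4 && bm$Ca_max < 1.2e-3)
})

test_that("default Maleckar beats match published model behavior", {
  tr <- simulate_ap("maleckar",
                    protocol = pacing_protocol(cl = 1000, n_beats = 10))
  bm <- extract_biomarkers(tr)
  # Nygren-lineage resting potential ~ -74 to -79 mV, APD90 ~ 150-250 ms
  expect_lt(bm$RestVm, -70)
  expect_gt(bm$RestVm, -82)
  expect_gt(bm$APD_90, 120)
  expect_lt(bm$APD_90, 280)
  expect_lt(bm$APD_50 / bm$APD_90, 0.5) # spike-and-dome shape
})

test_that("simulation is deterministic and converged in solver tolerance", {
  proto <- pacing_protocol(cl = 1000, n_beats = 5)
  tr1 <- simulate_ap("courtemanche", protocol = proto)
  tr2 <- simulate_ap("courtemanche", protocol = proto)
  expect_identical(tr1$V_mV, tr2$V_mV)
  tight <- solver_settings(rtol = 1e-7, atol = 1e-7)
  tr3 <- simulate_ap("courtemanche", protocol = proto, solver = tight)
  a1 <- extract_biomarkers(tr1)$APD_90
  a3 <- extract_biomarkers(tr3)$APD_90
  expect_lt(abs(a1 - a3), 0.5)
})

test_that("Maleckar stimulus is a fixed 750 pA current (density 750/Cm)", {
  # initial dV/dt during the stimulus scales as 1/Cm if the absolute
  # current is Cm-independent
  proto <- pacing_protocol(cl = 500, n_beats = 1)
  slope_at_onset <- function(cm) {
    tr <- simulate_ap("maleckar", list(C_m = cm), proto, dt_out = 0.25)
    v <- tr$V_mV
    (v[2] - v[1]) / (tr$time_ms[2] - tr$time_ms[1])
  }
  s50 <- slope_at_onset(50)
  s100 <- slope_at_onset(100)
  expect_equal(s50 / s100, 2, tolerance = 0.05)
})

test_that("S2 timing follows APD90 of the final S1 beat plus offset plus DI", {
  proto <- pacing_protocol(cl = 1000, n_beats = 5, s2_di = 200)
  tr <- simulate_ap("courtemanche", protocol = proto)
  stim <- attr(tr, "stim_times")
  expect_length(stim, 6)
  # recompute APD90 of beat 5 from the trace itself
  apd5 <- extract_biomarkers(tr, beat = 5)$APD_90
  expect_equal(stim[6], stim[5] + apd5 + 10 + 200, tolerance = 1.0)
  act <- detect_activations(tr)
  expect_equal(nrow(act), 6)
})

test_that("unknown or non-positive parameters are rejected", {
  expect_error(simulate_ap("courtemanche", list(G_whatever = 1)),
               "unknown parameter")
  expect_error(simulate_ap("courtemanche", list(G_Na = -1)),
               "strictly positive")
})
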