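# Biomarker extraction and the plausibility filter.

test_that("triangular AP yields closed-form biomarkers", {
  tr <- triangle_trace(dt = 0.1)
  bm <- extract_biomarkers(tr, beat = 1)
  expect_equal(bm$RestVm, -80, tolerance = 1e-8)
  expect_equal(bm$V_max, 20, tolerance = 0.05)
  expect_equal(bm$APD_90, 450, tolerance = 1)
  expect_equal(bm$APD_50, 250, tolerance = 1)
  expect_equal(bm$V_20, 2, tolerance = 0.1)   # V at t = 0.2 * 450 = 90 ms
  expect_equal(bm$V_40, -16, tolerance = 0.1) # 20 - 0.2 * 180
  expect_lt(bm$APD_50, bm$APD_90)
  expect_equal(bm$Ca_max, 7e-4)
  expect_equal(bm$Ca_min, 1e-4)
})

test_that("raising the repolarization fraction raises APDx", {
  tr <- simulate_toy_ap(protocol = pacing_protocol(cl = 900, n_beats = 2))
  bm <- extract_biomarkers(tr)
  expect_lt(bm$APD_50, bm$APD_90)
  expect_gt(bm$V_max, bm$RestVm)
})

test_that("spontaneous upstrokes outside stimulus windows are flagged", {
  tr <- simulate_toy_ap(protocol = pacing_protocol(cl = 1000, n_beats = 2))
  act0 <- detect_activations(tr)
  expect_equal(sum(act0$spontaneous), 0)
  # inject a stimulus-free upstroke at t = 500 ms
  tr2 <- tr
  bump <- tr2$time_ms >= 500 & tr2$time_ms <= 520
  prof <- seq(0, 100, length.out = sum(bump))
  tr2$V_mV[bump] <- pmax(tr2$V_mV[bump], -80 + prof)
  act <- detect_activations(tr2)
  expect_equal(sum(act$spontaneous), 1)
  expect_lt(abs(act$time[act$spontaneous] - 500), 25)
})

test_that("no capture is reported when a stimulus elicits nothing", {
  t <- seq(0, 1000, by = 0.5)
  flat <- tibble::tibble(time_ms = t, V_mV = rep(-80, length(t)),
                         Ca_mM = rep(1e-4, length(t)))
  tr <- apsens:::new_ap_trace(flat, "toy", list(),
                              pacing_protocol(cl = 1000, n_beats = 1),
                              NULL, stim_times = 0)
  expect_error(extract_biomarkers(tr, 1), "no capture")
})

test_that("plausibility filter applies the four exclusion rules", {
  mk <- function(rest = -80, apd39 = 300, apd40 = 300, spont = 0,
                 apd_final = NULL) {
    fin <- tibble::tibble(RestVm = rest,
                          APD_90 = if (is.null(apd_final)) apd40
                                   else apd_final)
    list(final = fin,
         pair = list(tibble::tibble(APD_90 = apd39, RestVm = rest),
                     tibble::tibble(APD_90 = apd40, RestVm = rest)),
         activations = tibble::tibble(spontaneous = rep(TRUE, spont)))
  }
  expect_true(plausibility_filter(mk())$keep)
  # resting potential above -60 mV
  r <- plausibility_filter(mk(rest = -59))
  expect_false(r$keep)
  expect_match(r$reasons, "depolarized_rest")
  # APD90 just above 600 ms
  r <- plausibility_filter(mk(apd39 = 600.5, apd40 = 600.5))
  expect_match(r$reasons, "long_apd")
  # 3.2% beat-to-beat difference is kept; > 5% is alternans
  expect_true(plausibility_filter(mk(apd39 = 300, apd40 = 310))$keep)
  r <- plausibility_filter(mk(apd39 = 280, apd40 = 310, apd_final = 310))
  expect_false(r$keep)
  expect_match(r$reasons, "alternans")
  # pacemaking
  r <- plausibility_filter(mk(spont = 2))
  expect_match(r$reasons, "pacemaking")
})

test_that("the filter is deterministic and order-independent across runs", {
  sp <- build_input_space("toy", 1)
  dd1 <- generate_toy_design_data(sp, n = 30, seed = 12)
  dd2 <- generate_toy_design_data(sp, n = 30, seed = 12)
  expect_identical(dd1$exclusions, dd2$exclusions)
})
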