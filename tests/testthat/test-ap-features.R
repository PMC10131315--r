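test_that("AP count matches construction and flat traces yield none", {
  tr <- simulate_ap_train(ap_waveform_spec(rate = 60, duration_s = 10, seed = 1))
  expect_equal(nrow(detect_aps(tr)), 10)
  flat <- list(time_s = seq(0, 5, 1 / 1000), sample_rate = 1000,
               potential_mv = rep(-70, 5001))
  expect_equal(nrow(detect_aps(flat)), 0)
})

test_that("features round-trip the generating spec within tolerance", {
  cases <- list(
    c(apd50 = 209.9, apd90 = 253.6, apa = 114.8),   # WT-like
    c(apd50 = 170.5, apd90 = 207.7, apa = 109.5),   # symptomatic-like
    c(apd50 = 224.6, apd90 = 277.5, apa = 114.8))   # asymptomatic-like
  for (p in cases) {
    spec <- ap_waveform_spec(rate = 60, apd50 = p["apd50"], apd90 = p["apd90"],
                             amplitude = p["apa"], duration_s = 8, seed = 5)
    tr <- simulate_ap_train(spec)
    ft <- compute_ap_features(detect_aps(tr), tr)
    expect_lt(abs(ft$apd50 - p["apd50"]), 2)
    expect_lt(abs(ft$apd90 - p["apd90"]), 2)
    expect_lt(abs(ft$apa - p["apa"]), 1)
    expect_lt(abs(ft$bpm - 60), 0.5)
    expect_lt(abs(ft$mdp - spec$mdp), 0.5)
    expect_lt(abs(ft$vmax - spec$upstroke_vmax) / spec$upstroke_vmax, 0.1)
    expect_gte(ft$apd90, ft$apd50)
    expect_gte(ft$apd_ratio, 1)
  }
})

test_that("square pulse has APD50 = APD90 = pulse width", {
  fs <- 2000
  t <- seq(0, 4, 1 / fs)
  v <- rep(-80, length(t))
  for (t0 in c(0.5, 2)) v[t >= t0 & t < t0 + 0.2] <- 30
  tr <- list(time_s = t, potential_mv = v, sample_rate = fs)
  segs <- detect_aps(tr, sustain_ms = 0.5)
  expect_equal(nrow(segs), 2)
  ft <- compute_ap_features(segs, tr)
  expect_equal(ft$apd50, 200, tolerance = 0.02)
  expect_equal(ft$apd90, 200, tolerance = 0.02)
})

test_that("sixty beats in sixty seconds give BPM 60", {
  tr <- simulate_ap_train(ap_waveform_spec(rate = 60, duration_s = 60, seed = 2))
  ft <- compute_ap_features(detect_aps(tr), tr)
  expect_equal(ft$bpm, 60, tolerance = 0.01)
})

test_that("MDP shifts with a constant offset while APA does not", {
  tr <- simulate_ap_train(ap_waveform_spec(duration_s = 6, seed = 3))
  ft1 <- compute_ap_features(detect_aps(tr), tr)
  tr2 <- tr
  tr2$potential_mv <- tr$potential_mv + 7
  ft2 <- compute_ap_features(detect_aps(tr2), tr2)
  expect_equal(ft2$mdp, ft1$mdp + 7, tolerance = 1e-9)
  expect_equal(ft2$apa, ft1$apa, tolerance = 1e-9)
  expect_equal(ft2$apd90, ft1$apd90, tolerance = 1e-6)
})

test_that("subtype boundaries are strict", {
  expect_equal(classify_subtype(apd_ratio = 253.6 / 209.9, apa = 114.8),
               "ventricular-like")
  expect_equal(classify_subtype(apd_ratio = 1.35, apa = 114.8), "other")
  expect_equal(classify_subtype(apd_ratio = 1.3499, apa = 114.8),
               "ventricular-like")
  expect_equal(classify_subtype(apd_ratio = 1.2, apa = 90.0), "other")
  expect_equal(classify_subtype(apd_ratio = 1.2, apa = 90.01), "ventricular-like")
})

test_that("triggered activity is counted but never mistaken for APs", {
  ta <- list(list(beat = 2, coupling = 600, amplitude = 25),
             list(beat = 5, coupling = 650, amplitude = 25))
  spec <- ap_waveform_spec(rate = 50, duration_s = 10, ta_events = ta,
                           noise_sd = 0.5, seed = 21)
  tr <- simulate_ap_train(spec)
  segs <- detect_aps(tr)
  expect_equal(nrow(segs), length(tr$beat_times_s))  # TA not counted as APs
  res <- detect_triggered_activity(segs, tr)
  expect_equal(res$ta_count, 2)
  expect_true(res$arrhythmic)
  clean <- simulate_ap_train(ap_waveform_spec(rate = 50, duration_s = 10,
                                              noise_sd = 0.5, seed = 22))
  res0 <- detect_triggered_activity(detect_aps(clean), clean)
  expect_equal(res0$ta_count, 0)
  expect_false(res0$arrhythmic)
})

test_that("cohort TA fractions reproduce count arithmetic exactly", {
  expect_equal(cohort_ta_fraction(c(rep(TRUE, 11), rep(FALSE, 30))),
               100 * 11 / 41)
  expect_equal(cohort_ta_fraction(c(TRUE, rep(FALSE, 28))), 100 / 29)
  expect_equal(cohort_ta_fraction(rep(FALSE, 10)), 0)
  expect_equal(round(cohort_ta_fraction(c(rep(TRUE, 11), rep(FALSE, 30))), 1),
               26.8)
})

test_that("spike-and-dome detection needs a real notch", {
  mk <- function(depth, sad = TRUE) {
    simulate_ap_train(ap_waveform_spec(spike_and_dome = sad,
                                       notch_depth = depth,
                                       duration_s = 5, seed = 8))
  }
  tr <- mk(8)
  res <- detect_spike_and_dome(detect_aps(tr), tr)
  expect_true(res$flag)
  expect_gt(res$dome_minus_notch, 2)
  tr2 <- mk(0, sad = FALSE)  # monotone repolarization
  expect_false(detect_spike_and_dome(detect_aps(tr2), tr2)$flag)
  tr3 <- mk(0.5)             # below the dome threshold
  expect_false(detect_spike_and_dome(detect_aps(tr3), tr3)$flag)
})

test_that("symmetric triangular contractions give 50-ms half-widths", {
  tr <- simulate_contraction_trace(c(1, 3, 5), duration_s = 7, fps = 600,
                                   rise_ms = 100, fall_ms = 100)
  res <- contraction_halfwidths(tr)
  expect_equal(nrow(res$per_event), 3)
  expect_equal(res$contraction_halfwidth, 50, tolerance = 0.04)
  expect_equal(res$relaxation_halfwidth, 50, tolerance = 0.04)
})

test_that("contraction analysis round-trips at video frame rate and sees TA", {
  spec <- ap_waveform_spec(rate = 50, duration_s = 10, seed = 31,
                           ta_events = list(list(beat = 3, coupling = 600,
                                                 amplitude = 25)))
  ap <- simulate_ap_train(spec)
  motion <- simulate_contraction_trace(c(ap$beat_times_s, ap$ta_times_s),
                                       duration_s = 10, fps = 60,
                                       rise_ms = 120, fall_ms = 140)
  res <- contraction_halfwidths(motion, sync_times_s = 0)
  # extra motion event coincident with the TA
  expect_equal(nrow(res$per_event),
               length(ap$beat_times_s) + length(ap$ta_times_s))
  frame_ms <- 1000 / 60
  expect_lt(abs(res$contraction_halfwidth - 60), frame_ms)
  expect_lt(abs(res$relaxation_halfwidth - 70), frame_ms)
})
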