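test_that("IV family peaks follow Gmax * act(V) * (V - Erev)", {
  m <- wt_model()
  fam <- simulate_iv_family(m, noise_sd = 0, capacitance = 20, seed = 1)
  iv <- measure_peak_currents(fam)
  expected <- m$gmax * boltzmann(iv$voltage, m$vhalf_act, m$k_act) *
    (iv$voltage - m$e_rev)
  expect_equal(iv$peak_density, expected, tolerance = 1e-9)
  # zero driving force at the reversal potential
  expect_equal(iv$peak_density[iv$voltage == m$e_rev], 0, tolerance = 1e-12)
  # Boltzmann midpoint: half-activation times driving force
  m2 <- gating_model(vhalf_act = -30)
  iv2 <- measure_peak_currents(simulate_iv_family(m2, noise_sd = 0, seed = 1))
  expect_equal(iv2$peak_density[iv2$voltage == -30],
               0.5 * m2$gmax * (-30 - m2$e_rev), tolerance = 1e-9)
})

test_that("recovery protocol matches the closed-form biexponential", {
  m <- gating_model(recovery_A_fast = 0.5)
  rec <- simulate_recovery_protocol(m, intervals = c(5, 74.8, 1500, 1e5),
                                    noise_sd = 0)
  ratio <- rec$p2 / rec$p1
  expect_equal(ratio[2], 1 - 0.5 * exp(-1) - 0.5 * exp(-74.8 / 700.3),
               tolerance = 1e-12)
  # full recovery in the long-interval limit
  expect_equal(ratio[4], 1, tolerance = 1e-9)
})

test_that("protocol validation rejects malformed inputs", {
  m <- wt_model()
  expect_error(simulate_recovery_protocol(m, intervals = numeric(0)), "empty")
  expect_error(simulate_recovery_protocol(m, intervals = c(10, 5)), "increasing")
  expect_error(simulate_iv_family(m, v_from = 20, v_to = -60), "protocol")
  expect_error(simulate_slowentry_protocol(m, durations = numeric(0)), "empty")
  expect_error(gating_model(k_act = -1), "k_act")
  expect_error(ap_waveform_spec(rate = 300, apd90 = 250),
               class = "cardioclamp_spec_error")
  expect_error(ca_trace_spec(abnormalities = list(
    list(type = "LP", site = 2, magnitude = 0.3),
    list(type = "OS", site = 2, magnitude = 2))),
    class = "cardioclamp_spec_error")
  expect_error(ca_trace_spec(abnormalities = list(
    list(type = "OS", site = 2, magnitude = 1))),
    class = "cardioclamp_spec_error")
})

test_that("identical seed and spec give byte-identical traces", {
  spec <- ap_waveform_spec(noise_sd = 1, beat_jitter_sd = 10, duration_s = 4,
                           seed = 99)
  expect_identical(serialize(simulate_ap_train(spec), NULL),
                   serialize(simulate_ap_train(spec), NULL))
  m <- wt_model()
  expect_identical(
    serialize(simulate_iv_family(m, noise_sd = 0.3, seed = 5), NULL),
    serialize(simulate_iv_family(m, noise_sd = 0.3, seed = 5), NULL))
  s2 <- ca_trace_spec(noise_sd = 1, seed = 3)
  expect_identical(serialize(simulate_ca_trace(s2), NULL),
                   serialize(simulate_ca_trace(s2), NULL))
})

test_that("generator seeds do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(simulate_iv_family(wt_model(), noise_sd = 0.1, seed = 7))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("fitted-parameter spread grows monotonically with noise", {
  m <- wt_model()
  spread <- vapply(c(0.005, 0.02, 0.08), function(ns) {
    vh <- vapply(1:40, function(i) {
      av <- simulate_availability_curve(m, noise_sd = ns, seed = 1000 + i)
      unname(coef(fit_boltzmann(av$voltage, av$availability,
                                "inactivation"))["vhalf"])
    }, numeric(1))
    sd(vh)
  }, numeric(1))
  expect_lt(spread[1], spread[2])
  expect_lt(spread[2], spread[3])
})

test_that("Ct table follows the log-linear allele-ratio model", {
  tab1 <- simulate_ct_table(ratios = 1, include_controls = FALSE)
  dct1 <- mean(tab1$ct[tab1$allele == "mut"]) - mean(tab1$ct[tab1$allele == "WT"])
  expect_equal(dct1, 0, tolerance = 1e-12)  # log2(1) = 0: intercept point
  tab2 <- simulate_ct_table(ratios = 2, include_controls = FALSE)
  dct2 <- mean(tab2$ct[tab2$allele == "mut"]) - mean(tab2$ct[tab2$allele == "WT"])
  expect_equal(dct2 - dct1, 1, tolerance = 1e-12)  # one cycle per doubling
  # controls carry NA for the absent allele
  tab3 <- simulate_ct_table()
  expect_true(all(is.na(tab3$ct[tab3$sample == "1/0" & tab3$allele == "mut"])))
})

test_that("MEA round-trip recovers rate and FPD near the spec", {
  tr <- simulate_mea_trace(mea_trace_spec(rate = 60, fpd = 400, seed = 1))
  r <- analyze_fp(tr)
  expect_equal(r$bpm, 60, tolerance = 0.02)
  expect_equal(r$fpd, 400, tolerance = 0.03)
  expect_equal(r$fpdc, 400, tolerance = 0.03)  # RR = 1 s: Bazett identity
  expect_false(r$excluded)
  expect_false(r$arrhythmic)
})
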