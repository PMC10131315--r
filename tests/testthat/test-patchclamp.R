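test_that("conductance transform and exclusion band behave as specified", {
  iv <- data.frame(voltage = c(-20, 40, 42), peak_density = c(-26, 0.1, 0.5))
  g <- conductance_curve(iv, e_rev = 40)
  expect_equal(g$g[g$voltage == -20], -26 / (-20 - 40), tolerance = 1e-12)
  expect_equal(g$g[g$voltage == -20], 0.43333, tolerance = 1e-4)
  # V = Erev and points within 2.5 mV are excluded and flagged
  expect_false(40 %in% g$voltage)
  expect_false(42 %in% g$voltage)
  expect_equal(sort(attr(g, "excluded")$voltage), c(40, 42))
  expect_error(conductance_curve(data.frame(voltage = 40, peak_density = 1), 40),
               "exclusion band")
})

test_that("noiseless conductance equals the generator's activation curve", {
  m <- wt_model()
  fam <- simulate_iv_family(m, noise_sd = 0, seed = 1)
  g <- conductance_curve(measure_peak_currents(fam), m$e_rev)
  act <- boltzmann(g$voltage, m$vhalf_act, m$k_act)
  expect_equal(g$g / m$gmax, act, tolerance = 1e-9)
})

test_that("zero-amplitude sweeps give zero densities and density needs capacitance", {
  fam <- sweep_family(time_s = seq(0, 0.05, 1 / 20000),
                      current = matrix(0, 1001, 3),
                      voltages = c(-20, 0, 20), capacitance = 20,
                      step_onset_s = 0.005)
  expect_equal(measure_peak_currents(fam)$peak_density, c(0, 0, 0))
  fam$capacitance <- NA_real_
  expect_error(measure_peak_currents(fam), class = "cardioclamp_density_error")
  fam$capacitance <- 20
  expect_error(measure_peak_currents(fam, window = c(-5, 10)), "window")
})

test_that("inactivation decay fit recovers generator kinetics per voltage", {
  m <- gating_model(tau_fast = 2, tau_slow = 20, A_frac_fast = 0.8)
  fam <- simulate_iv_family(m, noise_sd = 0, seed = 1)
  f <- fit_inactivation_decay(family = fam, sweep = which(fam$voltages == -20))
  cf <- coef(f)
  expect_equal(unname(cf["tau_fast"]), 2, tolerance = 1e-4)
  expect_equal(unname(cf["tau_slow"]), 20, tolerance = 1e-4)
  expect_equal(unname(cf["A_fast"] / (cf["A_fast"] + cf["A_slow"])), 0.8,
               tolerance = 1e-4)
  expect_error(fit_inactivation_decay(family = fam, sweep = 1, window_ms = 0.5),
               "too short")
})

test_that("mutant decay comparison reports smaller fast time constants", {
  tau_wt <- function(v) 1.5 + 2 * exp(-(v + 60) / 30)
  tau_mut <- function(v) 0.8 * tau_wt(v)
  fit_tau <- function(tf) {
    m <- gating_model(tau_fast = tf, tau_slow = 25, A_frac_fast = 0.85)
    fam <- simulate_iv_family(m, noise_sd = 0, seed = 1)
    vapply(c(-15, -10, 0, 10), function(v)
      unname(coef(fit_inactivation_decay(family = fam,
                                         sweep = which(fam$voltages == v)))["tau_fast"]),
      numeric(1))
  }
  expect_true(all(fit_tau(tau_mut) < fit_tau(tau_wt)))
})

test_that("recovery analysis round-trips the generator's constants", {
  m <- wt_model()
  rec <- analyze_recovery(simulate_recovery_protocol(m, noise_sd = 0))
  cf <- coef(rec)
  expect_lt(abs(cf["tau_fast"] - 74.8) / 74.8, 1e-6)
  expect_lt(abs(cf["tau_slow"] - 700.3) / 700.3, 1e-6)
  expect_gte(min(rec$p2_over_p1), 0)
  expect_lte(unname(cf["A_fast"] + cf["A_slow"]), 1.05)
  # long-interval limit approaches full recovery
  expect_gt(rec$p2_over_p1[length(rec$p2_over_p1)], 0.85)
  expect_error(analyze_recovery(data.frame(interval = c(5, 10, 20), p1 = 1,
                                           p2 = c(0.2, 0.4, 0.6))), "fewer than 6")
  expect_error(analyze_recovery(data.frame(interval = 1:10, p1 = 0, p2 = 1)),
               "P1")
})

test_that("asymptomatic-line simulation yields faster recovery than WT", {
  wt <- analyze_recovery(simulate_recovery_protocol(wt_model(), noise_sd = 0.01,
                                                    seed = 11))
  asym <- analyze_recovery(simulate_recovery_protocol(
    gating_model_preset("asymptomatic"), noise_sd = 0.01, seed = 11))
  expect_lt(coef(asym)["tau_fast"], coef(wt)["tau_fast"])
})

test_that("slow-inactivation entry analysis round-trips and is monotone", {
  m <- wt_model()
  dat <- simulate_slowentry_protocol(m, noise_sd = 0)
  f <- analyze_slow_inactivation_entry(dat)
  cf <- coef(f)
  expect_lt(abs(cf["tau_fast"] - m$slowentry_tau_fast) / m$slowentry_tau_fast, 1e-5)
  expect_lt(abs(cf["tau_slow"] - m$slowentry_tau_slow) / m$slowentry_tau_slow, 1e-5)
  # no entry at zero duration; fitted curve non-increasing in duration
  expect_equal(predict(f, 1e-9), 1, tolerance = 1e-6)
  grid <- predict(f, seq(1, 2000, length.out = 100))
  expect_true(all(diff(grid) <= 1e-12))
})

test_that("capacitance follows Q/dV and recovers an RC transient", {
  # 250 pA for 1 ms = 0.25 pC; 0.25 pC / 5 mV = 50 pF
  expect_equal(measure_capacitance(c(0, 1), c(250, 250), dv = 5), 50)
  expect_equal(measure_capacitance(seq(0, 1, 0.1), rep(0, 11), dv = 5), 0)
  expect_error(measure_capacitance(c(0, 1), c(1, 1), dv = 0), "nonzero")
  tr <- simulate_capacitive_transient(capacitance = 20, dv = -5, seed = 1)
  expect_equal(measure_capacitance(tr$time_ms, tr$current_pa, dv = -5), 20,
               tolerance = 0.025)
})

test_that("IKr peak and tail currents are read from annotated windows", {
  fs <- 10000
  t <- seq(0, 1, 1 / fs)
  mk_sweep <- function(steady, tail_amp) {
    i <- numeric(length(t))
    i[t >= 0.1 & t < 0.5] <- steady
    tail_reg <- t >= 0.5 & t < 0.8
    i[tail_reg] <- tail_amp * exp(-(t[tail_reg] - 0.5) / 0.05)
    i
  }
  fam <- sweep_family(t, cbind(mk_sweep(120, 80), mk_sweep(0, 0)),
                      voltages = c(20, 40), capacitance = 20,
                      step_onset_s = 0.1, step_end_s = 0.5,
                      protocol = list(tail_start_s = 0.5, tail_end_s = 0.8))
  res <- measure_ikr(fam)
  expect_equal(res$peak_end_pa[1], 120, tolerance = 1e-9)
  expect_equal(res$tail_pa[1], 80, tolerance = 0.02)
  expect_true(res$tail_at_boundary[1])  # exponential tail peaks at window start
  expect_equal(res$peak_end_pa[2], 0)
  expect_equal(res$tail_pa[2], 0)
  fam$protocol <- list()
  expect_error(measure_ikr(fam), "annotations")
})

test_that("median absolute V1/2 error across noisy replicates stays below the reported SE", {
  m <- wt_model()
  err <- vapply(1:100, function(i) {
    av <- simulate_availability_curve(m, noise_sd = 0.02, seed = 3000 + i)
    abs(unname(coef(fit_boltzmann(av$voltage, av$availability,
                                  "inactivation"))["vhalf"]) - m$vhalf_inact)
  }, numeric(1))
  expect_lt(median(err), 2.0)
})
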