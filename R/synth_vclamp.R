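#' Simulate a voltage-clamp step family (I-V protocol)
#'
#' Generates a family of whole-cell current sweeps for a step protocol from a
#' holding potential, using a [gating_model()]: at each command voltage the
#' peak current is \eqn{G_{max} \cdot act_\infty(V) \cdot (V - E_{rev})}
#' (availability is complete at the holding potential) and the decay after the
#' peak is biexponential with the model's voltage-dependent time constants.
#' Inward current is negative. Additive i.i.d. Gaussian noise is applied per
#' sample.
#'
#' @param model A [gating_model()].
#' @param v_from,v_to,v_by Step potentials, mV (default -60 to 80 in 5-mV
#'   increments).
#' @param holding Holding potential, mV.
#' @param capacitance Cell capacitance, pF (scales current; densities are
#'   current/capacitance).
#' @param noise_sd Noise SD in density units (pA/pF).
#' @param sample_rate Sampling rate, Hz.
#' @param pre_ms,step_ms Baseline and step durations, ms.
#' @param peak_latency_ms Time to peak after the step onset, ms; the current
#'   holds its peak value until then, so artifact blanking shorter than the
#'   latency never clips the peak.
#' @param seed Optional RNG seed (the caller's RNG state is preserved).
#' @return A [sweep_family()] object.
#' @examples
#' fam <- simulate_iv_family(gating_model(), noise_sd = 0, seed = 1)
#' @export
simulate_iv_family <- function(model, v_from = -60, v_to = 80, v_by = 5,
                               holding = -100, capacitance = 20,
                               noise_sd = 0, sample_rate = 20000,
                               pre_ms = 5, step_ms = 45, peak_latency_ms = 1,
                               seed = NULL) {
  if (!inherits(model, "gating_model")) stop_cc("'model' must be a gating_model")
  if (!is.finite(v_from) || !is.finite(v_to) || !is.finite(v_by) || v_by <= 0 ||
      v_to < v_from) {
    stop_cc("invalid step protocol: require finite v_from <= v_to and v_by > 0")
  }
  assert_number(capacitance, "capacitance", lower = 1e-6)
  assert_number(noise_sd, "noise_sd", lower = 0)
  voltages <- seq(v_from, v_to, by = v_by)
  dt <- 1 / sample_rate
  time_s <- seq(0, (pre_ms + step_ms) / 1000 - dt, by = dt)
  onset_s <- pre_ms / 1000
  nsamp <- length(time_s)

  with_seed(seed, {
    cur <- matrix(0, nrow = nsamp, ncol = length(voltages))
    for (j in seq_along(voltages)) {
      v <- voltages[j]
      peak <- model$gmax * boltzmann(v, model$vhalf_act, model$k_act) *
        (v - model$e_rev) * capacitance
      tf <- model$tau_fast(v); ts <- model$tau_slow(v)
      after <- time_s >= onset_s
      t_ms <- pmax((time_s[after] - onset_s) * 1000 - peak_latency_ms, 0)
      cur[after, j] <- peak * (model$A_frac_fast * exp(-t_ms / tf) +
                                 (1 - model$A_frac_fast) * exp(-t_ms / ts))
    }
    if (noise_sd > 0) {
      cur <- cur + matrix(rnorm(length(cur), 0, noise_sd * capacitance),
                          nrow = nsamp)
    }
    sweep_family(time_s = time_s, current = cur, voltages = voltages,
                 holding = holding, capacitance = capacitance,
                 sample_rate = sample_rate,
                 step_onset_s = onset_s, step_end_s = onset_s + step_ms / 1000,
                 meta = list(generator = "simulate_iv_family", model = model,
                             noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate a steady-state activation curve
#'
#' Normalized conductance points following the model's activation Boltzmann
#' curve plus Gaussian noise, as produced by dividing peak currents by the
#' driving force and normalizing.
#'
#' @inheritParams simulate_iv_family
#' @param voltages Test potentials, mV.
#' @param noise_sd SD of the noise on the normalized conductance.
#' @return Data frame with columns `voltage` and `g_norm`.
#' @export
simulate_activation_curve <- function(model, voltages = seq(-60, 20, 5),
                                      noise_sd = 0, seed = NULL) {
  if (!inherits(model, "gating_model")) stop_cc("'model' must be a gating_model")
  assert_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    y <- boltzmann(voltages, model$vhalf_act, model$k_act)
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    data.frame(voltage = voltages, g_norm = y)
  })
}

#' Simulate a steady-state availability (inactivation) curve
#'
#' Normalized peak current after 200-ms conditioning pulses, following the
#' model's inactivation Boltzmann curve plus Gaussian noise.
#'
#' @inheritParams simulate_iv_family
#' @param voltages Conditioning potentials, mV.
#' @param noise_sd SD of the noise on the normalized response.
#' @return Data frame with columns `voltage` and `availability`.
#' @export
simulate_availability_curve <- function(model, voltages = seq(-120, -20, 5),
                                        noise_sd = 0, seed = NULL) {
  if (!inherits(model, "gating_model")) stop_cc("'model' must be a gating_model")
  assert_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    y <- boltzmann(voltages, model$vhalf_inact, model$k_inact,
                   orientation = "inactivation")
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    data.frame(voltage = voltages, availability = y)
  })
}

#' Simulate a double-pulse recovery-from-inactivation protocol
#'
#' P1/P2 peak pairs at the given recovery intervals; the expected normalized
#' recovery is \eqn{P2/P1(t) = 1 - A_f e^{-t/\tau_f} - A_s e^{-t/\tau_s}} with
#' the model's recovery constants, plus Gaussian noise, clipped at zero.
#'
#' @inheritParams simulate_iv_family
#' @param intervals Recovery intervals, ms (positive, strictly increasing).
#'   Defaults to the standard 15-interval series 5--1500 ms.
#' @param p1_peak Peak P1 current (pA; sign irrelevant to the normalized
#'   analysis).
#' @param noise_sd SD of the noise on the P2/P1 ratio.
#' @return Data frame with columns `interval`, `p1`, `p2` (class
#'   `recovery_data`).
#' @export
simulate_recovery_protocol <- function(model,
                                       intervals = c(5, 10, 20, 50, 100, 200,
                                                     300, 400, 500, 600, 700,
                                                     800, 900, 1000, 1500),
                                       p1_peak = -1000, noise_sd = 0,
                                       seed = NULL) {
  if (!inherits(model, "gating_model")) stop_cc("'model' must be a gating_model")
  if (!length(intervals)) stop_cc("empty recovery-interval list")
  if (any(!is.finite(intervals)) || any(intervals <= 0) ||
      is.unsorted(intervals, strictly = TRUE)) {
    stop_cc("recovery intervals must be positive and strictly increasing")
  }
  assert_number(noise_sd, "noise_sd", lower = 0)
  af <- model$recovery_A_fast; as_ <- 1 - af
  with_seed(seed, {
    frac <- 1 - af * exp(-intervals / model$recovery_tau_fast) -
      as_ * exp(-intervals / model$recovery_tau_slow)
    if (noise_sd > 0) frac <- frac + rnorm(length(frac), 0, noise_sd)
    frac <- pmax(frac, 0)
    out <- data.frame(interval = intervals, p1 = p1_peak, p2 = p1_peak * frac)
    class(out) <- c("recovery_data", class(out))
    out
  })
}

#' Simulate entry into slow inactivation (double-pulse, varying P1 duration)
#'
#' Normalized availability after a conditioning pulse of increasing duration:
#' \eqn{P2/P1(d) = C + A_f e^{-d/\tau_f} + A_s e^{-d/\tau_s}} with
#' \eqn{C + A_f + A_s = 1} (full availability at zero duration), plus noise.
#'
#' @inheritParams simulate_recovery_protocol
#' @param durations Conditioning-pulse durations, ms. Defaults to the
#'   16-duration series 5--2000 ms.
#' @return Data frame with columns `duration`, `p1`, `p2`.
#' @export
simulate_slowentry_protocol <- function(model,
                                        durations = c(5, 10, 20, 50, 100, 200,
                                                      300, 400, 500, 600, 700,
                                                      800, 900, 1000, 1500, 2000),
                                        p1_peak = -1000, noise_sd = 0,
                                        seed = NULL) {
  if (!inherits(model, "gating_model")) stop_cc("'model' must be a gating_model")
  if (!length(durations)) stop_cc("empty duration list")
  if (any(!is.finite(durations)) || any(durations <= 0) ||
      is.unsorted(durations, strictly = TRUE)) {
    stop_cc("conditioning durations must be positive and strictly increasing")
  }
  assert_number(noise_sd, "noise_sd", lower = 0)
  C <- model$slowentry_steady
  af <- (1 - C) * model$slowentry_A_fast
  as_ <- (1 - C) * (1 - model$slowentry_A_fast)
  with_seed(seed, {
    frac <- C + af * exp(-durations / model$slowentry_tau_fast) +
      as_ * exp(-durations / model$slowentry_tau_slow)
    if (noise_sd > 0) frac <- frac + rnorm(length(frac), 0, noise_sd)
    frac <- pmax(frac, 0)
    data.frame(duration = durations, p1 = p1_peak, p2 = p1_peak * frac)
  })
}

#' Simulate a capacitive transient for a small voltage step
#'
#' RC-circuit current response to a voltage step `dv`:
#' \eqn{I(t) = (dV/R_s) e^{-t/R_sC}}. The integral of the transient equals
#' \eqn{C \cdot dV}, so integrating and dividing by the step recovers the
#' membrane capacitance.
#'
#' @param capacitance True membrane capacitance, pF.
#' @param dv Voltage step, mV (default -5, hyperpolarizing).
#' @param rs Series resistance, MOhm.
#' @param sample_rate Sampling rate, Hz.
#' @param dur_ms Trace duration, ms.
#' @param noise_sd Current noise SD, pA.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `time_ms` and `current_pa`.
#' @export
simulate_capacitive_transient <- function(capacitance = 20, dv = -5, rs = 10,
                                          sample_rate = 100000, dur_ms = 5,
                                          noise_sd = 0, seed = NULL) {
  assert_number(capacitance, "capacitance", lower = 1e-6)
  if (dv == 0) stop_cc("voltage step dv must be nonzero")
  with_seed(seed, {
    t_ms <- seq(0, dur_ms, by = 1000 / sample_rate)
    tau_ms <- rs * capacitance / 1000  # MOhm * pF = us
    i_pa <- (dv / rs) * 1000 * exp(-t_ms / tau_ms)  # mV/MOhm = nA -> pA
    if (noise_sd > 0) i_pa <- i_pa + rnorm(length(i_pa), 0, noise_sd)
    data.frame(time_ms = t_ms, current_pa = i_pa)
  })
}
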