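#' Voltage-clamp sweep family
#'
#' Container for a voltage-clamp protocol's sweeps: a shared time base, one
#' current column per command voltage, and protocol metadata.
#'
#' @param time_s Time base, seconds (shared by all sweeps).
#' @param current Matrix of currents (pA), one column per sweep.
#' @param voltages Command voltage per sweep, mV (unique).
#' @param holding Holding potential, mV.
#' @param capacitance Cell capacitance, pF (optional; required for densities).
#' @param sample_rate Sampling rate, Hz.
#' @param step_onset_s,step_end_s Step timing, seconds.
#' @param protocol Optional list of extra window annotations (e.g.
#'   `tail_start_s`, `tail_end_s` for tail-current protocols).
#' @param meta Free-form metadata (cell id, temperature tag, generator spec).
#' @return An object of class `sweep_family`.
#' @export
sweep_family <- function(time_s, current, voltages, holding = NA_real_,
                         capacitance = NA_real_, sample_rate = NULL,
                         step_onset_s = 0, step_end_s = max(time_s),
                         protocol = list(), meta = list()) {
  current <- as.matrix(current)
  if (nrow(current) != length(time_s)) {
    stop_cc("current matrix has %d rows but time has %d samples",
            nrow(current), length(time_s))
  }
  if (ncol(current) != length(voltages)) {
    stop_cc("current matrix has %d sweeps but %d voltages given",
            ncol(current), length(voltages))
  }
  if (anyDuplicated(voltages)) stop_cc("command voltages must be unique")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(time_s))
  structure(list(time_s = time_s, current = current, voltages = voltages,
                 holding = holding, capacitance = capacitance,
                 sample_rate = sample_rate, step_onset_s = step_onset_s,
                 step_end_s = step_end_s, protocol = protocol, meta = meta),
            class = "sweep_family")
}

#' @export
print.sweep_family <- function(x, ...) {
  cat(sprintf("Voltage-clamp sweep family: %d sweeps, %d samples @ %.0f Hz\n",
              ncol(x$current), nrow(x$current), x$sample_rate))
  cat(sprintf("  steps %g to %g mV, holding %g mV, capacitance %s pF\n",
              min(x$voltages), max(x$voltages), x$holding,
              ifelse(is.na(x$capacitance), "?", format(x$capacitance))))
  invisible(x)
}

#' Peak currents and current densities across a sweep family
#'
#' Per sweep, the signed extremum of the current inside the search window
#' after blanking the capacitive artifact at the step onset; densities are
#' peaks divided by the cell capacitance.
#'
#' @param family A [sweep_family()].
#' @param window Search window in ms relative to the step onset,
#'   `c(start, end)`; defaults to the whole step.
#' @param blank_ms Capacitive-artifact blanking after the step onset, ms.
#' @param smooth_ms Moving-average smoothing before the peak search, ms
#'   (reduces the extremum bias of picking the largest noisy sample).
#' @return A data frame of class `iv_curve` with columns `voltage`, `peak_pa`,
#'   `peak_density` (pA/pF, inward negative).
#' @export
measure_peak_currents <- function(family, window = NULL, blank_ms = 0.5,
                                  smooth_ms = 0.25) {
  if (!inherits(family, "sweep_family")) stop_cc("'family' must be a sweep_family")
  if (is.na(family$capacitance)) {
    stop_cc("capacitance missing: current density unavailable",
            class = "cardioclamp_density_error")
  }
  step_ms <- (family$step_end_s - family$step_onset_s) * 1000
  if (is.null(window)) window <- c(0, step_ms)
  if (window[1] < 0 || window[2] > step_ms + 1e-9 || window[1] >= window[2]) {
    stop_cc("search window [%g, %g] ms outside the step (0-%g ms)",
            window[1], window[2], step_ms)
  }
  t_rel_ms <- (family$time_s - family$step_onset_s) * 1000
  sel <- t_rel_ms >= max(window[1], blank_ms) & t_rel_ms <= window[2]
  if (!any(sel)) stop_cc("search window contains no samples after blanking")
  ks <- max(1L, round(smooth_ms / 1000 * family$sample_rate))
  peaks <- apply(family$current[sel, , drop = FALSE], 2, function(i) {
    if (ks > 1L && length(i) > ks) {
      sm <- as.numeric(stats::filter(i, rep(1 / ks, ks), sides = 2))
      i <- ifelse(is.na(sm), i, sm)
    }
    i[which.max(abs(i))]
  })
  out <- data.frame(voltage = family$voltages, peak_pa = peaks,
                    peak_density = peaks / family$capacitance)
  class(out) <- c("iv_curve", class(out))
  out
}

#' Normalized conductance-voltage curve from an I-V relationship
#'
#' \eqn{g(V) = I(V) / (V - E_{rev})}, excluding points within `exclude_mv` of
#' the reversal potential (the driving force vanishes there), normalized to
#' the maximum conductance.
#'
#' @param iv An `iv_curve` (from [measure_peak_currents()]) or a data frame
#'   with columns `voltage` and `peak_density`.
#' @param e_rev Reversal potential, mV.
#' @param exclude_mv Half-width of the exclusion band around `e_rev` (default
#'   2.5 mV, half a 5-mV protocol increment).
#' @return Data frame with columns `voltage`, `g` (same units as the current
#'   per mV), `g_norm`, and `excluded` flags for the dropped points (returned
#'   as attribute `excluded`).
#' @export
conductance_curve <- function(iv, e_rev, exclude_mv = 2.5) {
  assert_number(e_rev, "e_rev")
  v <- iv$voltage
  i <- iv$peak_density %||% iv$peak_pa
  keep <- abs(v - e_rev) > exclude_mv
  if (!any(keep)) stop_cc("all points fall in the exclusion band around e_rev")
  g <- i[keep] / (v[keep] - e_rev)
  out <- data.frame(voltage = v[keep], g = g, g_norm = g / max(g))
  attr(out, "excluded") <- data.frame(voltage = v[!keep], peak = i[!keep])
  attr(out, "e_rev") <- e_rev
  out
}

#' Biexponential fit of current decay after the peak (inactivation onset)
#'
#' Locates the peak inside the step, then fits the decay of the current
#' magnitude from the peak onward with [fit_biexp()] (`form = "decay"`).
#'
#' @param time_s,current_pa Single sweep (or pass a [sweep_family()] plus
#'   `sweep` index).
#' @param family Optional [sweep_family()]; overrides `time_s`/`current_pa`.
#' @param sweep Sweep index into `family`.
#' @param window_ms Fit window length from the peak, ms (default: to the end
#'   of the step).
#' @param blank_ms Capacitive blanking after step onset, ms.
#' @param step_onset_s Step onset (seconds) when raw vectors are given.
#' @return A `biexp_fit` (tau in ms); monoexponential collapse is flagged via
#'   `$mono`.
#' @export
fit_inactivation_decay <- function(time_s = NULL, current_pa = NULL,
                                   family = NULL, sweep = NULL,
                                   window_ms = NULL, blank_ms = 0.5,
                                   step_onset_s = 0) {
  if (!is.null(family)) {
    if (!inherits(family, "sweep_family")) stop_cc("'family' must be a sweep_family")
    if (is.null(sweep)) stop_cc("'sweep' index required with a family")
    time_s <- family$time_s
    current_pa <- family$current[, sweep]
    step_onset_s <- family$step_onset_s
  }
  t_ms <- (time_s - step_onset_s) * 1000
  sel <- t_ms >= blank_ms
  t_ms <- t_ms[sel]; i <- current_pa[sel]
  # last sample attaining the extremum: fits start where the decay begins,
  # not at the front of a flat peak
  pk <- max(which(abs(i) >= max(abs(i)) * (1 - 1e-12)))
  t_fit <- t_ms[pk:length(t_ms)] - t_ms[pk]
  y_fit <- abs(i[pk:length(i)])
  if (!is.null(window_ms)) {
    keep <- t_fit <= window_ms
    t_fit <- t_fit[keep]; y_fit <- y_fit[keep]
  }
  if (length(t_fit) < 20L) {
    stop_cc("decay window too short: %d samples (need >= 20)", length(t_fit))
  }
  fit_biexp(t_fit, y_fit, form = "decay")
}

#' Recovery-from-inactivation analysis (double-pulse P2/P1)
#'
#' Normalizes the P2 peaks by their conditioning P1 peaks and fits the
#' biexponential recovery curve
#' \eqn{P2/P1(t) = 1 - A_f e^{-t/\tau_f} - A_s e^{-t/\tau_s}}.
#'
#' @param data Data frame with columns `interval` (ms), `p1`, `p2` (peak
#'   currents), e.g. from [simulate_recovery_protocol()]; alternatively
#'   columns `interval` and `p2_over_p1`.
#' @return An object of class `recovery_curve`: the normalized points plus a
#'   `biexp_fit` in `$fit`.
#' @export
analyze_recovery <- function(data) {
  if (!all(c("interval") %in% names(data))) stop_cc("'data' needs an 'interval' column")
  if ("p2_over_p1" %in% names(data)) {
    ratio <- data$p2_over_p1
  } else {
    if (any(data$p1 == 0)) stop_cc("P1 peak of zero: cannot normalize")
    ratio <- data$p2 / data$p1
  }
  if (length(unique(data$interval)) < 6L) {
    stop_cc("recovery fit refused: fewer than 6 distinct intervals")
  }
  fit <- fit_biexp(data$interval, ratio, form = "recovery")
  structure(list(intervals = data$interval, p2_over_p1 = ratio, fit = fit),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("Recovery from inactivation: %d intervals (%g-%g ms)\n",
              length(x$intervals), min(x$intervals), max(x$intervals)))
  print(x$fit)
  invisible(x)
}

#' @export
coef.recovery_curve <- function(object, ...) coef(object$fit)

#' @export
plot.recovery_curve <- function(x, ...) {
  plot(x$intervals, x$p2_over_p1, log = "x", ylim = c(0, 1.05),
       xlab = "Recovery interval (ms)", ylab = "P2/P1",
       main = "Recovery from inactivation", ...)
  tt <- exp(seq(log(min(x$intervals)), log(max(x$intervals)), length.out = 200))
  lines(tt, predict(x$fit, tt), col = "firebrick")
  invisible(x)
}

#' Entry into slow inactivation (double-pulse, varying conditioning duration)
#'
#' Normalizes P2/P1 and fits the decaying biexponential
#' \eqn{P2/P1(d) = C + A_f e^{-d/\tau_f} + A_s e^{-d/\tau_s}} of the
#' conditioning-pulse duration.
#'
#' @param data Data frame with columns `duration` (ms), `p1`, `p2` (or
#'   `p2_over_p1`), e.g. from [simulate_slowentry_protocol()].
#' @return A `biexp_fit` (form `"entry"`); `coef()` includes the steady
#'   `offset`.
#' @export
analyze_slow_inactivation_entry <- function(data) {
  if (!"duration" %in% names(data)) stop_cc("'data' needs a 'duration' column")
  if ("p2_over_p1" %in% names(data)) {
    ratio <- data$p2_over_p1
  } else {
    if (any(data$p1 == 0)) stop_cc("P1 peak of zero: cannot normalize")
    ratio <- data$p2 / data$p1
  }
  if (length(unique(data$duration)) < 6L) {
    stop_cc("slow-entry fit refused: fewer than 6 distinct durations")
  }
  fit_biexp(data$duration, ratio, form = "entry")
}

#' Membrane capacitance from a capacitive transient
#'
#' Integrates the baseline-subtracted capacitive transient evoked by a small
#' voltage step and divides the charge by the step:
#' \eqn{C = |Q / \Delta V|}. With current in pA, time in ms and the step in
#' mV the result is in pF.
#'
#' @param time_ms,current_pa Transient trace.
#' @param dv Voltage step, mV (nonzero).
#' @param baseline Baseline current to subtract, pA (default 0, i.e. a
#'   pre-corrected trace), or `"tail"` to use the mean of the last 10% of
#'   samples.
#' @return Capacitance in pF.
#' @export
measure_capacitance <- function(time_ms, current_pa, dv, baseline = 0) {
  if (dv == 0) stop_cc("voltage step dv must be nonzero")
  if (identical(baseline, "tail")) {
    n <- length(current_pa)
    baseline <- mean(current_pa[max(1, floor(0.9 * n)):n])
  }
  q <- trapz(time_ms, current_pa - baseline)  # pA*ms = fC
  abs(q / dv)  # fC/mV = pF
}

#' Peak and tail currents from a tail-current protocol
#'
#' Per sweep: the steady current at the end of the test pulse (mean over the
#' final `steady_ms`), and the extremum of the current in the annotated tail
#' window. A tail extremum sitting on the window's first sample is flagged as
#' censored (`tail_at_boundary`).
#'
#' @param family A [sweep_family()] whose `protocol` carries `tail_start_s`
#'   and `tail_end_s` annotations.
#' @param steady_ms Averaging window for the end-of-pulse current, ms.
#' @return Data frame with columns `voltage`, `peak_end_pa`, `tail_pa`,
#'   `tail_at_boundary`.
#' @export
measure_ikr <- function(family, steady_ms = 5) {
  if (!inherits(family, "sweep_family")) stop_cc("'family' must be a sweep_family")
  p <- family$protocol
  if (is.null(p$tail_start_s) || is.null(p$tail_end_s)) {
    stop_cc("protocol lacks tail-window annotations (tail_start_s/tail_end_s)")
  }
  t <- family$time_s
  end_sel <- t >= family$step_end_s - steady_ms / 1000 & t < family$step_end_s
  tail_sel <- t >= p$tail_start_s & t <= p$tail_end_s
  if (!any(end_sel) || !any(tail_sel)) stop_cc("annotated windows contain no samples")
  steady <- colMeans(family$current[end_sel, , drop = FALSE])
  tail_idx <- which(tail_sel)
  tails <- apply(family$current[tail_idx, , drop = FALSE], 2,
                 function(i) {
                   k <- which.max(abs(i))
                   c(value = i[k], at_start = as.numeric(k == 1L))
                 })
  data.frame(voltage = family$voltages,
             peak_end_pa = unname(steady),
             tail_pa = unname(tails["value", ]),
             tail_at_boundary = as.logical(tails["at_start", ]))
}
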