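#' Specification for a synthetic action-potential train
#'
#' Parameterizes a spontaneously beating current-clamp recording directly by
#' the target feature values: the waveform is a piecewise-smooth template
#' (exponential upstroke, plateau, sigmoidal repolarization) built so that the
#' downstream feature extraction recovers the requested BPM, APD50, APD90,
#' amplitude and MDP. Triggered-activity (TA) events are injected as
#' subthreshold diastolic depolarization humps; spike-and-dome morphology as
#' an early-repolarization notch.
#'
#' @param rate Beating rate, beats/min.
#' @param apd50,apd90 AP durations at 50% and 90% repolarization, ms
#'   (`apd90 > apd50 > 0`).
#' @param amplitude AP amplitude (peak minus MDP), mV.
#' @param mdp Maximum diastolic potential, mV (negative).
#' @param upstroke_vmax Target maximal upstroke velocity, V/s.
#' @param spike_and_dome Inject an early-repolarization notch/dome.
#' @param notch_depth Notch depth, mV.
#' @param ta_events List of TA directives, each
#'   `list(beat = i, coupling = ms, amplitude = mV)`: a diastolic
#'   depolarization starting `coupling` ms after beat `i`'s upstroke.
#' @param ta_width TA hump width, ms.
#' @param beat_jitter_sd SD of beat-time jitter, ms.
#' @param noise_sd Additive Gaussian noise SD, mV.
#' @param sample_rate Sampling rate, Hz.
#' @param duration_s Recording length, s.
#' @param seed Optional RNG seed.
#' @return An object of class `ap_spec`.
#' @export
ap_waveform_spec <- function(rate = 60, apd50 = 209.9, apd90 = 253.6,
                             amplitude = 114.8, mdp = -70, upstroke_vmax = 20,
                             spike_and_dome = FALSE, notch_depth = 8,
                             ta_events = list(), ta_width = 80,
                             beat_jitter_sd = 0, noise_sd = 0,
                             sample_rate = 20000, duration_s = 10,
                             seed = NULL) {
  assert_number(rate, "rate", lower = 1e-6)
  assert_number(apd50, "apd50", lower = 1e-6)
  assert_number(apd90, "apd90", lower = apd50 + 1e-9)
  assert_number(amplitude, "amplitude", lower = 1e-6)
  assert_number(mdp, "mdp", upper = -1e-9)
  assert_number(sample_rate, "sample_rate", lower = 1)
  assert_number(upstroke_vmax, "upstroke_vmax", lower = 1e-6)
  period_ms <- 60000 / rate
  if (apd90 >= period_ms) {
    stop_cc("infeasible spec: apd90 (%g ms) >= beat period (%g ms)",
            apd90, period_ms, class = "cardioclamp_spec_error")
  }
  structure(list(rate = rate, apd50 = apd50, apd90 = apd90,
                 amplitude = amplitude, mdp = mdp,
                 upstroke_vmax = upstroke_vmax,
                 spike_and_dome = isTRUE(spike_and_dome),
                 notch_depth = notch_depth,
                 ta_events = ta_events, ta_width = ta_width,
                 beat_jitter_sd = beat_jitter_sd, noise_sd = noise_sd,
                 sample_rate = sample_rate, duration_s = duration_s,
                 seed = seed),
            class = "ap_spec")
}

#' Simulate a spontaneous action-potential train
#'
#' Renders the [ap_waveform_spec()] template: beats at the requested rate
#' (with optional jitter), each beat an exponential upstroke (time constant
#' `amplitude / upstroke_vmax`) multiplied by a logistic repolarization whose
#' midpoint and slope are placed so the 50% and 90% repolarization crossings
#' land at `apd50` and `apd90`; optional spike-and-dome notch and diastolic
#' TA humps; additive Gaussian noise.
#'
#' @param spec An [ap_waveform_spec()].
#' @return An `ap_trace` object: `time_s`, `potential_mv`, `sample_rate`,
#'   plus the generating `spec`, `beat_times_s` and `ta_times_s`.
#' @examples
#' tr <- simulate_ap_train(ap_waveform_spec(rate = 60, duration_s = 5, seed = 1))
#' @export
simulate_ap_train <- function(spec) {
  if (!inherits(spec, "ap_spec")) stop_cc("'spec' must be an ap_waveform_spec")
  with_seed(spec$seed, {
    fs <- spec$sample_rate
    dt_ms <- 1000 / fs
    time_s <- seq(0, spec$duration_s, by = 1 / fs)
    n <- length(time_s)
    period_s <- 60 / spec$rate
    first <- 0.25
    beat_times <- seq(first, spec$duration_s - 0.05, by = period_s)
    if (spec$beat_jitter_sd > 0 && length(beat_times) > 1L) {
      jit <- rnorm(length(beat_times) - 1L, 0, spec$beat_jitter_sd / 1000)
      beat_times[-1] <- beat_times[-1] + jit
      beat_times <- sort(beat_times)
    }

    tau_up <- spec$amplitude / spec$upstroke_vmax           # ms
    w <- (spec$apd90 - spec$apd50) / log(9)                 # ms
    seg_ms <- min(spec$apd90 + 12 * w, period_s * 1000 * 0.98)
    seg_n <- floor(seg_ms / dt_ms)
    x_ms <- seq_len(seg_n) * dt_ms                          # time after upstroke
    u <- (1 - exp(-x_ms / tau_up)) / (1 + exp((x_ms - spec$apd50) / w))
    if (spec$spike_and_dome) {
      xn <- 0.12 * spec$apd90
      sn <- 0.035 * spec$apd90
      u <- u - (spec$notch_depth / spec$amplitude) * exp(-((x_ms - xn) / sn)^2)
    }

    v <- rep(spec$mdp, n)
    for (bt in beat_times) {
      i0 <- round(bt * fs) + 1L
      idx <- i0 + seq_len(seg_n) - 1L
      keep <- idx <= n
      v[idx[keep]] <- v[idx[keep]] + spec$amplitude * u[keep]
    }

    ta_times <- numeric(0)
    if (length(spec$ta_events)) {
      hw_n <- floor(spec$ta_width / dt_ms)
      hump <- 0.5 * (1 - cos(2 * pi * seq_len(hw_n) / hw_n))
      for (ev in spec$ta_events) {
        b <- ev$beat %||% 1L
        if (b > length(beat_times)) next
        t_ta <- beat_times[b] + (ev$coupling %||% 600) / 1000
        amp <- ev$amplitude %||% 25
        i0 <- round(t_ta * fs) + 1L
        idx <- i0 + seq_len(hw_n) - 1L
        keep <- idx <= n & idx >= 1L
        v[idx[keep]] <- v[idx[keep]] + amp * hump[keep]
        ta_times <- c(ta_times, t_ta)
      }
    }
    if (spec$noise_sd > 0) v <- v + rnorm(n, 0, spec$noise_sd)

    structure(list(time_s = time_s, potential_mv = v, sample_rate = fs,
                   spec = spec, beat_times_s = beat_times,
                   ta_times_s = ta_times),
              class = "ap_trace")
  })
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("AP trace: %.1f s @ %.0f Hz, %d beats, %d TA events\n",
              max(x$time_s), x$sample_rate, length(x$beat_times_s),
              length(x$ta_times_s)))
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ...) {
  plot(x$time_s, x$potential_mv, type = "l", xlab = "Time (s)",
       ylab = "Membrane potential (mV)", main = "Simulated AP train", ...)
  invisible(x)
}

#' Simulate a contraction (motion) trace synchronized to beat times
#'
#' Triangular contraction events at the given event times, sampled at video
#' frame rate, with optional noise. Used as the paired ground truth for
#' [contraction_halfwidths()].
#'
#' @param event_times_s Contraction onsets (e.g. an `ap_trace`'s
#'   `beat_times_s`, optionally plus its `ta_times_s`).
#' @param duration_s Trace length, s.
#' @param fps Frame rate, frames/s (default 60).
#' @param rise_ms,fall_ms Rise (contraction) and fall (relaxation) durations
#'   of the triangular event, ms.
#' @param amplitude Event amplitude, arbitrary units.
#' @param noise_sd Additive noise SD.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `time_s` and `motion`.
#' @export
simulate_contraction_trace <- function(event_times_s, duration_s, fps = 60,
                                       rise_ms = 100, fall_ms = 100,
                                       amplitude = 1, noise_sd = 0,
                                       seed = NULL) {
  with_seed(seed, {
    time_s <- seq(0, duration_s, by = 1 / fps)
    y <- numeric(length(time_s))
    for (t0 in event_times_s) {
      x <- (time_s - t0) * 1000
      up <- x >= 0 & x < rise_ms
      dn <- x >= rise_ms & x <= rise_ms + fall_ms
      y[up] <- pmax(y[up], amplitude * x[up] / rise_ms)
      y[dn] <- pmax(y[dn], amplitude * (1 - (x[dn] - rise_ms) / fall_ms))
    }
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    data.frame(time_s = time_s, motion = y)
  })
}
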