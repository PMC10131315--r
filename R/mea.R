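#' Specification for a synthetic MEA field-potential trace
#'
#' Beats at a fixed rate, each a sharp biphasic depolarization spike followed
#' by a slower repolarization wave whose peak sits `fpd` ms after the spike.
#' Optional arrhythmia patterns perturb the beat sequence.
#'
#' @param rate Beating rate, beats/min.
#' @param fpd Field-potential duration (spike to repolarization peak), ms.
#' @param spike_amplitude Depolarization spike amplitude, a.u.
#' @param repol_amplitude Repolarization wave amplitude, a.u.
#' @param noise_sd Noise SD, a.u.
#' @param arrhythmic Inject an arrhythmic beat pattern.
#' @param pattern `"irregular"` (jittered interbeat intervals, CV about 25%)
#'   or `"ectopic"` (premature extra beats at 0.35 of the cycle length).
#' @param sample_rate Sampling rate, Hz.
#' @param duration_s Trace length, s.
#' @param seed Optional RNG seed.
#' @return An object of class `mea_spec`.
#' @export
mea_trace_spec <- function(rate = 60, fpd = 400, spike_amplitude = 100,
                           repol_amplitude = 25, noise_sd = 1,
                           arrhythmic = FALSE,
                           pattern = c("irregular", "ectopic"),
                           sample_rate = 10000, duration_s = 30,
                           seed = NULL) {
  assert_number(rate, "rate", lower = 1e-6)
  assert_number(fpd, "fpd", lower = 1e-6)
  assert_number(sample_rate, "sample_rate", lower = 1)
  pattern <- match.arg(pattern)
  rr_ms <- 60000 / rate
  if (fpd >= rr_ms) stop_cc("fpd (%g ms) must be below the beat period (%g ms)",
                            fpd, rr_ms, class = "cardioclamp_spec_error")
  structure(list(rate = rate, fpd = fpd, spike_amplitude = spike_amplitude,
                 repol_amplitude = repol_amplitude, noise_sd = noise_sd,
                 arrhythmic = isTRUE(arrhythmic), pattern = pattern,
                 sample_rate = sample_rate, duration_s = duration_s,
                 seed = seed),
            class = "mea_spec")
}

#' Simulate an MEA field-potential trace
#'
#' @param spec An [mea_trace_spec()].
#' @return An `fp_trace` object: `time_s`, `signal`, `sample_rate`,
#'   generating `spec` and ground-truth `beat_times_s`.
#' @export
simulate_mea_trace <- function(spec) {
  if (!inherits(spec, "mea_spec")) stop_cc("'spec' must be an mea_trace_spec")
  with_seed(spec$seed, {
    fs <- spec$sample_rate
    time_s <- seq(0, spec$duration_s, by = 1 / fs)
    n <- length(time_s)
    rr_s <- 60 / spec$rate
    beats <- seq(0.5, spec$duration_s - rr_s * 0.5, by = rr_s)
    if (spec$arrhythmic) {
      if (spec$pattern == "irregular") {
        iei <- diff(beats)
        iei <- iei * exp(rnorm(length(iei), 0, 0.25))
        beats <- cumsum(c(beats[1], iei))
        beats <- beats[beats < spec$duration_s - 0.2]
      } else {
        ect <- beats[seq(2, length(beats), by = 3)] + 0.35 * rr_s
        beats <- sort(c(beats, ect))
      }
    }
    sig <- numeric(n)
    for (b in beats) {
      x <- (time_s - b) * 1000  # ms after beat
      # biphasic spike: derivative-of-Gaussian, width ~2 ms
      w <- abs(x) < 10
      sig[w] <- sig[w] - spec$spike_amplitude * x[w] / 2 * exp(0.5 - (x[w] / 2)^2 / 2)
      # repolarization wave at fpd
      wr <- abs(x - spec$fpd) < 150
      sig[wr] <- sig[wr] + spec$repol_amplitude *
        exp(-((x[wr] - spec$fpd) / 40)^2 / 2)
    }
    if (spec$noise_sd > 0) sig <- sig + rnorm(n, 0, spec$noise_sd)
    structure(list(time_s = time_s, signal = sig, sample_rate = fs,
                   spec = spec, beat_times_s = beats),
              class = "fp_trace")
  })
}

#' Bazett rate correction
#'
#' `FPDc = FPD / sqrt(RR)` with the interbeat interval RR in seconds; the
#' correction is the identity at RR = 1 s.
#'
#' @param fpd_ms Field-potential duration, ms.
#' @param rr_s Interbeat interval, seconds.
#' @return Corrected FPD, ms.
#' @examples
#' bazett(400, 1)      # 400
#' bazett(350, 0.667)  # ~428.6
#' @export
bazett <- function(fpd_ms, rr_s) {
  if (any(rr_s <= 0)) stop_cc("RR interval must be positive")
  fpd_ms / sqrt(rr_s)
}

#' Analyze an MEA field-potential trace
#'
#' Detects depolarization spikes (largest-magnitude deflections with a
#' refractory separation), measures the field-potential duration per beat as
#' the interval from the spike to the largest-magnitude deflection in the
#' post-spike repolarization window (polarity-agnostic), applies the Bazett
#' correction, and flags rate-based exclusion (beating rate below 20 or
#' above 90 per minute) and arrhythmia (interbeat-interval coefficient of
#' variation above `arr_cv`, or any premature interval below half the median).
#'
#' @param trace An `fp_trace` (or list with `time_s`, `signal`,
#'   `sample_rate`).
#' @param repol_window_ms Repolarization search window after the spike, ms;
#'   the upper bound is additionally capped at 92% of the median beat
#'   interval.
#' @param arr_cv Arrhythmia threshold on the IEI coefficient of variation.
#' @return An `fp_record`: `bpm`, `fpd` (ms), `fpdc` (ms), `arrhythmic`,
#'   `excluded` (+ `exclusion_reason`), `n_beats`, `beat_times_s`,
#'   `fpd_per_beat`.
#' @export
analyze_fp <- function(trace, repol_window_ms = c(120, 900), arr_cv = 0.15) {
  y <- trace$signal
  t <- trace$time_s
  fs <- trace$sample_rate
  thr <- 0.5 * max(abs(y))
  sep_n <- max(1L, round(0.25 * fs))
  pk <- find_peaks(abs(y), min_height = thr, min_sep = sep_n)
  if (length(pk) < 3L) {
    stop_cc("insufficient data: %d beats detected (need >= 3)", length(pk),
            class = "cardioclamp_data_error")
  }
  beat_t <- t[pk]
  iei <- diff(beat_t)
  rr <- stats::median(iei)
  bpm <- 60 / mean(iei)

  w_lo <- repol_window_ms[1] / 1000
  w_hi <- min(repol_window_ms[2] / 1000, 0.92 * rr)
  fpd_beats <- vapply(seq_along(pk), function(i) {
    i0 <- pk[i] + round(w_lo * fs)
    i1 <- pk[i] + round(w_hi * fs)
    if (i < length(pk)) i1 <- min(i1, pk[i + 1L] - round(0.05 * fs))
    if (i1 <= i0 || i1 > length(y)) return(NA_real_)
    seg <- i0:i1
    rp <- seg[which.max(abs(y[seg]))]
    (t[rp] - t[pk[i]]) * 1000
  }, numeric(1))
  fpd <- mean(fpd_beats, na.rm = TRUE)
  fpdc <- bazett(fpd, rr)

  excluded <- bpm < 20 || bpm > 90
  reason <- if (bpm < 20) "beating rate below 20" else
    if (bpm > 90) "beating rate above 90" else NA_character_
  arrhythmic <- (sd(iei) / mean(iei) > arr_cv) || any(iei < 0.5 * rr)
  structure(list(bpm = bpm, fpd = fpd, fpdc = fpdc,
                 arrhythmic = arrhythmic, excluded = excluded,
                 exclusion_reason = reason, n_beats = length(pk),
                 beat_times_s = beat_t, fpd_per_beat = fpd_beats),
            class = "fp_record")
}

#' @export
print.fp_record <- function(x, ...) {
  cat(sprintf("MEA record: %.1f BPM, FPD %.1f ms, FPDc %.1f ms%s%s\n",
              x$bpm, x$fpd, x$fpdc,
              if (x$arrhythmic) " [arrhythmic]" else "",
              if (x$excluded) sprintf(" [excluded: %s]", x$exclusion_reason) else ""))
  invisible(x)
}

#' Cohort MEA summary
#'
#' Group means and SEMs of the Bazett-corrected FPD over non-excluded
#' records, plus the arrhythmia percentage per group. Rate-based exclusion is
#' applied before any averaging; excluded records are counted but never
#' averaged.
#'
#' @param records List of `fp_record` objects.
#' @param groups Group label per record.
#' @return Data frame per group: `n`, `n_excluded`, `fpdc_mean`, `fpdc_sem`,
#'   `bpm_mean`, `pct_arrhythmic`, `all_excluded` flag.
#' @export
cohort_fp_summary <- function(records, groups) {
  if (length(records) != length(groups)) stop_cc("one group label per record required")
  do.call(rbind, lapply(unique(groups), function(g) {
    rs <- records[groups == g]
    exc <- vapply(rs, function(r) r$excluded, logical(1))
    keep <- rs[!exc]
    if (!length(keep)) {
      return(data.frame(group = g, n = 0L, n_excluded = sum(exc),
                        fpdc_mean = NA_real_, fpdc_sem = NA_real_,
                        bpm_mean = NA_real_, pct_arrhythmic = NA_real_,
                        all_excluded = TRUE))
    }
    fpdc <- vapply(keep, function(r) r$fpdc, numeric(1))
    arr <- vapply(keep, function(r) r$arrhythmic, logical(1))
    data.frame(group = g, n = length(keep), n_excluded = sum(exc),
               fpdc_mean = mean(fpdc), fpdc_sem = sem(fpdc),
               bpm_mean = mean(vapply(keep, function(r) r$bpm, numeric(1))),
               pct_arrhythmic = 100 * mean(arr),
               all_excluded = FALSE)
  }))
}
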