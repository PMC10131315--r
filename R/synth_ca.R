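#' Specification for a synthetic Ca2+ transient recording
#'
#' Parameterizes a fluorescence trace of spontaneous Ca2+ transients:
#' triangular-ramp events (linear rise and decay sized so the 10-90% rise and
#' 90-10% decay times match the targets) on a constant baseline, plus additive
#' Gaussian noise. Abnormalities are injected by directives:
#' \describe{
#'   \item{OS}{oscillations: `magnitude` (>= 2) consecutive peaks whose
#'     intervening troughs do not return to baseline.}
#'   \item{LP}{low-amplitude peak inserted after event `site`, with amplitude
#'     `magnitude` expressed as a fraction of the preceding peak.}
#'   \item{VA}{continuously varying amplitude over 5 events starting at
#'     `site`, amplitude coefficient of variation = `magnitude`.}
#'   \item{PA}{prolonged decay: event `site`'s decay time multiplied by
#'     `magnitude`.}
#'   \item{RD}{prolonged rise: event `site`'s rise time multiplied by
#'     `magnitude`.}
#' }
#'
#' @param rate Event rate, events/min.
#' @param amplitude Transient amplitude in dF/F0 units.
#' @param rise_10_90 10-90% rise time, ms.
#' @param decay_90_10 90-10% decay time, ms.
#' @param baseline_f0 Baseline fluorescence, a.u.
#' @param background Constant background fluorescence, a.u.
#' @param noise_sd Noise SD, a.u.
#' @param abnormalities List of directives
#'   `list(type = "OS"|"LP"|"VA"|"PA"|"RD", site = i, magnitude = m)`.
#' @param sample_rate Sampling rate, Hz (20-30 typical).
#' @param duration_s Recording length, s.
#' @param seed Optional RNG seed.
#' @return An object of class `ca_spec`.
#' @export
ca_trace_spec <- function(rate = 30, amplitude = 1.0, rise_10_90 = 150,
                          decay_90_10 = 400, baseline_f0 = 100,
                          background = 20, noise_sd = 0.5,
                          abnormalities = list(), sample_rate = 25,
                          duration_s = 40, seed = NULL) {
  assert_number(rate, "rate", lower = 1e-6)
  assert_number(amplitude, "amplitude", lower = 1e-9)
  assert_number(rise_10_90, "rise_10_90", lower = 1e-9)
  assert_number(decay_90_10, "decay_90_10", lower = 1e-9)
  assert_number(baseline_f0, "baseline_f0", lower = 1e-9)
  assert_number(sample_rate, "sample_rate", lower = 1)
  sites <- vapply(abnormalities, function(a) a$site %||% NA_integer_, numeric(1))
  if (anyDuplicated(stats::na.omit(sites))) {
    stop_cc("conflicting abnormality directives at the same site",
            class = "cardioclamp_spec_error")
  }
  for (a in abnormalities) {
    type <- a$type %||% stop_cc("abnormality directive lacks a type")
    if (!type %in% c("OS", "LP", "VA", "PA", "RD")) {
      stop_cc("unknown abnormality type '%s'", type)
    }
    if (type == "OS" && (a$magnitude %||% 0) < 2) {
      stop_cc("OS magnitude is a number of unreturned peaks and must be >= 2",
              class = "cardioclamp_spec_error")
    }
  }
  structure(list(rate = rate, amplitude = amplitude, rise_10_90 = rise_10_90,
                 decay_90_10 = decay_90_10, baseline_f0 = baseline_f0,
                 background = background, noise_sd = noise_sd,
                 abnormalities = abnormalities, sample_rate = sample_rate,
                 duration_s = duration_s, seed = seed),
            class = "ca_spec")
}

#' Simulate a Ca2+ fluorescence trace
#'
#' Renders a [ca_trace_spec()]: raw fluorescence
#' `F = background + F0 * (1 + dF)` where `dF` is the sum of the event
#' templates in dF/F0 units, plus noise. A spec with an empty abnormality
#' list produces a trace the classifier calls normal (round-trip contract).
#'
#' @param spec A [ca_trace_spec()].
#' @return A `ca_raw` object: `time_s`, `f` (a.u.), `background`,
#'   `sample_rate`, the generating `spec`, and the ground-truth event table
#'   in `$truth`.
#' @export
simulate_ca_trace <- function(spec) {
  if (!inherits(spec, "ca_spec")) stop_cc("'spec' must be a ca_trace_spec")
  with_seed(spec$seed, {
    fs <- spec$sample_rate
    time_s <- seq(0, spec$duration_s, by = 1 / fs)
    n <- length(time_s)
    period_s <- 60 / spec$rate
    onsets <- seq(1, spec$duration_s - 1, by = period_s)
    nev <- length(onsets)

    amp <- rep(spec$amplitude, nev)
    rise <- rep(spec$rise_10_90, nev)
    decay <- rep(spec$decay_90_10, nev)
    lp_extra <- list()
    os_runs <- list()
    for (a in spec$abnormalities) {
      s <- a$site %||% 2L
      m <- a$magnitude
      switch(a$type,
        VA = {
          idx <- s:min(s + 4L, nev)
          fac <- c(1 + m, 1 - m, 1 + m, 1 - m, 1)[seq_along(idx)]
          amp[idx] <- amp[idx] * fac
        },
        PA = decay[s] <- decay[s] * (m %||% 2.5),
        RD = rise[s] <- rise[s] * (m %||% 2.5),
        LP = lp_extra[[length(lp_extra) + 1L]] <- list(site = s, frac = m),
        OS = os_runs[[length(os_runs) + 1L]] <- list(site = s, npeaks = m))
    }

    dff <- numeric(n)
    add_event <- function(dff, t0, a, r_ms, d_ms) {
      r_tot <- r_ms / 0.8 / 1000
      d_tot <- d_ms / 0.8 / 1000
      x <- time_s - t0
      up <- x >= 0 & x < r_tot
      dn <- x >= r_tot & x <= r_tot + d_tot
      dff[up] <- dff[up] + a * x[up] / r_tot
      dff[dn] <- dff[dn] + a * (1 - (x[dn] - r_tot) / d_tot)
      dff
    }
    peak_times <- onsets + rise / 0.8 / 1000
    for (i in seq_len(nev)) {
      dff <- add_event(dff, onsets[i], amp[i], rise[i], decay[i])
    }
    truth <- data.frame(onset_s = onsets, peak_time_s = peak_times,
                        amplitude = amp, rise_10_90 = rise,
                        decay_90_10 = decay)
    for (lp in lp_extra) {
      s <- min(lp$site, nev - 1L)
      t0 <- onsets[s] + period_s * 0.55
      a <- lp$frac * amp[s]
      dff <- add_event(dff, t0, a, spec$rise_10_90, spec$decay_90_10)
    }
    for (os in os_runs) {
      i0 <- min(os$site, nev)
      i1 <- min(os$site + os$npeaks - 1L, nev)
      reg <- time_s >= peak_times[i0] & time_s <= peak_times[i1]
      floor_level <- 0.45 * min(amp[i0:i1])
      dff[reg] <- pmax(dff[reg], floor_level)
    }

    f <- spec$background + spec$baseline_f0 * (1 + dff)
    if (spec$noise_sd > 0) f <- f + rnorm(n, 0, spec$noise_sd)
    structure(list(time_s = time_s, f = f, background = spec$background,
                   sample_rate = fs, spec = spec, truth = truth),
              class = "ca_raw")
  })
}

#' @export
print.ca_raw <- function(x, ...) {
  cat(sprintf("Raw Ca2+ trace: %.0f s @ %g Hz, %d events, %d abnormality directives\n",
              max(x$time_s), x$sample_rate, nrow(x$truth),
              length(x$spec$abnormalities)))
  invisible(x)
}
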