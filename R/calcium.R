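#' Preprocess a raw Ca2+ fluorescence trace
#'
#' Subtracts the background (constant or series), estimates the baseline
#' fluorescence F0 as the 10th percentile of the background-subtracted trace,
#' and expresses the signal as dF/F0.
#'
#' @param raw A `ca_raw` object from [simulate_ca_trace()], or a list/data
#'   frame with `time_s` and `f`.
#' @param background Background to subtract: a constant, a series the same
#'   length as the trace, or `NULL` to use `raw$background` (0 if absent).
#' @param f0_quantile Quantile defining F0.
#' @return A `ca_trace` object: `time_s`, `dff`, `f0`, `sample_rate`.
#' @export
ca_preprocess <- function(raw, background = NULL, f0_quantile = 0.10) {
  f <- raw$f
  t <- raw$time_s
  bg <- background %||% raw$background %||% 0
  if (!(length(bg) %in% c(1L, length(f)))) {
    stop_cc("background length %d incompatible with trace length %d",
            length(bg), length(f))
  }
  fb <- f - bg
  f0 <- as.numeric(stats::quantile(fb, f0_quantile))
  if (!is.finite(f0) || f0 <= 0) {
    stop_cc("nonpositive baseline F0 (%.3g): check background subtraction", f0)
  }
  fs <- raw$sample_rate %||% (1 / stats::median(diff(t)))
  structure(list(time_s = t, dff = (fb - f0) / f0, f0 = f0, sample_rate = fs),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("Ca2+ trace (dF/F0): %.0f s @ %g Hz, F0 = %.3g\n",
              max(x$time_s), x$sample_rate, x$f0))
  invisible(x)
}

#' Detect and parameterize Ca2+ transients
#'
#' Peak detection with a prominence threshold of `prom_factor` times the
#' baseline noise SD (estimated from the high-frequency residual) and a
#' minimum event separation. Per event: amplitude (peak minus preceding
#' trough), 10-90% rise time, 90-10% decay time, half-width (width at 50%
#' amplitude), Ca90 duration (between the 10% amplitude points, i.e. to 90%
#' recovery), and interevent interval. The instantaneous frequency is the
#' mean over events of 1/IEI. Events smaller than `major_frac` of the median
#' amplitude are retained in the table but excluded from the interevent and
#' variability statistics (they are candidate low-amplitude peaks, not full
#' transients).
#'
#' @param trace A `ca_trace` from [ca_preprocess()].
#' @param prom_factor Prominence threshold in baseline-noise SDs.
#' @param min_separation_ms Minimum event separation, ms.
#' @param major_frac Fraction of the median amplitude below which an event is
#'   minor.
#' @param min_duration_s Warn below this recording length.
#' @return A `ca_events` object: `$events` data frame, `$stats` (per-cell
#'   means/SDs and instantaneous frequency), `$n_events`, `$baseline_noise`.
#' @export
ca_transients <- function(trace, prom_factor = 4, min_separation_ms = 150,
                          major_frac = 0.5, min_duration_s = 30) {
  if (!inherits(trace, "ca_trace")) stop_cc("'trace' must come from ca_preprocess()")
  y <- trace$dff
  t <- trace$time_s
  fs <- trace$sample_rate
  if (max(t) - min(t) < min_duration_s) {
    warning(sprintf("recording is %.1f s (< %g s); statistics may be unstable",
                    max(t) - min(t), min_duration_s))
  }
  resid <- y - stats::runmed(y, 5)
  noise <- stats::mad(resid)
  prom <- max(prom_factor * noise, 0.02 * max(y))
  sep_n <- max(1L, round(min_separation_ms / 1000 * fs))
  pk <- find_peaks(y, min_sep = sep_n, min_prom = prom)
  pk <- pk[y[pk] > prom]

  rows <- lapply(seq_along(pk), function(i) {
    p <- pk[i]
    lo <- if (i > 1L) pk[i - 1L] else 1L
    hi <- if (i < length(pk)) pk[i + 1L] else length(y)
    tr_l <- lo + which.min(y[lo:p]) - 1L
    tr_r <- p + which.min(y[p:hi]) - 1L
    amp_l <- y[p] - y[tr_l]
    amp_r <- y[p] - y[tr_r]
    lvl <- function(base, frac, amp) base + frac * amp
    t10u <- cross_time(t, y, lvl(y[tr_l], 0.1, amp_l), idx = tr_l:p, direction = "up")
    t90u <- cross_time(t, y, lvl(y[tr_l], 0.9, amp_l), idx = tr_l:p, direction = "up")
    t50u <- cross_time(t, y, lvl(y[tr_l], 0.5, amp_l), idx = tr_l:p, direction = "up")
    t90d <- cross_time(t, y, lvl(y[tr_r], 0.9, amp_r), idx = p:tr_r, direction = "down")
    t10d <- cross_time(t, y, lvl(y[tr_r], 0.1, amp_r), idx = p:tr_r, direction = "down")
    t50d <- cross_time(t, y, lvl(y[tr_r], 0.5, amp_r), idx = p:tr_r, direction = "down")
    data.frame(peak_idx = p, peak_time_s = t[p], amplitude = amp_l,
               trough_left = y[tr_l], trough_right = y[tr_r],
               rise_10_90 = (t90u - t10u) * 1000,
               decay_90_10 = (t10d - t90d) * 1000,
               half_width = (t50d - t50u) * 1000,
               ca90_duration = (t10d - t10u) * 1000)
  })
  events <- if (length(rows)) do.call(rbind, rows) else data.frame()
  stats <- list(instantaneous_frequency = NA_real_, frequency_defined = FALSE)
  if (nrow(events)) {
    med_amp <- stats::median(events$amplitude)
    events$major <- events$amplitude >= major_frac * med_amp
    maj <- events[events$major, , drop = FALSE]
    events$iei_s <- NA_real_
    if (nrow(maj) >= 2L) {
      iei <- diff(maj$peak_time_s)
      events$iei_s[match(maj$peak_idx[-1], events$peak_idx)] <- iei
      stats <- list(
        instantaneous_frequency = instantaneous_frequency(iei),
        frequency_defined = TRUE,
        mean_iei_s = mean(iei),
        amplitude_mean = mean(maj$amplitude),
        amplitude_sd = sd(maj$amplitude),
        ca90_mean = mean(maj$ca90_duration, na.rm = TRUE),
        ca90_sd = sd(maj$ca90_duration[is.finite(maj$ca90_duration)]),
        half_width_mean = mean(maj$half_width, na.rm = TRUE),
        rise_mean = mean(maj$rise_10_90, na.rm = TRUE),
        rise_sd = sd(maj$rise_10_90[is.finite(maj$rise_10_90)]),
        decay_mean = mean(maj$decay_90_10, na.rm = TRUE))
    } else {
      stats$note <- "fewer than 2 major events: frequency undefined"
    }
  }
  structure(list(events = events, stats = stats, n_events = nrow(events),
                 baseline_noise = noise),
            class = "ca_events")
}

#' Instantaneous event frequency from interevent intervals
#'
#' Each interevent interval is converted to a frequency and the frequencies
#' are averaged: `mean(1 / iei)`.
#'
#' @param iei_s Interevent intervals, seconds.
#' @return Frequency in Hz.
#' @examples
#' instantaneous_frequency(c(0.5, 1))  # (2 + 1)/2 = 1.5 Hz
#' @export
instantaneous_frequency <- function(iei_s) {
  iei_s <- iei_s[is.finite(iei_s) & iei_s > 0]
  if (!length(iei_s)) return(NA_real_)
  mean(1 / iei_s)
}

#' @export
print.ca_events <- function(x, ...) {
  cat(sprintf("Ca2+ transients: %d events (noise SD %.3g)\n",
              x$n_events, x$baseline_noise))
  if (isTRUE(x$stats$frequency_defined)) {
    cat(sprintf("  instantaneous frequency %.3f Hz, amplitude %.3g +/- %.3g\n",
                x$stats$instantaneous_frequency, x$stats$amplitude_mean,
                x$stats$amplitude_sd))
  }
  invisible(x)
}

#' Five-class Ca2+ transient abnormality classification
#'
#' Applies the abnormality taxonomy to a parameterized trace:
#' \describe{
#'   \item{OS}{two or more consecutive peaks whose intervening troughs stay
#'     above baseline + `os_tol` times the median amplitude (oscillation
#'     without baseline return).}
#'   \item{LP}{a low-amplitude peak of at least `lp_threshold` (strict 10%
#'     rule: events below the threshold are sub-threshold deflections, not
#'     LP) and below `lp_upper` of the preceding full-size peak.}
#'   \item{PA}{decay 90-10% of any full-size event above `pa_factor` times
#'     the cell's median decay (prolonged decay / plateau).}
#'   \item{RD}{rise 10-90% above `rd_factor` times the cell's median rise
#'     (rise delay).}
#'   \item{VA}{amplitude coefficient of variation above `va_cv` over any
#'     `va_window` consecutive full-size events.}
#' }
#' A trace is normal iff no label fires. All rules are ratio/shape based, so
#' classification is invariant to uniform rescaling of the fluorescence.
#'
#' @param ca A `ca_events` object from [ca_transients()].
#' @param lp_threshold,lp_upper LP band as fractions of the preceding
#'   full-size amplitude (default \[0.10, 0.45)); ratios at or above
#'   `lp_upper` are full-size beats (amplitude variation, not LP).
#' @param os_tol Baseline-return tolerance as a fraction of the median
#'   amplitude.
#' @param pa_factor,rd_factor Prolongation factors over the cell median.
#' @param va_cv,va_window Amplitude-variability rule.
#' @return An `abnormality_call`: `labels` (subset of OS, LP, VA, PA, RD),
#'   `normal` flag, and `evidence` (event indices per label).
#' @export
classify_ca_abnormalities <- function(ca, lp_threshold = 0.10, lp_upper = 0.45,
                                      os_tol = 0.10, pa_factor = 2,
                                      rd_factor = 2, va_cv = 0.20,
                                      va_window = 5) {
  if (!inherits(ca, "ca_events")) stop_cc("'ca' must come from ca_transients()")
  ev <- ca$events
  labels <- character(0)
  evidence <- list()
  if (!nrow(ev)) {
    return(structure(list(labels = labels, normal = TRUE, evidence = evidence),
                     class = "abnormality_call"))
  }
  # size classes relative to the preceding full-size peak
  size <- character(nrow(ev))
  last_major <- NA_real_
  for (i in seq_len(nrow(ev))) {
    a <- ev$amplitude[i]
    if (is.na(last_major)) {
      size[i] <- "major"; last_major <- a
    } else {
      rel <- a / last_major
      if (rel < lp_threshold) {
        size[i] <- "minor"
      } else if (rel < lp_upper) {
        size[i] <- "lp"
      } else {
        size[i] <- "major"; last_major <- a
      }
    }
  }
  maj_idx <- which(size == "major")
  lp_idx <- which(size == "lp")
  med_amp <- stats::median(ev$amplitude[maj_idx])

  if (length(lp_idx)) {
    labels <- c(labels, "LP"); evidence$LP <- lp_idx
  }
  # OS: consecutive full-size peaks with unreturned intervening troughs
  if (length(maj_idx) >= 2L) {
    troughs <- ev$trough_right[maj_idx[-length(maj_idx)]]
    unret <- troughs > os_tol * med_amp
    r <- rle(unret)
    if (any(r$values & r$lengths >= 1L)) {
      runs <- which(r$values)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      os_ev <- unique(unlist(lapply(runs, function(k)
        maj_idx[starts[k]:(ends[k] + 1L)])))
      labels <- c(labels, "OS"); evidence$OS <- sort(os_ev)
    }
  }
  maj <- ev[maj_idx, , drop = FALSE]
  if (nrow(maj) >= 3L) {
    med_decay <- stats::median(maj$decay_90_10, na.rm = TRUE)
    med_rise <- stats::median(maj$rise_10_90, na.rm = TRUE)
    pa_ev <- maj_idx[which(maj$decay_90_10 > pa_factor * med_decay)]
    rd_ev <- maj_idx[which(maj$rise_10_90 > rd_factor * med_rise)]
    if (length(pa_ev)) { labels <- c(labels, "PA"); evidence$PA <- pa_ev }
    if (length(rd_ev)) { labels <- c(labels, "RD"); evidence$RD <- rd_ev }
  }
  if (nrow(maj) >= va_window) {
    # peak height above baseline: robust to trough elevation under OS
    amps <- maj$amplitude + maj$trough_left
    for (s in seq_len(nrow(maj) - va_window + 1L)) {
      w <- amps[s:(s + va_window - 1L)]
      if (sd(w) / mean(w) > va_cv) {
        labels <- c(labels, "VA")
        evidence$VA <- maj_idx[s:(s + va_window - 1L)]
        break
      }
    }
  }
  labels <- unique(labels)
  structure(list(labels = labels, normal = length(labels) == 0L,
                 evidence = evidence),
            class = "abnormality_call")
}

#' @export
print.abnormality_call <- function(x, ...) {
  if (x$normal) cat("Ca2+ transients: normal\n")
  else cat("Ca2+ abnormalities:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort Ca2+ abnormality summary
#'
#' Percentage of abnormal cells per condition and the within-cohort breakdown
#' by abnormality type; when cell identifiers are given, paired
#' baseline-vs-drug deltas per type are added.
#'
#' @param calls List of `abnormality_call` objects (one per cell).
#' @param conditions Condition label per cell.
#' @param cell_ids Optional cell identifier per cell (for paired deltas).
#' @param baseline Name of the baseline condition for deltas.
#' @return List with `summary` (per condition: `n`, `n_abnormal`,
#'   `pct_abnormal`, `pct_normal`), `breakdown` (per condition and type:
#'   percentage of cells carrying the label), and `deltas` (vs baseline, or
#'   `NULL`).
#' @export
cohort_abnormality_summary <- function(calls, conditions,
                                       cell_ids = NULL,
                                       baseline = "baseline") {
  if (length(calls) != length(conditions)) {
    stop_cc("one condition label per call required")
  }
  conds <- unique(conditions)
  types <- c("OS", "LP", "VA", "PA", "RD")
  abn <- !vapply(calls, function(cl) cl$normal, logical(1))
  summary <- do.call(rbind, lapply(conds, function(cc) {
    sel <- conditions == cc
    data.frame(condition = cc, n = sum(sel), n_abnormal = sum(abn[sel]),
               pct_abnormal = 100 * sum(abn[sel]) / sum(sel),
               pct_normal = 100 * sum(!abn[sel]) / sum(sel))
  }))
  breakdown <- do.call(rbind, lapply(conds, function(cc) {
    sel <- which(conditions == cc)
    cnt <- vapply(types, function(tp)
      sum(vapply(calls[sel], function(cl) tp %in% cl$labels, logical(1))),
      numeric(1))
    data.frame(condition = cc, type = types, n = cnt,
               pct = 100 * cnt / length(sel))
  }))
  deltas <- NULL
  if (!is.null(cell_ids) && baseline %in% conds) {
    others <- setdiff(conds, baseline)
    base_b <- breakdown[breakdown$condition == baseline, ]
    deltas <- do.call(rbind, lapply(others, function(cc) {
      b <- breakdown[breakdown$condition == cc, ]
      data.frame(condition = cc, type = b$type,
                 delta_pct = b$pct - base_b$pct[match(b$type, base_b$type)])
    }))
  }
  list(summary = summary, breakdown = breakdown, deltas = deltas)
}
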