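#' Detect action potentials in a current-clamp trace
#'
#' Upstrokes are marked where dV/dt exceeds `dvdt_threshold` for at least
#' `sustain_ms`; candidate events whose amplitude (peak minus the preceding
#' diastolic minimum) is below `min_amplitude` are rejected, which separates
#' full APs from subthreshold triggered-activity humps. A flat trace yields
#' zero segments (not an error).
#'
#' @param trace An `ap_trace` (see [simulate_ap_train()]) or a list with
#'   `time_s`, `potential_mv`, `sample_rate`.
#' @param dvdt_threshold Upstroke detection threshold, V/s.
#' @param sustain_ms Minimum time dV/dt must stay above threshold, ms.
#' @param min_amplitude Minimum AP amplitude, mV.
#' @return An `ap_segments` data frame: one row per AP with `upstroke_time_s`,
#'   `t_vmax_s`, `peak_time_s`, `peak_mv`, `mdp_mv` (preceding diastolic
#'   minimum), `vmax` (V/s), and index columns into the trace.
#' @export
detect_aps <- function(trace, dvdt_threshold = 2, sustain_ms = 1,
                       min_amplitude = 40) {
  v <- trace$potential_mv
  fs <- trace$sample_rate
  t <- trace$time_s
  dt_ms <- 1000 / fs
  # dV/dt as a 0.5-ms span slope: suppresses sample-to-sample noise the way
  # an acquisition low-pass filter would, without biasing the upstroke
  k <- max(1L, round(0.5 / dt_ms))
  n_v <- length(v)
  dvdt <- c((v[(1L + k):n_v] - v[1:(n_v - k)]) / (k * dt_ms), rep(0, k))
  above <- dvdt > dvdt_threshold
  sustain_n <- max(1L, round(sustain_ms / dt_ms))

  empty <- data.frame(upstroke_idx = integer(0), upstroke_time_s = numeric(0),
                      t_vmax_s = numeric(0), peak_idx = integer(0),
                      peak_time_s = numeric(0), peak_mv = numeric(0),
                      mdp_idx = integer(0), mdp_mv = numeric(0),
                      vmax = numeric(0))
  if (!any(above)) return(structure(empty, class = c("ap_segments", "data.frame")))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- starts[r$values & r$lengths >= sustain_n]
  if (!length(cand)) return(structure(empty, class = c("ap_segments", "data.frame")))
  # merge candidates within 50 ms (same upstroke)
  keep <- c(TRUE, diff(t[cand]) > 0.05)
  cand <- cand[keep]

  n <- length(v)
  rows <- lapply(seq_along(cand), function(i) {
    u <- cand[i]
    seg_end <- if (i < length(cand)) cand[i + 1L] - 1L else n
    search_end <- min(u + round(0.3 * fs), seg_end)
    pk <- u + which.max(v[u:search_end]) - 1L
    base_start <- if (i > 1L) {
      prev_end <- cand[i - 1L] + round(0.3 * fs)
      max(min(prev_end, u - 1L), 1L)
    } else 1L
    mdp_i <- base_start + which.min(v[base_start:max(base_start, u - 1L)]) - 1L
    up_win <- max(1L, u - 2L):pk
    vx <- max(dvdt[up_win])
    t_vmax <- t[up_win[which.max(dvdt[up_win])]]
    data.frame(upstroke_idx = u, upstroke_time_s = t[u], t_vmax_s = t_vmax,
               peak_idx = pk, peak_time_s = t[pk], peak_mv = v[pk],
               mdp_idx = mdp_i, mdp_mv = v[mdp_i], vmax = vx)
  })
  segs <- do.call(rbind, rows)
  segs <- segs[segs$peak_mv - segs$mdp_mv >= min_amplitude, , drop = FALSE]
  rownames(segs) <- NULL
  structure(segs, class = c("ap_segments", "data.frame"))
}

#' Action-potential features per cell
#'
#' From detected AP segments: beating rate from the mean inter-upstroke
#' interval; per-AP amplitude (peak minus preceding MDP), maximal upstroke
#' velocity, and AP durations measured from the time of maximal dV/dt to the
#' crossing of the repolarization level `MDP + (1 - x/100) * APA`
#' (sub-sample linear interpolation).
#'
#' @param segments An `ap_segments` frame from [detect_aps()].
#' @param trace The trace the segments were detected in.
#' @return An `ap_features` object: `$per_ap` data frame and scalar summary
#'   fields `bpm`, `vmax`, `apd50`, `apd90`, `apa`, `mdp`, `apd_ratio`,
#'   `subtype`, `n_aps`, `bpm_defined`.
#' @export
compute_ap_features <- function(segments, trace) {
  if (!nrow(segments)) stop_cc("no AP segments to featurize")
  v <- trace$potential_mv
  t <- trace$time_s
  n <- length(v)
  per <- segments
  per$apa <- per$peak_mv - per$mdp_mv
  per$apd50 <- NA_real_
  per$apd90 <- NA_real_
  for (i in seq_len(nrow(per))) {
    seg_end <- if (i < nrow(per)) per$upstroke_idx[i + 1L] - 1L else n
    idx <- per$peak_idx[i]:seg_end
    for (x in c(50, 90)) {
      level <- per$mdp_mv[i] + (1 - x / 100) * per$apa[i]
      tc <- cross_time(t, v, level, idx = idx, direction = "down")
      if (is.finite(tc)) {
        per[[paste0("apd", x)]][i] <- (tc - per$t_vmax_s[i]) * 1000
      }
    }
  }
  bpm_defined <- nrow(per) >= 2L
  bpm <- if (bpm_defined) 60 / mean(diff(per$upstroke_time_s)) else NA_real_
  apd50 <- mean(per$apd50, na.rm = TRUE)
  apd90 <- mean(per$apd90, na.rm = TRUE)
  apa <- mean(per$apa)
  out <- structure(list(
    per_ap = per,
    bpm = bpm, bpm_defined = bpm_defined,
    vmax = mean(per$vmax),
    apd50 = apd50, apd90 = apd90,
    apa = apa, mdp = mean(per$mdp_mv),
    apd_ratio = apd90 / apd50,
    n_aps = nrow(per)
  ), class = "ap_features")
  out$subtype <- classify_subtype(out)
  out
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("AP features (%d APs, %s)\n", x$n_aps, x$subtype))
  cat(sprintf("  BPM %.1f | Vmax %.1f V/s | APD50 %.1f ms | APD90 %.1f ms\n",
              x$bpm, x$vmax, x$apd50, x$apd90))
  cat(sprintf("  APA %.1f mV | MDP %.1f mV | APD90/APD50 %.3f\n",
              x$apa, x$mdp, x$apd_ratio))
  invisible(x)
}

#' Ventricular-like subtype classification
#'
#' A cell is classified as ventricular-like iff its APD90/APD50 ratio is
#' strictly below 1.35 (pronounced plateau) and its AP amplitude strictly
#' above 90 mV; anything else (including values exactly at either boundary)
#' is "other".
#'
#' @param features An `ap_features` object, or `NULL` if `apd_ratio`/`apa`
#'   are given directly.
#' @param apd_ratio,apa Optional direct values.
#' @param ratio_max,apa_min Classification boundaries (strict).
#' @return `"ventricular-like"` or `"other"`.
#' @export
classify_subtype <- function(features = NULL, apd_ratio = NULL, apa = NULL,
                             ratio_max = 1.35, apa_min = 90) {
  if (!is.null(features)) {
    apd_ratio <- features$apd_ratio
    apa <- features$apa
  }
  if (!is.finite(apd_ratio) || !is.finite(apa)) return("other")
  if (apd_ratio < ratio_max && apa > apa_min) "ventricular-like" else "other"
}

#' Triggered-activity detection in diastolic intervals
#'
#' Scans each diastolic interval (from shortly after an AP's 90%
#' repolarization to just before the next upstroke) for depolarization humps
#' exceeding the local diastolic baseline by more than `threshold`; a cell is
#' flagged arrhythmic iff at least one TA event is found.
#'
#' @param segments `ap_segments` from [detect_aps()].
#' @param trace The underlying trace.
#' @param threshold TA amplitude threshold above the diastolic baseline, mV.
#' @param margin_ms Guard margin after repolarization / before the next
#'   upstroke, ms.
#' @return List with `ta_count`, `arrhythmic`, and `events` (data frame of
#'   peak times and amplitudes above baseline).
#' @export
detect_triggered_activity <- function(segments, trace, threshold = 10,
                                      margin_ms = 30) {
  v <- trace$potential_mv
  t <- trace$time_s
  fs <- trace$sample_rate
  n <- length(v)
  events <- list()
  if (nrow(segments)) {
    feats <- compute_ap_features(segments, trace)
    per <- feats$per_ap
    for (i in seq_len(nrow(per))) {
      apd90_s <- if (is.finite(per$apd90[i])) per$apd90[i] / 1000 else 0.4
      di_start <- per$t_vmax_s[i] + apd90_s + margin_ms / 1000
      di_end <- if (i < nrow(per)) per$upstroke_time_s[i + 1L] - margin_ms / 1000 else t[n]
      i0 <- max(1L, round(di_start * fs) + 1L)
      i1 <- min(n, round(di_end * fs) + 1L)
      if (i1 - i0 < fs * 0.05) next
      seg <- v[i0:i1]
      ks <- max(1L, round(0.005 * fs))  # 5-ms smoothing against noise chatter
      if (ks > 1L) {
        sm <- stats::filter(seg, rep(1 / ks, ks), sides = 2)
        seg <- ifelse(is.na(sm), seg, as.numeric(sm))
      }
      baseline <- stats::median(seg)
      above <- seg > baseline + threshold
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- starts[k]:ends[k]
        pk <- run[which.max(seg[run])]
        events[[length(events) + 1L]] <- data.frame(
          time_s = t[i0 + pk - 1L],
          amplitude_mv = seg[pk] - baseline)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), amplitude_mv = numeric(0))
  list(ta_count = nrow(events), arrhythmic = nrow(events) >= 1L,
       events = events)
}

#' Cohort triggered-activity fraction
#'
#' Percentage of cells flagged arrhythmic (at least one TA event).
#'
#' @param flags Logical vector, one per cell.
#' @return Percentage in \[0, 100\].
#' @examples
#' cohort_ta_fraction(c(rep(TRUE, 11), rep(FALSE, 30)))  # 26.8%
#' @export
cohort_ta_fraction <- function(flags) {
  if (!length(flags)) return(0)
  100 * sum(flags) / length(flags)
}

#' Spike-and-dome morphology detection
#'
#' Searches the early-repolarization window (first `notch_window_frac` of
#' APD90 after the upstroke) for a local minimum (notch) followed by a
#' secondary local maximum (dome); the AP is flagged when the dome exceeds
#' the notch by more than `dome_threshold`.
#'
#' @param segments `ap_segments` from [detect_aps()].
#' @param trace The underlying trace.
#' @param notch_window_frac Fraction of APD90 defining the notch search
#'   window.
#' @param dome_threshold Minimum dome-over-notch amplitude, mV.
#' @param smooth_ms Moving-average smoothing before extremum search, ms.
#' @return List with `flag`, and when flagged `notch_mv`, `dome_mv`,
#'   `dome_minus_notch`, `ap_index`.
#' @export
detect_spike_and_dome <- function(segments, trace, notch_window_frac = 0.25,
                                  dome_threshold = 2, smooth_ms = 1) {
  if (!nrow(segments)) return(list(flag = FALSE))
  v <- trace$potential_mv
  fs <- trace$sample_rate
  k <- max(1L, round(smooth_ms * fs / 1000))
  vs <- if (k > 1L) stats::filter(v, rep(1 / k, k), sides = 2) else v
  feats <- compute_ap_features(segments, trace)
  per <- feats$per_ap
  best <- list(flag = FALSE, dome_minus_notch = -Inf)
  for (i in seq_len(nrow(per))) {
    if (!is.finite(per$apd90[i])) next
    u <- per$upstroke_idx[i]
    w_end <- u + round(notch_window_frac * per$apd90[i] / 1000 * fs)
    d_end <- u + round(0.6 * per$apd90[i] / 1000 * fs)
    w_end <- min(w_end, length(v) - 1L); d_end <- min(d_end, length(v) - 1L)
    win <- (u + round(0.002 * fs)):w_end
    if (length(win) < 5L) next
    loc_min <- win[which(diff(sign(diff(vs[win]))) > 0) + 1L]
    if (!length(loc_min)) next
    notch <- loc_min[which.min(vs[loc_min])]
    after <- notch:d_end
    if (length(after) < 5L) next
    loc_max <- after[which(diff(sign(diff(vs[after]))) < 0) + 1L]
    if (!length(loc_max)) next
    dome <- loc_max[which.max(vs[loc_max])]
    delta <- vs[dome] - vs[notch]
    if (is.finite(delta) && delta > best$dome_minus_notch) {
      best <- list(flag = delta > dome_threshold,
                   notch_mv = unname(vs[notch]), dome_mv = unname(vs[dome]),
                   dome_minus_notch = unname(delta), ap_index = i)
    }
  }
  if (!is.finite(best$dome_minus_notch)) best <- list(flag = FALSE)
  best
}

#' Contraction and relaxation half-widths from a motion trace
#'
#' Detects contraction events in a video-derived motion trace and measures,
#' per event, the time from the half-maximum crossing on the rising phase to
#' the peak (contraction half-width) and from the peak to the half-maximum
#' crossing on the falling phase (relaxation half-width). When
#' synchronization pulse times from the patch-clamp record are supplied, the
#' motion time base is aligned to the AP time base (offset = first sync
#' pulse); otherwise the analysis proceeds unaligned with a warning.
#'
#' @param motion Data frame with columns `time_s` and `motion`.
#' @param sync_times_s Optional synchronization pulse times in the AP record,
#'   seconds.
#' @param min_rel_height Event detection threshold as a fraction of the
#'   largest excursion.
#' @param min_separation_s Minimum separation between event peaks, s.
#' @return List with `per_event` (data frame: `peak_time_s`,
#'   `contraction_halfwidth_ms`, `relaxation_halfwidth_ms`), summary means
#'   `contraction_halfwidth`/`relaxation_halfwidth` (ms), and `sync_offset_s`.
#' @export
contraction_halfwidths <- function(motion, sync_times_s = NULL,
                                   min_rel_height = 0.5,
                                   min_separation_s = 0.2) {
  t <- motion$time_s
  y <- motion$motion
  offset <- NA_real_
  if (!is.null(sync_times_s) && length(sync_times_s)) {
    offset <- sync_times_s[1]
    t <- t + offset
  } else if (!is.null(sync_times_s)) {
    warning("no synchronization pulses found; analysis is unaligned")
  }
  base <- min(y)
  thr <- base + min_rel_height * (max(y) - base)
  pk_idx <- find_peaks(y, min_height = thr,
                       min_sep = max(1L, round(min_separation_s /
                                                 stats::median(diff(t)))))
  rows <- lapply(pk_idx, function(p) {
    half <- base + 0.5 * (y[p] - base)
    # rising crossing: last sample before p below half
    i_up <- rev(which(y[1:p] <= half))
    t_up <- if (length(i_up)) {
      i <- i_up[1]
      t[i] + (half - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
    } else NA_real_
    i_dn <- which(y[p:length(y)] <= half)
    t_dn <- if (length(i_dn)) {
      i <- p + i_dn[1] - 1L
      t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
    } else NA_real_
    data.frame(peak_time_s = t[p],
               contraction_halfwidth_ms = (t[p] - t_up) * 1000,
               relaxation_halfwidth_ms = (t_dn - t[p]) * 1000)
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_time_s = numeric(0), contraction_halfwidth_ms = numeric(0),
               relaxation_halfwidth_ms = numeric(0))
  list(per_event = per,
       contraction_halfwidth = mean(per$contraction_halfwidth_ms, na.rm = TRUE),
       relaxation_halfwidth = mean(per$relaxation_halfwidth_ms, na.rm = TRUE),
       sync_offset_s = offset)
}

# simple local-maximum peak finder with height and separation constraints
find_peaks <- function(y, min_height = -Inf, min_sep = 1L, min_prom = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # plateau apex handling: keep first sample of flat tops
  cand <- cand[y[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  if (min_prom > 0) {
    keep <- vapply(cand, function(p) {
      lo_l <- min(y[max(1L, p - 10L * min_sep):p])
      lo_r <- min(y[p:min(n, p + 10L * min_sep)])
      (y[p] - max(lo_l, lo_r)) >= min_prom
    }, logical(1))
    cand <- cand[keep]
  }
  if (!length(cand)) return(integer(0))
  # greedy separation by descending height
  ord <- cand[order(-y[cand])]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}
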