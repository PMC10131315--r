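# shared fixtures built in code

wt_model <- function(...) gating_model(...)

# a ca_events object built directly from event parameters, for classifier
# boundary tests that need exact amplitude ratios
make_ca_events <- function(amplitude, rise = 150, decay = 400,
                           trough_left = 0, trough_right = 0,
                           iei = 2) {
  n <- length(amplitude)
  rise <- rep_len(rise, n); decay <- rep_len(decay, n)
  trough_left <- rep_len(trough_left, n)
  trough_right <- rep_len(trough_right, n)
  ev <- data.frame(
    peak_idx = seq_len(n) * 50L,
    peak_time_s = seq_len(n) * iei,
    amplitude = amplitude,
    trough_left = trough_left, trough_right = trough_right,
    rise_10_90 = rise, decay_90_10 = decay,
    half_width = (rise + decay) / 2, ca90_duration = rise + decay,
    major = TRUE, iei_s = iei)
  structure(list(events = ev, stats = list(), n_events = n,
                 baseline_noise = 0.001),
            class = "ca_events")
}

# an fp_record with chosen summary fields (for cohort arithmetic tests)
make_fp_record <- function(fpdc = 700, bpm = 60, arrhythmic = FALSE,
                           excluded = FALSE, reason = NA_character_) {
  structure(list(bpm = bpm, fpd = fpdc, fpdc = fpdc, arrhythmic = arrhythmic,
                 excluded = excluded, exclusion_reason = reason,
                 n_beats = 10L, beat_times_s = seq_len(10),
                 fpd_per_beat = rep(fpdc, 10)),
            class = "fp_record")
}
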