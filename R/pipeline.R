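#' Write a time-series trace with a JSON sidecar
#'
#' Emits a two-column delimited file (`time_s`, `value`) plus a `.json`
#' sidecar holding the generating specification, so synthetic recordings are
#' self-describing.
#'
#' @param time_s,value Trace columns.
#' @param path Output path (`.tsv` or `.csv`; the sidecar replaces the
#'   extension with `.json`).
#' @param spec Optional list serialized to the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(time_s, value, path, spec = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(data.frame(time_s = time_s, value = value), path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(spec)) {
    side <- sub("\\.[a-z]+$", ".json", path)
    writeLines(jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE), side)
  }
  invisible(path)
}

#' Read a delimited time-series trace
#'
#' Reads `time_s`/`value` tables written by [write_trace()] (TSV or CSV; an
#' ATF-style header of lines before the column header is skipped).
#'
#' @param path Input path.
#' @return Data frame with columns `time_s` and `value`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("time", lines, ignore.case = TRUE)[1]
  if (is.na(hdr)) stop_cc("no time column header found in '%s'", path)
  sep <- if (grepl(",", lines[hdr])) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, skip = hdr - 1L)
}

#' Default configuration for the synthetic end-to-end pipeline
#'
#' Cohort sizes are kept small enough that the full run completes in well
#' under a minute while still exercising every stage; every entry can be
#' overridden.
#'
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    groups = c("wt", "asymptomatic", "symptomatic"),
    vclamp = list(n_cells = 6, noise_sd = 0.02, recovery_noise_sd = 0.01),
    ap = list(n_cells = 6, duration_s = 8,
              ta_cells = list(wt = 0, asymptomatic = 2, symptomatic = 1)),
    ca = list(n_cells = 6, duration_s = 35,
              abnormal_cells = list(wt = 1, asymptomatic = 3, symptomatic = 3)),
    mea = list(n_aggregates = 5,
               arrhythmic = list(wt = 0, asymptomatic = 1, symptomatic = 1),
               fpdc = list(wt = 743.6, asymptomatic = 659.4, symptomatic = 755.2)),
    qpcr = list(true_ratio = 1.5, replicate_sd = 0.05)
  )
}

#' Run the full synthetic end-to-end analysis pipeline
#'
#' Generates synthetic recordings for every stage (voltage clamp, action
#' potentials, Ca2+ imaging, MEA, qPCR) from group-level gating presets,
#' analyzes them with the package's extractors and fitters, writes feature
#' CSVs, fit JSONs and a run log to `out_dir`, and returns the report bundle.
#' Reruns with the same seed produce identical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing all randomness.
#' @return A `cardioclamp_report` list, invisibly: `vclamp`, `ap`, `ca`,
#'   `mea`, `qpcr` stage results plus `seed` and `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("cardioclamp_"), seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || !length(config)) {
    stop_cc("empty or invalid pipeline configuration", class = "cardioclamp_usage_error")
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- config$groups
  log <- c(sprintf("cardioclamp %s", as.character(utils::packageVersion("cardioclamp"))),
           sprintf("seed: %d", seed), sprintf("R: %s", R.version.string))
  report <- list(seed = seed, out_dir = out_dir)

  # -- voltage clamp: per-cell activation/inactivation fits + recovery
  vc <- list()
  rows <- list()
  for (g in groups) {
    model <- gating_model_preset(g)
    for (cell in seq_len(config$vclamp$n_cells)) {
      s <- seed * 1000L + match(g, groups) * 100L + cell
      fam <- simulate_iv_family(model, noise_sd = config$vclamp$noise_sd, seed = s)
      iv <- measure_peak_currents(fam)
      gc_ <- conductance_curve(iv, model$e_rev)
      act <- fit_boltzmann(gc_$voltage, gc_$g_norm, "activation")
      av <- simulate_availability_curve(model, noise_sd = config$vclamp$noise_sd,
                                        seed = s + 50000L)
      inact <- fit_boltzmann(av$voltage, av$availability, "inactivation")
      rec <- analyze_recovery(simulate_recovery_protocol(
        model, noise_sd = config$vclamp$recovery_noise_sd, seed = s + 90000L))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cell = cell,
        act_vhalf = coef(act)["vhalf"], act_k = coef(act)["k"],
        inact_vhalf = coef(inact)["vhalf"], inact_k = coef(inact)["k"],
        rec_tau_fast = coef(rec)["tau_fast"], rec_tau_slow = coef(rec)["tau_slow"],
        peak_density_m20 = iv$peak_density[iv$voltage == -20])
    }
  }
  vc$per_cell <- do.call(rbind, rows)
  rownames(vc$per_cell) <- NULL
  vc$comparison <- compare_groups(vc$per_cell$act_vhalf, vc$per_cell$group)
  write.csv(vc$per_cell, file.path(out_dir, "vclamp_per_cell.csv"),
            row.names = FALSE)
  report$vclamp <- vc
  log <- c(log, sprintf("vclamp: %d cells x %d groups", config$vclamp$n_cells,
                        length(groups)))

  # -- action potentials: features, subtype, TA
  ap_rows <- list()
  for (g in groups) {
    n_ta <- config$ap$ta_cells[[g]] %||% 0
    for (cell in seq_len(config$ap$n_cells)) {
      s <- seed * 2000L + match(g, groups) * 100L + cell
      ta <- if (cell <= n_ta) list(list(beat = 2, coupling = 600, amplitude = 25)) else list()
      spec <- ap_waveform_spec(duration_s = config$ap$duration_s, ta_events = ta,
                               noise_sd = 0.5, seed = s)
      tr <- simulate_ap_train(spec)
      segs <- detect_aps(tr)
      ft <- compute_ap_features(segs, tr)
      ta_res <- detect_triggered_activity(segs, tr)
      ap_rows[[length(ap_rows) + 1L]] <- data.frame(
        group = g, cell = cell, bpm = ft$bpm, vmax = ft$vmax,
        apd50 = ft$apd50, apd90 = ft$apd90, apa = ft$apa, mdp = ft$mdp,
        apd_ratio = ft$apd_ratio, subtype = ft$subtype,
        ta_count = ta_res$ta_count, arrhythmic = ta_res$arrhythmic)
    }
  }
  ap <- list(per_cell = do.call(rbind, ap_rows))
  ap$ta_fraction <- vapply(groups, function(g)
    cohort_ta_fraction(ap$per_cell$arrhythmic[ap$per_cell$group == g]),
    numeric(1))
  write.csv(ap$per_cell, file.path(out_dir, "ap_per_cell.csv"), row.names = FALSE)
  report$ap <- ap
  log <- c(log, sprintf("ap: TA%% = %s",
                        paste(sprintf("%s %.1f", groups, ap$ta_fraction),
                              collapse = ", ")))

  # -- calcium: abnormality calls and cohort summary
  calls <- list(); conds <- character(0)
  for (g in groups) {
    n_ab <- config$ca$abnormal_cells[[g]] %||% 0
    for (cell in seq_len(config$ca$n_cells)) {
      s <- seed * 3000L + match(g, groups) * 100L + cell
      ab <- if (cell <= n_ab) {
        type <- c("OS", "LP", "VA")[(cell - 1L) %% 3L + 1L]
        mag <- switch(type, OS = 2, LP = 0.3, VA = 0.35)
        list(list(type = type, site = 3, magnitude = mag))
      } else list()
      spec <- ca_trace_spec(duration_s = config$ca$duration_s,
                            abnormalities = ab, seed = s)
      tr <- ca_preprocess(simulate_ca_trace(spec))
      ev <- suppressWarnings(ca_transients(tr))
      calls[[length(calls) + 1L]] <- classify_ca_abnormalities(ev)
      conds <- c(conds, g)
    }
  }
  ca <- cohort_abnormality_summary(calls, conds)
  write.csv(ca$summary, file.path(out_dir, "ca_cohort.csv"), row.names = FALSE)
  report$ca <- ca
  log <- c(log, sprintf("ca: %% abnormal = %s",
                        paste(sprintf("%s %.0f", ca$summary$condition,
                                      ca$summary$pct_abnormal), collapse = ", ")))

  # -- MEA: per-aggregate records + cohort
  recs <- list(); gl <- character(0)
  for (g in groups) {
    fpdc_target <- config$mea$fpdc[[g]] %||% 700
    n_arr <- config$mea$arrhythmic[[g]] %||% 0
    for (agg in seq_len(config$mea$n_aggregates)) {
      s <- seed * 4000L + match(g, groups) * 100L + agg
      # fpd at 60 BPM equals the target corrected value (RR = 1 s)
      spec <- mea_trace_spec(rate = 60, fpd = fpdc_target,
                             arrhythmic = agg <= n_arr, pattern = "ectopic",
                             duration_s = 20, seed = s)
      recs[[length(recs) + 1L]] <- analyze_fp(simulate_mea_trace(spec))
      gl <- c(gl, g)
    }
  }
  mea <- list(records = recs, summary = cohort_fp_summary(recs, gl))
  write.csv(mea$summary, file.path(out_dir, "mea_cohort.csv"), row.names = FALSE)
  report$mea <- mea
  log <- c(log, "mea: cohort summary written")

  # -- qPCR: standard curve + sample interpolation
  std <- simulate_ct_table(replicate_sd = config$qpcr$replicate_sd,
                           seed = seed * 5000L)
  curve <- build_standard_curve(std)
  true_r <- config$qpcr$true_ratio
  sample_dct <- curve$intercept + curve$slope * log2(true_r)
  ratio <- interpolate_ratio(curve, sample_dct)
  qp <- list(curve = curve, sample = ratio)
  report$qpcr <- qp
  log <- c(log, sprintf("qpcr: slope %.3f, sample ratio %.3f",
                        curve$slope, ratio$ratio))

  fits <- list(
    standard_curve = list(slope = curve$slope, intercept = curve$intercept,
                          r_squared = curve$r_squared),
    vclamp_group_means = lapply(split(vc$per_cell, vc$per_cell$group), function(d)
      list(act_vhalf = mean(d$act_vhalf), act_k = mean(d$act_k),
           inact_vhalf = mean(d$inact_vhalf), inact_k = mean(d$inact_k),
           rec_tau_fast = mean(d$rec_tau_fast),
           rec_tau_slow = mean(d$rec_tau_slow))))
  writeLines(jsonlite::toJSON(fits, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "fits.json"))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  class(report) <- "cardioclamp_report"
  invisible(report)
}

#' @export
print.cardioclamp_report <- function(x, ...) {
  cat("cardioclamp pipeline report (seed", x$seed, ")\n")
  cat("  outputs in:", x$out_dir, "\n")
  cat("  TA fractions (%):",
      paste(sprintf("%s %.1f", names(x$ap$ta_fraction), x$ap$ta_fraction),
            collapse = ", "), "\n")
  cat(sprintf("  qPCR sample WT/mut ratio: %.3f\n", x$qpcr$sample$ratio))
  invisible(x)
}
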