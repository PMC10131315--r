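test_that("preprocessing identities hold", {
  # constant trace at F0: all-zero dF/F0
  raw <- list(time_s = seq(0, 10, 0.04), f = rep(80, 251), sample_rate = 25)
  tr <- ca_preprocess(raw, background = 0)
  expect_true(all(abs(tr$dff) < 1e-12))
  # adding a constant background then preprocessing with it is the identity
  spec <- ca_trace_spec(noise_sd = 0, background = 0, seed = 1)
  a <- ca_preprocess(simulate_ca_trace(spec), background = 0)
  spec_bg <- ca_trace_spec(noise_sd = 0, background = 35, seed = 1)
  b <- ca_preprocess(simulate_ca_trace(spec_bg), background = 35)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)
  # nonpositive baseline is an error
  bad <- list(time_s = seq(0, 10, 0.04), f = rep(0, 251), sample_rate = 25)
  expect_error(ca_preprocess(bad, background = 0), "F0")
})

test_that("transient parameters round-trip the generating spec", {
  spec <- ca_trace_spec(rate = 30, amplitude = 1.0, rise_10_90 = 150,
                        decay_90_10 = 400, noise_sd = 0, seed = 2)
  ev <- ca_transients(ca_preprocess(simulate_ca_trace(spec)))
  expect_equal(ev$n_events, nrow(simulate_ca_trace(spec)$truth))
  sample_ms <- 1000 / spec$sample_rate
  expect_lt(abs(ev$stats$amplitude_mean - 1.0), 0.05)
  expect_lt(abs(ev$stats$rise_mean - 150), sample_ms)
  expect_lt(abs(ev$stats$decay_mean - 400), sample_ms)
  expect_lt(abs(ev$stats$mean_iei_s - 2), 0.05)
  expect_equal(ev$stats$instantaneous_frequency, 0.5, tolerance = 0.02)
})

test_that("instantaneous frequency averages per-interval frequencies", {
  expect_equal(instantaneous_frequency(c(0.5, 1.0)), 1.5)
  expect_true(is.na(instantaneous_frequency(numeric(0))))
})

test_that("linear ramp upstroke gives rise 10-90% of 80% of the ramp", {
  # 100-ms linear ramp: the 10-90% span is 80 ms
  spec <- ca_trace_spec(rise_10_90 = 80, decay_90_10 = 400, noise_sd = 0,
                        sample_rate = 100, seed = 3)
  ev <- ca_transients(ca_preprocess(simulate_ca_trace(spec)))
  expect_lt(abs(ev$stats$rise_mean - 80), 10)
})

test_that("LP threshold is strict at 10% of the preceding amplitude", {
  base <- rep(1, 8)
  lp_at <- function(frac) {
    amps <- c(base[1:3], frac, base[4:8])
    classify_ca_abnormalities(make_ca_events(amps))
  }
  expect_true("LP" %in% lp_at(0.30)$labels)
  expect_true("LP" %in% lp_at(0.10)$labels)       # "at least 10%"
  expect_false("LP" %in% lp_at(0.099)$labels)     # strictly below: not LP
  expect_true(lp_at(0.099)$normal)
})

test_that("injected abnormalities are recovered by the classifier", {
  run <- function(ab) {
    spec <- ca_trace_spec(abnormalities = ab, seed = 7)
    classify_ca_abnormalities(ca_transients(ca_preprocess(simulate_ca_trace(spec))))
  }
  expect_true(run(list())$normal)
  expect_true("LP" %in% run(list(list(type = "LP", site = 3, magnitude = 0.3)))$labels)
  expect_true(run(list(list(type = "LP", site = 3, magnitude = 0.05)))$normal)
  os <- run(list(list(type = "OS", site = 3, magnitude = 3)))
  expect_true("OS" %in% os$labels)
  expect_gte(length(os$evidence$OS), 3)
  expect_true("VA" %in% run(list(list(type = "VA", site = 3, magnitude = 0.35)))$labels)
  expect_true("PA" %in% run(list(list(type = "PA", site = 3, magnitude = 2.5)))$labels)
  expect_true("RD" %in% run(list(list(type = "RD", site = 3, magnitude = 2.5)))$labels)
})

test_that("raising the LP threshold never increases the LP call count", {
  specs <- lapply(1:6, function(i)
    ca_trace_spec(abnormalities = if (i <= 4)
      list(list(type = "LP", site = 2, magnitude = 0.1 + 0.05 * i)) else list(),
      seed = 40 + i))
  evs <- lapply(specs, function(s)
    ca_transients(ca_preprocess(simulate_ca_trace(s))))
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.45), function(thr)
    sum(vapply(evs, function(e)
      "LP" %in% classify_ca_abnormalities(e, lp_threshold = thr)$labels,
      logical(1))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classification is invariant to uniform fluorescence rescaling", {
  spec <- ca_trace_spec(abnormalities = list(list(type = "VA", site = 3,
                                                  magnitude = 0.35)),
                        noise_sd = 0, background = 0, seed = 9)
  raw <- simulate_ca_trace(spec)
  raw3 <- raw
  raw3$f <- raw$f * 3
  c1 <- classify_ca_abnormalities(ca_transients(ca_preprocess(raw)))
  c2 <- classify_ca_abnormalities(ca_transients(ca_preprocess(raw3)))
  expect_identical(sort(c1$labels), sort(c2$labels))
})

test_that("cohort summary percentages partition normal/abnormal exactly", {
  calls <- c(lapply(1:18, function(i)
    structure(list(labels = "OS", normal = FALSE), class = "abnormality_call")),
    lapply(1:82, function(i)
      structure(list(labels = character(0), normal = TRUE),
                class = "abnormality_call")))
  res <- cohort_abnormality_summary(calls, rep("wt", 100))
  expect_equal(res$summary$pct_abnormal, 18)
  expect_equal(res$summary$pct_abnormal + res$summary$pct_normal, 100)
  # all-normal cohort: 0% with empty breakdown
  res0 <- cohort_abnormality_summary(calls[19:28], rep("wt", 10))
  expect_equal(res0$summary$pct_abnormal, 0)
  expect_true(all(res0$breakdown$n == 0))
})

test_that("a cohort VA shift is recovered by the summary deltas", {
  mk_call <- function(labels) structure(
    list(labels = labels, normal = length(labels) == 0L),
    class = "abnormality_call")
  # baseline: 11% VA; drug: 34% VA (out of 100 cells each)
  calls <- c(lapply(seq_len(100), function(i) mk_call(if (i <= 11) "VA" else character(0))),
             lapply(seq_len(100), function(i) mk_call(if (i <= 34) "VA" else character(0))))
  conds <- rep(c("baseline", "adrenaline"), each = 100)
  res <- cohort_abnormality_summary(calls, conds, cell_ids = rep(1:100, 2))
  va <- res$breakdown[res$breakdown$type == "VA", ]
  expect_equal(va$pct[va$condition == "baseline"], 11)
  expect_equal(va$pct[va$condition == "adrenaline"], 34)
  expect_equal(res$deltas$delta_pct[res$deltas$type == "VA"], 23)
})
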