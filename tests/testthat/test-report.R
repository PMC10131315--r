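test_that("Dunn z statistics match independent reference values", {
  # reference values computed externally for this tie-free fixture
  v <- c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6, 7.7, 8.8, 2.0, 3.0, 5.0, 9.9)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- compare_groups(v, g)
  pw <- res$pairwise
  get <- function(g1, g2, col) pw[[col]][pw$group1 == g1 & pw$group2 == g2]
  expect_equal(get("a", "b", "statistic"), -2.255336, tolerance = 1e-5)
  expect_equal(get("a", "b", "p_raw"), 0.024112, tolerance = 1e-4)
  expect_equal(get("a", "c", "statistic"), -0.980581, tolerance = 1e-5)
  expect_equal(get("b", "c", "statistic"), 1.274755, tolerance = 1e-5)
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-12))
  expect_equal(unname(res$n_per_group), c(4L, 4L, 4L))
})

test_that("identical groups are ns; well-separated groups reach ***", {
  set.seed(5)
  x <- rnorm(30)
  same <- compare_groups(c(x, x, x), rep(c("a", "b", "c"), each = 30))
  expect_true(all(same$pairwise$band == "ns"))
  expect_gt(same$omnibus$p, 0.5)
  far <- compare_groups(c(rnorm(30), rnorm(30) + 5, rnorm(30)),
                        rep(c("a", "b", "c"), each = 30))
  expect_equal(far$pairwise$band[far$pairwise$group1 == "a" &
                                   far$pairwise$group2 == "b"], "***")
})

test_that("paired comparisons use the signed-rank test and validate lengths", {
  set.seed(6)
  x <- rnorm(20)
  res <- compare_groups(c(x, x + 2), rep(c("pre", "post"), each = 20),
                        paired = TRUE)
  expect_lt(res$omnibus$p, 0.001)
  expect_error(compare_groups(c(rnorm(5), rnorm(4)),
                              c(rep("a", 5), rep("b", 4)), paired = TRUE),
               "unmatched")
})

test_that("indistinguishable groups are pooled before comparison", {
  set.seed(7)
  v <- c(rnorm(20), rnorm(20), rnorm(20) + 4)
  g <- rep(c("wt1", "wt2", "mut"), each = 20)
  pooled <- pool_equivalent_groups(v, g, pool = c("wt1", "wt2"),
                                   pooled_label = "wt")
  expect_true(pooled$pooled)
  expect_equal(sort(unique(pooled$groups)), c("mut", "wt"))
  # clearly different lines are not pooled
  v2 <- c(rnorm(20), rnorm(20) + 4)
  notp <- pool_equivalent_groups(v2, rep(c("a", "b"), each = 20),
                                 pool = c("a", "b"))
  expect_false(notp$pooled)
})

test_that("pipeline runs end-to-end, writes outputs, and is deterministic", {
  out1 <- tempfile("ccl1_")
  out2 <- tempfile("ccl2_")
  rep1 <- run_pipeline(seed = 3, out_dir = out1)
  rep2 <- run_pipeline(seed = 3, out_dir = out2)
  for (f in c("vclamp_per_cell.csv", "ap_per_cell.csv", "ca_cohort.csv",
              "mea_cohort.csv", "fits.json", "run_log.txt")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_s3_class(rep1, "cardioclamp_report")
  expect_true(all(is.finite(rep1$ap$ta_fraction)))
  expect_equal(rep1$qpcr$sample$ratio, 1.5, tolerance = 0.15)
  expect_error(run_pipeline(config = list(), out_dir = tempfile()),
               class = "cardioclamp_usage_error")
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("trace IO round-trips through the sidecar format", {
  path <- tempfile(fileext = ".tsv")
  t <- seq(0, 1, 0.01)
  write_trace(t, sin(t), path, spec = list(kind = "demo", seed = 1))
  back <- read_trace(path)
  expect_equal(back$time_s, t, tolerance = 1e-9)
  expect_equal(back$value, sin(t), tolerance = 1e-9)
  side <- sub("\\.tsv$", ".json", path)
  expect_true(file.exists(side))
  expect_equal(jsonlite::fromJSON(side)$kind, "demo")
  unlink(c(path, side))
})
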