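test_that("perfect-efficiency synthetic data yield slope 1 and intercept 0", {
  tab <- simulate_ct_table(replicate_sd = 0)
  cv <- build_standard_curve(tab)
  expect_equal(cv$slope, 1, tolerance = 1e-9)
  expect_equal(cv$intercept, 0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  # single-allele mixes are controls, not regression points
  expect_equal(nrow(cv$points), 7)
  expect_equal(sort(cv$controls$sample), c("0/1", "1/0"))
  # the 1/1 mix contributes the intercept point
  expect_equal(cv$points$dct[cv$points$sample == "1/1"], 0, tolerance = 1e-12)
})

test_that("replicate SDs propagate to curve points in quadrature", {
  tab <- simulate_ct_table(replicate_sd = 0.08, n_replicates = 3, seed = 2)
  cv <- build_standard_curve(tab)
  expect_true(all(cv$points$dct_sd > 0))
  expect_true(all(cv$points$n == 3))
  expect_error(build_standard_curve(simulate_ct_table(ratios = c(2, 1),
                                                      include_controls = FALSE)),
               "at least 3")
})

test_that("ratio interpolation inverts the curve and guards extrapolation", {
  cv <- build_standard_curve(simulate_ct_table())
  expect_equal(interpolate_ratio(cv, cv$intercept)$ratio, 1, tolerance = 1e-9)
  r <- interpolate_ratio(cv, cv$intercept + cv$slope * log2(1.5))
  expect_equal(r$ratio, 1.5, tolerance = 1e-9)
  expect_true(r$ratio > 1 && r$ratio < 2)  # between the 1/1 and 2/1 mixes
  expect_false(r$extrapolated)
  expect_true(interpolate_ratio(cv, 10)$extrapolated)
  cv0 <- cv; cv0$slope <- 1e-12
  expect_error(interpolate_ratio(cv0, 0), "degenerate")
})

test_that("standard-curve round trip recovers all printed mix ratios", {
  ratios <- c(8, 4, 2, 1, 1 / 2, 1 / 4, 1 / 8)
  tab <- simulate_ct_table(ratios = ratios, replicate_sd = 0.05, seed = 3)
  cv <- build_standard_curve(tab)
  for (r in ratios) {
    dct <- cv$points$dct[abs(cv$points$ratio - r) < 1e-9]
    est <- interpolate_ratio(cv, dct)$ratio
    expect_lt(abs(log2(est) - log2(r)), 0.25)
  }
})

test_that("ddCt folds follow 2^(-ddCt) and shift invariance", {
  tab <- data.frame(
    sample = rep(c("w1", "w2", "m1", "m2"), each = 2),
    target = rep(c("GAPDH", "SCN5A"), 4),
    ct = c(15, 22, 15, 22, 15, 21, 15, 21))
  grp <- c(w1 = "wt", w2 = "wt", m1 = "mut", m2 = "mut")
  res <- ddct_expression(tab, grp, calibrator_group = "wt")
  folds <- res$per_group$fold[res$per_group$target == "SCN5A"]
  names(folds) <- res$per_group$group[res$per_group$target == "SCN5A"]
  expect_equal(unname(folds["wt"]), 1, tolerance = 1e-12)   # ddCt = 0
  expect_equal(unname(folds["mut"]), 2, tolerance = 1e-12)  # ddCt = -1
  # adding a constant to every Ct of one sample changes nothing
  tab2 <- tab
  tab2$ct[tab2$sample == "m1"] <- tab2$ct[tab2$sample == "m1"] + 3
  res2 <- ddct_expression(tab2, grp, calibrator_group = "wt")
  expect_equal(res2$per_sample$fold, res$per_sample$fold, tolerance = 1e-12)
  # missing control: sample excluded with a warning
  tab3 <- tab[!(tab$sample == "m2" & tab$target == "GAPDH"), ]
  expect_warning(ddct_expression(tab3, grp, calibrator_group = "wt"),
                 "lacks")
})
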