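#' Simulate a qPCR Ct table for an allelic standard-curve experiment
#'
#' Ct values for plasmid mixes of two alleles (WT and mutant) combined at
#' known ratios, following the log-linear model
#' `Ct = base_ct - slope_per_log2 * log2(amount)` per allele plus replicate
#' noise. At perfect amplification efficiency one cycle corresponds to a
#' doubling, so `dCt = Ct(mut) - Ct(WT) = log2(WT/mut)` and the standard
#' curve has slope 1.
#'
#' @param ratios WT/mutant mix ratios. `Inf` and `0` encode the single-allele
#'   controls (1/0 and 0/1): the absent allele's Ct is `NA`.
#' @param base_ct Ct of a pure single-allele sample at unit amount.
#' @param slope_per_log2 Cycles per twofold amount change (1 at perfect
#'   efficiency).
#' @param replicate_sd Replicate Ct noise SD, cycles.
#' @param n_replicates Technical replicates per mix.
#' @param include_controls Append the 1/0 and 0/1 single-allele controls.
#' @param seed Optional RNG seed.
#' @return A `ct_table` data frame: `sample`, `allele` (`"WT"`/`"mut"`),
#'   `ct`, `replicate`, with the true ratio in column `ratio`.
#' @export
simulate_ct_table <- function(ratios = c(8, 4, 2, 1, 1 / 2, 1 / 4, 1 / 8),
                              base_ct = 20, slope_per_log2 = 1,
                              replicate_sd = 0, n_replicates = 3,
                              include_controls = TRUE, seed = NULL) {
  if (any(ratios < 0, na.rm = TRUE)) stop_cc("ratios must be nonnegative")
  if (include_controls) ratios <- unique(c(Inf, ratios, 0))
  with_seed(seed, {
    rows <- lapply(ratios, function(r) {
      wt_frac <- if (is.infinite(r)) 1 else r / (r + 1)
      mut_frac <- 1 - wt_frac
      name <- if (is.infinite(r)) "1/0" else if (r == 0) "0/1" else
        if (r >= 1) sprintf("%g/1", r) else sprintf("1/%g", 1 / r)
      ct_for <- function(frac) {
        if (frac <= 0) return(rep(NA_real_, n_replicates))
        noise <- if (replicate_sd > 0) rnorm(n_replicates, 0, replicate_sd) else
          numeric(n_replicates)
        base_ct - slope_per_log2 * log2(frac) + noise
      }
      data.frame(sample = name,
                 allele = rep(c("WT", "mut"), each = n_replicates),
                 ct = c(ct_for(wt_frac), ct_for(mut_frac)),
                 replicate = rep(seq_len(n_replicates), 2),
                 ratio = r)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("ct_table", class(out))
    out
  })
}

#' Build an allelic-imbalance standard curve
#'
#' Aggregates replicate Ct values per mix and allele, forms
#' `dCt = Ct(mutant) - Ct(WT)` (the Ct measured for the WT allele subtracted
#' from the Ct measured for the mutant allele), and fits the linear model of
#' dCt against log2(WT/mutant ratio) over the mixes with finite log-ratios.
#' The single-allele controls (1/0, 0/1) are retained as qualitative controls
#' but excluded from the regression. Replicate SDs are propagated to the dCt
#' points in quadrature.
#'
#' @param table A `ct_table` (columns `sample`, `allele`, `ct`, `replicate`,
#'   and either a `ratio` column or samples named like `"2/1"`).
#' @return A `standard_curve` object: `slope` and `intercept` of dCt vs
#'   log2(ratio), `r_squared`, `points` (per-mix dCt with SDs), `controls`.
#' @export
build_standard_curve <- function(table) {
  need <- c("sample", "allele", "ct")
  if (!all(need %in% names(table))) {
    stop_cc("ct table needs columns: %s", paste(need, collapse = ", "))
  }
  ratio_of <- function(s, tab) {
    if ("ratio" %in% names(tab)) return(tab$ratio[match(s, tab$sample)])
    parts <- strsplit(s, "/")[[1]]
    if (length(parts) == 2L) {
      num <- suppressWarnings(as.numeric(parts))
      if (!anyNA(num)) {
        if (num[2] == 0) return(Inf)
        return(num[1] / num[2])
      }
    }
    NA_real_
  }
  samples <- unique(table$sample)
  pts <- do.call(rbind, lapply(samples, function(s) {
    sub <- table[table$sample == s, ]
    agg <- function(al) {
      x <- sub$ct[sub$allele == al & is.finite(sub$ct)]
      c(mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1L) sd(x) else 0,
        n = length(x))
    }
    wt <- agg("WT"); mut <- agg("mut")
    data.frame(sample = s, ratio = ratio_of(s, table),
               ct_wt = wt["mean"], ct_mut = mut["mean"],
               dct = mut["mean"] - wt["mean"],
               dct_sd = sqrt(wt["sd"]^2 + mut["sd"]^2),
               n = min(wt["n"], mut["n"]))
  }))
  rownames(pts) <- NULL
  finite <- is.finite(pts$ratio) & pts$ratio > 0 & is.finite(pts$dct)
  controls <- pts[!finite, , drop = FALSE]
  pts_fit <- pts[finite, , drop = FALSE]
  if (nrow(pts_fit) < 3L) {
    stop_cc("standard curve needs at least 3 mixes with finite log2 ratios, got %d",
            nrow(pts_fit))
  }
  pts_fit$log2_ratio <- log2(pts_fit$ratio)
  fit <- lm(dct ~ log2_ratio, data = pts_fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((pts_fit$dct - mean(pts_fit$dct))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 points = pts_fit, controls = controls,
                 dct_range = range(pts_fit$dct), lm = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Allelic standard curve: dCt = %.4f + %.4f * log2(WT/mut), r^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  %d mixes fitted, %d single-allele controls\n",
              nrow(x$points), nrow(x$controls)))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.standard_curve <- function(object, newdata, ...) {
  dct <- if (is.data.frame(newdata)) newdata$dct else newdata
  interpolate_ratio(object, dct)$ratio
}

#' @export
plot.standard_curve <- function(x, ...) {
  plot(x$points$log2_ratio, x$points$dct, xlab = "log2(WT/mutant)",
       ylab = expression(Delta * Ct), main = "Allelic standard curve", ...)
  abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

#' Interpolate a WT/mutant ratio from a sample's dCt
#'
#' `ratio = 2^((dCt - intercept)/slope)`; a dCt outside the calibrated range
#' (plus a small guard) is flagged as extrapolation.
#'
#' @param curve A [build_standard_curve()] result.
#' @param dct Sample dCt value(s) (`Ct_mut - Ct_WT`).
#' @param guard Extrapolation guard in cycles beyond the calibrated dCt
#'   range.
#' @return Data frame with `dct`, `ratio`, `extrapolated`.
#' @export
interpolate_ratio <- function(curve, dct, guard = 0.5) {
  if (!inherits(curve, "standard_curve")) stop_cc("'curve' must be a standard_curve")
  if (abs(curve$slope) < 1e-8) {
    stop_cc("degenerate standard curve: slope is approximately zero")
  }
  rng <- curve$dct_range
  data.frame(dct = dct,
             ratio = 2^((dct - curve$intercept) / curve$slope),
             extrapolated = dct < rng[1] - guard | dct > rng[2] + guard)
}

#' Relative expression by the comparative (delta-delta-Ct) method
#'
#' Per sample: mean replicate Ct per target, `dCt = Ct(target) -
#' Ct(endogenous control)`; `ddCt` subtracts the calibrator group's mean dCt
#' per target; fold change is `2^(-ddCt)`. Optionally the fold changes are
#' secondarily normalized to a reference gene's fold within each group.
#' Samples missing the control Ct are excluded with a warning. Adding a
#' constant to all Cts of a sample leaves the folds unchanged.
#'
#' @param table Data frame with columns `sample`, `target`, `ct` (and
#'   optionally `replicate`).
#' @param groups Named character vector or function mapping sample -> group.
#' @param control_gene Endogenous control target (e.g. `"GAPDH"`).
#' @param calibrator_group Group used as the calibrator.
#' @param normalizer_gene Optional reference gene for second-stage
#'   normalization (e.g. `"TNNT2"`), or `NULL`.
#' @return List with `per_sample` (sample, group, target, dct, ddct, fold)
#'   and `per_group` (group means of fold per target).
#' @export
ddct_expression <- function(table, groups, control_gene = "GAPDH",
                            calibrator_group, normalizer_gene = NULL) {
  need <- c("sample", "target", "ct")
  if (!all(need %in% names(table))) {
    stop_cc("expression table needs columns: %s", paste(need, collapse = ", "))
  }
  grp_of <- if (is.function(groups)) groups else function(s) unname(groups[s])
  agg <- stats::aggregate(ct ~ sample + target, data = table, FUN = mean)
  samples <- unique(agg$sample)
  rows <- list()
  for (s in samples) {
    sub <- agg[agg$sample == s, ]
    ctrl <- sub$ct[sub$target == control_gene]
    if (!length(ctrl) || !is.finite(ctrl)) {
      warning(sprintf("sample '%s' lacks a %s Ct; excluded", s, control_gene))
      next
    }
    tg <- sub[sub$target != control_gene, , drop = FALSE]
    rows[[s]] <- data.frame(sample = s, group = grp_of(s), target = tg$target,
                            dct = tg$ct - ctrl)
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || !nrow(per)) stop_cc("no usable samples")
  if (!calibrator_group %in% per$group) {
    stop_cc("calibrator group '%s' not present", calibrator_group)
  }
  cal <- stats::aggregate(dct ~ target, data = per[per$group == calibrator_group, ],
                          FUN = mean)
  per$ddct <- per$dct - cal$dct[match(per$target, cal$target)]
  per$fold <- 2^(-per$ddct)
  if (!is.null(normalizer_gene)) {
    normf <- stats::aggregate(fold ~ group, data = per[per$target == normalizer_gene, ],
                              FUN = mean)
    per$fold_normalized <- per$fold /
      normf$fold[match(per$group, normf$group)]
  }
  per_group <- stats::aggregate(fold ~ group + target, data = per, FUN = mean)
  list(per_sample = per, per_group = per_group)
}
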