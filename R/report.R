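#' Nonparametric group comparison with post-hoc tests
#'
#' For two or more unpaired groups: Kruskal-Wallis omnibus test followed by
#' Dunn's pairwise rank comparisons (with tie correction); with
#' `adjustment = "bonferroni"` the pairwise p-values are Bonferroni-adjusted,
#' with `"dunn"` they are Holm-adjusted (the conventional reporting of Dunn's
#' test). Two unpaired groups fall back to the Wilcoxon rank-sum test. Paired
#' comparisons use the Wilcoxon signed-rank test. Significance bands follow
#' the ns / * / ** / *** convention at 0.05 / 0.01 / 0.001.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param paired Paired comparison (exactly two groups of equal length, in
#'   matching order).
#' @param adjustment `"dunn"` (Holm) or `"bonferroni"`.
#' @return A `group_comparison`: `omnibus` (statistic, p), `pairwise` data
#'   frame (`group1`, `group2`, `z` or `W`, `p_raw`, `p_adj`, `band`),
#'   `n_per_group`, `method`, `adjustment`.
#' @export
compare_groups <- function(values, groups, paired = FALSE,
                           adjustment = c("dunn", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  lv <- unique(groups)
  n_per <- vapply(lv, function(g) sum(groups == g), integer(1))
  if (length(lv) < 2L) stop_cc("need at least 2 groups")
  adj_method <- if (adjustment == "bonferroni") "bonferroni" else "holm"

  if (paired) {
    if (length(lv) != 2L) stop_cc("paired comparison needs exactly 2 groups")
    x <- values[groups == lv[1]]; y <- values[groups == lv[2]]
    if (length(x) != length(y)) {
      stop_cc("paired groups have unmatched lengths (%d vs %d)",
              length(x), length(y))
    }
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    pw <- data.frame(group1 = lv[1], group2 = lv[2],
                     statistic = unname(wt$statistic),
                     p_raw = wt$p.value, p_adj = wt$p.value)
    pw$band <- signif_band(pw$p_adj)
    return(structure(list(omnibus = list(statistic = unname(wt$statistic),
                                         p = wt$p.value,
                                         test = "Wilcoxon signed-rank"),
                          pairwise = pw, n_per_group = n_per,
                          method = "wilcoxon-paired", adjustment = adjustment),
                     class = "group_comparison"))
  }

  if (length(lv) == 2L) {
    wt <- suppressWarnings(wilcox.test(values[groups == lv[1]],
                                       values[groups == lv[2]], exact = FALSE))
    pw <- data.frame(group1 = lv[1], group2 = lv[2],
                     statistic = unname(wt$statistic),
                     p_raw = wt$p.value, p_adj = wt$p.value)
    pw$band <- signif_band(pw$p_adj)
    return(structure(list(omnibus = list(statistic = unname(wt$statistic),
                                         p = wt$p.value,
                                         test = "Wilcoxon rank-sum"),
                          pairwise = pw, n_per_group = n_per,
                          method = "wilcoxon", adjustment = adjustment),
                     class = "group_comparison"))
  }

  kw <- kruskal.test(values, factor(groups))
  pw <- dunn_pairwise(values, groups)
  pw$p_adj <- p.adjust(pw$p_raw, method = adj_method)
  pw$band <- signif_band(pw$p_adj)
  structure(list(omnibus = list(statistic = unname(kw$statistic),
                                p = kw$p.value, test = "Kruskal-Wallis"),
                 pairwise = pw, n_per_group = n_per,
                 method = "kruskal-dunn", adjustment = adjustment),
            class = "group_comparison")
}

# Dunn's z statistics on joint ranks with tie correction
dunn_pairwise <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- unique(groups)
  combs <- utils::combn(lv, 2)
  rows <- apply(combs, 2, function(pair) {
    i <- groups == pair[1]; j <- groups == pair[2]
    ni <- sum(i); nj <- sum(j)
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    data.frame(group1 = pair[1], group2 = pair[2], statistic = z,
               p_raw = 2 * pnorm(-abs(z)))
  })
  do.call(rbind, rows)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", x$omnibus$test,
              x$omnibus$statistic, x$omnibus$p))
  cat(sprintf("n per group: %s\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: p_adj = %.4g (%s)\n", pw$group1[i], pw$group2[i],
                pw$p_adj[i], pw$band[i]))
  }
  invisible(x)
}

#' Pool statistically indistinguishable groups
#'
#' Merges the specified groups into one pooled label when a rank-sum test
#' finds no difference at `alpha` (used e.g. to pool two wild-type lines
#' whose parameter values are similar before cross-line comparison).
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param pool Character vector of group labels that are candidates for
#'   pooling.
#' @param pooled_label Label for the merged group.
#' @param alpha Significance level below which pooling is refused.
#' @return List with `groups` (possibly merged labels), `pooled` flag, `p`.
#' @export
pool_equivalent_groups <- function(values, groups, pool,
                                   pooled_label = paste(pool, collapse = "+"),
                                   alpha = 0.05) {
  if (length(pool) != 2L) stop_cc("pooling is pairwise: give exactly 2 groups")
  x <- values[groups == pool[1]]; y <- values[groups == pool[2]]
  if (!length(x) || !length(y)) stop_cc("pool groups not found in 'groups'")
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE))$p.value
  out <- as.character(groups)
  pooled <- p >= alpha
  if (pooled) out[out %in% pool] <- pooled_label
  list(groups = out, pooled = pooled, p = p)
}
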