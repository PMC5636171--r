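#' Normality-gated comparison of two or more groups
#'
#' Applies a Shapiro-Wilk test to each group at level `alpha`; if every
#' group is consistent with normality, compares groups with a t test (two
#' groups) or one-way ANOVA (more than two), otherwise with the
#' Mann-Whitney-Wilcoxon test (two groups; normal approximation with tie
#' correction) or the Kruskal-Wallis test. All tests are two-sided.
#'
#' @param groups Named or unnamed list of numeric vectors, each of length
#'   >= 3 (the Shapiro-Wilk minimum).
#' @param alpha Level of the normality gate (default 0.05).
#' @return Object of class `stat_result`: list with `test_name` (one of
#'   `"t-test"`, `"anova"`, `"mann-whitney"`, `"kruskal-wallis"`),
#'   `statistic`, `p_value`, `normal` (gate outcome), per-group
#'   `shapiro_p`, and a `groups` summary data.frame (n, mean, median).
#' @export
normality_gated_compare <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 numeric vectors")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) < 3L) stop("group '", nm, "' has fewer than 3 observations")
    if (!all(is.finite(g))) stop("group '", nm, "' contains non-finite values")
  }
  shapiro_p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, 0)
  normal <- all(shapiro_p > alpha)
  k <- length(groups)
  if (normal && k == 2L) {
    ht <- stats::t.test(groups[[1L]], groups[[2L]])
    test_name <- "t-test"
  } else if (normal) {
    ht <- stats::oneway.test(values ~ grp, data = stack_groups(groups), var.equal = TRUE)
    test_name <- "anova"
  } else if (k == 2L) {
    ht <- stats::wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE, correct = TRUE)
    test_name <- "mann-whitney"
  } else {
    ht <- stats::kruskal.test(groups)
    test_name <- "kruskal-wallis"
  }
  summaries <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    median = vapply(groups, stats::median, 0),
    stringsAsFactors = FALSE
  )
  structure(list(
    test_name = test_name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    normal = normal,
    shapiro_p = shapiro_p,
    groups = summaries
  ), class = "stat_result")
}

stack_groups <- function(groups) {
  data.frame(
    values = unlist(groups, use.names = FALSE),
    grp = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (normality gate: %s)\n",
              x$test_name, x$statistic, x$p_value,
              if (isTRUE(x$normal)) "normal" else "non-normal"))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Two-sample test for equality of proportions
#'
#' Chi-square test on the 2x2 table of successes and failures, with an
#' optional Yates continuity correction (correction capped at the absolute
#' observed-expected deviation, as in standard implementations). Two-sided
#' p-value from the chi-square distribution with 1 degree of freedom.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param yates Apply the continuity correction (default TRUE).
#' @return `stat_result` with `test_name = "prop-test"`, the chi-square
#'   `statistic`, `p_value`, and group proportions.
#' @export
prop_test_2sample <- function(x1, n1, x2, n2, yates = TRUE) {
  if (n1 < 1 || n2 < 1) stop("each group needs n >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n in both groups")
  obs <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2L, byrow = TRUE)
  if (sum(obs) == 0) stop("degenerate table: all cells zero")
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expd == 0)) stop("degenerate margins: expected cell count of zero")
  cc <- if (yates) min(0.5, abs(obs[1L, 1L] - expd[1L, 1L])) else 0
  stat <- sum((abs(obs - expd) - cc)^2 / expd)
  structure(list(
    test_name = "prop-test",
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    normal = NA,
    groups = data.frame(group = c("group1", "group2"),
                        n = c(n1, n2),
                        mean = c(x1 / n1, x2 / n2),
                        median = NA_real_, stringsAsFactors = FALSE)
  ), class = "stat_result")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; each adjusted value is at least
#' its raw p and at most 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-level roll-up of transcript results
#'
#' A gene is called responsive when at least one of its transcripts is
#' significant (`p < p_max` and `fdr < fdr_max`); its direction is
#' `"induced"` or `"repressed"` when all qualifying transcripts agree in the
#' sign of their fold change, `"mixed"` otherwise, `"none"` for
#' non-responsive genes.
#'
#' @param rows data.frame with columns `gene_id`, `transcript_id`,
#'   `fold_change` (signed ratio), `p_value`, `fdr`.
#' @param p_max,fdr_max Significance thresholds (defaults 0.05 and 0.05).
#' @return data.frame with one row per gene: `gene_id`, `responsive`,
#'   `direction`, `n_transcripts`, `n_significant`.
#' @export
responsive_gene_rollup <- function(rows, p_max = 0.05, fdr_max = 0.05) {
  stopifnot(nrow(rows) > 0L,
            all(c("gene_id", "transcript_id", "fold_change", "p_value", "fdr")
                %in% names(rows)))
  per_gene <- lapply(split(rows, rows$gene_id), function(d) {
    hit <- d$p_value < p_max & d$fdr < fdr_max
    direction <- if (!any(hit)) "none"
      else if (all(d$fold_change[hit] > 0)) "induced"
      else if (all(d$fold_change[hit] < 0)) "repressed"
      else "mixed"
    data.frame(gene_id = d$gene_id[1L], responsive = any(hit),
               direction = direction, n_transcripts = nrow(d),
               n_significant = sum(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}
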