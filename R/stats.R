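#' Two-sided Fisher exact test on a 2x2 table
#'
#' Used for the cluster-enrichment comparison between disease/cancer-annotated
#' candidate variants and all other candidates. The two-sided p value sums
#' hypergeometric probabilities no larger than that of the observed table
#' (the convention of [stats::fisher.test()], which performs the computation).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p`, `odds_ratio`, `table`.
#' @examples
#' fisher_exact(matrix(c(2, 25, 660, 75), 2))$p  # < 2.2e-16
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || any(table != round(table)))
    stop("table must be a 2x2 matrix of non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, odds_ratio = NA_real_, table = table))
  ft <- stats::fisher.test(table, alternative = "two.sided")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = table)
}

#' Correlation coefficient with two-sided test
#'
#' Pearson product-moment correlation by default (with the usual
#' t-distribution p value); Spearman rank correlation available via `method`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `coefficient`, `p`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in x or y")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(coefficient = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Chi-square homogeneity test for transition/transversion counts
#'
#' Compares the Ti/Tv composition of two variant groups with a 2x2 chi-square
#' test without continuity correction. When any expected cell count falls
#' below 1 the chi-square approximation is unreliable; a warning is issued
#' and the Fisher exact p value is reported alongside.
#'
#' @param counts_a,counts_b Length-2 integer vectors `(ti, tv)`.
#' @return List with `statistic`, `p`, `expected`, and `fisher_p` (NA unless
#'   the small-count fallback triggered).
#' @export
titv_chisq <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L)
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stop("both groups must have at least one variant")
  tab <- rbind(a = counts_a, b = counts_b)
  colnames(tab) <- c("ti", "tv")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab == expected)) {   # identical proportions: statistic exactly 0
    return(list(statistic = 0, p = 1, expected = expected, fisher_p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fisher_p <- NA_real_
  if (any(expected < 1)) {
    warning("expected cell count < 1; reporting Fisher exact p alongside")
    fisher_p <- fisher_exact(tab)$p
  }
  list(statistic = unname(ct$statistic), p = ct$p.value,
       expected = expected, fisher_p = fisher_p)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact p for small samples (combined n <= 20 and no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param alternative Passed through; default two-sided.
#' @return List with `p`, `statistic` (Mann-Whitney U of `x`), `exact`.
#' @export
ranksum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("x and y must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(p = wt$p.value, statistic = unname(wt$statistic), exact = exact)
}

#' Normalize a phosphatase-activity panel within experiments
#'
#' Enzymatic activity measurements from different experiments (substrate x
#' dataset conditions) are combined by z-scoring within each experiment:
#' subtract the experiment mean and divide by the experiment standard
#' deviation (sample, n-1 convention). The operation is idempotent.
#'
#' @param panel `data.frame` with columns `variant`, `experiment`, `activity`.
#' @return The panel with an added/replaced `score` column.
#' @export
normalize_activity <- function(panel) {
  need <- c("variant", "experiment", "activity")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  p <- as.data.table(panel)
  nconst <- p[, .(n = .N, s = sd(activity)), by = experiment]
  if (any(nconst$n < 2L) || any(nconst$s == 0))
    stop("each experiment needs >= 2 distinct activity values")
  p[, score := (activity - mean(activity)) / sd(activity), by = experiment]
  as.data.frame(p)
}

#' Compare pooled normalized activity between two variant groups
#'
#' One-sided Mann-Whitney rank-sum test on the pooled within-experiment
#' z-scores, testing whether `group_a` scores are stochastically greater than
#' `group_b`. (The rank-based choice is recorded in the method metadata;
#' parametric alternatives give similar conclusions on panels this size.)
#'
#' @param panel Normalized panel from [normalize_activity()].
#' @param group_a,group_b Character vectors of variant identifiers.
#' @return List with `p`, `method`, `n_a`, `n_b`.
#' @export
compare_activity_groups <- function(panel, group_a, group_b) {
  if (!"score" %in% names(panel))
    stop("panel must be normalized first (see normalize_activity)")
  a <- panel$score[panel$variant %in% group_a]
  b <- panel$score[panel$variant %in% group_b]
  if (!length(a) || !length(b)) stop("both groups need at least one record")
  rs <- ranksum(a, b, alternative = "greater")
  list(p = rs$p, method = "one-sided Mann-Whitney on pooled z-scores",
       n_a = length(a), n_b = length(b))
}
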