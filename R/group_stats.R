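# Rank-sum group comparison with Benjamini-Hochberg correction.

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around `stats::wilcox.test` fixing the conventions used
#' throughout the analysis: two-sided, exact enumeration of the
#' rank-sum distribution when `min(nA, nB) <= 8` and no ties are
#' present, otherwise the midrank normal approximation with tie
#' correction (no continuity correction).
#'
#' @param a,b numeric value vectors (each length >= 2).
#' @param label comparison label carried into the result.
#' @return object of class `test_result`: list with `label`,
#'   `statistic` (Mann-Whitney U for sample A), `p_value`,
#'   `adjusted_p` (NA until a family adjustment is applied), `tier`
#'   (significance stars at 0.05 / 0.01 / 0.001).
#' @export
ranksum_test <- function(a, b, label = "A vs B") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_param("each group needs >= 2 finite values")
  if (length(unique(c(a, b))) == 1L)
    stop_param("degenerate data: all values identical across both groups")
  ties <- any(duplicated(c(a, b)))
  use_exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = FALSE))
  res <- list(label = label, statistic = unname(wt$statistic),
              p_value = min(wt$p.value, 1), adjusted_p = NA_real_,
              n_a = length(a), n_b = length(b))
  res$tier <- significance_tier(res$p_value)
  structure(res, class = "test_result")
}

#' Significance tier stars
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `""` otherwise.
#' @param p numeric vector of p-values.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Benjamini-Hochberg adjustment, in two dialects
#'
#' `dialect = "step_up"` is the textbook BH procedure
#' (`stats::p.adjust(method = "BH")`): `p * m / rank` followed by a
#' cumulative minimum from the largest rank, clipped at 1.
#'
#' `dialect = "plain"` omits the step-up monotonization and reports the
#' raw `p * m / rank` values (rank by ascending p, ties in input
#' order). This is the dialect that reproduces published
#' multiple-comparison tables in this literature exactly -- such tables
#' can show a smaller adjusted value at a *later* rank, which the
#' step-up pass would smooth away -- and is therefore the default for
#' reproduction work. Values are reported unclipped and can exceed 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param dialect `"plain"` or `"step_up"`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p, dialect = c("plain", "step_up")) {
  dialect <- match.arg(dialect)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_param("p-values must lie in [0, 1]")
  if (dialect == "step_up") return(p.adjust(p, method = "BH"))
  m <- length(p)
  r <- rank(p, ties.method = "first")
  p * m / r
}

#' Family-wise group comparison over biomarker features
#'
#' Runs [ranksum_test()] for every named feature column between the two
#' groups and applies [bh_adjust()] across the family of comparisons
#' (one call per metric family, e.g. the 11 site-pair MCCC summaries or
#' the 11 site-pair delay summaries). Subjects with a missing value are
#' dropped from the affected comparison only.
#'
#' @param features data.frame of per-subject feature values.
#' @param labels factor/character of group labels, one per row.
#' @param columns feature columns to compare (default: all numeric).
#' @param groups length-2 character, the two labels to compare (first =
#'   reference).
#' @param dialect BH dialect, see [bh_adjust()].
#' @return data.frame: comparison, n_a, n_b, statistic, p_value,
#'   adjusted_p, tier (tier from the adjusted p-value).
#' @export
compare_groups <- function(features, labels, columns = NULL,
                           groups = c("healthy", "stroke"),
                           dialect = c("plain", "step_up")) {
  dialect <- match.arg(dialect)
  if (nrow(features) != length(labels))
    stop_param("labels must have one entry per feature row")
  if (is.null(columns))
    columns <- names(features)[vapply(features, is.numeric, TRUE)]
  missing_cols <- setdiff(columns, names(features))
  if (length(missing_cols))
    stop_param("feature column(s) not found: %s", paste(missing_cols, collapse = ", "))
  rows <- lapply(columns, function(cl) {
    a <- features[[cl]][labels == groups[1]]
    b <- features[[cl]][labels == groups[2]]
    tr <- ranksum_test(a, b, label = cl)
    data.frame(comparison = cl, n_a = tr$n_a, n_b = tr$n_b,
               statistic = tr$statistic, p_value = tr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value, dialect = dialect)
  out$tier <- significance_tier(pmin(out$adjusted_p, 1))
  out
}
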