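# Two-group comparison used by both the repertoire statistics (paired
# EAT/SAT panels) and the signature-score comparison.

#' Compare two groups of values
#'
#' Two-sided tests. Mann-Whitney uses the exact null distribution when the
#' combined sample size is at most 20 and there are no ties, and the normal
#' approximation with tie correction (and continuity correction) otherwise.
#' The paired Wilcoxon signed-rank test requires equal-length groups in
#' pairing order; all-zero differences are flagged degenerate with p = 1.
#'
#' @param values_by_group list of exactly two numeric vectors (names used as
#'   group labels), each with >= 2 observations.
#' @param test `"mannwhitney"`, `"ttest"` (Welch) or `"wilcoxon_paired"`.
#' @return list: statistic, p, test, groups, degenerate flag.
#' @export
group_compare <- function(values_by_group,
                          test = c("mannwhitney", "ttest", "wilcoxon_paired")) {
  test <- match.arg(test)
  if (!is.list(values_by_group) || length(values_by_group) != 2L) {
    stop_param("values_by_group must be a list of exactly two numeric vectors")
  }
  x <- as.numeric(values_by_group[[1]])
  y <- as.numeric(values_by_group[[2]])
  if (length(x) < 2L || length(y) < 2L) {
    stop_param("each group needs >= 2 observations")
  }
  labels <- names(values_by_group)
  if (is.null(labels)) labels <- c("group1", "group2")
  degenerate <- FALSE
  res <- switch(test,
    mannwhitney = {
      ties <- anyDuplicated(c(x, y)) > 0
      exact <- (length(x) + length(y)) <= 20L && !ties
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = !exact))
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    ttest = {
      if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
        degenerate <- TRUE
        list(statistic = 0, p = 1)
      } else {
        ht <- stats::t.test(x, y)
        list(statistic = unname(ht$statistic), p = ht$p.value)
      }
    },
    wilcoxon_paired = {
      if (length(x) != length(y)) {
        stop_param("paired test requires equal group lengths")
      }
      d <- x - y
      if (all(d == 0)) {
        degenerate <- TRUE
        list(statistic = 0, p = 1)
      } else {
        ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
        list(statistic = unname(ht$statistic), p = ht$p.value)
      }
    }
  )
  list(statistic = res$statistic, p = res$p, test = test,
       groups = labels, degenerate = degenerate)
}
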