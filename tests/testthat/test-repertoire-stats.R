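# Expansion, sharing, V-J usage and group comparison.

worked_rep <- function() make_rep(c(200, 80, 9, 6, rep(1, 705)))

test_that("worked expansion example matches hand computation exactly", {
  e <- expansion_summary(worked_rep(), thresholds = c(0.001, 0.005, 0.01),
                         top_n = 2)
  expect_equal(unname(e$bin_fractions), c(0.295, 0.295, 0.28))
  expect_equal(e$top_n_proportion, 0.28)
  expect_equal(e$n_clonotypes, 709L)
})

test_that("expansion handles uniform repertoires and validates thresholds", {
  r <- make_rep(rep(10, 10))
  e <- expansion_summary(r, thresholds = 0.01, top_n = 3)
  expect_equal(unname(e$bin_fractions), 1)
  expect_equal(e$top_n_proportion, 0.3)
  e_count <- expansion_summary(r, thresholds = 0.01, bin_mode = "count")
  expect_equal(unname(e_count$bin_fractions), 1)
  expect_error(expansion_summary(r, thresholds = c(0, 0.5)),
               class = "eat_param_error")
  expect_error(expansion_summary(r, thresholds = c(0.5, 0.1)),
               class = "eat_param_error")
})

test_that("bin fractions decrease in threshold; top-N increases to 1", {
  withr::with_seed(21, {
    for (i in 1:15) {
      r <- random_rep()
      e <- expansion_summary(r, thresholds = c(0.001, 0.01, 0.1, 0.5))
      expect_true(all(diff(unname(e$bin_fractions)) <= 1e-12))
      n_ct <- e$n_clonotypes
      tops <- vapply(c(1, ceiling(n_ct / 2), n_ct), function(n) {
        expansion_summary(r, top_n = n)$top_n_proportion
      }, 0)
      expect_true(all(diff(tops) >= -1e-12))
      expect_equal(tops[3], 1, tolerance = 1e-9)
    }
  })
})

test_that("sharing set arithmetic matches the spec examples", {
  a <- make_rep(c(3, 2, 1), cdr3 = c("CAF", "CDF", "CEF"), sample_id = "A")
  b <- make_rep(c(1, 1, 1), cdr3 = c("CDF", "CEF", "CGF"), sample_id = "B")
  s <- sharing_summary(a, b)
  expect_equal(s$n_shared, 2L)
  expect_equal(s$fraction_a, 2 / 3)
  expect_equal(s$jaccard, 0.5)

  ident <- sharing_summary(a, a)
  expect_equal(ident$jaccard, 1)
  expect_equal(ident$freq_correlation$rho, 1)
})

test_that("reversed shared frequencies give Spearman rho -1; small overlap is flagged", {
  a <- make_rep(c(30, 20, 10, 5), cdr3 = c("CAF", "CDF", "CEF", "CWF"))
  b <- make_rep(c(10, 20, 30, 7), cdr3 = c("CAF", "CDF", "CEF", "CYF"))
  s <- sharing_summary(a, b)
  expect_equal(s$freq_correlation$rho, -1)
  expect_equal(s$freq_correlation$n_used, 3L)

  tiny_b <- make_rep(c(1, 1), cdr3 = c("CAF", "CVF"))
  s2 <- sharing_summary(a, tiny_b)
  expect_true(s2$freq_correlation$undefined)
  expect_true(is.na(s2$freq_correlation$rho))
})

test_that("sharing is symmetric under argument swap", {
  withr::with_seed(31, {
    a <- random_rep(sample_id = "A")
    b <- random_rep(sample_id = "B")
    # force some overlap
    b$records$cdr3_aa[1:2] <- a$records$cdr3_aa[1:2]
    b <- repertoire(b$records, "B")
    ab <- sharing_summary(a, b)
    ba <- sharing_summary(b, a)
    expect_equal(ab$n_shared, ba$n_shared)
    expect_equal(ab$jaccard, ba$jaccard)
    expect_equal(ab$fraction_a, ba$fraction_b)
    expect_equal(ab$fraction_b, ba$fraction_a)
  })
})

test_that("vj_usage normalizes mass and strips alleles", {
  r <- make_rep(c(3, 1), v = c("TRBV1*01", "TRBV2"), j = c("TRBJ1-1", "TRBJ1-1"))
  u <- vj_usage(r)
  expect_equal(sum(u$matrix), 1)
  expect_equal(unname(u$matrix["TRBV1", "TRBJ1-1"]), 0.75)
  expect_equal(unname(u$matrix["TRBV2", "TRBJ1-1"]), 0.25)
  one <- vj_usage(make_rep(c(4, 2), v = c("TRBV1", "TRBV1"),
                           j = c("TRBJ1-1", "TRBJ1-1")))
  expect_equal(dim(one$matrix), c(1L, 1L))
  expect_equal(sum(one$matrix), 1)
  # clonotype-count weighting ignores read counts
  uc <- vj_usage(r, weight = "clonotypes")
  expect_equal(unname(uc$matrix["TRBV1", "TRBJ1-1"]), 0.5)
})

test_that("vj_usage_correlation filters on the reference mean and reports rho", {
  r1 <- make_rep(c(6, 4), v = c("TRBV1", "TRBV2"), j = c("TRBJ1-1", "TRBJ1-1"),
                 sample_id = "A")
  r2 <- make_rep(c(6, 4), v = c("TRBV1", "TRBV2"), j = c("TRBJ1-1", "TRBJ1-1"),
                 sample_id = "B")
  u <- list(vj_usage(r1), vj_usage(r2))
  res <- vj_usage_correlation(u, reference = "A", min_avg_usage = 0)
  expect_equal(res$correlations$rho, 1)
  expect_equal(length(res$retained), 2L)
  # threshold excludes everything -> explicit error
  expect_error(vj_usage_correlation(u, reference = "A", min_avg_usage = 0.9),
               class = "eat_data_error")
})

test_that("a reference built with 19 combinations above threshold retains exactly 19", {
  withr::with_seed(41, {
    n_hi <- 19
    n_lo <- 30
    v <- c(sprintf("TRBV%d", 1:n_hi), sprintf("TRBV%d", 1:n_lo))
    j <- c(rep("TRBJ1-1", n_hi), rep("TRBJ2-2", n_lo))
    # 19 combos with ~4.8% each, 30 with ~0.25% each
    counts_ref <- c(rep(48, n_hi), rep(3, n_lo))
    ref <- make_rep(counts_ref, cdr3 = paste0("CR", aa_code(seq_along(v)), "F"),
                    v = v, j = j, sample_id = "HEART")
    other <- make_rep(sample(counts_ref),
                      cdr3 = paste0("CG", aa_code(seq_along(v)), "F"),
                      v = v, j = j, sample_id = "EAT")
    res <- vj_usage_correlation(list(vj_usage(ref), vj_usage(other)),
                                reference = "HEART", min_avg_usage = 0.01)
    expect_equal(length(res$retained), 19L)
    expect_equal(res$correlations$n_combinations, 19L)
  })
})

test_that("group_compare matches exact references and handles degenerates", {
  tt <- group_compare(list(a = c(1, 2, 3), b = c(1, 2, 3)), test = "ttest")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  mw <- group_compare(list(a = c(1, 2, 3), b = c(10, 20, 30)),
                      test = "mannwhitney")
  expect_equal(mw$statistic, 0)      # U = 0: complete separation
  expect_equal(mw$p, 0.1)            # exact: 2 / choose(6, 3)

  wp <- group_compare(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                      test = "wilcoxon_paired")
  expect_true(wp$degenerate)
  expect_equal(wp$p, 1)

  expect_error(group_compare(list(a = 1, b = c(1, 2))),
               class = "eat_param_error")
  expect_error(group_compare(list(a = c(1, 2), b = c(1, 2), c = c(1, 2))),
               class = "eat_param_error")
})

test_that("large-sample Mann-Whitney uses the tie-corrected approximation", {
  withr::with_seed(5, {
    x <- round(rnorm(15), 1)
    y <- round(rnorm(15, 1), 1)
    res <- group_compare(list(x = x, y = y), test = "mannwhitney")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(res$p, ref$p.value)
  })
})
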