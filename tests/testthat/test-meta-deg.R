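# Preprocessing, per-dataset ranking, RRA aggregation and DEG calling.

make_ds <- function(m, groups = NULL, id = "D1") {
  if (is.null(groups)) groups <- rep(c("SAT", "EAT"), each = ncol(m) / 2)
  expression_dataset(m, factor(groups, levels = unique(groups)), id)
}

test_that("quantile normalization replaces order statistics by their mean", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- c("A", "B", "C")
  qn <- eatimmune:::quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  # identical value multisets are unchanged
  m2 <- cbind(s1 = c(3, 1, 2), s2 = c(1, 2, 3))
  expect_equal(sort(eatimmune:::quantile_normalize(m2)[, 1]), c(1, 2, 3))
  # ties receive the mean of their positions' targets
  m3 <- cbind(s1 = c(1, 1, 5), s2 = c(2, 4, 6))
  qn3 <- eatimmune:::quantile_normalize(m3)
  expect_equal(unname(qn3[1, 1]), unname(qn3[2, 1]))
  expect_equal(unname(qn3[1, 1]), mean(rowMeans(apply(m3, 2, sort))[1:2]))
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  withr::with_seed(8, {
    m <- matrix(rnorm(200), 40, 5,
                dimnames = list(sprintf("G%02d", 1:40), sprintf("S%d", 1:5)))
    expect_equal(unname(eatimmune:::quantile_normalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
  })
})

test_that("preprocess_expression logs, normalizes and collapses duplicates", {
  m <- rbind(A = c(3, 3, 3, 3), A = c(10, 10, 10, 10), B = c(1, 1, 1, 1))
  colnames(m) <- sprintf("S%d", 1:4)
  ds <- preprocess_expression(m, rep(c("SAT", "EAT"), 2), "D1", already_log = FALSE)
  expect_equal(sort(rownames(ds$matrix)), c("A", "B"))
  # the higher-mean duplicate row of A survives
  expect_gt(mean(ds$matrix["A", ]), mean(ds$matrix["B", ]))
  expect_error(
    preprocess_expression(m - 5, rep(c("SAT", "EAT"), 2), "D1", already_log = FALSE),
    class = "eat_data_error"
  )
})

test_that("rank_genes matches stats::t.test and handles degenerate genes", {
  withr::with_seed(12, {
    m <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(sprintf("G%02d", 1:50), sprintf("S%d", 1:8)))
    m["G01", ] <- 5                       # constant in both groups
    m["G02", 5:8] <- m["G02", 5:8] + 3    # strong up-regulation
    ds <- make_ds(m)
    rl <- suppressMessages(rank_genes(ds))
    expect_equal(rl[gene == "G01"]$p, 1)
    expect_equal(rl[gene == "G01"]$log2fc, 0)
    expect_lte(rl[gene == "G02"]$rank_up, 5L)
    expect_gte(rl[gene == "G02"]$rank_down, 45L)
    # ranks are permutations
    expect_setequal(rl$rank_up, seq_len(50))
    expect_setequal(rl$rank_down, seq_len(50))
    # Welch p agrees with stats::t.test on a non-degenerate gene
    g <- m["G10", ]
    ref <- stats::t.test(g[5:8], g[1:4])
    expect_equal(rl[gene == "G10"]$p, ref$p.value, tolerance = 1e-12)
    expect_equal(rl[gene == "G10"]$log2fc, unname(diff(ref$estimate)) * -1 + 0,
                 tolerance = 1e-12)
  })
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  # computed by hand: sorted p * m / i, then cumulative min from the largest
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  withr::with_seed(2, {
    m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(sprintf("G%02d", 1:20), NULL))
    rl <- rank_genes(make_ds(m))
    expect_true(all(rl$p_adj >= rl$p))
  })
})

test_that("RRA closed-form example: rank 1/100 in both of two lists", {
  # p_1 = 1 - 0.99^2 = 0.0199; p_2 = 0.01^2 = 1e-4; rho = 1e-4, adj = 2e-4
  expect_equal(eatimmune:::rra_rho(c(0.01, 0.01)), 1e-4, tolerance = 1e-12)
  expect_equal(eatimmune:::rra_rho(c(1, 1)), 1)
})

test_that("rra_aggregate orders by evidence, unions universes, ranks missing worst", {
  withr::with_seed(33, {
    m1 <- matrix(rnorm(100 * 10), 100, 10,
                 dimnames = list(sprintf("G%03d", 1:100), NULL))
    m1["G001", 6:10] <- m1["G001", 6:10] + 4
    m2 <- m1 + matrix(rnorm(1000, 0, 0.5), 100, 10)
    # second dataset lacks G050
    m2 <- m2[rownames(m2) != "G050", ]
    l1 <- rank_genes(make_ds(m1, id = "D1"))
    l2 <- rank_genes(make_ds(m2, id = "D2"))
    up <- rra_aggregate(list(l1, l2), "up")
    expect_equal(up$gene[1], "G001")
    expect_lt(up$rho[1], 0.01)
    g50 <- up[gene == "G050"]
    expect_equal(g50$n_lists, 1L)
    # missing-from-list = normalized rank 1: rho bounded by the beta tail at
    # the observed rank alone
    r_obs <- l1[gene == "G050"]$rank_up / 100
    expect_equal(g50$rho, eatimmune:::rra_rho(c(r_obs, 1)), tolerance = 1e-12)
  })
})

test_that("rho is order-invariant and monotone in every rank", {
  withr::with_seed(44, {
    for (i in 1:10) {
      r <- runif(sample(2:5, 1))
      expect_equal(eatimmune:::rra_rho(r), eatimmune:::rra_rho(sample(r)))
      # worsening any one rank cannot decrease the score
      k <- sample(length(r), 1)
      worse <- r
      worse[k] <- min(1, r[k] + runif(1, 0, 1 - r[k]))
      expect_gte(eatimmune:::rra_rho(worse) + 1e-12, eatimmune:::rra_rho(r))
    }
  })
})

test_that("call_degs conjoins the RRA cut with the per-dataset filter", {
  withr::with_seed(55, {
    sim <- simulate_expression(expression_sim_params(
      n_datasets = 2, n_genes = 300, n_per_group = 10, deg_fraction = 0.1,
      lfc_mean = 2, noise_sd = 0.4, seed = 55
    ))
    lists <- lapply(sim$datasets, rank_genes)
    degs <- call_degs(lists)
    called <- degs[degs$passed_filters]
    truth <- sim$truth$deg
    hit <- merge(called, truth, by = "gene")
    expect_gt(nrow(hit), 0)
    expect_true(all(hit$direction.x == hit$direction.y))
    # a huge lfc_cut defeats the per-dataset filter but keeps score passers
    strict <- call_degs(lists, lfc_cut = 50)
    expect_true(nrow(strict) > 0)
    expect_false(any(strict$passed_filters))
    expect_error(call_degs(lists, score_cut = 0), class = "eat_param_error")
  })
})

test_that("consistency fraction approaches 1 as noise vanishes", {
  sim <- simulate_expression(expression_sim_params(
    n_datasets = 3, n_genes = 200, n_per_group = 8, deg_fraction = 0.1,
    lfc_mean = 1.5, noise_sd = 0.05, platform_sd = 0.5, seed = 66
  ))
  degs <- call_degs(lapply(sim$datasets, rank_genes))
  expect_equal(attr(degs, "consistency_fraction"), 1)
})

test_that("gene_set_intersect matches case-insensitively and warns on empty sets", {
  degs <- data.table::data.table(
    gene = c("A", "B"), direction = c("up", "down"),
    rra_score = c(0.01, 0.02), passed_filters = c(TRUE, TRUE),
    supporting_datasets = c("D1", "D1"), direction_consistent = c(TRUE, TRUE)
  )
  res <- gene_set_intersect(degs, list(mod = c("b", "C")))
  expect_equal(res$mod$gene, "B")
  expect_equal(res$mod$direction, "down")
  expect_warning(out <- gene_set_intersect(degs, list(empty = character())))
  expect_equal(nrow(out$empty), 0L)
  expect_lte(nrow(res$mod), min(nrow(degs), 2))
})
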