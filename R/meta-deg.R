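# Cross-dataset consensus differential expression.
#
# Per dataset: two-group ranking (Welch's t on log2-scale data) -> ranked
# gene lists; across datasets: Robust Rank Aggregation (rra.R) and a DEG
# call that conjoins the RRA score cut with a per-dataset significance and
# fold-change filter, plus direction-consistency accounting.

#' Gene-by-sample expression dataset with two-group labels
#'
#' @param matrix numeric gene x sample matrix with rownames (gene symbols)
#'   and colnames (sample ids), on log2 scale unless `log_scale = FALSE`.
#' @param groups per-sample group labels (two levels; second level is the
#'   "case" whose positive log2fc means up-regulation).
#' @param dataset_id platform / dataset identifier.
#' @param log_scale is the matrix already log2-transformed?
#' @return class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, groups, dataset_id, log_scale = TRUE) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) stop_data("expression matrix must have gene rownames")
  if (anyDuplicated(rownames(m))) {
    stop_data("duplicate gene symbols; collapse with preprocess_expression()")
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) stop_data("one group label per sample required")
  if (nlevels(groups) != 2) stop_data("exactly two group levels required")
  if (any(table(groups) < 2)) stop_data("need >= 2 samples per group")
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  structure(list(dataset_id = as.character(dataset_id), matrix = m,
                 groups = groups, log_scale = isTRUE(log_scale)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples (%s: %s)\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              paste(levels(x$groups), collapse = " vs "),
              paste(table(x$groups), collapse = "/")))
  invisible(x)
}

# Quantile-normalize columns: each sample's sorted values are replaced by the
# across-sample mean of order statistics; tied values receive the mean of the
# target values at their tied positions.
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    y <- numeric(length(x))
    y[order(x)] <- target
    stats::ave(y, x, FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Preprocess a raw expression matrix
#'
#' Applies `log2(x + 1)` when `already_log = FALSE`, then quantile
#' normalization across samples, then collapses duplicate gene symbols by
#' keeping the row with maximum mean expression.
#'
#' @param raw gene x sample numeric matrix (rownames = symbols).
#' @param groups per-sample two-level group labels.
#' @param dataset_id dataset identifier.
#' @param already_log skip the log2 step.
#' @return an [expression_dataset()] on log2 scale.
#' @export
preprocess_expression <- function(raw, groups, dataset_id, already_log = TRUE) {
  m <- as.matrix(raw)
  if (!already_log) {
    if (any(m < 0, na.rm = TRUE)) {
      stop_data("negative entries are incompatible with already_log = FALSE")
    }
    m <- log2(m + 1)
  }
  m <- quantile_normalize(m)
  if (anyDuplicated(rownames(m))) {
    keep <- order(-rowMeans(m))
    m <- m[keep, , drop = FALSE]
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  expression_dataset(m, groups, dataset_id, log_scale = TRUE)
}

# Vectorised Welch's t over rows; returns two-sided and one-sided (case >
# control) p-values. Zero variance in both groups -> p = 1, p_up = 0.5.
welch_rows <- function(m, case_idx, ctrl_idx) {
  n1 <- length(case_idx); n0 <- length(ctrl_idx)
  x1 <- m[, case_idx, drop = FALSE]; x0 <- m[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  degenerate <- se2 == 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p_up <- stats::pt(tstat, df, lower.tail = FALSE)
  p[degenerate] <- 1
  p_up[degenerate] <- 0.5
  tstat[degenerate] <- 0
  list(log2fc = m1 - m0, t = tstat, p = p, p_up = p_up,
       n_degenerate = sum(degenerate))
}

#' Rank genes within one dataset
#'
#' Per gene: `log2fc = mean(case) - mean(control)`, two-sided Welch's t
#' p-value, Benjamini-Hochberg adjustment, and two direction-specific rank
#' orderings. `rank_up` orders genes by the one-sided (up-favoring) Welch p
#' ascending, tie-broken by `|log2fc|` descending then gene symbol;
#' `rank_down` symmetrically. Genes with zero variance in both groups get
#' p = 1 (with a message, not NaN).
#'
#' @param ds an [expression_dataset()].
#' @return data.table: gene, log2fc, t, p, p_adj, rank_up, rank_down, with
#'   the dataset id as attribute `dataset_id`.
#' @export
rank_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  case <- which(ds$groups == levels(ds$groups)[2])
  ctrl <- which(ds$groups == levels(ds$groups)[1])
  w <- welch_rows(ds$matrix, case, ctrl)
  if (w$n_degenerate > 0) {
    message(ds$dataset_id, ": ", w$n_degenerate,
            " gene(s) with zero variance in both groups; p set to 1")
  }
  res <- data.table::data.table(
    gene = rownames(ds$matrix), log2fc = w$log2fc, t = w$t,
    p = w$p, p_adj = stats::p.adjust(w$p, "BH")
  )
  ord_up <- order(w$p_up, -abs(w$log2fc), res$gene)
  ord_down <- order(1 - w$p_up, -abs(w$log2fc), res$gene)
  res[ord_up, "rank_up" := seq_len(.N)]
  res[ord_down, "rank_down" := seq_len(.N)]
  data.table::setattr(res, "dataset_id", ds$dataset_id)
  res[]
}

#' Call consensus differential genes
#'
#' A gene is called in a direction when its aggregated RRA score passes
#' `score_cut` AND at least one dataset shows `p_adj < p_cut` together with
#' a log2 fold change of at least `lfc_cut` in that direction. The returned
#' table covers every gene passing the score cut in either direction, with
#' `passed_filters` marking the conjunction; `consistency_fraction` (the
#' fraction of filter-passing genes whose fold-change sign agrees across all
#' datasets where observed) is carried as an attribute.
#'
#' @param lists list of [rank_genes()] outputs.
#' @param rra_up,rra_down [rra_aggregate()] results for the two directions;
#'   computed from `lists` when `NULL`.
#' @param score_cut,p_cut,lfc_cut filter thresholds (defaults 0.05 / 0.05 / 0.5).
#' @param use_adjusted_score threshold the multiplicity-corrected `score_adj`
#'   (default) or the raw beta-order-statistic `rho`.
#' @return data.table: gene, direction, rra_score, passed_filters,
#'   supporting_datasets (comma-joined), direction_consistent.
#' @export
call_degs <- function(lists, rra_up = NULL, rra_down = NULL,
                      score_cut = 0.05, p_cut = 0.05, lfc_cut = 0.5,
                      use_adjusted_score = TRUE) {
  if (score_cut <= 0 || score_cut > 1 || p_cut <= 0 || p_cut > 1 || lfc_cut < 0) {
    stop_param("score_cut and p_cut must be in (0,1]; lfc_cut >= 0")
  }
  if (is.null(rra_up)) rra_up <- rra_aggregate(lists, "up")
  if (is.null(rra_down)) rra_down <- rra_aggregate(lists, "down")
  ids <- vapply(lists, function(l) attr(l, "dataset_id"), "")
  score_col <- if (use_adjusted_score) "score_adj" else "rho"
  one_direction <- function(rra, dir) {
    hits <- rra[rra[[score_col]] < score_cut]
    if (nrow(hits) == 0L) return(NULL)
    sgn <- if (dir == "up") 1 else -1
    support <- lapply(hits$gene, function(g) {
      ok <- vapply(seq_along(lists), function(i) {
        row <- lists[[i]][gene == g]
        nrow(row) == 1L && row$p_adj < p_cut && sgn * row$log2fc >= lfc_cut
      }, TRUE)
      ids[ok]
    })
    data.table::data.table(
      gene = hits$gene, direction = dir, rra_score = hits[[score_col]],
      passed_filters = lengths(support) > 0,
      supporting_datasets = vapply(support, paste, "", collapse = ","),
      direction_consistent = hits$direction_consistent
    )
  }
  out <- data.table::rbindlist(list(one_direction(rra_up, "up"),
                                    one_direction(rra_down, "down")))
  if (nrow(out) == 0L) {
    out <- data.table::data.table(gene = character(), direction = character(),
                                  rra_score = numeric(), passed_filters = logical(),
                                  supporting_datasets = character(),
                                  direction_consistent = logical())
  }
  passed <- out[out$passed_filters]
  cf <- if (nrow(passed)) mean(passed$direction_consistent) else NA_real_
  data.table::setattr(out, "consistency_fraction", cf)
  out[]
}

#' Intersect called DEGs with named gene sets
#'
#' Mirrors the construction of a "key gene" set as the overlap of consensus
#' DEGs with externally derived module gene lists. Symbols are
#' case-normalized (upper-cased) before matching.
#'
#' @param degs a [call_degs()] table (only `passed_filters` genes are used).
#' @param gene_sets named list of character vectors.
#' @return named list of data.tables (gene, direction) per set.
#' @export
gene_set_intersect <- function(degs, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  called <- degs[degs$passed_filters]
  called_up <- toupper(called$gene)
  lapply(gene_sets, function(set) {
    if (length(set) == 0L) {
      warning("empty gene set")
      return(data.table::data.table(gene = character(), direction = character()))
    }
    idx <- called_up %in% toupper(set)
    data.table::data.table(gene = called$gene[idx], direction = called$direction[idx])
  })
}
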