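# T cell-inflamed gene-expression-profile (GEP) scoring.
#
# The score summarizes inflammatory T-cell infiltration as the (optionally
# weighted) mean of z-scored signature-gene expressions. Because downstream
# use is comparative (case vs control; correlation with individual genes),
# the score is invariant to affine rescaling, so unweighted z-score
# averaging is the default and published weights can be supplied when
# available.

#' Define a gene signature
#'
#' @param genes unique gene symbols.
#' @param weights optional numeric weights aligned to `genes`.
#' @param name signature name.
#' @return class `gene_signature`.
#' @export
gene_signature <- function(genes, weights = NULL, name = "signature") {
  genes <- as.character(genes)
  if (length(genes) == 0L || anyDuplicated(genes)) {
    stop_param("signature genes must be non-empty and unique")
  }
  if (!is.null(weights)) {
    if (length(weights) != length(genes) || any(!is.finite(weights))) {
      stop_param("weights must be finite and aligned to genes")
    }
    weights <- as.numeric(weights)
  }
  structure(list(name = name, genes = genes, weights = weights),
            class = "gene_signature")
}

#' Read a signature from a two-column TSV
#'
#' Format: gene symbol, optional weight; `#` starts a comment line.
#'
#' @param path file path.
#' @param name signature name (defaults to the file name stem).
#' @return a [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop_data("signature file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("signature file ", path, " has no entries")
  parts <- strsplit(lines, "[\t ]+")
  genes <- vapply(parts, `[`, "", 1L)
  weights <- NULL
  if (all(lengths(parts) >= 2L)) {
    weights <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (any(is.na(weights))) stop_format("non-numeric weight in ", path)
  }
  gene_signature(genes, weights, name)
}

#' Score samples against a gene signature
#'
#' Each available signature gene's expression row is z-scored across
#' samples; the per-sample score is the (weighted) mean of those z-scores.
#' Zero-variance genes are dropped with a message (synthetic nulls can
#' produce them); genes absent from the dataset reduce coverage, and
#' coverage below `min_coverage` is an error naming the missing genes.
#'
#' @param ds an [expression_dataset()].
#' @param sig a [gene_signature()].
#' @param min_coverage minimum fraction of signature genes required, in (0, 1].
#' @return data.table of class `signature_scores`: sample_id, score, group;
#'   attributes `coverage`, `signature`, `genes_used`, `genes_dropped`.
#' @export
gep_score <- function(ds, sig, min_coverage = 0.5) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(sig, "gene_signature"))
  if (min_coverage <= 0 || min_coverage > 1) {
    stop_param("min_coverage must be in (0, 1]")
  }
  present <- sig$genes %in% rownames(ds$matrix)
  coverage <- mean(present)
  if (coverage < min_coverage) {
    stop_data("signature coverage ", signif(coverage, 3), " below min_coverage ",
              min_coverage, "; missing: ",
              paste(sig$genes[!present], collapse = ", "))
  }
  genes <- sig$genes[present]
  w <- if (is.null(sig$weights)) rep(1, length(genes)) else sig$weights[present]
  x <- ds$matrix[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    message("gep_score: dropping zero-variance signature gene(s): ",
            paste(genes[!keep], collapse = ", "))
  }
  if (!any(keep)) stop_data("all available signature genes have zero variance")
  z <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sds[keep]
  wk <- w[keep]
  score <- as.vector(crossprod(z, wk) / sum(wk))
  out <- data.table::data.table(sample_id = colnames(ds$matrix),
                                score = score,
                                group = as.character(ds$groups))
  data.table::setattr(out, "coverage", coverage)
  data.table::setattr(out, "signature", sig$name)
  data.table::setattr(out, "genes_used", genes[keep])
  data.table::setattr(out, "genes_dropped", genes[!keep])
  data.table::setattr(out, "class", c("signature_scores", class(out)))
  out[]
}

#' Correlate gene expression with the signature score
#'
#' @param scores a [gep_score()] table for the same samples as `ds`.
#' @param ds the [expression_dataset()].
#' @param genes gene symbols to correlate (must be present in `ds`).
#' @param method `"pearson"` or `"spearman"`.
#' @return data.table: gene, r, p, n, in_signature (flagging the partial
#'   circularity of correlating a signature member with its own score),
#'   undefined (constant gene; r reported as NA, not propagated as NaN).
#' @export
score_gene_correlation <- function(scores, ds, genes,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "expression_dataset"))
  absent <- setdiff(genes, rownames(ds$matrix))
  if (length(absent)) {
    stop_data("gene(s) absent from dataset: ", paste(absent, collapse = ", "))
  }
  if (nrow(scores) < 3L) stop_param("need >= 3 samples for correlation")
  s <- scores$score[match(colnames(ds$matrix), scores$sample_id)]
  if (any(is.na(s))) stop_data("scores and dataset samples do not match")
  sig_genes <- attr(scores, "genes_used")
  data.table::rbindlist(lapply(genes, function(g) {
    x <- ds$matrix[g, ]
    if (stats::sd(x) == 0 || stats::sd(s) == 0) {
      return(data.table::data.table(gene = g, r = NA_real_, p = NA_real_,
                                    n = length(x),
                                    in_signature = g %in% sig_genes,
                                    undefined = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(x, s, method = method, exact = FALSE))
    data.table::data.table(gene = g, r = unname(ct$estimate), p = ct$p.value,
                           n = length(x), in_signature = g %in% sig_genes,
                           undefined = FALSE)
  }))
}

#' Compare signature scores between the two groups
#'
#' Delegates to [group_compare()] (Mann-Whitney by default) and reports
#' which group has the higher median score.
#'
#' @param scores a [gep_score()] table.
#' @param test test name passed to [group_compare()].
#' @return list: statistic, p, test, higher_group (NA on exact tie).
#' @export
score_group_compare <- function(scores, test = "mannwhitney") {
  groups <- unique(scores$group)
  if (length(groups) != 2L) {
    stop_param("scores must contain exactly two groups, got: ",
               paste(groups, collapse = ", "))
  }
  vals <- split(scores$score, scores$group)[groups]
  res <- group_compare(vals, test = test)
  med <- vapply(vals, stats::median, 0)
  res$higher_group <- if (med[1] == med[2]) NA_character_ else names(which.max(med))
  res
}
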