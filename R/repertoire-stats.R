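# Repertoire statistics: clonal expansion, cross-tissue clonotype sharing,
# and V-J gene-segment usage.

#' Clonal-expansion summary of a repertoire
#'
#' Computes clone and clonotype counts, the repertoire mass in frequency
#' bins, and the proportion held by the top N clonotypes. A bin at threshold
#' t collects clonotypes with frequency strictly greater than t (so the
#' default thresholds 0.001 / 0.005 / 0.01 are the low / middle / high
#' frequency bins at 0.1% / 0.5% / 1%). `bin_mode = "mass"` (default)
#' reports the cumulative read-frequency mass of those clonotypes;
#' `"count"` reports their fraction of distinct clonotypes. Top-N ties at
#' the cutoff are broken by descending count then lexicographic CDR3, for
#' determinism.
#'
#' @param rep a [repertoire()].
#' @param thresholds strictly increasing frequencies in (0, 1).
#' @param top_n number of leading clonotypes for the top-N proportion.
#' @param bin_mode `"mass"` or `"count"`.
#' @return list of class `expansion_summary`: sample_id, n_clones,
#'   n_clonotypes, bin_fractions (named by threshold), top_n_proportion.
#' @export
expansion_summary <- function(rep, thresholds = c(0.001, 0.005, 0.01),
                              top_n = 10L, bin_mode = c("mass", "count")) {
  stopifnot(inherits(rep, "repertoire"))
  bin_mode <- match.arg(bin_mode)
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop_param("thresholds must lie strictly inside (0, 1)")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_param("thresholds must be strictly increasing")
  }
  if (top_n < 1) stop_param("top_n must be >= 1")
  ct <- aggregate_repertoire(rep, "clonotype")
  cl <- aggregate_repertoire(rep, "clone")
  bin_fractions <- vapply(thresholds, function(t) {
    above <- ct$frequency > t
    if (bin_mode == "mass") sum(ct$frequency[above]) else mean(above)
  }, 0)
  names(bin_fractions) <- format(thresholds, trim = TRUE)
  ord <- order(-ct$read_count, ct$cdr3_aa)
  top <- utils::head(ord, top_n)
  structure(list(sample_id = rep$sample_id,
                 n_clones = nrow(cl), n_clonotypes = nrow(ct),
                 bin_fractions = bin_fractions,
                 top_n = as.integer(top_n),
                 top_n_proportion = sum(ct$frequency[top]),
                 bin_mode = bin_mode),
            class = "expansion_summary")
}

#' Clonotype sharing between two repertoires
#'
#' The shared set is the intersection of clonotype (CDR3 amino-acid) keys.
#' `fraction_a` / `fraction_b` divide the shared count by each repertoire's
#' clonotype count; `jaccard` divides by the union size. The frequency
#' correlation pairs the two repertoires' clonotype frequencies; by default
#' over the shared clonotypes only (`corr_mode = "shared"`), or over the
#' union with absent clonotypes at frequency zero (`"union-zeros"`). With
#' fewer than 3 usable pairs the correlation is reported as `NA` and
#' flagged `undefined`, never coerced to zero.
#'
#' @param rep_a,rep_b non-empty [repertoire()] objects.
#' @param corr_method `"spearman"` (default) or `"pearson"`.
#' @param corr_mode `"shared"` or `"union-zeros"`.
#' @return list of class `sharing_summary`.
#' @export
sharing_summary <- function(rep_a, rep_b, corr_method = c("spearman", "pearson"),
                            corr_mode = c("shared", "union-zeros")) {
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  corr_method <- match.arg(corr_method)
  corr_mode <- match.arg(corr_mode)
  a <- aggregate_repertoire(rep_a, "clonotype")
  b <- aggregate_repertoire(rep_b, "clonotype")
  shared <- intersect(a$cdr3_aa, b$cdr3_aa)
  union_keys <- union(a$cdr3_aa, b$cdr3_aa)
  keys <- if (corr_mode == "shared") shared else union_keys
  fa <- stats::setNames(a$frequency, a$cdr3_aa)[keys]
  fb <- stats::setNames(b$frequency, b$cdr3_aa)[keys]
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  corr <- if (length(keys) >= 3L) {
    ct <- suppressWarnings(
      stats::cor.test(fa, fb, method = corr_method, exact = FALSE)
    )
    list(rho = unname(ct$estimate), p = ct$p.value,
         n_used = length(keys), undefined = is.na(ct$estimate))
  } else {
    list(rho = NA_real_, p = NA_real_, n_used = length(keys), undefined = TRUE)
  }
  structure(list(sample_pair = c(rep_a$sample_id, rep_b$sample_id),
                 n_shared = length(shared),
                 fraction_a = length(shared) / nrow(a),
                 fraction_b = length(shared) / nrow(b),
                 jaccard = length(shared) / length(union_keys),
                 freq_correlation = corr,
                 corr_method = corr_method, corr_mode = corr_mode),
            class = "sharing_summary")
}

#' V-J usage matrix of a repertoire
#'
#' Usage mass of a (V, J) cell is the summed read frequency (default) or
#' clonotype-count fraction of records with that allele-stripped V and J
#' call. Rows and columns are ordered by gene name for reproducibility.
#'
#' @param rep a [repertoire()].
#' @param weight `"reads"` (read-frequency weighted) or `"clonotypes"`.
#' @return list of class `vj_usage`: sample_id, `matrix` (V x J), and
#'   `vector` (flattened, named `"V|J"`); entries sum to 1.
#' @export
vj_usage <- function(rep, weight = c("reads", "clonotypes")) {
  stopifnot(inherits(rep, "repertoire"))
  weight <- match.arg(weight)
  rec <- data.table::copy(rep$records)
  rec[, "v_gene" := strip_allele(v_call)]
  rec[, "j_gene" := strip_allele(j_call)]
  mass <- if (weight == "reads") {
    rec[, list(w = sum(frequency)), by = c("v_gene", "j_gene")]
  } else {
    ag <- unique(rec, by = c("cdr3_aa", "v_call", "d_call", "j_call"))
    ag[, list(w = .N), by = c("v_gene", "j_gene")]
  }
  mass[, "w" := w / sum(w)]
  vs <- sort(unique(mass$v_gene)); js <- sort(unique(mass$j_gene))
  m <- matrix(0, length(vs), length(js), dimnames = list(vs, js))
  m[cbind(mass$v_gene, mass$j_gene)] <- mass$w
  vec <- as.vector(t(m))
  names(vec) <- paste(rep(vs, each = length(js)), rep(js, length(vs)), sep = "|")
  structure(list(sample_id = rep$sample_id, matrix = m, vector = vec,
                 weight = weight),
            class = "vj_usage")
}

#' Pairwise correlation of V-J usage across samples
#'
#' Retains the V-J combinations whose mean usage over the reference samples
#' exceeds `min_avg_usage` (mirroring a "frequency above 1% in the reference
#' tissue" filter), then reports Spearman's rho over the retained
#' combination vector for every sample pair.
#'
#' @param usage_list list (>= 2) of [vj_usage()] objects.
#' @param reference sample id(s) forming the reference group whose mean
#'   usage drives the filter.
#' @param min_avg_usage retention threshold in \[0, 1).
#' @return list: `retained` (combination names) and `correlations`
#'   (data.table sample_a / sample_b / rho / p / n_combinations).
#' @export
vj_usage_correlation <- function(usage_list, reference, min_avg_usage = 0.01) {
  stopifnot(is.list(usage_list), all(vapply(usage_list, inherits, TRUE, "vj_usage")))
  if (length(usage_list) < 2L) stop_param("need >= 2 usage matrices")
  if (min_avg_usage < 0 || min_avg_usage >= 1) {
    stop_param("min_avg_usage must lie in [0, 1)")
  }
  ids <- vapply(usage_list, function(u) u$sample_id, "")
  names(usage_list) <- ids
  if (!all(reference %in% ids)) {
    stop_param("reference sample(s) not in usage list: ",
               paste(setdiff(reference, ids), collapse = ", "))
  }
  combos <- sort(unique(unlist(lapply(usage_list, function(u) names(u$vector)))))
  umat <- vapply(usage_list, function(u) {
    v <- stats::setNames(numeric(length(combos)), combos)
    v[names(u$vector)] <- u$vector
    v
  }, numeric(length(combos)))
  ref_mean <- rowMeans(umat[, reference, drop = FALSE])
  retained <- combos[ref_mean > min_avg_usage]
  if (length(retained) == 0L) {
    stop_data("no V-J combination exceeds min_avg_usage = ", min_avg_usage,
              " in the reference group")
  }
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  cors <- data.table::rbindlist(lapply(pairs, function(pr) {
    x <- umat[retained, pr[1]]; y <- umat[retained, pr[2]]
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.table::data.table(sample_a = pr[1], sample_b = pr[2],
                           rho = unname(ct$estimate), p = ct$p.value,
                           n_combinations = length(retained))
  }))
  list(retained = retained, correlations = cors)
}
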