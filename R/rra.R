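# Robust Rank Aggregation.
#
# For a gene with normalized ranks r_1..r_m across m lists (rank / list
# length; missing-from-list = 1, the conservative worst rank), sort the
# ranks ascending and compute, for each k, the probability that at least k
# of m independent Uniform(0,1) variables fall at or below r_(k):
#
#   p_k = P(U_(k) <= r_(k)) = sum_{j>=k} C(m,j) r^j (1-r)^(m-j)
#       = pbeta(r_(k), k, m - k + 1)
#
# The rho score is min_k p_k; the adjusted score applies a Bonferroni
# correction over the m minima considered: score_adj = min(1, m * rho).

rra_rho <- function(r) {
  r <- sort(r)
  m <- length(r)
  min(stats::pbeta(r, seq_len(m), m - seq_len(m) + 1))
}

#' Aggregate per-dataset gene rankings with Robust Rank Aggregation
#'
#' Takes the union of gene universes across lists; a gene absent from a list
#' receives normalized rank 1 (worst) in that list. Direction consistency is
#' the agreement of each list's fold-change sign with the aggregation
#' direction, evaluated over the lists where the gene is observed.
#'
#' @param lists list (>= 2) of [rank_genes()] outputs.
#' @param direction `"up"` aggregates `rank_up`, `"down"` aggregates
#'   `rank_down`.
#' @return data.table: gene, rho, score_adj, n_lists (lists containing the
#'   gene), direction_consistent (all observed signs match the direction),
#'   consistency_fraction (per-gene fraction of observed lists matching).
#' @export
rra_aggregate <- function(lists, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.list(lists) || length(lists) < 2L) {
    stop_param("rra_aggregate needs >= 2 ranked lists")
  }
  rank_col <- paste0("rank_", direction)
  m <- length(lists)
  universe <- sort(unique(unlist(lapply(lists, function(l) l$gene))))
  rmat <- matrix(1, length(universe), m, dimnames = list(universe, NULL))
  smat <- matrix(NA_real_, length(universe), m, dimnames = list(universe, NULL))
  for (i in seq_len(m)) {
    l <- lists[[i]]
    n <- nrow(l)
    rmat[l$gene, i] <- l[[rank_col]] / n
    smat[l$gene, i] <- sign(l$log2fc)
  }
  sgn <- if (direction == "up") 1 else -1
  rho <- apply(rmat, 1, rra_rho)
  n_lists <- rowSums(!is.na(smat))
  match_frac <- rowSums(smat == sgn, na.rm = TRUE) / pmax(n_lists, 1L)
  res <- data.table::data.table(
    gene = universe, rho = rho, score_adj = pmin(1, m * rho),
    n_lists = as.integer(n_lists),
    direction_consistent = n_lists > 0 & match_frac == 1,
    consistency_fraction = match_frac
  )
  dropped <- res$n_lists == 0L
  if (any(dropped)) {
    message("rra_aggregate: ", sum(dropped),
            " gene(s) absent from every list; excluded")
    res <- res[!dropped]
  }
  data.table::setorder(res, rho, gene)
  res[]
}
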