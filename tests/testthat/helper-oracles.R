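# Fixture builders and independent brute-force oracles. Oracles are written
# from first principles and never call the implementation they check.

# Encode an integer as a 3-letter amino-acid string (base-20) so generated
# CDR3s stay inside the legal alphabet.
aa_code <- function(i) {
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(i - 1L, function(k) {
    paste0(ab[(k %/% 400) %% 20 + 1], ab[(k %/% 20) %% 20 + 1], ab[k %% 20 + 1])
  }, "")
}

make_rep <- function(counts, cdr3 = NULL, v = NULL, d = NULL, j = NULL,
                     sample_id = "S1", patient_id = "P1", tissue = "EAT") {
  n <- length(counts)
  if (is.null(cdr3)) cdr3 <- paste0("CASS", aa_code(seq_len(n)), "F")
  if (is.null(v)) v <- rep("TRBV1", n)
  if (is.null(d)) d <- rep("", n)
  if (is.null(j)) j <- rep("TRBJ1-1", n)
  repertoire(
    data.frame(cdr3_aa = cdr3, v_call = v, d_call = d, j_call = j,
               read_count = counts, stringsAsFactors = FALSE),
    sample_id, patient_id, tissue
  )
}

# Random small repertoire for property tests (call inside withr::with_seed).
random_rep <- function(max_clonotypes = 50, sample_id = "S1") {
  n <- sample(3:max_clonotypes, 1)
  prefix <- paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 3, TRUE),
                   collapse = "")
  cdr3 <- paste0("C", prefix, aa_code(seq_len(n)), "F")
  make_rep(counts = sample(1:200, n, replace = TRUE), cdr3 = cdr3,
           v = sample(sprintf("TRBV%d", 1:5), n, replace = TRUE),
           j = sample(sprintf("TRBJ1-%d", 1:3), n, replace = TRUE),
           sample_id = sample_id)
}

# --- brute-force oracles -------------------------------------------------

bf_bin_mass <- function(counts, t) {
  f <- counts / sum(counts)
  sum(f[f > t])
}

bf_top_n <- function(counts, cdr3, n) {
  f <- counts / sum(counts)
  ord <- order(-counts, cdr3)
  sum(f[ord][seq_len(min(n, length(f)))])
}

bf_jaccard <- function(keys_a, keys_b) {
  length(intersect(keys_a, keys_b)) / length(union(keys_a, keys_b))
}

# Spearman as rank-then-Pearson with average ranks.
bf_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Monte-Carlo oracle for the RRA beta order-statistic score: estimate
# P(U_(k) <= r_(k)) for each k by drawing uniform rank vectors, take the min.
mc_rra <- function(r, n_draws = 1e5) {
  m <- length(r)
  u <- matrix(stats::runif(n_draws * m), n_draws, m)
  u <- t(apply(u, 1, sort))
  rs <- sort(r)
  ps <- vapply(seq_len(m), function(k) mean(u[, k] <= rs[k]), 0)
  k <- which.min(ps)
  list(est = ps[k], se = sqrt(ps[k] * (1 - ps[k]) / n_draws))
}

# Normalized ranks of one gene across ranked lists, as rra_aggregate sees them.
gene_norm_ranks <- function(lists, gene, direction = "up") {
  col <- paste0("rank_", direction)
  vapply(lists, function(l) {
    row <- l[l$gene == gene]
    if (nrow(row) == 0L) 1 else row[[col]] / nrow(l)
  }, 0)
}
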