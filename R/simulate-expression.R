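# Multi-platform expression simulator with planted differential genes and a
# latent T-cell-infiltration factor.
#
# Matrices are generated directly on a log2-like additive scale:
#   x[g, s] = baseline_g + platform_shift[g, d] + I(group1, s) * lfc_g
#             + coupling * factor_s * I(g in signature) + N(0, noise_sd)
# so the pipeline's log2 step is the identity for synthetic input
# (exponentiate = TRUE emits 2^x - 1 to exercise the transform path).

#' Parameters for the multi-platform expression simulator
#'
#' @param n_datasets number of simulated "platforms" (independent datasets).
#' @param n_genes genes per dataset (shared gene universe `G0001...`).
#' @param n_per_group samples per group per dataset.
#' @param deg_fraction fraction of genes planted as differential.
#' @param lfc_mean planted log2 fold-change magnitude.
#' @param deg_direction `"both"` (random sign per gene, consistent across
#'   datasets) or `"up"` / `"down"`.
#' @param platform_sd sd of per-gene dataset-level shifts (platform effect).
#' @param noise_sd sd of i.i.d. Gaussian measurement noise (> 0).
#' @param infiltration_coupling loading of signature genes on the latent
#'   per-sample infiltration factor (standard normal); 0 decouples the score.
#' @param n_signature number of signature genes (drawn from non-DEG genes so
#'   group effects and the latent factor stay orthogonal).
#' @param groups two group labels, second = the "case" group carrying the lfc.
#' @param exponentiate emit `2^x - 1` (linear scale) instead of log2 scale.
#' @param seed integer seed.
#' @return class `expression_sim_params` list.
#' @export
expression_sim_params <- function(n_datasets = 2, n_genes = 1000, n_per_group = 10,
                                  deg_fraction = 0.1, lfc_mean = 1,
                                  deg_direction = c("both", "up", "down"),
                                  platform_sd = 1, noise_sd = 0.5,
                                  infiltration_coupling = 0, n_signature = 20,
                                  groups = c("SAT", "EAT"), exponentiate = FALSE,
                                  seed = 1) {
  deg_direction <- match.arg(deg_direction)
  if (n_datasets < 1 || n_genes < 1 || n_per_group < 2 || n_signature < 1) {
    stop_param("n_datasets, n_genes, n_signature must be >= 1 and n_per_group >= 2")
  }
  if (deg_fraction <= 0 || deg_fraction >= 1 || round(deg_fraction * n_genes) < 1) {
    stop_param("deg_fraction must be in (0,1) and deg_fraction * n_genes >= 1")
  }
  if (noise_sd <= 0 || platform_sd < 0 || infiltration_coupling < 0) {
    stop_param("noise_sd must be > 0; platform_sd and infiltration_coupling >= 0")
  }
  if (n_signature + round(deg_fraction * n_genes) > n_genes) {
    stop_param("n_signature plus planted DEGs exceed n_genes")
  }
  structure(list(n_datasets = as.integer(n_datasets), n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group), deg_fraction = deg_fraction,
                 lfc_mean = lfc_mean, deg_direction = deg_direction,
                 platform_sd = platform_sd, noise_sd = noise_sd,
                 infiltration_coupling = infiltration_coupling,
                 n_signature = as.integer(n_signature),
                 groups = as.character(groups), exponentiate = exponentiate,
                 seed = as.integer(seed)),
            class = "expression_sim_params")
}

#' Simulate multi-platform expression datasets with planted truth
#'
#' @param params an [expression_sim_params()].
#' @return list with `datasets` (list of [expression_dataset()]) and `truth`:
#'   `deg` (data.table gene / direction / lfc, identical across datasets),
#'   `signature_genes`, and per-dataset latent `factor` values per sample.
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  with_rng_seed(params$seed, {
    genes <- sprintf("G%04d", seq_len(params$n_genes))
    n_deg <- round(params$deg_fraction * params$n_genes)
    deg_genes <- sample(genes, n_deg)
    dir_sign <- switch(params$deg_direction,
                       both = sample(c(-1, 1), n_deg, replace = TRUE),
                       up = rep(1, n_deg),
                       down = rep(-1, n_deg))
    lfc <- dir_sign * params$lfc_mean
    sig_genes <- sample(setdiff(genes, deg_genes), params$n_signature)
    baseline <- stats::setNames(stats::rnorm(params$n_genes, 8, 2), genes)
    gene_lfc <- stats::setNames(numeric(params$n_genes), genes)
    gene_lfc[deg_genes] <- lfc
    sig_mask <- as.numeric(genes %in% sig_genes)
    n_s <- 2L * params$n_per_group
    group_lab <- factor(rep(params$groups, each = params$n_per_group),
                        levels = params$groups)
    datasets <- vector("list", params$n_datasets)
    factors <- vector("list", params$n_datasets)
    for (d in seq_len(params$n_datasets)) {
      did <- sprintf("D%d", d)
      platform <- stats::rnorm(params$n_genes, 0, params$platform_sd)
      fac <- stats::rnorm(n_s)
      case <- as.numeric(group_lab == params$groups[2])
      m <- baseline + platform +
        outer(gene_lfc, case) +
        params$infiltration_coupling * outer(sig_mask, fac) +
        matrix(stats::rnorm(params$n_genes * n_s, 0, params$noise_sd),
               params$n_genes, n_s)
      rownames(m) <- genes
      colnames(m) <- sprintf("%s_S%02d", did, seq_len(n_s))
      if (params$exponentiate) m <- 2^m - 1
      datasets[[d]] <- expression_dataset(m, group_lab, did,
                                          log_scale = !params$exponentiate)
      factors[[d]] <- stats::setNames(fac, colnames(m))
    }
    names(datasets) <- names(factors) <- sprintf("D%d", seq_len(params$n_datasets))
    truth <- list(
      deg = data.table::data.table(gene = deg_genes,
                                   direction = ifelse(dir_sign > 0, "up", "down"),
                                   lfc = lfc),
      signature_genes = sig_genes,
      factor = factors
    )
    list(datasets = datasets, truth = truth)
  })
}
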