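# Paired-tissue repertoire simulator.
#
# World model: each patient carries, per tissue, a universe of n_clonotypes
# CDR3 clonotypes. For every tissue pair a planted fraction of clonotypes is
# shared (same CDR3 in both universes); the rest are private. Clone-size
# weights come from a discrete power law over sizes (P(s) ~ s^-alpha),
# assigned independently per tissue, and `depth` reads are drawn
# multinomially — so finite sequencing depth censors rare clonotypes
# exactly as it does in real repertoire sequencing.

#' Parameters for the paired-tissue repertoire simulator
#'
#' @param n_patients number of patients; each gets one sample per tissue.
#' @param tissues ordered character vector of tissue labels.
#' @param depth reads sampled per repertoire.
#' @param n_clonotypes clonotype universe size per tissue.
#' @param powerlaw_alpha exponent (> 1) of the discrete power law over clone
#'   sizes; scalar or named per tissue. Smaller alpha = heavier tail = more
#'   clonal expansion; very large alpha approaches a uniform repertoire.
#' @param sharing symmetric matrix (tissues x tissues, unit diagonal) of
#'   target pairwise clonotype-sharing fractions in \[0, 1\] (shared count /
#'   universe size).
#' @param vj_profile per-tissue V-J usage profile: named list of data.frames
#'   with columns `v`, `j`, `prob` (rows summing to 1). `NULL` generates
#'   mildly tissue-specific default profiles over 12 TRBV x 6 TRBJ genes.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return class `repertoire_sim_params` list.
#' @export
repertoire_sim_params <- function(n_patients = 4, tissues = c("EAT", "SAT", "HEART"),
                                  depth = 20000, n_clonotypes = 2000,
                                  powerlaw_alpha = 2, sharing = NULL,
                                  vj_profile = NULL, seed = 1) {
  if (n_patients < 1 || n_clonotypes < 1 || depth < 1) {
    stop_param("n_patients, depth and n_clonotypes must be positive")
  }
  tissues <- as.character(tissues)
  if (length(tissues) < 1 || anyDuplicated(tissues)) {
    stop_param("tissues must be a non-empty vector of unique labels")
  }
  if (length(powerlaw_alpha) == 1L && is.null(names(powerlaw_alpha))) {
    powerlaw_alpha <- stats::setNames(rep(powerlaw_alpha, length(tissues)), tissues)
  }
  if (!all(tissues %in% names(powerlaw_alpha)) || any(powerlaw_alpha <= 1)) {
    stop_param("powerlaw_alpha must be > 1 and named for every tissue")
  }
  nt <- length(tissues)
  if (is.null(sharing)) sharing <- diag(nt)
  sharing <- as.matrix(sharing)
  dimnames(sharing) <- list(tissues, tissues)
  if (!isTRUE(all.equal(sharing, t(sharing))) || any(diag(sharing) != 1) ||
      any(sharing < 0) || any(sharing > 1)) {
    stop_param("sharing must be symmetric with unit diagonal and entries in [0, 1]")
  }
  # Feasibility: pairwise shared blocks for tissue i are disjoint subsets of
  # its universe, so their counts must fit inside n_clonotypes.
  off <- sharing; diag(off) <- 0
  if (any(rowSums(round(off * n_clonotypes)) > n_clonotypes)) {
    stop_param("sharing targets jointly infeasible: requested shared counts ",
               "exceed n_clonotypes for at least one tissue")
  }
  if (is.null(vj_profile)) vj_profile <- default_vj_profiles(tissues, seed)
  for (tt in tissues) {
    pr <- vj_profile[[tt]]
    if (is.null(pr) || !all(c("v", "j", "prob") %in% names(pr)) ||
        abs(sum(pr$prob) - 1) > 1e-9) {
      stop_param("vj_profile for tissue ", tt,
                 " must have columns v, j, prob with prob summing to 1")
    }
  }
  structure(list(n_patients = as.integer(n_patients), tissues = tissues,
                 depth = as.integer(depth), n_clonotypes = as.integer(n_clonotypes),
                 powerlaw_alpha = powerlaw_alpha, sharing = sharing,
                 vj_profile = vj_profile, seed = as.integer(seed)),
            class = "repertoire_sim_params")
}

# Mildly tissue-specific V-J profiles: a shared Dirichlet-like base with a
# per-tissue multiplicative tilt, deterministic given the seed.
default_vj_profiles <- function(tissues, seed) {
  with_rng_seed(seed + 7L, {
    v_genes <- sprintf("TRBV%d", 1:12)
    j_genes <- sprintf("TRBJ%d-%d", rep(1:2, each = 3), rep(1:3, 2))
    combos <- expand.grid(v = v_genes, j = j_genes, stringsAsFactors = FALSE)
    base <- stats::rgamma(nrow(combos), shape = 1.5)
    out <- lapply(tissues, function(tt) {
      tilt <- exp(stats::rnorm(nrow(combos), sd = 0.5))
      w <- base * tilt
      data.frame(v = combos$v, j = combos$j, prob = w / sum(w),
                 stringsAsFactors = FALSE)
    })
    stats::setNames(out, tissues)
  })
}

random_cdr3 <- function(n) {
  len <- sample(8:20, n, replace = TRUE)
  inner <- vapply(len, function(l) {
    paste(sample(AA_ALPHABET, l - 2L, replace = TRUE), collapse = "")
  }, "")
  paste0("C", inner, "F")  # canonical CDR3 framing residues
}

# Draw a unique CDR3 pool of size n (collisions at length 8-20 are
# astronomically rare; dedupe defensively anyway).
cdr3_pool <- function(n) {
  pool <- unique(random_cdr3(n))
  while (length(pool) < n) pool <- unique(c(pool, random_cdr3(n - length(pool))))
  pool
}

# Clone-size weights: latent sizes drawn from a discrete power law
# P(s) proportional to s^-alpha over s = 1..size_max, normalized to weights.
# Smaller alpha = heavier tail = stronger clonal expansion; large alpha
# degenerates to near-uniform (all sizes 1).
powerlaw_clone_weights <- function(n, alpha, size_max = 1e5L) {
  probs <- (seq_len(size_max))^(-alpha)
  sizes <- sample.int(size_max, n, replace = TRUE, prob = probs)
  sizes / sum(sizes)
}

#' Simulate paired-tissue repertoires with known ground truth
#'
#' See [repertoire_sim_params()] for the generative model. Shared clonotype
#' blocks are planted per patient and tissue pair at the CDR3 (clonotype)
#' level; Zipf rank weights are assigned independently per tissue, so a
#' shared clonotype can be expanded in one tissue and rare in the other.
#'
#' @param params a [repertoire_sim_params()].
#' @return list with `set` (a [repertoire_set()]; sample ids are
#'   `<patient>_<tissue>`) and `truth` (params plus, per patient, the planted
#'   shared CDR3 sets per tissue pair and per-tissue clonotype weights).
#' @export
simulate_repertoires <- function(params) {
  stopifnot(inherits(params, "repertoire_sim_params"))
  with_rng_seed(params$seed, {
    tissues <- params$tissues
    nt <- length(tissues)
    nc <- params$n_clonotypes
    pairs <- if (nt > 1) utils::combn(tissues, 2, simplify = FALSE) else list()
    reps <- list()
    truth_patients <- list()
    for (p in seq_len(params$n_patients)) {
      pid <- sprintf("P%02d", p)
      # planted shared blocks, disjoint within each tissue's universe
      shared_sets <- list()
      universes <- stats::setNames(rep(list(character(0)), nt), tissues)
      for (pr in pairs) {
        # binomial draw: realized shared fraction has the target as its mean
        n_shared <- stats::rbinom(1, nc, params$sharing[pr[1], pr[2]])
        if (n_shared > 0) {
          cds <- cdr3_pool(n_shared)
          shared_sets[[paste(pr, collapse = ":")]] <- cds
          universes[[pr[1]]] <- c(universes[[pr[1]]], cds)
          universes[[pr[2]]] <- c(universes[[pr[2]]], cds)
        } else {
          shared_sets[[paste(pr, collapse = ":")]] <- character(0)
        }
      }
      weights <- list()
      for (tt in tissues) {
        n_private <- nc - length(universes[[tt]])
        if (n_private < 0) {
          stop_param("sharing targets jointly infeasible for tissue ", tt,
                     ": planted shared clonotypes exceed n_clonotypes")
        }
        universes[[tt]] <- c(universes[[tt]], cdr3_pool(n_private))
        prof <- params$vj_profile[[tt]]
        vj_idx <- sample.int(nrow(prof), nc, replace = TRUE, prob = prof$prob)
        d_call <- sample(c("TRBD1", "TRBD2", ""), nc, replace = TRUE,
                         prob = c(0.4, 0.4, 0.2))
        w <- powerlaw_clone_weights(nc, params$powerlaw_alpha[[tt]])
        counts <- as.vector(stats::rmultinom(1, params$depth, w))
        keep <- counts > 0
        rec <- data.table::data.table(
          cdr3_aa = universes[[tt]][keep],
          v_call = prof$v[vj_idx][keep],
          d_call = d_call[keep],
          j_call = prof$j[vj_idx][keep],
          read_count = counts[keep]
        )
        sid <- paste(pid, tt, sep = "_")
        reps[[sid]] <- repertoire(rec, sid, pid, tt)
        weights[[tt]] <- stats::setNames(w, universes[[tt]])
      }
      truth_patients[[pid]] <- list(shared = shared_sets, weights = weights)
    }
    list(set = repertoire_set(unname(reps)),
         truth = list(params = params[setdiff(names(params), "vj_profile")],
                      patients = truth_patients))
  })
}
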