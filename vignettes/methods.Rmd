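---
title: "Methods: paired-tissue repertoire statistics, consensus DEGs and GEP scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-tissue repertoire statistics, consensus DEGs and GEP scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented by
`eatimmune`, the assumptions behind them, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
the numerical decisions a maintainer should know about. It states no
empirical result that the test suite does not itself compute.

## 1. Repertoire model

A *clonotype* is identified by its CDR3 amino-acid sequence alone; a
*clone* by the full (CDR3, V, D, J) combination. Raw tables may repeat
either key; `aggregate_repertoire()` deduplicates on demand, so clone keys
are always at least as numerous as clonotype keys.

**Frequencies** are read counts divided by the sample's total reads (the
MiXCR `cloneFraction` convention), not by the number of distinct
clonotypes. All bin-mass, top-N, sharing-correlation and V–J statistics are
therefore read-mass-weighted by default.

**Non-productive sequences.** CDR3s containing `*` (stop) or `_`
(frameshift) are retained and flagged; `filter_productive()` (CLI
`--productive-only`) drops them. No singleton filtering is applied by
default; `filter_min_count()` (CLI `--min-count`) exposes a threshold,
because whether singletons were removed upstream is usually unknowable
from a clonotype table alone.

**Gene calls** are allele-stripped (`TRBV5-1*01` → `TRBV5-1`) before any
V–J analysis, so usage is at gene level; empty `d_call` (TRBD is frequently
unresolvable) is a legitimate literal key component of a clone.

## 2. Repertoire statistics

*Expansion.* For thresholds t the bin statistic sums the read-frequency
mass of clonotypes with frequency **strictly** greater than t (the "> 0.1%"
reading). Mass, not clonotype-count fraction, is the default because the
quantity of interest is how much of the repertoire is held by expanded
clonotypes; `bin_mode = "count"` computes the count fraction instead, and
both modes are tested. Top-N ties are broken by descending count then
lexicographic CDR3, making the statistic deterministic.

*Sharing.* The shared set is the intersection of CDR3 key sets. The
frequency correlation defaults to shared clonotypes only: including
non-shared clonotypes as zeros turns the correlation into a sharing
statistic rather than a frequency-agreement statistic. The union-with-zeros
variant is available (`corr_mode = "union-zeros"`) since the choice is a
genuine analytical fork. With fewer than 3 shared clonotypes the
correlation is reported as `NA` and flagged undefined — never coerced to 0,
which would silently fabricate "no correlation".

*V–J usage.* Usage matrices are read-frequency weighted (clonotype-count
weighting available). The pairwise usage correlation first filters to
combinations whose **mean usage over a reference sample group** exceeds
`min_avg_usage` (default 0.01), mirroring the practice of conditioning on
combinations that are non-trivially used in a reference tissue such as
heart; the retained combination list is part of the output so the filter is
auditable.

*Group comparison.* Mann–Whitney uses the exact null when the combined
sample size is ≤ 20 and tie-free, else the tie-corrected normal
approximation; Welch's t and the paired Wilcoxon test are also exposed.
Degenerate inputs (all-zero paired differences; two identical constant
groups) return p = 1 with a flag rather than `NaN`.

## 3. Consensus differential expression

**Preprocessing** is `log2(x + 1)` (when the input is not already on log
scale) followed by quantile normalization: each sample's k-th order
statistic is replaced by the across-sample mean of k-th order statistics;
tied values receive the mean of the target values at their tied positions
(verified against `limma::normalizeQuantiles` in the tests). Duplicate
symbols collapse to the row with maximum mean expression.

**Ranking.** Per gene: `log2fc = mean(case) − mean(control)`, two-sided
Welch's t, BH adjustment. The package deliberately does **not** reimplement
moderated (empirical-Bayes) t statistics: the aggregation step consumes
only ranks, the validation surface is simulation-based recovery, and the
ranking function is pluggable if a moderated ranking is wanted. The
direction-specific orderings (`rank_up`, `rank_down`) sort by the
**one-sided** Welch p ascending — a two-sided p cannot favor a direction,
and the one-sided p is its signed counterpart — with ties broken by
|log2fc| descending then symbol. Genes with zero variance in both groups
get p = 1 (flagged via a message), keeping them rankable.

**Robust Rank Aggregation.** With normalized ranks r (missing from a list
= 1, the conservative convention), the score is
`rho = min_k pbeta(r_(k), k, m − k + 1)`, i.e. the smallest tail
probability that at least k of m uniform ranks would be as extreme, and
`score_adj = min(1, m · rho)` Bonferroni-corrects the minimum over k. The
implementation is checked against a Monte-Carlo oracle (10^5 uniform
rank-vector draws) and a closed-form example. Up and down aggregations run
separately, matching separate up-/down-regulated consensus lists. The
threshold defaults to the corrected score (`use_adjusted_score = TRUE`); a
flag thresholds raw rho instead, since published "RRA score" usage is
ambiguous between the two. No additional BH pass across genes is applied by
default because the score itself is thresholded directly at 0.05.

**DEG call.** Direction d is called when `score < 0.05` AND at least one
dataset has `p_adj < 0.05` with a fold change of ≥ 0.5 in direction d. The
consistency fraction — called genes whose fold-change sign agrees across
all datasets where observed — is reported alongside.

## 4. GEP scoring

Each available signature gene is z-scored across samples; the score is the
(weighted) mean of z-scores. Published T cell-inflamed GEP formulations are
weighted sums with proprietary-ish weights; because downstream use here is
comparative (two-group tests, correlations), which is invariant to affine
rescaling of the score, the default is the unweighted mean and a weights
column is accepted when available. Zero-variance genes are dropped with a
message rather than erroring (synthetic nulls produce them); coverage below
`min_coverage` errors naming the missing genes. Correlating a signature
member with the score is partially circular and the output flags it.

## 5. The synthetic world

`simulate_repertoires()` generates, per patient and tissue, a universe of
`n_clonotypes` CDR3 strings (length 8–20, canonical C…F framing); for each
tissue pair a Binomial(n_clonotypes, target) number of clonotypes is shared
between the two universes, so the planted sharing fraction has the target
as its expectation. Clone-size weights are drawn from a discrete power law
over sizes, P(s) ∝ s^−alpha: smaller alpha gives a heavier tail and
stronger clonal expansion, and large alpha degenerates to a near-uniform
repertoire. (A rank-based Zipf law was considered, but its expansion knob
runs in the opposite direction to the package's stated
smaller-alpha-more-expanded convention; the size law keeps one knob with
the intended monotonicity.) Reads are drawn multinomially at the given
depth.

Defaults encode the qualitative paired-tissue findings the package is
designed to detect: EAT more expanded than SAT (alpha 1.6 vs 2.2, heart
1.8 — chosen as plausibly heavy-tailed repertoires with a clear but not
caricatured contrast), EAT–heart sharing 0.30 vs SAT–heart 0.05, depth
20000 and 2000 clonotypes per sample (desk-scale stand-ins for bulk TCR-seq
depth).

Two things the generator deliberately does **not** emulate: sequencing
error/PCR bias (no read-level simulation), and the detection process's
effect on sharing — finite depth censors rare clonotypes, so *observed*
sharing sits systematically below the planted target (roughly by the
partner repertoire's detection probability). Tests of the sharing target
therefore measure the planted truth record; tests of observed quantities
only assert the planted *ordering* (EAT–heart above SAT–heart), which
survives censoring. A green test establishes that the pipeline recovers
planted structure under these idealized conditions — not that any
particular tissue pair in real data behaves this way.

`simulate_expression()` generates per-dataset matrices on an additive
log2-like scale: gene baseline N(8, 2), per-gene platform shift
N(0, platform_sd), a planted log2 fold change of fixed magnitude
`lfc_mean` on a `deg_fraction` of genes (consistent direction across
datasets), a latent per-sample N(0,1) infiltration factor loading with
coefficient `infiltration_coupling` on `n_signature` designated non-DEG
genes, and N(0, noise_sd) noise. Because the scale is already log2-like,
the preprocessing log step is the identity for synthetic input;
`exponentiate = TRUE` emits `2^x − 1` to exercise the transform path. The
`n_signature` field is this package's addition: something must designate
which genes carry the latent factor, and keeping them disjoint from DEGs
keeps factor recovery and DEG recovery orthogonal.

## 6. Numerical choices and degenerate inputs

- Frequency sums are validated to 1 within 1e-9 at every aggregation level.
- Thresholds use strict `>`; threshold parameters are validated to (0, 1).
- Spearman p-values use the asymptotic approximation (`exact = FALSE`)
  uniformly, since usage vectors and shared-frequency vectors routinely
  contain ties.
- Constant vectors anywhere in a correlation yield `NA` + an `undefined`
  flag, not an error or a silent 0.
- All simulation randomness flows through a single per-call seed; RNG state
  is saved and restored, so library calls never perturb the caller's
  stream. Rerunning any CLI subcommand with the same config and seed
  produces byte-identical outputs.
- Config is YAML; flags override file values; every run writes
  `config_resolved.yaml` and `run_manifest.json` beside its outputs.

## 7. Known limitations

- Welch's t is a stand-in for moderated statistics; at very small n per
  group its ranks are noisier than limma's would be.
- The RRA score is per-gene; with very many genes the 0.05 score threshold
  is not a genome-wide error rate (an optional BH pass over scores exists
  but is off by default).
- Pairwise sharing is planted independently per tissue pair; triple-wise
  overlap structure (clonotypes shared by all three tissues beyond chance)
  is not modeled.
- The GEP score treats signature genes as exchangeable; no gene-specific
  calibration is attempted.
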