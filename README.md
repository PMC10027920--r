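# eatimmune

Quantitative analysis of T-cell immunity in paired tissues — built around the
comparison of epicardial adipose tissue (EAT) with subcutaneous adipose tissue
(SAT) and heart in heart-failure patients, but applicable to any paired-tissue
design. The package bundles three analysis families plus a synthetic-data
generator with known ground truth, so every statistic can be validated without
any external download:

1. **TCR repertoire statistics.** Clonotype tables (AIRR Rearrangement TSV or
   MiXCR clone exports) are summarized per sample and per tissue pair:
   - *Clonal expansion*: clone vs clonotype counts (a clonotype is a unique
     CDR3 amino-acid sequence; a clone a unique CDR3+V+D+J combination),
     frequency-bin mass (repertoire fraction held by clonotypes with
     frequency > 0.1%, > 0.5%, > 1%), and the proportion of the top-N
     clonotypes.
   - *Cross-tissue sharing*: shared clonotype counts, per-repertoire sharing
     fractions, Jaccard index, and Spearman correlation of shared-clonotype
     frequencies.
   - *V–J usage*: read-mass distribution over (TRBV, TRBJ) gene combinations
     and pairwise Spearman correlation of usage vectors after filtering to
     combinations with mean usage above a threshold in a reference tissue.
2. **Consensus differential expression.** Per-dataset two-group ranking
   (Welch's t on log2 / quantile-normalized matrices, Benjamini–Hochberg
   adjustment), cross-dataset aggregation by **Robust Rank Aggregation**:
   for normalized ranks r_(1) ≤ … ≤ r_(m) of a gene across m datasets,

       rho = min_k P(Beta(k, m − k + 1) ≤ r_(k)),   score = min(1, m · rho)

   and a DEG call that requires the RRA score < 0.05 **and** adjusted
   p < 0.05 with |log2FC| ≥ 0.5 in at least one dataset, with
   direction-consistency accounting.
3. **T cell-inflamed GEP scoring.** Per-sample signature score as the
   (weighted) mean of z-scored signature-gene expressions, score–gene
   correlations, and Mann–Whitney group comparison.

## Worked example

Simulate two patients with three tissues each, planting stronger clonal
expansion in EAT (power-law exponent 1.6 vs 2.2 for SAT) and stronger
EAT–heart clonotype sharing (target 0.30 vs 0.05 for SAT–heart):

```r
library(eatimmune)
sharing <- matrix(c(1, .05, .30,  .05, 1, .05,  .30, .05, 1), 3, 3)
params <- repertoire_sim_params(
  n_patients = 2, tissues = c("EAT", "SAT", "HEART"), depth = 20000,
  n_clonotypes = 2000, powerlaw_alpha = c(EAT = 1.6, SAT = 2.2, HEART = 1.8),
  sharing = sharing, seed = 42)
sim <- simulate_repertoires(params)

expansion_summary(sim$set$repertoires[["P01_EAT"]])$bin_fractions
#> 0.924 0.844 0.814            # EAT: >81% of reads in clonotypes above 1%
expansion_summary(sim$set$repertoires[["P01_SAT"]])$bin_fractions
#> 0.702 0.563 0.529            # SAT is visibly less expanded

sharing_summary(sim$set$repertoires[["P01_EAT"]],
                sim$set$repertoires[["P01_HEART"]])$jaccard   #> 0.064
sharing_summary(sim$set$repertoires[["P01_SAT"]],
                sim$set$repertoires[["P01_HEART"]])$jaccard   #> 0.010
```

The planted EAT-vs-SAT contrasts come back: EAT holds more repertoire mass in
high-frequency clonotypes (top-10 proportion 0.745 vs 0.563) and shares ~6x
more clonotypes with the heart. (Observed Jaccard sits below the planted
target because finite depth censors rare clonotypes — see the vignette.)

Consensus DEGs and GEP scoring on simulated two-platform expression data:

```r
es <- simulate_expression(expression_sim_params(
  n_datasets = 2, n_genes = 1000, n_per_group = 20, deg_fraction = 0.1,
  lfc_mean = 1.5, noise_sd = 0.5, infiltration_coupling = 1, seed = 7))
degs <- call_degs(lapply(es$datasets, rank_genes))
called <- degs[degs$passed_filters]
nrow(called)                             #> 100 (52 up, 48 down)
attr(degs, "consistency_fraction")       #> 1
# perfect recovery of the 100 planted DEGs at these settings:
length(intersect(called$gene, es$truth$deg$gene))  #> 100

sc <- gep_score(es$datasets[[1]], gene_signature(es$truth$signature_genes))
cor(sc$score, es$truth$factor[[1]])      #> 0.996  (latent infiltration factor)
score_group_compare(sc)$p                #> 0.797  (no planted group shift)
```

## Command line

`inst/cli/eatimmune` (or `eat_cli()` from R) provides subcommands
`simulate`, `repstats`, `metadeg`, `gep` and `demo` (end-to-end synthetic
run). Configuration is YAML with flag overrides; defaults: frequency-bin
thresholds 0.001/0.005/0.01, top_n 10, min average V–J usage 0.01, RRA score
cut 0.05, adjusted-p cut 0.05, |log2FC| cut 0.5. Every run writes the
resolved config and a run manifest next to its outputs. Exit codes: 0 ok,
1 data error, 2 parameter error.

```sh
Rscript inst/cli/eatimmune demo --out demo_run --seed 1
```

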