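# ctapr — cell-type abundance phenotypes for single-cell cohorts

Inflamed tissues differ dramatically between patients in *which* cell
lineages dominate them. `ctapr` implements the analysis framework built
around that observation for multi-sample single-cell studies (the motivating
application is rheumatoid arthritis synovium): it stratifies samples into
**cell-type abundance phenotypes (CTAPs)** from the proportions of the six
major lineages — T, B/plasma, NK, myeloid, stromal and endothelial cells —
and then asks which fine-grained cell neighbourhoods, cytokine programs,
risk genes and clinical outcomes track those phenotypes.

## What the package computes

* **Stratification** (`compute_composition`, `cluster_samples`,
  `name_ctaps`, `project_samples`, `composition_pca`,
  `cytokine_categorize`). Per-sample lineage proportions
  `p_{s,t} = n_{s,t} / n_s` are clustered with Ward linkage on Euclidean
  distance; the number of clusters `k` maximizes bootstrap stability (mean
  adjusted Rand index between the reference partition and re-clustered
  bootstrap cohorts), subject to a minimum cluster size. Clusters are named
  by their enriched lineages via z-scores
  `z_t = (mean_cluster p_t − mean p_t) / sd p_t` (letters E, F, M, T, B).
* **Neighbourhood association** (`build_graph`, `compute_nam`,
  `associate`, `summarize_by_state`). A CNA-style test: the
  samples × cells neighbourhood abundance matrix `NAM = D W^s` (D the
  per-sample cell-membership distribution, W the row-stochastic kNN
  transition matrix) is residualized on covariates, decomposed by PCA, and
  the phenotype's max-R² over leading components is tested with a
  Westfall–Young permutation p. Per-cell correlations get an
  empirical-null FDR mask.
* **Cross-platform transfer** (`flow_nn_classify`, `derive_signatures`,
  `bulk_deconvolve`, `bulk_classify`, `transition_summary`). A
  nearest-neighbour classifier for flow-style compositions, NNLS
  deconvolution of bulk RNA-seq on single-cell signature profiles followed
  by centroid assignment, and baseline/follow-up CTAP transition
  arithmetic.
* **Downstream statistics** (`variance_explained`,
  `proportion_correlation`, `filter_low_count_genes`,
  `gene_score_correlation`, `risk_gene_enrichment_count`,
  `response_association`, `paired_stability_test`).
* **Synthetic cohorts** (`default_sim_config`, `generate_cohort`,
  `mix_pseudobulk`, `simulate_flow_panel`, `write_cohort`/`read_cohort`).
  A generative model — Dirichlet lineage compositions per latent phenotype,
  multinomial cells, within-lineage state mixtures, negative-binomial
  counts with planted markers, Gaussian embeddings — that makes every stage
  of the pipeline testable offline.

## Worked example

```r
library(ctapr)

cfg    <- default_sim_config(seed = 7)       # 80 samples, 6 phenotypes
cohort <- generate_cohort(cfg, counts = FALSE)
comp   <- compute_composition(cohort$cell_table)
model  <- cluster_samples(comp, seed = 3)
model
#> ctap_model: k = 6 ( M, EFM, TF, F, TB, TM )
#> stability profile:
#>     2     3     4     5     6     7     8
#> 0.537 0.661 0.862 0.832 0.978 0.916 0.878
#> cluster sizes: 13, 14, 13, 14, 13, 13
adjusted_rand_index(model$labels, cohort$truth$phenotype[rownames(comp)])
#> [1] 1
```

The stability profile peaks at `k = 6` (0.978): six composition phenotypes
are the most reproducible partition under cohort bootstrap, and the labels
recover the generator's planted phenotypes exactly (adjusted Rand index 1).
Neighbourhood association on the same cohort's T cells (`associate` with
age, sex and log cell count as covariates, TB vs rest) reports a global
permutation p < 0.01 and flags ~60% of the peripheral-helper-like T cells
— the state the generator expands two-fold in the TB phenotype — in the
positive FDR < 0.05 mask.

## Command line

```sh
Rscript inst/cli/ctap.R simulate --out DIR --seed 7
Rscript inst/cli/ctap.R stratify --cells DIR/cells.tsv --k-range 2:8 --boot 200 --seed 7 --out DIR
Rscript inst/cli/ctap.R validate --cells DIR/cells.tsv
Rscript inst/cli/ctap.R pipeline --out DIR --seed 7
```

See `vignettes/ctap-methods.Rmd` for the model, parameter choices, and
what the synthetic world does and does not establish.
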