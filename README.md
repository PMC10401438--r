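# hoxsig

Consensus subtyping of pediatric gliomas from HOX family gene expression,
and derivation of a nearest-centroid prognostic risk classifier.

## What this package does

Deregulated HOX transcription-factor expression is a recurrent feature of
pediatric brain tumors. `hoxsig` implements an analysis pipeline that

1. **discovers expression subtypes** by resampling consensus clustering of
   samples on the 39 HOX family genes (HOXA/B/C/D clusters), choosing the
   number of clusters k by the proportion of ambiguous clustering (PAC)
   with CDF delta-area curves for inspection;
2. **screens differentially expressed genes (DEGs)** between the two
   subtypes (Welch t-test; screen: p < 0.01 and |log2 FC| > 1);
3. **derives a compact risk signature**: iterative random-forest
   elimination (1000 trees, permutation importance, discarding the least
   important third of genes per round) reduces the DEGs to 9 candidates;
   all 2^9 − 1 = 511 nonempty subsets are fitted as two-centroid
   classifiers and the smallest subset within 0.01 AUC of the best is
   selected;
4. **classifies patients by Euclidean distance.** With centroids CD₁
   (low-risk, the good-prognosis mean profile) and CD₂ (high-risk), sample
   *i* with signature expression Exp^i is assigned by

   Dic_{i,g} = sqrt( Σ_j (Exp_j^i − CD_{g,j})² ),  g ∈ {1, 2}

   low-risk iff Dic_{i,1} < Dic_{i,2}, high-risk otherwise (ties high);
   the continuous risk score is Dic_{i,1} − Dic_{i,2};
5. **evaluates prognosis**: Kaplan–Meier curves, log-rank tests, Cox
   proportional-hazards models (Efron ties), ROC/AUC, Wilcoxon and
   chi-square comparisons, CNV gain/loss calls (segment mean = log2(cn/2);
   gain > 0.2, loss < −0.2) and mutation-count comparisons.

Because the patient cohorts this style of analysis is run on are
access-restricted, the package ships a **synthetic cohort generator** with
known ground truth (planted subtypes, DE genes, hazard ratio, batch
effects, mutation rates), so every stage is testable end to end by
parameter recovery. The published five-gene signature (HOXA6, HOXC4,
HOXC5, HOXC6, HOXA-AS3, with its printed centroids) is included as a
ready-to-apply classifier.

## Worked example

Full pipeline on a simulated 300-patient cohort:

```r
library(hoxsig)
spec <- cohort_spec(n_samples = 300, seed = 20)   # 2000 genes, 1000 planted DEGs, HR 2
res  <- run_hox_pipeline(list(cohort = spec, n_iter = 500, seed = 20))
res
#> HOX subtype/signature pipeline (seed 20 )
#>   samples: 300  chosen k: 2  subtype I/II: 207 / 93
#>   DEGs: 1039  split: 200 train / 100 test
#>   signature: DE0322, DE0715
#>   AUC train 0.998 / test 0.968
```

The clustering recovers the two planted subtypes exactly (chosen k = 2;
the 207/93 split matches the simulated 70/30 prevalence), the DEG screen
finds the planted genes, and the selected two-gene signature separates the
held-out test split with AUC 0.968. `res$signature` prints the fitted
centroids, and `res$evaluation$train$logrank_p` gives the survival
separation of the predicted risk groups (0.0105 here).

Applying the published five-gene classifier to new expression profiles:

```r
sig <- published_classifier()
set.seed(1)
m <- cbind(P1 = sig$low_centroid  + rnorm(5, 0, 0.5),
           P2 = sig$high_centroid + rnorm(5, 0, 0.5),
           P3 = (sig$low_centroid + sig$high_centroid) / 2 + rnorm(5, 0, 0.5))
rownames(m) <- sig$genes
apply_published(m)
#>   sample_id   dic_low  dic_high risk      score
#> 1        P1 0.9718463 9.2953572  low -8.3235109
#> 2        P2 9.4366188 0.6856867 high  8.7509320
#> 3        P3 5.0157626 4.7767152 high  0.2390474
```

P1 sits near the low-risk centroid (distance 0.97 vs 9.30) and is called
low-risk; P3 is almost equidistant and falls to high-risk, the
conservative side of the rule.

## Package layout

- `cohort_spec()` / `generate_cohort()` / `generate_gene_sets()` — synthetic cohorts
- `read_expression()`, `batch_standardize()`, `split_cohort()`,
  `segment_mean()`, `call_cnv_state()`, `mutation_frequency()` — I/O and transforms
- `consensus_cluster()`, `pac_score()`, `cdf_delta_area()`, `select_k()`,
  `pca_project()` — subtype discovery
- `differential_expression()`, `deg_filter()` — DEG screen
- `pathway_activity_score()`, `compare_pathway_scores()` — single-sample pathway scores
- `km_estimate()`, `logrank_test()`, `cox_ph()`, `wilcoxon_rank_sum()`,
  `chi_square_test()`, `roc_auc()` — survival/statistics
- `derive_signature()` (returns a `centroid_signature` with `print`/`summary`/`predict`),
  `rf_iterative_elimination()`, `enumerate_subsets()`, `build_centroids()`,
  `classify_samples()`, `select_optimal_signature()`, `published_classifier()` — the classifier
- `run_hox_pipeline()`, `apply_published()` — orchestration

See `vignettes/hox-signature-methods.Rmd` for the statistical methods and
design choices.
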