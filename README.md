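# aqun

Cross-platform miRNA expression studies rarely share a probe set or an
intensity scale: cohorts measured on different array technologies disagree in
coverage, in dynamic range, and in systematic batch structure strong enough to
dominate sample-to-sample distances. `aqun` merges such cohorts into one joint
matrix and normalizes it with **adjusted quantile normalization (AQuN)**, a
quantile-normalization variant that tolerates partially overlapping probe
sets, then runs the nonparametric downstream battery such a joint analysis
calls for.

## The method

Let `M(i, j)` be the log2 intensity of miRNA *i* in sample *j* of the joint
matrix, with `NA` marking miRNAs never measured on sample *j*'s platform
(distinct from 0, which means probed but not detected). AQuN:

1. jitters `M` with Gaussian noise of scale ε to break rank ties,
2. assigns each non-missing entry the percentile grid point nearest to
   `100·(r − 0.5)/n_j`, where `r` is its rank among the sample's `n_j`
   non-missing values (uniform grid of `grid_size` points on 0..100,
   default 101),
3. replaces every entry by the median of all values in the matrix sharing
   its quantized percentile,
4. restores `NA` wherever the miRNA is missing from the platform.

Where vanilla quantile normalization pools values *rank-wise* and requires a
complete matrix, AQuN pools *percentile-bin-wise*, so samples with different
coverage remain comparable and within-bin measurement noise is averaged away.
Jitter only affects ranking; pooled medians use the original values, making
the output independent of the jitter seed whenever the data are tie-free.

Around the normalizer the package provides, each testable against a bundled
synthetic multi-batch generator with known ground truth:

- full-outer-join cohort merging with an explicit missing-from-platform mask,
  replicate collapse, minimum subtraction, alias renaming (`merge_cohorts`,
  `collapse_replicates`, `min_subtract`, `apply_alias_map`);
- comparison normalizations: vanilla quantile, mean-ratio, median-subtraction
  (`normalize_quantile`, `normalize_mean_ratio`,
  `normalize_median_subtract`);
- differential expression: log2 median fold change, directional Wilcoxon
  rank-sum tests, Benjamini–Hochberg Q-values, label-permutation nulls, and
  run-vs-run comparison tables (`de_table`, `permutation_null`,
  `compare_runs`);
- batch diagnostics: Euclidean sample distances, silhouette-by-dataset,
  batch-flagged dendrograms, cross-cohort rank reproducibility, and
  rank-distribution polygons (`batch_silhouette`, `rank_polygon`, ...);
- minimum-hypergeometric (mHG) target enrichment: Spearman anti-correlation
  gene rankings, the mHG statistic with an exact O(N·K) dynamic-programming
  p-value, and prefix-scan matching of predicted-target lists
  (`build_g_mu`, `mhg_statistic`, `mhg_pvalue`, `mitea_match`);
- a-priori power analysis for the one-tailed rank-sum test via the 3/π
  asymptotic-relative-efficiency adjustment of noncentral-t power, with a
  Monte-Carlo cross-check and a bilinear power surface (`wrs_power`,
  `power_surface`).

## Worked example

Simulate a three-cohort study (80 samples each, 20% of miRNAs missing per
platform, 30 miRNAs shifted between two groups at Cohen's d = 1), merge,
normalize, and test:

```r
library(aqun)

cfg  <- sim_config(seed = 42)
sim  <- simulate_joint(cfg)
joint <- merge_cohorts(sim$cohorts)
joint
#> joint_cohort: 299 features x 240 samples, 3 batches; 153 features covered by every batch

norm <- aqun_normalize(joint$values, joint$mask, seed = 42)
de   <- de_table(norm, sim$samples, "group", "g1", "g2")
head(de[order(de$q_value), ], 5)
#>  mirna_id fold_change  p_value  q_value    direction  n1  n2
#>   mir-198      -1.231 4.92e-15 1.47e-12 up_in_group2 120 120
#>   mir-100       0.927 5.43e-14 8.12e-12 up_in_group1 120 120
#>   mir-171       1.042 9.11e-14 9.08e-12 up_in_group1 120 120
#>   mir-292       0.864 6.03e-13 4.51e-11 up_in_group1 120 120
#>   mir-098      -1.061 1.42e-12 8.51e-11 up_in_group2 120 120
```

All five top calls are planted miRNAs; the fold changes recover the planted
±1 log2 shifts. The batch-effect diagnostic shows what normalization did:

```r
batch <- sim$samples$batch[match(colnames(norm), sim$samples$sample_id)]
mean(batch_silhouette(pairwise_distances(joint$values), batch))  # 0.301
mean(batch_silhouette(pairwise_distances(norm), batch))          # 0.001
```

Samples cluster strongly by dataset before normalization (mean silhouette
0.30) and not at all after (0.00).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/aqun.R simulate --out simdir/ --seed 3
Rscript inst/cli/aqun.R pipeline \
    --cohorts batchA=simdir/batchA.tsv,batchB=simdir/batchB.tsv,batchC=simdir/batchC.tsv \
    --meta simdir/meta.tsv --label group --levels g1,g2 --out run/
Rscript inst/cli/aqun.R power --d 0.5 --n1 50 --n2 50
```

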