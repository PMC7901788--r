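Package: aqun
Title: Adjusted Quantile Normalization for Cross-Platform miRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges miRNA expression cohorts measured on different platforms
    into one joint matrix with an explicit platform-coverage mask, and
    normalizes it by adjusted quantile normalization (AQuN): values are
    replaced by the cross-sample median of their per-sample percentile bin,
    which tolerates partially overlapping probe sets. Includes the downstream
    battery the method is designed for: one-tailed Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg correction and
    permutation-label nulls, batch-effect diagnostics (silhouette by dataset,
    pairwise distances, dendrogram colouring, cross-cohort rank
    reproducibility, rank-distribution polygons), minimum-hypergeometric
    (mHG) miRNA-target enrichment with an exact dynamic-programming p-value,
    a-priori power analysis for the rank-sum test, and a seeded multi-batch
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
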