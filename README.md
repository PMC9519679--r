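# svharvest

Structural-variant (SV) ensemble benchmarking, cross-sample clustering,
annotation, population genetics, expression association, and
kernel-based phenotype prediction — built for diversity panels of inbred
lines, and shipped with a synthetic-data generator so the entire
pipeline can be exercised end to end without any external data.

## The science

Short-read SV discovery is unreliable enough that no single caller is
trusted on its own: callers differ sharply in sensitivity and precision
across SV types (deletions, insertions, duplications, inversions,
translocations) and length scales. `svharvest` implements a complete
survey pipeline around that reality:

1. **Benchmarking** (`match_calls`, `benchmark_callers`). Calls are
   matched to a truth set one-to-one under breakpoint tolerances that
   scale with the SV length category (INDEL 2–49 bp, then A 50–300 bp,
   B 0.3–5 kb, C 5–50 kb, D 50–250 kb, E 0.25–1 Mb). Matching is greedy
   by breakpoint distance with an augmenting-path repair, so the
   reported true-positive count is provably the maximum-cardinality
   matching.
2. **Caller combination** (`select_best_combination`). Boolean
   expressions over callers (OR = union with deduplication, AND =
   agreement within tolerance) are searched with a two-step rule: all
   callers meeting a 95% precision floor in every length category are
   OR-ed; the remaining callers are AND-ed together and OR-ed in if the
   AND meets the floor. This yields combinations such as
   `Manta|GRIDSS|Pindel|Delly|(Lumpy&NGSEP)` that beat every single
   caller's sensitivity without giving up precision.
3. **Cross-sample merging** (`filter_sample_calls`, `cluster_svs`,
   `genotype_clusters`). Per-sample calls are filtered (homozygous-ref
   and failed-filter calls dropped, assembly-gap straddlers removed,
   a 1 Mb length cap), then clustered across samples with
   category-scaled gap and breakpoint tolerances against a running
   median representative. Clusters are genotyped by presence/absence
   per line, giving a minor allele frequency for every SV cluster.
4. **Annotation** (`classify_gene_association`, `annotate_te`,
   `detect_hotspots`). Clusters are labelled by gene context
   (exon/intron/5 kb up/downstream, strand-aware), transposable-element
   derivation (≥ 80% reciprocal overlap; breakpoint-containment rules
   for unresolved insertions and translocations), and hotspot status
   (1 Mb windows whose cluster count exceeds the Poisson 99th
   percentile of the chromosome's mean window count).
5. **Population genetics** (`ld_r2`, `pi_windows`). Squared-correlation
   LD between presence/absence genotypes and SNVs, and windowed
   nucleotide diversity π with the small-sample correction
   `n/(n-1) · 2p(1-p)`.
6. **Expression association** (`expression_pca`,
   `pc_correlation_permutation`, `pk_association`). Global tests of SV
   association with expression principal components by per-cluster
   permutation, and per-gene mixed-model tests with population-structure
   covariates and a kinship random effect (the "PK" model), fitted by
   exact one-dimensional REML on the spectral decomposition of the
   kinship.
7. **Prediction** (`adjusted_entry_means`, `build_G`, `gblup_predict`,
   `cross_validate`, `grid_search_weights`). Adjusted entry means from
   replicated multi-environment trials, VanRaden-style relationship
   matrices from any feature set (SNVs, SV presence, expression),
   GBLUP with REML variance components, weighted joining of three
   kernels on a 66-point weight grid, and replicated five-fold
   cross-validation summarised as the median of per-replicate medians.

A call-level simulator (`simulate_reference`, `simulate_truth_svs`,
`caller_profile`, `simulate_callset`, `simulate_cohort_omics`) generates
reference skeletons, truth sets with per-category mutation rates,
imperfect call sets with calibrated sensitivity/precision/jitter, and a
full 23-line cohort with genotypes, expression, and multi-environment
phenotypes — so every claim above is testable on a desktop.

## Worked example

```r
library(svharvest)

## 1. simulate a reference skeleton and a deletion truth set
ref <- simulate_reference(c(chr1 = 2e7), seed = 11)
truth <- simulate_truth_svs(ref, rates = c(A = 3e-6, B = 3e-6, C = 1e-6),
                            types = "DEL", sample_id = "line1", seed = 12)
nrow(truth)
#> [1] 134
table(classify_length_category(truth$length, truth$sv_type))
#>  A  B  C
#> 48 63 23

## 2. simulate three imperfect callers and benchmark them
profiles <- list(
  precise = caller_profile("precise", sensitivity = 0.75,
                           precision_target = 0.995),
  eager   = caller_profile("eager", sensitivity = 0.92,
                           precision_target = 0.80),
  noisy   = caller_profile("noisy", sensitivity = 0.88,
                           precision_target = 0.85))
callsets <- lapply(profiles, function(p) simulate_callset(truth, p, ref,
                                                          seed = 13))
bench <- benchmark_callers(callsets, truth, "DEL")
subset(bench, category == "A")
#>    caller sv_type category tp fp fn sensitivity precision        f1
#> 1 precise     DEL        A 37  0 11   0.7708333 1.0000000 0.8705882
#> 4   eager     DEL        A 46 14  2   0.9583333 0.7666667 0.8518519
#> 7   noisy     DEL        A 43  3  5   0.8958333 0.9347826 0.9148936

## 3. select the best caller combination under the 95% precision floor
sel <- select_best_combination(bench, callsets, truth, "DEL")
sel$label
#> [1] "precise|(eager&noisy)"
unlist(evaluate_combination(sel$expr, callsets, truth, "DEL"))
#> sensitivity   precision          f1          tp          fp          fn
#>   0.8805970   0.9915966   0.9328063 118.0000000   1.0000000  16.0000000

## 4. simulate a 23-line cohort, cluster SV across samples, genotype
coh <- suppressWarnings(simulate_cohort_omics(
  ref, cohort_spec(), rates = c(A = 2e-5), seed = 21))
pooled <- do.call(rbind, coh$sample_truth)
clustering <- cluster_svs(pooled)
geno <- genotype_clusters(clustering, names(coh$sample_truth))
nrow(clustering$clusters)
#> [1] 1597
round(mean(rowSums(geno$presence) == 1), 3)   # singleton share
#> [1] 0.606

## 5. population genetics on the presence/absence genotypes
pi <- pi_windows(clustering$clusters$start, rowSums(geno$presence),
                 n = 23, chrom_length = 2e7, window = 1e6)
round(range(pi$pi), 7)
#> [1] 1.17e-05 1.95e-05
ld_r2(geno$presence[1, ], geno$presence[2, ])
#> [1] 0.04166667

## 6. kinship + PK mixed-model association with expression (null example)
K <- compute_kinship(t(geno$presence))
set.seed(22)
expr_null <- rnorm(23)
fit <- pk_association(geno$presence[1, ], expr_null, K = K)
round(unlist(fit[c("beta_sv", "se", "p_value")]), 4)
#>    beta_sv      se.sv p_value.sv
#>     0.1975     0.4285     0.6497

## 7. genomic prediction from the SV kernel
y <- adjusted_entry_means(coh$phenotypes)[colnames(coh$presence)]
G <- build_G(t(coh$presence), label = "sv")
cv <- cross_validate(G, y, k = 5, n_rep = 20, seed = 23)
round(cv$ability, 3)
#> [1] 0.384
```

Note how the selected combination (`precise|(eager&noisy)`) reaches a
sensitivity of 0.881 — above every single caller's overall sensitivity —
while holding precision at 0.99: the intersection of the two imprecise
callers contributes their shared true positives but almost none of
their (independent) false positives.

## File formats

`write_sv_vcf`/`read_sv_vcf` round-trip per-sample calls as VCF 4.2
(translocations as paired `BND` records with `MATEID`);
`write_cluster_vcf` emits the multi-sample genotyped cluster set;
`read_bed`/`write_bed` and `read_genes_gff3` handle interval tracks and
gene models. A thin command-line wrapper around the main entry points
is installed at `inst/cli/svharvest.R`.

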