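# regcl

Information-dense transcription factor binding site (TFBS) clusters for
regulatory prediction.

## What it does, and for whom

Promoters integrate transcription factor (TF) input through the number,
strength and spatial organization of binding sites. `regcl` is for
regulatory genomicists who want to ask, quantitatively: does the
information-theoretic organization of TFBS clusters in an accessible
promoter predict (a) which genes share a tissue-wide expression profile and
(b) which genes are direct, differentially expressed targets of a TF — and
what happens to those predictions when individual sites are mutated?

The package implements the full pipeline:

1. **Site scoring.** Bit-valued position weight matrices (iPWMs) score each
   k-mer by its individual information
   *R<sub>i</sub>* = Σ<sub>j</sub> w<sub>j,b(j)</sub> (in bits).
   *R<sub>sequence</sub>*, the mean *R<sub>i</sub>* over a factor's bound
   sites (the area under the sequence logo), sets two thresholds: sites with
   *R<sub>i</sub>* ≥ 0.1·*R<sub>sequence</sub>* are retained by the scanner,
   and sites with *R<sub>i</sub>* > *R<sub>sequence</sub>* count as "strong".
   Scanning covers both strands and can be restricted to DNase I
   hypersensitive (accessible) promoter intervals.
2. **IDBC clustering.** Information density-based clustering seeds an
   interval of radius *d* (default 25 bp) around each site, merges
   transitively overlapping seeds, and emits groups whose summed
   *R<sub>i</sub>* reaches a threshold *I* (for a panel of matrices, the sum
   of their *R<sub>sequence</sub>* values; for a single matrix, its
   *R<sub>sequence</sub>*).
3. **Featurization.** Each cluster yields its distance to the TSS, length,
   information content, and per-TF site/strong-site counts and information
   sums; genes are padded with all-zero "null clusters" at the distal (5')
   end to a common width.
4. **Labeling.** Target genes are labeled from CRISPR guide-coefficient
   matrices (consistent-sign fold changes, mean fold change beyond a
   threshold ε, ChIP-seq peak in the 10 kb promoter) or siRNA knockdown
   p-values (p ≤ 0.01 plus peak support), with Bray-Curtis-based class
   balancing.
5. **Classification.** A CART decision tree (Gini, unpruned; the primary
   learner), plus naive Bayes, random forest and SVM alternates; 10 × 10-fold
   stratified cross-validation, ROC/AUC, Gini importances.
6. **Expression similarity.** Tissue-wide profiles (median RPKM over a
   53-tissue panel) are compared with the Bray-Curtis similarity

   sim(a, b) = 1 − Σ|aᵢ − bᵢ| / Σ(aᵢ + bᵢ),  with sim = 1 when both
   profiles are identically zero,

   used both to rank genes by profile similarity and to balance classes.
7. **In-silico mutagenesis.** Single-nucleotide variants are applied to a
   promoter, which is re-scanned, re-clustered, re-featurized and
   re-classified; every wild-type cluster is reported as *retained* or
   *abolished* and the classifier output before/after is returned.

A seeded synthetic-data module generates every input the pipeline consumes
(matrices of specified information content, promoters with planted site
clusters, DHS/peak intervals, block-structured expression, knockdown
matrices with planted targets), so the whole framework is testable end to
end without external data.

## Worked example

```r
library(regcl)

cfg   <- sim_config(seed = 1, n_genes = 200, epsilon = 1.1)
bench <- planted_target_benchmark(cfg)   # simulate -> scan -> IDBC ->
                                         # featurize -> label -> 10x10 CV
bench$cv
#> decision_tree, 10 x 10-fold CV: accuracy 1.000, sensitivity 1.000, specificity 1.000

labels <- bench$labels
labels
#> labeled set: 100 positives, 95 negatives, 5 unlabeled

roc_auc(bench$model, bench$X, bench$y)$auc
#> [1] 1

head(sort(gini_importance(bench$model), decreasing = TRUE), 3)
#> c3.dist_tss c1.dist_tss   c1.length
#>           1           0           0
```

The simulated study plants 2–4 homotypic site clusters in each of 100
target promoters (out of 200 genes); the decision tree, trained on IDBC
cluster features, recovers the planted targets essentially perfectly at the
strongest perturbation threshold (ε = 1.1). Its single split lands on the
TSS distance of cluster slot 3 of 4 — the most distal slot that every true
target fills (all targets carry at least two clusters, padded to the 5'
end). At weaker planted effects (ε = 1.01) cluster information rides the
threshold *I* and accuracy drops into the mid-0.9s, reproducing the
expected monotone accuracy-vs-ε pattern.

Mutating a single cluster away leaves the prediction positive (the other
clusters buffer the loss); knocking out every cluster flips it:

```r
rep1 <- reevaluate_promoter(promoter, variants_one_cluster, ipwms, params,
                            genome, model = bench$model)
rep1$cluster_fates$fate
#> [1] "abolished" "retained" "retained"
rep1$prediction$class
#> [1] 1 1
```

## Command line

A thin CLI wraps the same functions
(`inst/cli/regcl <cmd> --config file [key=value ...]`), with subcommands
`simulate`, `scan`, `cluster`, `features`, `label`, `train`, `similar` and
`mutate`, each writing TSV/JSON outputs plus a log echoing the seed and
parameters. See the methods vignette for the configuration keys.
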