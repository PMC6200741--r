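# angiopep

Classification of short peptides (2–50 residues) as **anti-angiogenic**
vs **non-anti-angiogenic** from their primary sequence alone. Peptides
that inhibit blood-vessel growth are candidate cancer therapeutics, and
screening them *in silico* before wet-lab validation is far cheaper than
assaying every candidate. `angiopep` is aimed at computational biologists
and cheminformaticians who want a reproducible, leakage-aware QSAR
benchmark for this (or any similar) binary peptide-activity problem.

## What it computes

**Descriptors.** Each sequence is mapped to compositional molecular
descriptors:

- amino-acid composition (AAC), the fractions
  *f(i) = n(i) / L* of each of the 20 residues (20 features);
- dipeptide composition (DC), fractions of the 400 adjacent residue
  pairs over the *L − 1* windows;
- tripeptide composition (TC), fractions of the 20³ = 8000 adjacent
  triples over the *L − 2* windows;
- parallel- and series-correlation pseudo-amino-acid composition
  (PC-/SC-PseAAC): AAC augmented with λ sequence-order correlation
  factors θ_j built from standardized hydrophobicity, hydrophilicity and
  side-chain-mass scales, weighted by *w* and normalised so each vector
  sums to 1.

**Feature selection.** A univariate two-sample t-test (Welch by default)
ranks every feature by how well it separates the two activity classes;
the top-*k* features are kept (benchmark schedule: 5/10/15 for AAC,
25/50/75/100 for DC, 75/100/125/150 for TC, 50/100/150/200 for the
merged set).

**Benchmarking.** Four learner families — random forest, distance-weighted
k-NN, RBF-kernel SVM and elastic-net logistic regression (glmnet) — are
tuned and evaluated by nested resampling: an outer 5 × 10-fold
stratified cross-validation for performance estimation wrapping an inner
stratified 2/3–1/3 holdout used only for hyperparameter grid search.
AUC (normalised Mann-Whitney U) and accuracy are recorded per fold.
Feature selection and standardization are refit inside each outer
training fold by default (leakage-safe); a global mode is available for
comparison with whole-dataset preprocessing workflows.

**Model comparison.** Performance vectors are compared with a
significance cascade: Shapiro-Wilk and Bartlett gates, then the Friedman
test with the Iman-Davenport F extension, then Finner step-down post-hoc
adjustment (`APV_(i) = max_(j≤i) min{1, 1 − (1 − p_(j))^((k−1)/i)}`)
against the best-ranked control model.

**Importance.** Elastic-net coefficients are summed per feature over all
fold models; the sign (under the declared ANTI-positive encoding) tells
whether a residue or short motif is associated with anti-angiogenic
activity.

A seeded synthetic-peptide generator with class-specific composition
biases, planted motifs (SP, TC, SC, LSL in the positive class) and
redundancy curation (<70 % pairwise identity) makes the whole pipeline
testable without proprietary data.

## Worked example

```r
library(angiopep)

ds <- generate_dataset(benchmark_config(seed = 7))   # 107 ANTI + 105 NON_ANTI
mat <- remove_zero_features(featurize_dataset(ds, c("aac", "dc", "tc")))
mat
#> Descriptor matrix: 212 peptides x 3997 features
#> Sets: AAC (20), DC (400), TC (3577)

rk <- rank_features_ttest(mat)
head(rk, 3)
#>   feature         t            p rank
#> 1   AAC:S 10.508969 5.126052e-21    1
#> 2   AAC:C  9.102152 1.196446e-16    2
#> 3   DC:SC  9.548593 1.747351e-16    3

lrn <- make_default_learners(ncol(mat$values), profile = "fast",
                             families = "GLMNET")
cv <- run_nested_cv(mat, lrn, outer_repeats = 2, outer_folds = 5,
                    fs_k = 200, seed = 7)
summary(cv)$overall
#>   learner dataset       auc  accuracy     auc_sd accuracy_sd
#> 1  GLMNET    data 0.9725521 0.9174972 0.02011295  0.04604937

imp <- aggregate_betas(coef(cv), provenance = mat$provenance)
top_k_report(imp, 5)[, c("feature", "beta_sum", "anti_associated")]
#>  feature beta_sum anti_associated
#>    DC:SC 1.935144            TRUE
#>    DC:TC 1.627628            TRUE
#>    AAC:S 1.542216            TRUE
#>   TC:LSL 1.480869            TRUE
#>    DC:SP 1.452060            TRUE
```

The ranking puts the planted motif features (`DC:SP`, `DC:TC`, `DC:SC`,
`TC:LSL`) and the biased residues (`AAC:C`, `AAC:S`, `AAC:P`) at the
top, the nested CV reports the held-out discrimination (AUC ≈ 0.96–0.98
on the synthetic benchmark), and the importance report flags the motif
features as anti-associated — the signal the generator planted, recovered
end to end. Replace the generator with `read_fasta()` + `read_labels()`
(or `pipeline_config(input = list(fasta = ..., labels = ...))`) to run
the identical analysis on real curated peptide sets.

`run_pipeline(pipeline_config(...), out_dir)` executes every stage and
writes all artifacts (FASTA, rankings, per-fold results, comparison
report, importance table, effective config) reproducibly: the same
config and seed give byte-identical CSVs.

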