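---
title: "Methods: compositional QSAR benchmarking of anti-angiogenic peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional QSAR benchmarking of anti-angiogenic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiopep)
```

# The problem and the model

Anti-angiogenic peptides are short amino-acid chains (2–50 residues)
that inhibit the growth of new blood vessels, a mechanism exploited by
several cancer therapies. `angiopep` implements a quantitative
structure–activity relationship (QSAR) between a peptide's primary
sequence and a binary activity label: the sequence is converted to
compositional descriptors, noisy features are filtered out with a
univariate statistic, and regularised classifiers are benchmarked under
nested resampling. The package's core scientific claim is procedural,
not biological: given two classes of peptides that differ in residue
and short-motif composition, the pipeline recovers that signal without
information leaking from evaluation data into feature selection,
standardization or hyperparameter tuning.

# Descriptors

For a sequence of length $L$ over the 20-letter alphabet:

* **AAC** — $f_i = n_i / L$ for each residue type $i$; 20 features.
* **DC** — counts of adjacent residue pairs over the $L-1$ overlapping
  windows, divided by $L-1$; 400 features. We read the normalising
  constant as the number of windows (not the 400 possible pairs), so
  every row is a probability vector summing to 1; the alternative
  reading would make rows sum to $(L-1)/400$ and would not be a
  "fraction" in any useful sense.
* **TC** — identical construction over triples, $L-2$ windows, $20^3 =
  8000$ features.
* **PC-PseAAC** (type 1) — AAC augmented with $\lambda$ sequence-order
  factors $\theta_j = \frac{1}{L-j}\sum_{i=1}^{L-j}
  \Theta(R_i, R_{i+j})$, where $\Theta$ averages the squared
  differences of three standardized residue properties
  (hydrophobicity, hydrophilicity, side-chain mass). Components are
  normalised by $\sum f + w \sum \theta$, so the vector is nonnegative
  and sums to 1.
* **SC-PseAAC** (type 2) — per-property factors
  $\tau_{2(j-1)+g} = \frac{1}{L-j}\sum_i H_g(R_i) H_g(R_{i+j})$ for
  hydrophobicity and hydrophilicity separately ($2\lambda$ pseudo
  components). Because products of standardized values may be negative,
  individual components can be negative; the vector still sums to 1.
  This is inherent to the series-correlation definition, so
  nonnegativity is asserted only for the parallel variant.

The property table ships with the package (`pseaac_properties()`): the
Tanford/Chou hydrophobicity scale, Hopp–Woods hydrophilicity and
side-chain masses, each standardized to zero mean and unit population
variance over the 20 residues, as the PseAAC construction requires.

**Defaults.** $\lambda = 3$, $w = 0.05$. $\lambda$ must stay below the
shortest sequence length (peptides can be very short), and $0.05$ is
the conventional weight; both are arguments, not constants. All-zero
columns (k-mers never observed) are dropped by
`remove_zero_features()` before modelling.

**Standardization** uses the sample convention (denominator $n-1$);
features with zero spread on the fitting rows map to 0. By default the
standardizer is fitted on each outer-CV training fold only. A `global`
mode (fit once on all rows before resampling) exists because the
classical whole-dataset workflow does exactly that; having both makes
the optimism of global preprocessing measurable rather than arguable.

# Feature selection

A two-sample t-test per feature between the classes, ranked by
ascending p-value. Welch's unequal-variance statistic is the default —
the safer choice when group variances differ and equivalent to the
pooled test when they do not; the pooled variant sits behind a flag.
Ties are broken by larger $|t|$ and then feature name, making the
ranking a deterministic total order. Features with zero variance in
both groups have no defined statistic and receive the worst ranks.
Like standardization, the ranking is computed inside each training
fold by default, with a global mode for comparison; the spec-level
question of which the original workflow used is left open by its text,
so both are first-class.

# Nested resampling

Outer loop: `outer_repeats` (default 5) repetitions of a stratified
`outer_folds` (default 10) fold partition; stratification keeps each
fold's class count within one record of proportional. Inner loop: one
stratified 2/3–1/3 holdout of the outer-training rows; every
hyperparameter grid point is fitted on the 2/3 and scored by AUC on the
1/3 (AUC is the benchmark's headline metric, hence the tuning
criterion). The best point — first in documented grid order on ties —
is refitted on the full outer-training set and scored on the held-out
fold. Records in the test fold are never seen by selection,
standardization or tuning; the fold bookkeeping is asserted by tests.

Grids (the benchmark's): RF `mtry` $1..\lfloor\sqrt{p}\rfloor$,
`nodesize` 1–3, 1000 trees; weighted k-NN $k$ 1–5 (Minkowski/Euclidean
distance, inverse-distance vote); SVM-RBF $C,\sigma \in 2^{-12..12}$;
glmnet $\alpha \in \{10^{-4},10^{-3},10^{-2},0.1,1\}$, $\lambda \in
\{0,0.15,0.25,0.35,0.5,0.65,0.75,0.85,1\}$. A `fast` profile thins the
RF/SVM/glmnet grids and uses 200 trees; it changes cost, not logic, and
is what the test-suite and the acceptance script use.

Determinism: a master seed yields deterministic child seeds per
(repeat, fold, learner) cell, so identical inputs give byte-identical
result tables regardless of execution order. SVM decision values are
used directly as ranking scores (no probability calibration); they are
oriented against the training labels because the internal class coding
of the SVM implementation is not contractually fixed. Accuracy uses
each model's own label rule (forest vote, SVM sign, probability
threshold 0.5).

The class encoding is fixed package-wide: **ANTI is the positive
class**. Elastic-net coefficients are reported under this encoding, so
a positive aggregated beta marks an anti-angiogenic-associated feature;
the encoding is stored in every result object so the direction of the
published negative-beta convention (which used the opposite internal
coding) can be mapped onto ours unambiguously.

# Statistical comparison

The cascade mirrors standard practice for comparing k models over N
replicated experiments: Shapiro–Wilk on the pooled values and Bartlett
across models gate the parametric branch; AUC data essentially always
fail at least one gate, and the nonparametric branch is the only one
implemented (a parametric ANOVA branch would be dead code). The
Friedman statistic uses within-block mean ranks with the standard tie
correction; the Iman–Davenport extension
$F = (N-1)\chi^2 / (N(k-1) - \chi^2)$ is referred to
$F_{k-1,(k-1)(N-1)}$. When every block ranks the models identically the
F denominator vanishes; we report $p = 0$ with an explicit
`degenerate` flag instead of dividing by zero. Finner's step-down
adjustment is applied to two-sided normal p-values of rank differences
against the control model (highest mean performance, ties by average
rank then label). Blocks default to per-repeat means (N = repeats),
with per-fold blocks behind a flag, since the appropriate granularity
depends on how independent one believes folds to be.

# Synthetic data: what it emulates and what it does not

`benchmark_config()` reproduces the curated benchmark's *shape*: 107
positive and 105 negative sequences, lengths 5–50 (uniform — the real
length distribution is unpublished, and this assumption is flagged
here), a uniform residue background with the positive class biased by
+0.03 toward C, S, P and the negative class by +0.03 toward A, V, D, I
(the compositional contrast repeatedly reported for this activity),
and motifs SP, TC, SC, LSL planted into positives with probability 0.8
per record (overwriting residues at a uniform position, so lengths are
independent of motif settings; one attempt per record and motif keeps
the effect size interpretable). The bias magnitude was chosen once as a
realistic weak compositional signal — large enough that the filter can
find it, small enough that single features do not separate the classes.
A rejection-sampling curation step redraws any candidate with ≥70 %
global-alignment identity to an accepted sequence, emulating the
redundancy filtering applied to the real dataset; generation remains a
pure function of the seed. The default minimum length of 5 (the
biological minimum is 2) keeps TC and PseAAC($\lambda \le 3$) defined
for every record; it is configurable down to 2.

What passing tests on this generator shows: the pipeline recovers
planted compositional/motif signal, is calibrated (chance AUC on
permuted labels, ~1.0 on disjoint compositions), and is leakage-free
and deterministic. What it does not show: performance on real
anti-angiogenic peptides, whose signal includes secondary structure,
position effects and length biases the generator deliberately does not
simulate. Published real-data figures (AUC > 0.96 at 200 merged
features) are therefore not claims of this package; the synthetic
analogue reaching similar values says the machinery works, not that
the biology is solved.

# Numerical and design choices

* **Identity** (curation only, never modelling): Needleman–Wunsch with
  match 1, mismatch 0, linear gap −1; identity = matches / alignment
  length. Among co-optimal alignments the traceback prefers diagonal,
  then up, then left, and arguments are canonically ordered first, so
  the value is deterministic and symmetric. A ≥ threshold comparison is
  inclusive. (A general-purpose aligner was deliberately not used here:
  its choice among co-optimal alignments is unspecified, which makes
  "matches / alignment length" non-reproducible across versions.)
* **AUC** is the normalised Mann–Whitney U with ties counting 1/2 —
  exact, not trapezoidal.
* **Degenerate inputs** error loudly: empty classes, zero-variance
  columns in Bartlett, constant vectors in Shapiro–Wilk, all-invalid
  datasets, k exceeding the feature count.
* **glmnet** is fitted along a decreasing λ path containing the
  requested value, so coefficient extraction is exact; λ = 0 with a
  well-conditioned problem reproduces unpenalized logistic regression
  (asserted in tests).
* **Importance** aggregates betas by *sum* over fold models (a mean is
  available), orders by $|{\sum\beta}|$ with both signs displayed, and
  excludes never-selected features from top-k reports by default while
  keeping them in the table for audit.

# Problem sizes used by the tests and the acceptance script

Formula-equivalence checks run ≥100 random small instances per
operation against independently coded brute-force oracles; composition
conservation is checked over 1000 random sequences; motif recovery uses
10 generator seeds with fold-wise selection of 200 merged features and
a 1 × 3-fold elastic-net CV; calibration uses 2 × 3-fold CV with the
fast grids; the cascade null calibration uses 500 replicates of a
10 × 5 exchangeable matrix; the benchmark-style elastic-net figure uses
the full 5 × 10-fold design. These sizes were chosen so the entire
suite exercises every stage at meaningful scale while remaining
comfortable to run routinely; all of them are arguments the user can
turn up.

# Known limitations

* Uniform length distribution and i.i.d. residue emission are
  simplifications; real peptide sets have heavier short-length mass and
  positional structure.
* The full SVM grid (625 points × 50 outer folds) is hours of CPU; the
  `fast` profile is the practical default for exploration.
* The t-test filter is univariate by design — interacting features that
  are individually uninformative will be missed, a known property of
  filter selection, not a defect of the implementation.
* `max_identity_check` is exact but quadratic in the number of records
  (with a length-ratio prefilter); for thousands of sequences a
  clustering-based curation tool would be preferable.

# Why this shape

The package exposes its stages as plain functions and its core
computation, `run_nested_cv()`, as a classed model-like object with
`print`, `summary`, `coef` and `plot` methods: the benchmark result *is*
the fitted artifact a user inspects, so the classic R modelling idiom
fits there, while I/O, generation, selection and reporting remain
composable pipeline stages (`run_pipeline()` ties them together).
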