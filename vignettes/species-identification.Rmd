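---
title: "Methods: alignment-free species identification from DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free species identification from DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA barcoding assigns a species name to an organism from a short
standardized genomic region; for fungi the reference barcode is the
rDNA internal transcribed spacer (ITS1–5.8S–ITS2). Reference
collections compiled from public repositories are awkward for classical
classifiers: sequence lengths vary widely (roughly 200–2,000 bases),
classes are strongly imbalanced (from ~10 to many hundreds of sequences
per species), and sequences are unaligned. barcodeboost treats the
problem as supervised text classification: k-mers are the words,
sequences are the documents, species are the classes.

## Model and assumptions

**Featurization.** A sequence of length $L$ yields the $L - k + 1$
overlapping windows of width $k$ (stride 1). The training corpus defines
a frozen vocabulary — the sorted set of distinct k-mers it contains —
and each sequence becomes the sparse vector of its per-vocabulary-token
counts. Raw counts are used rather than TF–IDF or binary indicators:
barcode discrimination rests on presence and multiplicity of
species-diagnostic k-mers, and tree ensembles are insensitive to
monotone feature scaling anyway. IUPAC ambiguity codes are kept verbatim
inside tokens; masking them would discard the information that an
ambiguous call occurred, and tokens containing them are simply rare
vocabulary entries. Reverse-complement canonicalization is deliberately
not performed — deposited barcodes are orientation-consistent.

The implicit assumptions: species are separable by k-mer composition
(true when between-species divergence exceeds within-species variation,
the usual barcode-gap premise), and query sequences come from the same
orientation and broadly the same region as the references.

**Classifier.** The prediction of a gradient-boosted tree ensemble after
$K$ rounds is $\hat y_i^{(K)} = \sum_{k=1}^{K} f_k(x_i)$, fit to
multiclass log-loss with the standard per-tree regularization
$\Omega(f) = \gamma T + \tfrac12 \lambda \lVert w \rVert^2$ ($T$ leaves,
leaf weights $w$). Split finding and leaf-weight solving are delegated
to xgboost (histogram method, single-threaded for reproducibility); the
package owns the cross-validation, the hyperparameter search, model
selection, and all evaluation.

## Tunable parameters

| parameter | meaning | default | range | why |
|---|---|---|---|---|
| `k` | k-mer width (bases) | 7 | 3–10 | best trade-off between specificity and vocabulary sparsity for ITS-length barcodes; the sweep (`kmer_sweep()`) lets users re-derive it for their corpus |
| `min_count` | minimum sequences per retained species | 7 | ≥ 0 | species with fewer references cannot support a stratified split and inflate variance |
| `test_fraction` | stratified holdout share | 0.2 | (0,1) | conventional 80:20 |
| `n_estimators` | boosting rounds | tuned | 100–400 | searched |
| `max_depth` | tree depth | tuned | 5–10 | searched |
| `gamma` | leaf penalty γ | tuned | 0–1 | searched |
| `learning_rate` | shrinkage | tuned | (10⁻³, 1] | the open interval avoids the degenerate 0 endpoint |
| `budget` | search evaluations | 5 + 25 | — | 5 random initial points then 25 guided proposals; enough for a 4-dimensional space |
| `early_stopping_rounds` | patience on a 10% within-fold validation split | 50 | `NULL` = off | caps wasted rounds at large `n_estimators` |

Cross-validation is stratified 5-fold, shuffled, `random_state = 2020`;
per-fold class counts deviate from an even split by at most one record.

## The hyperparameter search

The objective is mean fold accuracy. Proposals are drawn in the unit
hypercube and mapped to the ranges above (`max_depth` and
`n_estimators` rounded to integers). After the random initial design, a
Gaussian-process surrogate (RBF kernel, fixed lengthscale 0.2 on
normalized coordinates, nugget 10⁻⁶, standardized responses) scores 500
random candidates by expected improvement and the best is evaluated;
`method = "random"` skips the surrogate entirely. A configuration whose
evaluation fails is scored −∞, logged, and the search continues. Ties on
the objective break by mean macro AUROC, then by smaller
`n_estimators` (prefer the cheaper model). The winner is refit on the
full training set. A fixed master seed pins the split, the fold
assignment, every proposal, and the engine seeds, so two runs are
identical end to end.

Whether headline metrics should come from the CV folds or from the
holdout is genuinely ambiguous in practice; the package computes both
and labels them (`bundle$cv_report` per fold; `evaluate_model()` on the
holdout) rather than choosing.

## Metrics

All scalar metrics derive from one-vs-rest confusion counts per class:
accuracy $(TP+TN)/N$, sensitivity/recall $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, FPR $= 1 -$ specificity, precision $TP/(TP+FP)$, F1 the
harmonic mean of precision and recall. Zero-denominator reductions
report 0 with a warning flag instead of NaN. Multiclass accuracy is
computed on raw labels, never as an average of OvR accuracies. ROC
curves use every distinct predicted score as a threshold plus a +∞
sentinel, integrated by the trapezoidal rule; macro AUROC is the
unweighted mean over classes present in the truth (absent classes are
NA, excluded with a warning). Because the aggregation rule behind
published summary tables is often unstated, precision/recall/F1 are
reported both macro- and support-weighted.

## The synthetic generator

Each species is a star phylogeny: one ancestor, iid descendants with
substitutions at rate μ per base (drawn among the three alternative
bases, so per-record substitution counts are exactly Binomial(L, μ));
indels are off by default since the features are alignment-free and
length variation already comes from ancestor lengths. Ancestors are
either independent uniform-ACGT sequences (divergence ≈ 75%) or, when a
between-species divergence $d$ is given, derived from one root mutated
at rate $d$ and truncated to per-species lengths — the knob that makes
classes genuinely confusable (two ancestors each mutated at rate $d$
from the root differ at $1-(1-d)^2-d^2/3 \approx 2d$ of their
positions, so the planted divergence scales directly with $d$). Setting μ > d is allowed with a warning: it is the stress
regime in which classes overlap and accuracy must fall. Class sizes are
either explicit (including the fixed long-tail 17-species profile of
799, 483, 94, 60, 34, 33, 30, 29, 24, 24, 17, 16, 15, 14, 12, 10, 10
records summing to 1,704) or sampled log-uniformly to mimic that tail.

What the generator does **not** emulate: real ITS secondary structure
and conserved/variable sub-regions, sequencing-error profiles, chimeras,
mislabeled references, and cross-repository duplication beyond exact
copies. Passing tests on synthetic data therefore demonstrates that the
pipeline recovers planted structure under the stated divergence/noise
contrast — not field-grade accuracy on curated repository data.

## Numerical and design choices

- **Label codes** are assigned by case-sensitive byte-order sort of the
  verbatim species strings (C locale, uppercase before lowercase), which
  makes the integer coding deterministic across platforms and
  reproduces the coding conventions of curated corpora that sort names
  the same way. Names like "sp." or "Uncultured X" are kept verbatim as
  distinct classes; normalizing them is a curation decision the package
  refuses to make silently.
- **Deduplication** removes exact (species, sequence) duplicates on
  read, the conservative merge rule when the same barcode is deposited
  in two repositories.
- **Degenerate inputs**: sequences shorter than k produce empty token
  lists; at prediction they are flagged `unclassifiable`, never silently
  scored. An all-empty corpus, an empty post-filter dataset, and
  singleton classes at split time are hard errors with actionable
  messages.
- **Determinism**: every stochastic step (generator, split, folds,
  proposals, engine) is seeded from user-visible arguments; xgboost and
  ranger run single-threaded.
- **Problem sizes in the test suite** were chosen to exercise every code
  path at desk scale: the vectorizer oracle uses 100 random sequences of
  50–300 bases across k = 3..8; the end-to-end recovery check uses 17
  species × 20 sequences at d = 5%, μ = 0.5% with a 5 + 10 search
  budget, which a single core completes in a few minutes.

## Known limitations

- Accuracy on real repository corpora depends on curation quality;
  mislabeled references propagate directly into the classifier.
- The GP surrogate uses a fixed lengthscale; for much larger search
  spaces a tuned or ARD kernel would be preferable.
- No reverse-complement handling: mixed-orientation inputs must be
  normalized upstream.
- Macro AUROC on classes with very few holdout records is high-variance;
  the per-class report should be read alongside the support column.
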