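---
title: "Methods: cancer-type-specific driver-mutation annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cancer-type-specific driver-mutation annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticdriver)
```

## The problem

Driver mutations confer a growth or survival advantage to tumour cells;
passengers are along for the ride. Missense drivers are hard to separate from
the passenger background because they are rare, have low per-mutation
prevalence, and act through heterogeneous mechanisms. `somaticdriver` builds
a cancer-type-specific classifier from two ingredients the user supplies: a
somatic mutation catalog (who observed which variant in which sample) and a
precomputed per-mutation feature table (conservation scores, protein-domain
annotations, functional-impact scores from upstream annotators). Computing
those features is out of scope; the package consumes them.

The pipeline has five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Curation** of driver/passenger training labels from recurrence and
   proximity rules (`curate_training_sets()`).
2. **Imputation** of missing feature cells by within-gene k-nearest
   neighbours (`impute_features()`).
3. **Screening and selection** of a feature subset under cross-validated
   ROC AUC (`screen_features()`, `enumerate_core()`, `hill_climb()`).
4. **Classification** with a class-weighted SVM and percentile-based
   three-way calls (`train_model()`, `predict_calls()`).
5. **Evaluation** (AUC/recall, prevalence correlation, panel enrichment,
   matched-model comparisons).

## Curation rules

Labels are derived at two stringency levels for a target cancer type.

**Stringent set (S)** — intended as high-confidence test data. A missense
variant (identical chromosome, position, ref and alt allele) is a driver
when seen in at least `stringent_min_samples` (default 2) distinct samples,
unless a carrying sample also harbours a putative functional confounder
(indel, nonsense, nonstop, splice-site or translation-start mutation) in the
same gene — recurrence is then explained without the missense being causal —
or the site is on the user-supplied blacklist of known polymorphic sites.
Stringent passengers are the missense mutations of hypermutated samples
(strictly more than `hypermutated_min_missense` missense mutations; this
threshold is dataset-specific — repair-deficient tumours differ by cancer
type — so it is a config value), excluding cancer-list genes and blacklisted
sites.

**Expanded set (E)** — the training data. Drivers exploit cross-cancer
hotspot structure: a missense record in a gene mutated in the target type
qualifies if (1) its exact variant recurs in ≥ 3 primary-tumour samples of
*any* cancer type, or (2) ≥ 4 records of any class share its exact site, or
(3) ≥ 5 records fall in the 25 bp window centred on it. Expanded passengers
are in-type primary-tumour singletons outside the cancer-gene list with no
other record within a centred 31 bp window. Stringent variants are
subtracted from the expanded sets so the two levels stay independent.

Reading "centred" literally, a 25 bp window is `pos ± 12` and a 31 bp window
is `pos ± 15`; windows are therefore required to be odd. Rules 2–3 count
mutation *records* rather than distinct samples by default — the rules are
phrased in terms of mutations, and a sample re-reporting the same site is
rare — but `site_intersect_unit = "samples"` switches the unit. A gene
counts as "mutated in this cancer type" as soon as it carries one record of
any class there. Cell-line records participate in the proximity rules 2–3
(hotspot evidence is hotspot evidence) but not in the primary-tumour
recurrence rule 1 or the passenger singleton rule. These counting rules are
verified in the test suite against a brute-force pairwise-distance oracle on
randomised catalogs.

## Imputation

Feature portals miss values non-uniformly, so the table is completed before
screening. For each missing cell the donors are same-gene mutations with the
feature observed; the `k = 5` nearest by genomic distance (ties: lower
position, then lexicographic id) contribute their values, aggregated by the
median (continuous) or mode (binary; an exact 0/1 tie resolves to 0, i.e.
toward "no annotation"). Neither k, the metric nor the aggregate is forced
by the method's description — nearest mutations of the same gene — so the
defaults were chosen for robustness and reproducibility. Without a same-gene
donor the table-wide central value is used (with a warning for mutations the
catalog cannot place). Observed cells are never touched, which makes
imputation idempotent — a property the tests assert.

The full table is imputed once, before cross-validation. Strictly this lets
unlabeled test rows influence imputed training cells (a mild form of
leakage); it mirrors the practical situation where the feature table is
completed once per catalog release, and the evaluation sets used in this
package's simulations carry little missingness, but users comparing models
on heavily-missing data should be aware of it.

## Feature screening and the hybrid search

Each feature is screened individually with a two-sided Mann–Whitney U test
(Bonferroni-corrected by the number of features actually screened — not the
nominal table width — with the exclusion list applied first) and its
single-feature AUC. A feature passes when the corrected p-value is below
`alpha = 0.05` and `|AUC − 0.5|` exceeds `auc_margin` (0.08 and 0.05 are the
reference choices for the two cancer types studied with this design; the
margin mainly limits the cost of the combinatorial step). Screening uses the
absolute margin because a feature may be protective rather than deleterious;
the raw feature enters the model either way and the classifier learns the
direction. The U test is `stats::wilcox.test` (exact for small untied
samples, tie- and continuity-corrected normal approximation otherwise). The
AUC uses the rank-sum identity `AUC = U/(n1·n2)` with half-credit ties — an
identity the tests verify against explicit pair enumeration.

Subset search proceeds in two steps under repeated stratified k-fold
cross-validated AUC (defaults 10 folds × 5 repeats; the fold layout is drawn
once from `cv_config(seed)`, making the whole search reproducible
bit-for-bit). The model inside the search is the same class-weighted SVM
used for the final classifier, with features z-standardised per training
fold. First, every subset of one to three screened features is enumerated
(`enumerate_core()`; ties favour the smaller then lexicographically earlier
subset). Second, hill-climbing adds, at each step, the single remaining
feature that maximises the cross-validated AUC, running until the screened
features are exhausted so that the entire AUC-versus-size curve is recorded;
the optimal set is the shortest prefix of that path attaining the maximum.
Running to exhaustion rather than stopping at the first decline costs little
and makes the trace plottable and auditable.

## Classifier, calls and confidence

The classifier is a support-vector machine (`e1071`, C-classification) with
per-class weights `w_c = N/(2·N_c)` — inverse class frequency normalised to
mean one — to counter the heavy driver/passenger imbalance of expanded
training sets (reference counts run near 1:5). The kernel defaults to RBF
(`gamma = 1/n_features`), appropriate for ~20 mixed continuous/binary
features at moderate n; a linear kernel is available by flag and is the
better choice for very low-dimensional problems (see limitations).
Standardisation statistics learned on the training table are stored with the
model; scores are signed decision values oriented so that higher means more
driver-like (the orientation is read from the fitted model's decision-value
labelling, never guessed from the data).

Calls are three-way, from training-score percentiles (linear interpolation
between order statistics, R `quantile` type 7, recorded with the model):
**driver** when the score strictly exceeds the 90th percentile of training
passenger scores, **passenger** when strictly below the 10th percentile of
training driver scores, otherwise **no-call**. The driver rule is applied
first; when a model separates so well that the two thresholds cross, a score
in the gap satisfies both rules and is called a driver, with a warning. By
construction at most ~10% of training passengers (plus any tie mass at the
threshold) can be called drivers — a property the tests check.

The confidence score is the empirical same-class tail probability: for a
driver call, the fraction of training drivers with *strictly* greater score
(ties are not "more extreme"); for a passenger call, the fraction of
training passengers strictly lower. A driver scoring above 95% of the
training drivers has confidence 0.05. No-calls have no natural reference
class and get `NA`. Sorted training scores are serialised with the model so
confidences are reproducible without retraining.

## Evaluation utilities

`roc_auc_and_recall()` shares the single AUC implementation; recall is the
fraction of true drivers called "driver". `prevalence_correlation()` is the
Pearson correlation between scores and observed mutation counts — a more
accurate scorer should track prevalence. `enrichment_pvalue()` is the
one-sided upper-tail hypergeometric probability that a gene panel contains
at least the observed number of predicted drivers among its rare mutations
(`find_rare_mutations()` identifies isolated singletons, default vicinity
± 3 bp). `compare_score_groups()` applies the same U test to matched- versus
mismatched-model score comparisons.

## The synthetic generator

`fixture_spec()` describes what the simulations emulate: the *statistical*
shape of a curated training table — informative continuous features shifted
by `effect_size` standard deviations for drivers, informative binary
features with a Bernoulli rate shift, pure-noise features, and missingness
that is either completely at random or concentrated in a feature block
(portal-wise dropout). For a single continuous feature with shift d, the
population AUC is Φ(d/√2), which anchors several tests analytically.
`make_catalog()` injects known curation structure — isolated singletons,
centred hotspots laid out so that exactly the centre accumulates the full
window count, and recurrent variants — in well-separated 10 kb
neighbourhoods, so curation on a generated catalog must recover exactly the
marked truth.

What the generator does **not** emulate: realistic mutation spectra,
trinucleotide context, gene length and expression covariates, correlated
features, or label noise in the curation rules themselves. Passing tests
demonstrate that the machinery is correct under its stated model, not that
any particular biological dataset will reach a given AUC.

Simulation problem sizes in the test suite follow the properties being
checked: combinatorial-search checks run 5-fold × 2-repeat cross-validation
on a few hundred mutations and ≤ 30 features (the exhaustive step visits 92
subsets per fixture); the feature-recovery study uses 3 informative features
of effect 1.5 SD among 30, n = 300 + 300, 20 seeds; the separation-limit
check uses 2 000 held-out mutations. Package defaults remain 10 × 5.

## Numerical choices and degenerate inputs

* Constant features screen at AUC 0.5 and never pass.
* Standardisation of a zero-variance column divides by 1 instead of 0.
* Fold assignment requires each class count ≥ folds; violations raise an
  error suggesting fewer folds.
* AUC tie handling is exact (rank midpoints), not jittered.
* Subset ties in the enumeration and step ties in the hill-climb are broken
  deterministically (size, then lexicographic), so selection never depends
  on hash or insertion order.
* Empty curation results are valid outputs, not errors; a feature missing
  for *every* mutation is an error naming the feature.

## Known limitations

* The RBF decision surface is non-monotone in the far tails: points far
  outside the support-vector envelope drift back toward the margin. On an
  essentially one-dimensional problem this sheds a few hundredths of AUC;
  use `model_spec(kernel = "linear")` there. With the intended feature-set
  sizes (10–30 features) the effect is negligible.
* Confidence scores are empirical class-wise tail fractions, not calibrated
  probabilities; no Platt scaling is attempted.
* Curation keys variants by (chrom, pos, ref, alt); protein-level
  identity (the same amino-acid change reached by different nucleotide
  substitutions) is annotation only and does not merge records.
* Whole-table imputation before cross-validation, as discussed above.
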