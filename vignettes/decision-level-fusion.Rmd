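---
title: "Decision-level fusion of paired omics classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-level fusion of paired omics classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binary cancer-subtype classification from bulk omics — for example
separating lung adenocarcinoma from squamous cell carcinoma — can draw on
several molecular layers of the same tumors. Gene expression (RNA-seq)
and gene-level copy number (GISTIC2-style) capture mechanistically linked
but distinct information: copy-number change measures structural dosage,
expression measures its transcriptional consequence. A classifier trained
on one layer misses what only the other sees, and the two layers usually
differ in how easy they make the classification task.

`omicsfusion` implements a *decision-level* (late) integration of the two
layers: one probabilistic classifier is trained per modality, and only
their output probabilities are combined, weighted by how well each
modality's model fits its training split. Around that core sit a
stratified cross-validation harness whose fold membership is aligned
across modalities, a ReliefF feature-weighting engine, a stability
gene-selection workflow, and a synthetic paired-omics generator that
makes every stage testable without external cohorts.

## The fusion model

Within one cross-validation fold, let $acc_R$ and $acc_C$ be the
train-split accuracies of the expression and copy-number models, and
$(p^R_{y=0}, p^R_{y=1})$, $(p^C_{y=0}, p^C_{y=1})$ their class
probabilities for a validation sample. The fused prediction is a convex
combination with exponential accuracy weighting:

$$\alpha = \left| e^{acc_C} - e^{acc_R} \right| \cdot k$$

$$w_R = \frac{e^{\alpha\, acc_R}}{e^{\alpha\, acc_R} + e^{\alpha\, acc_C}},
\qquad
w_C = \frac{e^{\alpha\, acc_C}}{e^{\alpha\, acc_R} + e^{\alpha\, acc_C}}$$

$$p^F_{y=c} = w_C\, p^C_{y=c} + w_R\, p^R_{y=c}, \qquad
\hat y = \arg\max_c p^F_{y=c}$$

The weights are a softmax over the $\alpha$-scaled accuracies. Because
$\alpha$ itself grows with the accuracy gap, the weighting is doubly
sensitive to which modality is stronger: equal accuracies give
$\alpha = 0$ and exact equal-weight soft voting, while a large gap pushes
the weights toward the stronger modality. As $k \to \infty$ with unequal
accuracies the fused output converges to the stronger modality's output.

Properties the test suite verifies: $w_R + w_C = 1$; $w_R > 0.5$ iff
$acc_R > acc_C$; each fused probability lies between the two modality
probabilities; fused pairs sum to 1 whenever the inputs do; no overflow
for any accuracies in $[0,1]$ and $k$ up to $10^6$ (the softmax is
computed with the maximum exponent subtracted).

Numerical and convention choices:

* The literal $\max(p^F_0, p^F_1)$ form of the label rule returns a
  probability, not a class, so the implementation uses the argmax class;
  accuracy against true labels requires it.
* Probability ties $p^F_0 = p^F_1$ resolve to class 0 — deterministic,
  and measure-zero for continuous scores.
* The absolute-value bars around the exponentials in the weight formulas
  are redundant once accuracies are validated into $[0,1]$ and are
  dropped.
* The default scaling factor is $k = 10$: fused accuracy as a function of
  integer $k \ge 2$ rises and then plateaus near 10 (`sweep_k()`
  reproduces the curve; `analysis/02_benchmark_fusion.R` writes one).
* Weights are computed **per fold** from that fold's train accuracies,
  not globally: train accuracy is defined on the fold's training split,
  which varies by fold. Computing it on anything containing validation
  samples would leak. Whether a published variant of this scheme averaged
  accuracies per run instead is not determinable from the description we
  follow; per-fold is the leakage-safe reading and the one implemented.

Two baselines are provided for comparison: equal-weight soft voting
(identically fusion with $w = 0.5$) and hard majority voting, which with
two voters falls back to the soft-vote label on every disagreement.
Feature-level concatenation (`concat_joint_features()`) supplies the
early-integration baseline.

## Cross-validation harness

`make_fold_plan()` builds a stratified k-fold partition as a pure
function of `(labels, k, seed)`: within each class the IDs are shuffled
by the seed and dealt round-robin, so every fold's class proportions are
within one sample of the global proportion and surplus samples land
deterministically in earlier folds. The **same plan is used for both
modalities**, which is what makes per-sample probability pairs alignable
at fusion time. The classifier seed is the plan seed, so a repetition
seed controls both fold shuffling and model initialization.

Classifiers are thin adapters over established implementations
(`xgboost`, `e1071`'s RBF SVM, `nnet`), each exposing
`fit(x, y, seed, hyperparameters)` and `predict_proba()`; the package's
contribution is the harness, the fusion and the selection, not the
models. Adapters run single-threaded with explicit seeds so end-to-end
runs are bit-reproducible. The MLP adapter defaults to a 16-unit hidden
layer rather than a dense-data default of 100: with far more genes than
samples a 100-unit layer is badly overparameterized and slow. A
transformer-based tabular model is deliberately not bundled — nothing
downstream depends on a specific model, and any classifier can be plugged
in through the custom-adapter interface.

## ReliefF and stability selection

ReliefF scores a feature by local class contrast: for each instance, find
its $k$ nearest same-class neighbors (*hits*, never the instance itself)
and $k$ nearest other-class neighbors (*misses*), and accumulate

$$W[A] \mathrel{+}= \frac{\overline{\mathrm{diff}}(A, x, \mathrm{miss})
  - \overline{\mathrm{diff}}(A, x, \mathrm{hit})}{n}$$

Choices fixed here, where the classical algorithm statement leaves them
open:

* `diff` for continuous attributes is the range-normalized absolute
  difference $|x_A - y_A| / \mathrm{range}_A$ (the standard Relief
  choice); constant attributes return 0.
* Neighbor distance is the Manhattan sum of those per-attribute diffs,
  with ties broken by row order for determinism.
* Every instance is evaluated (`n_sampled = "all"`): the "randomly select
  an instance" step becomes a deterministic full pass, matching the
  behavior of the widely used reference implementations. Random
  subsampling remains available and seeded.
* `k_neighbors` defaults to 100, the customary ReliefF default; on data
  too small for it the value is clipped to (min class size − 1) with a
  warning, or raises if clipping is disabled.

With these conventions weights are bounded in $[-1, 1]$, are near zero
under label permutation, and grow with class separation — all covered by
property tests, plus exact agreement (to $10^{-10}$) with an exhaustive
brute-force reference on random small instances. The inner loop is C++
(Rcpp); at 480 samples × 1000 genes one pass takes well under a second.

The stability workflow (`discover_genes()`) then runs, per seed: a
stratified fold plan; ReliefF on each fold's **training split only**, per
modality; aggregation of the five fold lists by cumulative score — the
per-gene *sum* of fold weights, read off the word "cumulative" (a
rank-sum mode exists behind a flag for sensitivity analysis); ties broken
lexicographically by gene ID; then a top-$n$ cut (default 500; the
analysis scripts use 100 against 1000 simulated genes to keep roughly the
paper-like 1:10 selection ratio). The per-seed top sets are intersected
within each modality, and the two stable sets intersected across
modalities for the final gene set; the union is also reported for the
union-vs-intersection comparison. The top-$n$ cut is applied per seed
*before* the cross-seed intersection — aggregation happens across folds
within a seed, selection across seeds by set intersection.

## The synthetic cohort generator

`generate_cohort()` draws the study conditions every test runs under:

* **Cohort shape.** Defaults of 505 and 483 samples per class — the size
  of a paired NSCLC ADC/SCC cohort after cross-modality barcode matching
  — with near-balance, so no imbalance correction is applied anywhere.
  Imbalance is configurable but untested territory by default.
* **Gene space.** 1000 genes per modality in a shared ID namespace
  (desk-scale rather than the 20k+ of real arrays, keeping the
  genes ≫ samples regime testable in seconds), of which 30 planted
  discriminative genes are shared across modalities, 10 are
  expression-only and 10 copy-number-only. Shared genes carry the same ID
  in both modalities, so cross-omics intersection is meaningful and
  modality-specific genes are known decoys for it.
* **Signal.** Standard-normal background per gene; informative genes
  shift the class-1 mean by the configured effect size — 1.5σ for
  expression, 1.0σ for copy number by default, so the modalities
  disagree in difficulty the way real expression and copy-number data do.
  This is the simplest structure that linear and nonlinear classifiers
  and ReliefF can all exploit.
* **Correlation.** Genes form equicorrelated blocks (default 10 genes at
  ρ = 0.3) via a shared Gaussian factor, mimicking co-expression; blocks
  never straddle an informative/noise boundary, keeping ground truth
  unambiguous.
* **Dropout.** By default 5% of samples are missing from each modality
  (disjoint sets), exercising the barcode-matching and common-sample
  machinery; IDs follow a fixed four-field `SYN-AA-0001-01` pattern so
  the barcode parser is exercised.
* **Determinism.** One integer seed drives all randomness through a
  saved-and-restored RNG context; identical config + seed gives
  bit-identical cohorts.

What the generator does **not** emulate: raw read counts or FPKM/TPM
transforms, GISTIC2 segmentation, survival or demographic structure,
batch effects, heavy-tailed expression noise, or gene-gene interaction
signal beyond block correlation. Passing tests therefore demonstrate the
pipeline's correctness and its qualitative behavior (fusion helps when
modalities are complementary; stability selection recovers planted
signal), not performance claims about any real cohort.

## Preprocessing conventions

Matrices load from either TSV dialect (genes-as-rows or samples-as-rows)
into a canonical samples × genes orientation; duplicate IDs and
non-numeric cells are hard errors, blank cells are tolerated only until
`audit_missing()` reports them — any missing cell blocks cohort
construction. Sample matching is exact full-barcode string equality;
participant-level collapsing is out of scope. Sample-wise z-scoring uses
the population (divide-by-$n$) standard deviation, matching the default
of the numerical stacks this pipeline mirrors; constant samples become
all-zero rather than raising. Normalization runs *after* common-sample
restriction, so it sees exactly the analyzed samples; labels come from an
explicit table rather than being inferred from file membership.

## Evaluation conventions

* The positive class defaults to label 1; all confusion-derived metrics
  (accuracy, PPV, sensitivity, specificity, F1, NPV) follow from the four
  cells, with zero-denominator ratios reported as flagged zeros.
* AUROC uses the rank (Mann–Whitney) formulation with ties counted ½;
  for fusion it is computed from the continuous fused positive-class
  probability.
* Per-seed metrics pool each seed's validation folds (every sample is
  validated exactly once per seed); aggregation over seeds reports the
  mean and *population* standard deviation, matching the "mean ± sd"
  table convention.
* Mann–Whitney comparisons are exact for two tie-free groups of ≤ 8
  values (the 5-seed case) and normal-approximate otherwise, with the
  rank-biserial effect size $1 - 2U/(n_A n_B)$. Whether to compare
  per-seed (n = 5) or per-fold (n = 25) values is left to the caller —
  both group constructions are reachable from the per-seed tables in the
  reports.

## Problem sizes used in tests and scripts

Unit and property tests run on cohorts of 24–120 samples and 20–100
genes. The planted-recovery acceptance check uses 300 samples/class ×
1000 genes/modality, 5 folds × 5 seeds, top-100 — small enough for
minutes on one core, large enough for the HDLSS regime. The
fusion-superiority check uses a complementary-signal design (no shared
informative genes, 5 per modality at 0.8σ, 200 samples/class, 500
genes): effect sizes were chosen so that single modalities sit well below
ceiling, leaving fusion measurable headroom, with a matched null cohort
(no signal) as control. The `analysis/` drivers run the full default
cohort (988 samples before dropout).

## Known limitations

* Exactly two modalities; the weight formulas are binary over modalities
  and generalizing the softmax to more layers is future work.
* Binary labels only; no multi-class Relief variants (RReliefF,
  SURF/MultiSURF) and no iterative feature elimination.
* Gaussian synthetic data cannot certify behavior on real count-derived
  expression values; the pipeline accepts any numeric matrices but all
  quantitative guarantees in the test suite are about the generator's
  regime.
* No confidence intervals beyond mean ± sd; no attribution (SHAP-style),
  enrichment, or survival analyses.
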