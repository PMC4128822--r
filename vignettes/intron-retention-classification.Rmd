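---
title: "Classifying retained versus constitutively spliced introns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying retained versus constitutively spliced introns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronclass)
```

This vignette is the package's own account of its science: the labeling
rules, the feature model, the two classifiers, the synthetic data that
the tests run on, and the numerical and design choices made where the
problem left them open. No empirical claim here goes beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## Intron labeling from isoform comparison

A *retained intron* (RI) is an interval that some isoform of a gene
splices out while another isoform of the same gene keeps it entirely
inside one exon. A *constitutively spliced intron* (CSI) is spliced out
by every isoform. `label_introns()` applies these rules to the distinct
intron intervals of a gene model:

* **RI** — the interval is an intron of at least one isoform *and* lies
  fully within a single exon of another isoform.
* **CSI** — the interval is never contained in a sibling exon, and every
  isoform whose genomic span covers the interval carries the identical
  interval as an intron.
* **ambiguous** — everything else.

The third bucket is a design choice. Introns involved in alternative
donor/acceptor events (two isoforms splice overlapping but unequal
intervals) are neither retained nor constitutive under the two
definitions; we exclude them from both classes rather than force them
into CSI, because a "constitutive" intron whose boundaries move between
isoforms is a contradiction in terms. The strictness costs a small
fraction of introns and keeps both class definitions exact.

Two further dataset rules:

* **Redundancy.** RIs of one gene whose 5′ splice sites *and* 3′ splice
  sites each differ by `< 6` bp are treated as variants of one retention
  event; the longest member survives (ties: leftmost). We read the rule
  as requiring both ends to be close — a pair agreeing at only one end
  describes a different splice event. Grouping is by transitive closure,
  so chains collapse to a single representative; the operation is
  idempotent (tested).
* **Length filtering.** Introns under 20 bp are removed by default (they
  are outliers that also break the 20-bp windowing below). No default
  upper cut is imposed: the extreme-length outliers worth removing are a
  property of each dataset, so `max_len` is a per-class user setting.

Coordinates are GFF3-native (1-based, inclusive) end to end; all
sequences are reported in transcription orientation, i.e.
reverse-complemented genomic slices on the minus strand. A mirrored toy
gene on the opposite strand yields byte-identical sequences and windows
(tested).

## The feature model

### Basic composition (A, 14 features)

Global features: length (bp), AT and GC content, and the four base
probabilities. Local features summarize *segmental* composition: the
sequence is cut into `m = ceiling(L/20)` consecutive sections of 20 bp
(the last keeps the remainder and is normalized by its true length),
and for each unordered base pair

$$\lambda_{XY} = \frac{1}{m}\sum_{j=1}^{m}\left|p_X^{(j)} - p_Y^{(j)}\right|,$$

with a seventh heterogeneity factor

$$\lambda_H = \frac{1}{m}\sum_{j=1}^{m}\frac{1}{2}\sum_{b}\left|p_b^{(j)} - p_b\right|$$

against the whole-sequence probabilities. All seven lie in [0, 1]; a
single-section sequence has $\lambda_H = 0$. The section width of 20 bp
matches the shortest admitted intron, so every intron has at least one
full section. |A| = 14 is the only size consistent with the published
mtry values (see below) and the 37-feature total of the A+B+C set.

### Contrastive motifs (B, 19 features)

For word sizes k = 2..5 (6-mers are too rare to be informative), each
k-mer *w* gets, per class dataset,

* `Fre(w)` — total occurrences over total sliding windows,
* `Conf(w)` — fraction of sequences containing *w*,

and the signed relative difference

$$D(w) = \frac{Fre_{CSI}(w) - Fre_{RI}(w)}{Fre_{CSI}(w) + Fre_{RI}(w)} \in [-1, 1],$$

defined as 0 when both frequencies vanish. Positive D means
CSI-enriched. D is antisymmetric under swapping the datasets and
invariant to duplicating every sequence (both tested). *Frequent
motifs* are those with `max(Conf_RI, Conf_CSI) >= 0.8` and
`|D| >= 0.1`, ranked by |D|; the confidence is required in *at least*
one class, since a motif confidently present in one class and rare in
the other is exactly the contrastive case. The classifier's B features
are the sliding-window frequencies of a fixed 19-motif panel — ten
GC-rich RI-enriched motifs and nine AT/TA-rich CSI-enriched ones.

### Splice sites and flanking similarity (C, 4 features)

Signal strength uses position weight matrices over the 9-nt donor
window (positions −3..+6: last 3 exonic + first 6 intronic nt) and the
23-nt acceptor window (−21..+2: last 21 intronic + first 2 exonic nt).
Entries are $\log_2((p_{b,l} + \varepsilon)/(q + \varepsilon))$ with
uniform background q = 0.25 and additive smoothing
$\varepsilon = 1/(4(N+1))$ for N training windows — the smoothing keeps
zero-count cells finite and vanishes as N grows, and a uniformly
trained position scores exactly 0. Scores (`SFvalue`, `SFaccvalue`) are
sums over positions; log base 2 is the standard bits scale for splice
signal strength.

Flank similarity uses the increment of diversity over
overlapping-trimer counts of the 20-nt exon-side and intron-side
windows at each splice site:
$D(X) = N\ln N - \sum_i n_i \ln n_i$ and
$ID(X, Y) = D(X{+}Y) - D(X) - D(Y)$, natural log (the only base on
which 20-nt windows produce ID values on the observed ~18 scale).
ID is symmetric, non-negative, and 0 for identical composition; small
ID at an intron boundary means the intron reads like its exon — the
compositional signature of retention.

Degenerate inputs: an exon-side window shorter than 3 nt cannot hold a
trimer, so the corresponding ID feature is set to 0 and a per-record
`id_truncated` flag raised. Introns of exactly 20 bp lack one base of
the 21-nt acceptor context; the window simply extends into the upstream
exon (never padded). Records containing non-ACGT letters are dropped
with a message — the composition formulas assume a resolved alphabet.

**PWM training population.** The PWMs model the *canonical* splice
signal, so they are trained on CSI windows and applied to all records.
On the random-forest path (a single 90/10 split) training uses only the
CSI records of the training partition, so the holdout never influences
the matrices. On the SVM path every record is out-of-fold exactly once
in 10-fold cross-validation and no single training partition exists;
there the PWM is a class-level estimate from all CSI rows of the
assembled table. A `pwm_train = "pooled"` flag trains on both classes
instead.

## Classifiers

The feature table (preset A = 14, A+C = 18, A+B+C = 37, complete = 52,
optimized = 27 columns) is standardized per column by training-row mean
and sample standard deviation (n − 1); zero-variance columns are
centered with divisor 1 under a warning. Class imbalance is handled by
under-sampling the majority class (all RIs kept, CSIs sampled without
replacement by seed).

* **Random forest** (`randomForest`): `mtry = round(sqrt(p))`, half-up
  — 37→6, 52→7, 27→5, 14→4, 18→4 — and the tree count selected from
  30..50 (step 2) by accuracy on a stratified 10% holdout, ties to the
  smallest count. The report (confusion counts, Accuracy, Sensitivity,
  Specificity, F-Measure, ROC, AUC) is computed on that holdout from
  class-probability votes. The split is stratified by class so both
  classes are always represented.
* **PSO-tuned SVM** (`e1071`/libsvm, RBF kernel): the swarm moves in
  (log2 C, log2 gamma) space within C ∈ (2⁻⁸, 2¹⁰), gamma ∈ (2⁻⁸, 2⁸),
  with 100 particles, 10 iterations, c1 = c2 = 1.49618, w = 0.7298 —
  the standard constriction-equivalent setting. Velocities start at
  zero; positions are clamped to the bounds with the velocity zeroed on
  the clamped dimension; personal/global best ties resolve toward
  smaller parameter values for reproducibility. Fitness is the mean
  10-fold cross-validated accuracy of the SVM at the particle's (C,
  gamma). The tuned model is then evaluated by stratified 10-fold
  cross-validation with pooled out-of-fold probability estimates
  (libsvm's calibration).

**Fitness problem size.** A full swarm run costs about 1,100 fitness
evaluations, each a 10-fold CV; the fitness is therefore evaluated on a
stratified subsample of the table (default `tune_n = 300` rows, folds
and subsample fixed per run so fitness is a pure deterministic function
of (C, gamma)). Hyperparameter selection on a subsample followed by
full-data evaluation is standard practice at this cost profile;
`tune_n = NA` restores full-table fitness.

Evaluation metrics follow the usual confusion-table algebra
(Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP), F-Measure =
2·Precision·Sensitivity/(Precision+Sensitivity)); the ROC sweeps all
score thresholds (tied scores share one point) and AUC is the trapezoid
area, cross-checked against pROC in the tests. Per-feature class
contrasts are reported as classical one-way ANOVA F statistics with raw
(uncorrected) p values.

## What the synthetic data emulates — and what it does not

`simulate_labeled_introns()` generates intron records whose
class-conditional structure mirrors the contrasts reported for
*Arabidopsis* introns, with every knob exposed in `sim_config()`:

| knob | default | rationale |
|---|---|---|
| intron length | log-normal, median ≈ 100 bp, clamped [20, 2000]; RI median 95, CSI 105 | plant introns are short; RIs slightly shorter (reported means 145 vs 160 bp) |
| GC content | CSI 0.3243, RI +0.0333 | reported 35.76% vs 32.43% |
| splice windows | plant-like consensus (caggtaagt; pyrimidine tract + tgcag) mutated per position at 0.20 (CSI) vs 0.35 (RI) | RIs have weaker donor/acceptor signals |
| terminal dinucleotides | gt-ag, with gc-ag at 2.6% (RI) vs 0.9% (CSI) | GC-AG introns are more frequent among RIs |
| planted motifs | GC-rich panel into RIs, AT/TA-rich into CSIs, 0.02 motifs/bp | the contrastive motif families |
| flank composition | exon windows mixed with intron composition, weight 0.5 (RI) vs 0.15 (CSI) | RIs resemble their exons (smaller ID) |

`simulate_genome_annotation()` embeds such introns in multi-isoform
gene models on two chromosomes (both strands): each designated RI is
spliced in the primary isoform and contained in a merged exon of a
second; three-isoform genes can carry an alternative-donor variant
whose intended label is `ambiguous`. The output GFF3 + FASTA round-trip
through `extract_introns()` with ≥ 95% label agreement (tested), and a
null configuration (`sim_config_null()`) switches every class contrast
off, driving both classifiers to chance AUC (tested).

What the simulation does **not** emulate: genomic base composition
beyond simple per-class multinomials (no isochores, no branch-point or
polypyrimidine variation beyond the consensus-mutation model), UTR/CDS
positional structure, expression levels, overlapping genes,
trans-splicing, or sequencing error. Passing tests on this surface
show that the pipeline recovers *planted* class structure of realistic
direction and magnitude; they do not certify the published real-data
accuracy, which depends on the full annotation release.

## Problem sizes and acceptance surface

The acceptance checks run the default conditions at 500 RI + 500 CSI
per seed over 10 seeds for both classifiers (swarm tuning once with the
full published configuration, evaluation per seed), null data at the
same size, and the swarm on a quadratic surrogate
$f(x) = -(x_1^2+x_2^2)$ over 20 seeds, where the global best must come
within 0.05 of the optimum — measured as the optimality gap in the
objective value, the usual benchmark reading — with a monotone
global-best trace. These sizes keep the whole suite within minutes on
one CPU while leaving Monte-Carlo noise on the asserted means at the
percent level.

## Known limitations

* The 27-feature optimized preset is a published *list*; four of its
  members are segmental factors whose identity the source table does
  not render. We ship `lambda_cg`, `lambda_ct` (the two factors the
  class-contrast analysis highlights), `lambda_gt` and `lambda_h`, and
  document the preset as a reconstruction.
* Labeling trusts the annotation: unannotated isoforms make true RIs
  look constitutive. Quantitative isoform expression is out of scope.
* The redundancy rule's 6-bp window and the strict-CSI reading are
  dataset conventions, switchable but not validated against an external
  gold standard here.
* RNA secondary structure and expression-aware features are out of
  scope by design.
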