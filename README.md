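# intronclass

Classification of retained introns (RIs) versus constitutively spliced
introns (CSIs) from genome annotation and sequence.

In plants, intron retention is the dominant form of alternative
splicing: an intron can be spliced out in one isoform of a gene yet kept
entirely inside an exon of another isoform. `intronclass` is for
genomicists and machine-learning practitioners who want to (a) derive
and label RI/CSI intron sets directly from a genome FASTA plus a
TAIR10-style GFF3 annotation, and (b) ask how well sequence alone
separates the two classes — and which sequence properties carry the
signal.

## The method

Every intron is summarized by a hybrid descriptor of up to 52 features
in three groups (the default working set **A+B+C** has 37):

* **A — basic composition (14).** Length, AT/GC content, the four base
  probabilities, and seven *segmental* factors computed over consecutive
  20-bp sections: for each base pair (X, Y),
  `lambda_XY = (1/m) * sum_j |p_X(j) - p_Y(j)|`, plus a heterogeneity
  factor `lambda_H = (1/m) * sum_j (1/2) * sum_b |p_b(j) - p_b(global)|`.
* **B — frequent contrastive motifs (19).** Sliding-window frequencies
  of a fixed k-mer panel (2-5-mers). Panel membership comes from
  per-dataset frequency `Fre`, per-dataset confidence `Conf` (fraction
  of sequences containing the k-mer), and the signed relative difference
  `D = (Fre_CSI - Fre_RI) / (Fre_CSI + Fre_RI)`; GC-rich motifs (cc, gg,
  cg, ccg, ...) are RI-enriched (D < 0), AT/TA-rich motifs (ta, at,
  taat, ...) CSI-enriched.
* **C — splice sites and flanks (4).** `SFvalue` / `SFaccvalue`: log2
  log-odds position-weight-matrix scores of the 9-nt donor (−3..+6) and
  23-nt acceptor (−21..+2) windows against a uniform background
  (q = 0.25). `IDdonv` / `IDacceptv`: the increment of diversity
  `ID(X, Y) = D(X+Y) − D(X) − D(Y)` with `D(X) = N ln N − Σ n_i ln n_i`
  over overlapping-trimer counts of the 20-nt exon-side and intron-side
  windows at each splice site — small ID means the intron boundary
  resembles its flanking exon, a hallmark of retention.

Two classifiers consume the (standardized, optionally under-sampled)
feature table: a random forest (`mtry = round(sqrt(p))`, tree count from
a 30-50 grid by holdout accuracy) and an RBF-kernel SVM whose cost C and
kernel width gamma are tuned by particle swarm optimization
(100 particles, 10 iterations, c1 = c2 = 1.49618, w = 0.7298, bounds
C ∈ (2⁻⁸, 2¹⁰), gamma ∈ (2⁻⁸, 2⁸)) with 10-fold cross-validated
accuracy as fitness. Reports cover the confusion matrix, Accuracy,
Sensitivity, Specificity, F-Measure, ROC and AUC from class-probability
estimates.

A synthetic-data module generates labeled intron records and complete
toy genome + GFF3 + truth-table fixtures with controllable
class-conditional structure, so the entire pipeline is testable without
downloads.

## Worked example

```r
library(intronclass)

cfg  <- sim_config(seed = 7)                     # paper-like class contrasts
recs <- simulate_labeled_introns(cfg, n_ri = 300, n_csi = 300)
fit  <- ri_classifier(recs, method = "rf", seed = 7)
fit
#> ri_classifier: rf on preset ABC (37 features, 600 introns)
#>   numTrees = 38 (grid search), mtry = 6; 90/10 holdout:
#>   confusion: TP=27 FP=1 TN=29 FN=3
#> accuracy=0.933 sensitivity=0.900 specificity=0.967 f_measure=0.931 auc=0.974

stats <- feature_group_stats(fit$table)
head(stats[order(stats$p_value), ], 5)
#>       feature mean_ri mean_csi f_statistic  p_value
#>    at_content  -0.681    0.705         534 5.82e-85
#>    gc_content   0.681   -0.705         534 5.82e-85
#>  sf_acc_value  -0.626    0.619         357 7.50e-63
#>           p_g   0.575   -0.599         313 1.41e-56
#>            cg   0.510   -0.515         209 8.98e-41
```

The forest separates the simulated classes almost perfectly (holdout
F-Measure 0.931, AUC 0.974), and the one-way ANOVA ranking shows *why*:
the strongest contrasts are GC/AT content (means are on the
standardized scale), the acceptor signal strength `sf_acc_value`
(weaker in RIs) and the RI-enriched `cg` motif — exactly the planted
class structure. `plot(fit)` draws the ROC curve;
`predict(fit, new_records)` scores new introns.

For annotation-derived data the entry point is
`extract_introns("annotation.gff3", "genome.fa")`, which labels each
intron RI/CSI/ambiguous by isoform comparison, collapses redundant RIs
(both splice sites within 6 bp), drops introns under 20 bp, and slices
all splice-site windows. A thin command-line wrapper with subcommands
`simulate / extract / features / motifs / train / evaluate` lives at
`inst/cli/intronclass`.

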