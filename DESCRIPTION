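Package: intronclass
Title: Classification of Retained Versus Constitutively Spliced Introns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives introns from genome annotation (GFF3) and genome
    sequence (FASTA), labels them as retained (RI) or constitutively
    spliced (CSI) by comparing isoforms of the same gene, and computes a
    hybrid sequence descriptor combining global and segmental nucleotide
    composition, contrastive frequent k-mer motifs, position weight matrix
    splice-site signal strength, and increment-of-diversity similarity
    between introns and their flanking exons.  Random forest and a
    particle-swarm-tuned RBF support vector machine classify the two
    intron types, with confusion-matrix metrics, ROC curves and AUC.  A
    synthetic-data generator emulates multi-isoform gene models with
    controllable class-conditional structure so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    randomForest,
    e1071,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
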