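test_that("GFF3 gene/mRNA/exon hierarchies parse into gene models", {
  path <- write_toy_gff(c(
    "Chr1\tt\tgene\t1\t300\t.\t+\t.\tID=g1",
    "Chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "Chr1\tt\texon\t1\t100\t.\t+\t.\tParent=g1.t1",
    "Chr1\tt\texon\t201\t300\t.\t+\t.\tParent=g1.t1"))
  genes <- parse_gene_models(path)
  expect_length(genes, 1)
  g <- genes[["g1"]]
  expect_equal(g$gene_type, "protein_coding")
  expect_length(g$isoforms, 1)
  expect_equal(unname(g$isoforms[[1]]$exons),
               matrix(c(1L, 100L, 201L, 300L), 2, byrow = TRUE))
})

test_that("pseudogenes are flagged and excluded by the default pipeline", {
  path <- write_toy_gff(c(
    "Chr1\tt\tpseudogene\t1\t200\t.\t+\t.\tID=p1",
    "Chr1\tt\tmRNA\t1\t200\t.\t+\t.\tID=p1.t1;Parent=p1",
    "Chr1\tt\texon\t1\t200\t.\t+\t.\tParent=p1.t1"))
  genes <- parse_gene_models(path)
  expect_equal(genes[["p1"]]$gene_type, "pseudogene")
})

test_that("exons with unknown parents and overlapping exons are rejected", {
  orphan <- write_toy_gff(c(
    "Chr1\tt\tgene\t1\t300\t.\t+\t.\tID=g1",
    "Chr1\tt\texon\t1\t100\t.\t+\t.\tParent=gX.t9"))
  expect_error(parse_gene_models(orphan), "unknown Parent 'gX.t9'")
  overlap <- write_toy_gff(c(
    "Chr1\tt\tgene\t1\t300\t.\t+\t.\tID=g1",
    "Chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "Chr1\tt\texon\t1\t150\t.\t+\t.\tParent=g1.t1",
    "Chr1\tt\texon\t100\t300\t.\t+\t.\tParent=g1.t1"))
  expect_warning(genes <- parse_gene_models(overlap), "overlapping exons")
  expect_length(genes[["g1"]]$isoforms, 0)
})

test_that("introns are the gaps between consecutive exons", {
  expect_equal(unname(derive_introns(make_transcript("t", list(c(1, 100), c(201, 300))))),
               matrix(c(101L, 200L), 1))
  expect_equal(nrow(derive_introns(make_transcript("t", list(c(1, 300))))), 0)
  expect_equal(unname(derive_introns(
    make_transcript("t", list(c(1, 50), c(61, 90), c(101, 140))))),
    matrix(c(51L, 60L, 91L, 100L), 2, byrow = TRUE))
  expect_warning(
    got <- derive_introns(make_transcript("t", list(c(1, 100), c(101, 200)))),
    "abutting")
  expect_equal(nrow(got), 0)
})

test_that("exons and derived introns tile the transcript span", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    bounds <- sort(sample(1:500, 2 * n))
    ex <- matrix(bounds, ncol = 2, byrow = TRUE)
    tr <- make_transcript("t", split(t(ex), rep(1:n, each = 2)))
    introns <- suppressWarnings(derive_introns(tr))  # abutting pairs possible
    covered <- sort(c(unlist(apply(ex, 1, function(r) r[1]:r[2])),
                      if (nrow(introns)) unlist(apply(introns, 1, function(r) r[1]:r[2]))))
    expect_equal(covered, min(ex):max(ex))
  }
})

test_that("retention inside a sibling exon labels an intron RI", {
  g <- make_gene(isoforms = list(
    make_transcript("t1", list(c(1, 100), c(201, 300))),
    make_transcript("t2", list(c(1, 300)))))
  lab <- label_introns(g)
  expect_equal(lab$label, "RI")
  expect_equal(lab$start, 101L)
  expect_equal(lab$end, 200L)
})

test_that("introns spliced in every isoform are CSI, single-isoform included", {
  g <- make_gene(isoforms = list(
    make_transcript("t1", list(c(1, 100), c(201, 300)))))
  expect_equal(label_introns(g)$label, "CSI")
})

test_that("alternative 5' splice-site variants are ambiguous, not CSI", {
  g <- make_gene(isoforms = list(
    make_transcript("t1", list(c(1, 100), c(201, 300))),
    make_transcript("t2", list(c(1, 120), c(201, 300)))))
  lab <- label_introns(g)
  expect_setequal(lab$label, "ambiguous")
  expect_equal(nrow(lab), 2)
})

test_that("labels are invariant to isoform order", {
  isoforms <- list(
    make_transcript("t1", list(c(1, 100), c(201, 300), c(401, 500))),
    make_transcript("t2", list(c(1, 300), c(401, 500))),
    make_transcript("t3", list(c(1, 100), c(201, 500))))
  ref <- label_introns(make_gene(isoforms = isoforms))
  ref <- ref[order(ref$start, ref$end), c("start", "end", "label")]
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    got <- label_introns(make_gene(isoforms = isoforms[perm]))
    got <- got[order(got$start, got$end), c("start", "end", "label")]
    expect_equal(got, ref, ignore_attr = TRUE)
  }
})

test_that("redundant RIs collapse to the longest (leftmost on ties)", {
  expect_equal(deduplicate_redundant_ris(ri_table(list(c(101, 200), c(103, 198))))$start, 101)
  both <- deduplicate_redundant_ris(ri_table(list(c(101, 200), c(101, 260))))
  expect_equal(nrow(both), 2)
  ## three-way chain: pairwise diffs 4 and 8; transitive closure joins all;
  ## equal lengths so the leftmost survives (brute-force grouping agrees)
  chain <- deduplicate_redundant_ris(ri_table(list(c(101, 200), c(105, 204), c(109, 208))))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$start, 101)
})

test_that("deduplication is idempotent and strand-aware", {
  set.seed(7)
  for (strand in c("+", "-")) {
    coords <- lapply(1:8, function(i) {
      s <- sample(100:140, 1); c(s, s + sample(80:120, 1))
    })
    tab <- ri_table(coords, strand = strand)
    once <- deduplicate_redundant_ris(tab)
    expect_equal(deduplicate_redundant_ris(once), once)
  }
})

test_that("length filtering removes only out-of-range introns", {
  tab <- ri_table(list(c(1, 10), c(1, 150), c(1, 2075)))
  tab$label <- c("RI", "CSI", "RI")
  expect_message(kept <- filter_by_length(tab, min_len = 20, max_len = c(RI = 2000)),
                 "removed")
  expect_equal(kept$length, 150)
  expect_error(filter_by_length(tab, min_len = 0), "min_len")
  ## never removes an in-range intron
  expect_equal(filter_by_length(tab, min_len = 1)$length, c(10, 150, 2075))
})

test_that("length quantiles follow type-7 interpolation", {
  expect_equal(length_quantiles(1:100, 0.5)$bp, 50.5)
  expect_equal(length_quantiles(c(10, 20, 30, 40), 0.25)$bp, 17.5)
  x <- c(3, 14, 159, 26, 5)
  expect_equal(length_quantiles(x, c(0, 1))$bp, c(min(x), max(x)))
  expect_error(length_quantiles(numeric(0), 0.5), "no introns")
})

test_that("sequence windows slice correct genomic coordinates on the plus strand", {
  chrom <- toy_chromosome(400)
  genome <- toy_genome(list(Chr1 = chrom))
  tab <- ri_table(list(c(101, 200)))
  rec <- extract_sequences(genome, tab)
  expect_equal(rec$sequence, substr(chrom, 101, 200))
  expect_equal(rec$donor_pwm_window, substr(chrom, 98, 106))
  expect_equal(rec$acceptor_pwm_window, substr(chrom, 180, 202))
  expect_equal(rec$donor_exon_window, substr(chrom, 81, 100))
  expect_equal(rec$donor_intron_window, substr(chrom, 101, 120))
  expect_equal(rec$acceptor_intron_window, substr(chrom, 181, 200))
  expect_equal(rec$acceptor_exon_window, substr(chrom, 201, 220))
})

test_that("minus-strand extraction mirrors the plus strand exactly", {
  chrom <- toy_chromosome(400, seed = 9)
  plus <- extract_sequences(toy_genome(list(Chr1 = chrom)),
                            ri_table(list(c(101, 200))))
  ## mirrored genome: reverse complement; interval maps to (201, 300)
  mir <- revcomp_str(chrom)
  tabm <- ri_table(list(c(201, 300)), strand = "-")
  minus <- extract_sequences(toy_genome(list(Chr1 = mir)), tabm)
  for (cl in c("sequence", "donor_pwm_window", "acceptor_pwm_window",
               "donor_exon_window", "donor_intron_window",
               "acceptor_intron_window", "acceptor_exon_window")) {
    expect_equal(minus[[cl]], plus[[cl]], label = cl)
  }
})

test_that("exon-side windows truncate to short flanking exons", {
  chrom <- toy_chromosome(400)
  tab <- ri_table(list(c(101, 200)))
  tab$flank_up_len <- 5L
  tab$flank_down_len <- 0L
  rec <- extract_sequences(toy_genome(list(Chr1 = chrom)), tab)
  expect_equal(nchar(rec$donor_exon_window), 5)
  expect_equal(rec$acceptor_exon_window, "")
  out_of_bounds <- ri_table(list(c(390, 450)))
  expect_error(extract_sequences(toy_genome(list(Chr1 = chrom)), out_of_bounds),
               "outside chromosome bounds")
})

test_that("terminal dinucleotide fractions sum to one per class", {
  tab <- data.frame(
    sequence = c("gtaaag", "gtccag", "gtggag", "gcttag"),
    label = c("RI", "RI", "RI", "RI"))
  out <- terminal_dinucleotide_summary(tab)
  expect_equal(out$gt_ag, 0.75)
  expect_equal(out$gc_ag, 0.25)
  expect_equal(out$gt_ag + out$gc_ag + out$other, 1)
})
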