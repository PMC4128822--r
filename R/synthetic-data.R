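## Synthetic data with controllable class-conditional structure: direct
## generation of labeled intron records, and full toy genome + GFF3
## annotation with multi-isoform gene models containing retained introns.
##
## Default effect sizes mirror the contrasts reported for Arabidopsis
## introns: RIs slightly shorter and GC-richer (+3.3 GC points), with
## weaker donor/acceptor consensus, GC-rich planted motifs and flanking
## exons whose trimer composition is closer to the intron's; CSIs carry
## AT/TA-rich motifs and stronger splice signals.

revcomp_chr <- function(s) {
  chartr("acgt", "tgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulation configuration
#'
#' All class-conditional knobs of the generator.  Lengths are log-normal
#' with a median near 100 bp, clamped to `len_range`; per-class GC is
#' `gc_csi` (+ `gc_shift_ri` for RIs); splice windows are mutated copies
#' of plant-like donor (`caggtaagt`) and acceptor
#' (pyrimidine tract + `tgcag` + `gt`) consensus strings, with a higher
#' mutation rate for RIs; class-specific motif panels are planted at
#' `motif_rate` expected motifs per bp; exon-side windows are drawn from
#' a mixture of exon and intron base composition with mixture weight
#' `exon_intron_mix` (higher for RIs, making their flanks more
#' intron-like and their increments of diversity smaller).
#'
#' @param n_genes Number of genes for the genome simulator.
#' @param isoform_prob Probabilities of 1, 2 or 3 isoforms per gene.
#' @param exons_range Range of exon counts per isoform.
#' @param ri_probability Probability that an intron of a multi-isoform
#'   gene is designated retained.
#' @param ambiguous_rate Probability that an intron of a three-isoform
#'   gene is given an alternative-donor variant (labeled ambiguous).
#' @param len_meanlog_ri,len_meanlog_csi,len_sdlog,len_range Log-normal
#'   intron length parameters (bp).
#' @param gc_csi,gc_shift_ri Intron GC content of CSIs and the RI shift.
#' @param exon_gc Exon GC content.
#' @param splice_mut_ri,splice_mut_csi Per-position consensus mutation
#'   rates of the splice windows (terminal dinucleotides preserved).
#' @param gc_ag_rate_ri,gc_ag_rate_csi Fraction of introns starting `gc`
#'   instead of `gt`.
#' @param ri_motifs,csi_motifs Motif panels planted per class.
#' @param motif_rate Expected planted motifs per bp.
#' @param exon_intron_mix Named vector (`RI`, `CSI`): weight of intron
#'   composition in the flanking-exon windows.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60L,
                       isoform_prob = c(0.35, 0.45, 0.20),
                       exons_range = c(2L, 5L),
                       ri_probability = 0.3,
                       ambiguous_rate = 0.02,
                       len_meanlog_ri = log(95), len_meanlog_csi = log(105),
                       len_sdlog = 0.5, len_range = c(20L, 2000L),
                       gc_csi = 0.3243, gc_shift_ri = 0.0333,
                       exon_gc = 0.44,
                       splice_mut_ri = 0.35, splice_mut_csi = 0.20,
                       gc_ag_rate_ri = 0.026, gc_ag_rate_csi = 0.009,
                       ri_motifs = c("cg", "ccg", "cga", "cgg", "ggag",
                                     "gggt", "gaag", "ttcg"),
                       csi_motifs = c("atgt", "taat", "tatat", "atatt",
                                      "aaata", "ttata", "attat"),
                       motif_rate = 0.02,
                       exon_intron_mix = c(RI = 0.5, CSI = 0.15),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  probs <- c(isoform_prob, ri_probability, ambiguous_rate, gc_csi,
             gc_csi + gc_shift_ri, exon_gc, splice_mut_ri, splice_mut_csi,
             gc_ag_rate_ri, gc_ag_rate_csi, motif_rate, exon_intron_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (len_range[1] < 20L) stop("minimum intron length must be >= 20 bp")
  cfg
}

#' All class differences switched off (null configuration)
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` in which RI and CSI records are exchangeable.
#' @export
sim_config_null <- function(...) {
  null_args <- list(gc_shift_ri = 0, len_meanlog_ri = log(105),
                    splice_mut_ri = 0.20, gc_ag_rate_ri = 0.009,
                    motif_rate = 0,
                    exon_intron_mix = c(RI = 0.15, CSI = 0.15))
  do.call(sim_config, utils::modifyList(null_args, list(...)))
}

class_base_probs <- function(cfg, class) {
  gc <- cfg$gc_csi + if (class == "RI") cfg$gc_shift_ri else 0
  c(a = (1 - gc) / 2, c = gc / 2, g = gc / 2, t = (1 - gc) / 2)
}

exon_base_probs <- function(cfg) {
  c(a = (1 - cfg$exon_gc) / 2, c = cfg$exon_gc / 2,
    g = cfg$exon_gc / 2, t = (1 - cfg$exon_gc) / 2)
}

rand_bases <- function(n, probs) sample(names(probs), n, replace = TRUE, prob = probs)

## substitute each non-fixed position by one of the three other bases
mutate_consensus <- function(consensus, rate, fixed = integer(0)) {
  v <- strsplit(consensus, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  hit <- setdiff(hit, fixed)
  for (i in hit) v[i] <- sample(setdiff(c("a", "c", "g", "t"), v[i]), 1)
  v
}

donor_consensus <- function() "caggtaagt"                       # -3..+6
acceptor_consensus <- function() paste0(strrep("t", 16), "tgcag", "gt")  # -21..+2

## one intron record in transcription orientation; class "RI"/"CSI"
## ("ambiguous" uses CSI-conditional sequence structure)
gen_intron_record <- function(cfg, class) {
  scls <- if (class == "RI") "RI" else "CSI"
  mut <- if (scls == "RI") cfg$splice_mut_ri else cfg$splice_mut_csi
  gc_ag <- if (scls == "RI") cfg$gc_ag_rate_ri else cfg$gc_ag_rate_csi
  meanlog <- if (scls == "RI") cfg$len_meanlog_ri else cfg$len_meanlog_csi
  L <- as.integer(round(pmin(pmax(stats::rlnorm(1, meanlog, cfg$len_sdlog),
                                  cfg$len_range[1]), cfg$len_range[2])))
  probs <- class_base_probs(cfg, scls)
  seqv <- rand_bases(L, probs)

  ## plant class motifs in the core, clear of both splice contexts
  panel <- if (scls == "RI") cfg$ri_motifs else cfg$csi_motifs
  lo <- 7L; hi <- L - 22L
  if (cfg$motif_rate > 0 && hi - lo > 6L) {
    n_plant <- stats::rpois(1, cfg$motif_rate * L)
    for (m in sample(panel, n_plant, replace = TRUE)) {
      k <- nchar(m)
      at <- sample(lo:(hi - k + 1L), 1)
      seqv[at:(at + k - 1L)] <- strsplit(m, "")[[1]]
    }
  }

  dcons <- donor_consensus()
  acons <- acceptor_consensus()
  donor_in <- mutate_consensus(substr(dcons, 4, 9), mut, fixed = 1:2)
  donor_in[1:2] <- if (stats::runif(1) < gc_ag) c("g", "c") else c("g", "t")
  acc_in <- mutate_consensus(substr(acons, 1, 21), mut, fixed = 20:21)
  acc_in[20:21] <- c("a", "g")
  ## acceptor context first, donor second: at the minimum length (20 bp)
  ## the two contexts overlap and the donor side wins at the 5' end
  idx <- max(1L, L - 20L):L
  seqv[idx] <- acc_in[(21L - length(idx) + 1L):21L]
  seqv[1:6] <- donor_in

  mixw <- cfg$exon_intron_mix[[scls]]
  exon_probs <- (1 - mixw) * exon_base_probs(cfg) + mixw * probs
  don_ex <- rand_bases(20L, exon_probs)
  don_ex[18:20] <- mutate_consensus(substr(dcons, 1, 3), mut)
  acc_ex <- rand_bases(20L, exon_probs)
  acc_ex[1:2] <- mutate_consensus(substr(acons, 22, 23), mut)

  sequence <- paste(seqv, collapse = "")
  acc_win21 <- if (L >= 21L) substr(sequence, L - 20L, L) else
    paste0(paste(don_ex[(20L - (20L - L)):20L], collapse = ""), sequence)
  list(length = L, label = class, sequence = sequence,
       donor_pwm_window = paste0(paste(don_ex[18:20], collapse = ""),
                                 substr(sequence, 1, 6)),
       acceptor_pwm_window = paste0(acc_win21, paste(acc_ex[1:2], collapse = "")),
       donor_exon_window = paste(don_ex, collapse = ""),
       donor_intron_window = substr(sequence, 1, 20),
       acceptor_intron_window = substr(sequence, L - 19L, L),
       acceptor_exon_window = paste(acc_ex, collapse = ""))
}

#' Directly simulate labeled intron records
#'
#' Generates RI- and CSI-labeled intron records (sequence plus all six
#' windows, no genome) with the class-conditional structure of the
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @param n_ri,n_csi Number of records per class.
#' @return A data frame shaped like the output of [extract_sequences()]:
#'   columns `gene_id`, `chromosome`, `strand`, `start`, `end`, `length`,
#'   `label`, `flank_up_len`, `flank_down_len`, `sequence` and the six
#'   window columns.
#' @export
simulate_labeled_introns <- function(cfg, n_ri = 500L, n_csi = 500L) {
  set.seed(cfg$seed)
  recs <- c(lapply(seq_len(n_ri), function(i) gen_intron_record(cfg, "RI")),
            lapply(seq_len(n_csi), function(i) gen_intron_record(cfg, "CSI")))
  out <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  n <- nrow(out)
  data.frame(gene_id = sprintf("simgene%05d", seq_len(n)),
             chromosome = "sim", strand = "+",
             start = 1L, end = out$length,
             length = out$length, label = out$label,
             transcript_ids = "", flank_up_len = 20L, flank_down_len = 20L,
             out[, c("sequence", "donor_pwm_window", "acceptor_pwm_window",
                     "donor_exon_window", "donor_intron_window",
                     "acceptor_intron_window", "acceptor_exon_window")],
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome with multi-isoform annotation
#'
#' Builds gene models of 1-3 isoforms on two chromosomes.  Introns
#' designated retained appear spliced in the primary isoform and inside a
#' merged exon of a second isoform; three-isoform genes may carry an
#' alternative-donor variant (intended label `ambiguous`).  Writes an
#' uncompressed genome FASTA, a GFF3 annotation (gene -> mRNA -> exon)
#' and a truth table of every intron's intended label, and the outputs
#' round-trip through [extract_introns()].
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed; default a fresh
#'   temporary directory).
#' @return List with `genome_file`, `gff3_file`, `truth_file` and `truth`
#'   (data frame: `gene_id`, `chromosome`, `strand`, `start`, `end`,
#'   `label`).
#' @export
simulate_genome_annotation <- function(cfg, out_dir = tempfile("simdata")) {
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- c("Chr1", "Chr2")
  chrom_seq <- stats::setNames(rep("", 2), chroms)
  inter_probs <- c(a = 0.34, c = 0.16, g = 0.16, t = 0.34)
  gff <- character(0)
  truth <- list()

  for (gi in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%04d", gi)
    chrom <- sample(chroms, 1)
    strand <- sample(c("+", "-"), 1)
    n_iso <- sample(1:3, 1, prob = cfg$isoform_prob)
    n_ex <- sample(cfg$exons_range[1]:cfg$exons_range[2], 1)
    n_int <- n_ex - 1L

    cls <- character(n_int)
    for (j in seq_len(n_int)) {
      cls[j] <- if (n_iso >= 2 && stats::runif(1) < cfg$ri_probability) "RI"
        else if (n_iso == 3 && stats::runif(1) < cfg$ambiguous_rate) "ambiguous"
        else "CSI"
    }
    introns <- lapply(cls, function(cl) gen_intron_record(cfg, cl))
    cls[cls == "ambiguous" & vapply(introns, `[[`, 0L, "length") < 60L] <- "CSI"

    exon_len <- sample(80:200, n_ex, replace = TRUE)
    exons <- lapply(exon_len, function(l) rand_bases(l, exon_base_probs(cfg)))
    for (j in seq_len(n_int)) {
      r <- introns[[j]]
      el <- exon_len[j]
      exons[[j]][(el - 19L):el] <- strsplit(r$donor_exon_window, "")[[1]]
      exons[[j + 1L]][1:20] <- strsplit(r$acceptor_exon_window, "")[[1]]
    }

    ## transcription-local layout
    pieces <- character(2 * n_ex - 1L)
    pieces[seq(1, by = 2, length.out = n_ex)] <-
      vapply(exons, paste, "", collapse = "")
    if (n_int > 0)
      pieces[seq(2, by = 2, length.out = n_int)] <-
        vapply(introns, `[[`, "", "sequence")
    gene_seq <- paste(pieces, collapse = "")
    Lg <- nchar(gene_seq)
    piece_len <- nchar(pieces)
    piece_end <- cumsum(piece_len)
    piece_start <- piece_end - piece_len + 1L
    ex_loc <- cbind(piece_start[seq(1, by = 2, length.out = n_ex)],
                    piece_end[seq(1, by = 2, length.out = n_ex)])
    int_loc <- if (n_int > 0)
      cbind(piece_start[seq(2, by = 2, length.out = n_int)],
            piece_end[seq(2, by = 2, length.out = n_int)]) else
      matrix(integer(0), 0, 2)

    ## isoform exon structures in local coordinates
    iso_exons <- list(ex_loc)
    if (n_iso >= 2) {
      ret <- which(cls == "RI")
      if (length(ret) == 0L) iso_exons[[2]] <- ex_loc else {
        keep_introns <- setdiff(seq_len(n_int), ret)
        bounds <- sort(c(1L, Lg,
                         int_loc[keep_introns, 1] - 1L, int_loc[keep_introns, 2] + 1L))
        iso_exons[[2]] <- matrix(bounds, ncol = 2, byrow = TRUE)
      }
    }
    if (n_iso >= 3) {
      amb <- which(cls == "ambiguous")
      ex3 <- ex_loc
      if (length(amb) > 0L) {
        j <- amb[1]
        ex3[j, 2] <- ex3[j, 2] + 9L    # alternative donor 9 nt downstream
      }
      iso_exons[[3]] <- ex3
    }

    ## place the gene on its chromosome
    gap <- paste(rand_bases(sample(100:300, 1), inter_probs), collapse = "")
    offset <- nchar(chrom_seq[[chrom]]) + nchar(gap) + 1L
    placed <- if (strand == "-") revcomp_chr(gene_seq) else gene_seq
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], gap, placed)

    to_genomic <- function(loc) {
      if (strand == "-")
        cbind(offset + Lg - loc[, 2], offset + Lg - loc[, 1])
      else
        cbind(offset + loc[, 1] - 1L, offset + loc[, 2] - 1L)
    }
    g_span <- c(offset, offset + Lg - 1L)
    gff <- c(gff, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          chrom, g_span[1], g_span[2], strand, gid))
    for (k in seq_len(n_iso)) {
      tid <- sprintf("%s.t%d", gid, k)
      gff <- c(gff, sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            chrom, g_span[1], g_span[2], strand, tid, gid))
      gex <- to_genomic(iso_exons[[k]])
      gex <- gex[order(gex[, 1]), , drop = FALSE]
      gff <- c(gff, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            chrom, gex[, 1], gex[, 2], strand, tid))
    }
    if (n_int > 0) {
      gint <- to_genomic(int_loc)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, chromosome = chrom, strand = strand,
        start = pmin(gint[, 1], gint[, 2]), end = pmax(gint[, 1], gint[, 2]),
        label = cls, stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(toupper(unlist(chrom_seq)))
  names(genome) <- chroms
  genome_file <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_file)
  gff3_file <- file.path(out_dir, "annotation.gff3")
  writeLines(c("##gff-version 3", gff), gff3_file)
  truth <- do.call(rbind, truth)
  truth_file <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(genome_file = genome_file, gff3_file = gff3_file,
       truth_file = truth_file, truth = truth)
}
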