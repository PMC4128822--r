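## Annotation parsing, intron derivation and RI/CSI labeling.
##
## Coordinates are GFF3-native throughout: 1-based, inclusive on both ends.
## All sequences are reported in transcription (spliced) orientation, i.e.
## reverse-complemented genomic slices on the minus strand.

#' Parse gene models from a GFF3 file
#'
#' Reads a TAIR10-style GFF3 (gene -> RNA -> exon hierarchy linked by
#' `Parent` attributes) and returns one gene model per gene.  Pseudogenes
#' and transposable-element genes are flagged via `gene_type` so callers
#' can exclude them; exon lists are sorted by start.
#'
#' @param gff3_file Path to a GFF3 file.
#' @return A list of `gene_model` objects, each a list with elements
#'   `gene_id`, `chromosome`, `strand`, `gene_type` (one of
#'   `"protein_coding"`, `"pseudogene"`, `"transposable_element"`,
#'   `"other"`) and `isoforms` (a list of transcripts, each with
#'   `transcript_id`, `rna_type` and an `exons` two-column matrix of
#'   1-based inclusive start/end coordinates).
#' @details Transcripts whose exons overlap one another are rejected with
#'   a warning; an exon whose `Parent` does not resolve to any RNA feature
#'   is an error naming the offending feature.
#' @export
parse_gene_models <- function(gff3_file) {
  gff <- rtracklayer::readGFF(gff3_file)
  gff$type <- as.character(gff$type)
  ids <- if ("ID" %in% names(gff)) as.character(gff$ID) else rep(NA_character_, nrow(gff))
  parents <- if ("Parent" %in% names(gff)) gff$Parent else replicate(nrow(gff), character(0), simplify = FALSE)

  gene_types <- c(gene = "protein_coding",
                  pseudogene = "pseudogene",
                  transposable_element_gene = "transposable_element")
  is_gene <- gff$type %in% c(names(gene_types)) |
    (gff$type != "exon" & lengths(parents) == 0 & !is.na(ids))
  gene_rows <- which(is_gene)
  gene_ids <- ids[gene_rows]
  if (anyNA(gene_ids)) stop("gene feature without an ID attribute")

  ## RNA features: non-exon rows whose Parent is a gene
  rna_rows <- which(gff$type != "exon" & lengths(parents) > 0 &
                      vapply(parents, function(p) any(p %in% gene_ids), logical(1)))
  rna_ids <- ids[rna_rows]
  if (anyNA(rna_ids)) stop("RNA feature without an ID attribute")
  rna_parent <- vapply(parents[rna_rows], function(p) p[p %in% gene_ids][1], character(1))

  exon_rows <- which(gff$type == "exon")
  exon_parents <- parents[exon_rows]
  unknown <- vapply(exon_parents, function(p) !any(p %in% rna_ids), logical(1))
  if (any(unknown)) {
    bad <- exon_rows[which(unknown)[1]]
    stop(sprintf("exon at %s:%d-%d has unknown Parent '%s'",
                 as.character(gff$seqid[bad]), gff$start[bad], gff$end[bad],
                 paste(parents[[bad]], collapse = ",")))
  }

  ## exon table keyed by transcript (an exon row may serve several parents)
  exon_tx <- rep(seq_along(exon_rows), lengths(exon_parents))
  exon_map <- data.frame(
    tx = unlist(exon_parents),
    start = gff$start[exon_rows][exon_tx],
    end = gff$end[exon_rows][exon_tx],
    stringsAsFactors = FALSE
  )
  exon_map <- exon_map[exon_map$tx %in% rna_ids, , drop = FALSE]

  genes <- vector("list", length(gene_rows))
  names(genes) <- gene_ids
  for (i in seq_along(gene_rows)) {
    g <- gene_rows[i]
    gid <- gene_ids[i]
    iso_idx <- which(rna_parent == gid)
    isoforms <- list()
    for (j in iso_idx) {
      tid <- rna_ids[j]
      ex <- exon_map[exon_map$tx == tid, c("start", "end"), drop = FALSE]
      if (nrow(ex) == 0L) next
      if (any(ex$start > ex$end)) {
        warning(sprintf("transcript %s has an exon with start > end; rejected", tid))
        next
      }
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        warning(sprintf("transcript %s has overlapping exons; rejected", tid))
        next
      }
      isoforms[[length(isoforms) + 1L]] <- list(
        transcript_id = tid,
        rna_type = gff$type[rna_rows[j]],
        exons = as.matrix(ex)
      )
    }
    gtype <- gene_types[gff$type[g]]
    if (is.na(gtype)) gtype <- "other"
    genes[[i]] <- structure(list(
      gene_id = gid,
      chromosome = as.character(gff$seqid[g]),
      strand = as.character(gff$strand[g]),
      gene_type = unname(gtype),
      isoforms = isoforms
    ), class = "gene_model")
  }
  genes
}

#' Derive intron coordinates from a transcript's exons
#'
#' Introns are the maximal gaps between consecutive exons:
#' `(exon_i end + 1, exon_{i+1} start - 1)`.  Abutting exons (no gap)
#' yield no intron and raise a warning.
#'
#' @param transcript A transcript element of a gene model (list with an
#'   `exons` matrix), or a bare two-column matrix of sorted exons.
#' @return A two-column matrix (`start`, `end`) with one row per intron;
#'   zero rows for single-exon transcripts.
#' @export
derive_introns <- function(transcript) {
  ex <- if (is.matrix(transcript)) transcript else transcript$exons
  n <- nrow(ex)
  if (n < 2L) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  starts <- ex[-n, 2] + 1L
  ends <- ex[-1, 1] - 1L
  keep <- starts <= ends
  if (!all(keep)) warning("abutting exons produce a zero-length intron; dropped")
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Label a gene's introns as RI, CSI or ambiguous
#'
#' An intron interval is a retained intron (RI) if it is an intron of some
#' isoform and lies fully within a single exon of another isoform of the
#' same gene.  It is constitutively spliced (CSI) if it is never fully
#' contained in any sibling isoform's exon and every sibling isoform whose
#' genomic span covers the interval carries the identical interval as an
#' intron.  Everything else (alternative donor/acceptor variants and the
#' like) is `"ambiguous"` and excluded from both classes downstream.
#'
#' @param gene A `gene_model`.
#' @return A data frame with one row per distinct intron interval:
#'   `gene_id`, `chromosome`, `strand`, `start`, `end`, `length`, `label`,
#'   `transcript_ids` (comma-separated isoforms carrying it as an intron),
#'   and `flank_up_len` / `flank_down_len`, the lengths of the flanking
#'   exons in (the first of) those isoforms, in transcription orientation.
#' @export
label_introns <- function(gene) {
  iso <- gene$isoforms
  empty <- data.frame(gene_id = character(0), chromosome = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      length = integer(0), label = character(0),
                      transcript_ids = character(0),
                      flank_up_len = integer(0), flank_down_len = integer(0),
                      stringsAsFactors = FALSE)
  if (length(iso) == 0L) return(empty)
  per_iso <- lapply(iso, derive_introns)
  spans <- t(vapply(iso, function(tr) c(min(tr$exons[, 1]), max(tr$exons[, 2])),
                    numeric(2)))

  key <- unique(do.call(rbind, per_iso))
  if (is.null(key) || nrow(key) == 0L) return(empty)
  key <- key[order(key[, 1], key[, 2]), , drop = FALSE]

  n <- nrow(key)
  label <- character(n)
  tx_ids <- character(n)
  fup <- integer(n); fdn <- integer(n)
  for (i in seq_len(n)) {
    s <- key[i, 1]; e <- key[i, 2]
    hosts <- which(vapply(per_iso, function(m) any(m[, 1] == s & m[, 2] == e), logical(1)))
    contained <- FALSE
    csi_ok <- TRUE
    for (j in seq_along(iso)) {
      ex <- iso[[j]]$exons
      if (any(ex[, 1] <= s & ex[, 2] >= e)) contained <- TRUE
      if (spans[j, 1] <= s && spans[j, 2] >= e && !(j %in% hosts)) csi_ok <- FALSE
    }
    label[i] <- if (contained) "RI" else if (csi_ok) "CSI" else "ambiguous"
    tx_ids[i] <- paste(vapply(iso[hosts], `[[`, "", "transcript_id"), collapse = ",")
    host <- iso[[hosts[1]]]$exons
    up_g <- host[host[, 2] == s - 1L, , drop = FALSE]   # genomic-left exon
    dn_g <- host[host[, 1] == e + 1L, , drop = FALSE]   # genomic-right exon
    left_len <- if (nrow(up_g)) up_g[1, 2] - up_g[1, 1] + 1L else 0L
    right_len <- if (nrow(dn_g)) dn_g[1, 2] - dn_g[1, 1] + 1L else 0L
    if (identical(gene$strand, "-")) {
      fup[i] <- right_len; fdn[i] <- left_len
    } else {
      fup[i] <- left_len; fdn[i] <- right_len
    }
  }
  data.frame(gene_id = gene$gene_id, chromosome = gene$chromosome,
             strand = gene$strand, start = as.integer(key[, 1]),
             end = as.integer(key[, 2]),
             length = as.integer(key[, 2] - key[, 1] + 1L),
             label = label, transcript_ids = tx_ids,
             flank_up_len = fup, flank_down_len = fdn,
             stringsAsFactors = FALSE)
}

#' Collapse redundant retained introns
#'
#' RIs of the same gene whose 5' splice sites AND 3' splice sites each
#' differ by fewer than `max_diff` bp are considered redundant variants of
#' one splice event; only the longest member of each (transitively closed)
#' group is kept, ties broken toward the smallest start coordinate.
#'
#' @param ris A data frame of introns labeled `"RI"` (as from
#'   [label_introns()]), all from one gene.
#' @param max_diff Splice-site difference below which two RIs are
#'   redundant (default 6 bp).
#' @return The input with redundant rows removed.
#' @export
deduplicate_redundant_ris <- function(ris, max_diff = 6L) {
  if (nrow(ris) <= 1L) return(ris)
  stopifnot(all(ris$label == "RI"))
  minus <- ris$strand == "-"
  five <- ifelse(minus, ris$end, ris$start)    # 5' splice site (transcription)
  three <- ifelse(minus, ris$start, ris$end)
  n <- nrow(ris)
  ## transitive closure over the redundancy relation (union-find)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(five[i] - five[j]) < max_diff && abs(three[i] - three[j]) < max_diff) {
      comp[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- unlist(lapply(split(seq_len(n), root), function(idx) {
    idx[order(-ris$length[idx], ris$start[idx])][1]
  }))
  ris[sort(keep), , drop = FALSE]
}

#' Filter introns by length
#'
#' Removes introns shorter than `min_len` or (when `max_len` is set)
#' longer than `max_len`; removal counts are reported per label class via
#' `message()`.
#'
#' @param introns Intron data frame with `length` and `label` columns.
#' @param min_len Minimum length in bp (default 20).
#' @param max_len Optional maximum length in bp (`NA` = no upper cut).
#'   May be a single value or a named vector like `c(RI = 2000, CSI = 7000)`
#'   applying per class.
#' @return The filtered data frame.
#' @export
filter_by_length <- function(introns, min_len = 20L, max_len = NA) {
  if (!is.numeric(min_len) || min_len < 1) stop("min_len must be >= 1")
  drop <- introns$length < min_len
  if (!all(is.na(max_len))) {
    if (!is.null(names(max_len))) {
      for (cls in names(max_len)) {
        if (!is.na(max_len[[cls]]))
          drop <- drop | (introns$label == cls & introns$length > max_len[[cls]])
      }
    } else {
      drop <- drop | introns$length > max_len
    }
  }
  if (any(drop)) {
    tab <- table(introns$label[drop])
    message("filter_by_length removed: ",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "))
  }
  introns[!drop, , drop = FALSE]
}

#' Intron length quantiles
#'
#' Type-7 (linear interpolation of order statistics) quantiles of the
#' intron length distribution, the default of R's `quantile()`.
#'
#' @param introns Intron data frame with a `length` column, or a numeric
#'   vector of lengths.
#' @param probs Probabilities in `[0, 1]`.
#' @return A data frame with columns `prob` and `bp`.
#' @export
length_quantiles <- function(introns, probs = c(0.02, 0.2, 0.4, 0.6, 0.8, 0.98)) {
  len <- if (is.numeric(introns)) introns else introns$length
  if (length(len) == 0L) stop("no introns supplied")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  data.frame(prob = probs, bp = unname(stats::quantile(len, probs, type = 7)))
}

## slice [tstart, tend] in transcription coordinates relative to an intron
## (1 = first intron base; 0, -1, ... upstream exon; length+1 ... downstream)
txn_slice <- function(chrom_seq, strand, istart, iend, tstart, tend) {
  if (strand == "-") {
    gstart <- iend - tend + 1L
    gend <- iend - tstart + 1L
  } else {
    gstart <- istart + tstart - 1L
    gend <- istart + tend - 1L
  }
  if (gstart < 1L || gend > length(chrom_seq))
    stop(sprintf("window %d..%d outside chromosome bounds", gstart, gend))
  s <- Biostrings::subseq(chrom_seq, gstart, gend)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  tolower(as.character(s))
}

#' Extract intron sequence and splice-site windows from the genome
#'
#' Populates, in transcription orientation, the full intron sequence plus
#' six windows per intron: the 9-nt donor PWM window (last 3 exonic nt +
#' first 6 intronic nt), the 23-nt acceptor PWM window (last 21 intronic
#' nt + first 2 exonic nt), and four 20-nt increment-of-diversity windows
#' (exon side and intron side at each splice site).  Exon-side windows are
#' truncated to the available flanking-exon length; intron-side windows
#' are taken from within the intron.  For introns shorter than the 21-nt
#' acceptor context the acceptor window simply extends into the upstream
#' exon (no padding characters are ever introduced).
#'
#' @param genome A `DNAStringSet` (as from [Biostrings::readDNAStringSet()])
#'   or the path to a FASTA file.  Record names must match chromosome names
#'   up to the first whitespace.
#' @param introns Intron data frame (from [label_introns()] /
#'   [filter_by_length()]) with `flank_up_len` / `flank_down_len` columns.
#' @return The input data frame with character columns `sequence`,
#'   `donor_pwm_window`, `acceptor_pwm_window`, `donor_exon_window`,
#'   `donor_intron_window`, `acceptor_intron_window`, `acceptor_exon_window`
#'   appended.
#' @export
extract_sequences <- function(genome, introns) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  n <- nrow(introns)
  cols <- c("sequence", "donor_pwm_window", "acceptor_pwm_window",
            "donor_exon_window", "donor_intron_window",
            "acceptor_intron_window", "acceptor_exon_window")
  for (cl in cols) introns[[cl]] <- character(n)
  for (i in seq_len(n)) {
    chrom <- introns$chromosome[i]
    if (!chrom %in% names(genome))
      stop(sprintf("chromosome '%s' not in genome (intron %s:%d-%d)",
                   chrom, chrom, introns$start[i], introns$end[i]))
    cs <- genome[[chrom]]
    st <- introns$strand[i]; s <- introns$start[i]; e <- introns$end[i]
    if (s < 1L || e > length(cs))
      stop(sprintf("intron %s:%d-%d outside chromosome bounds", chrom, s, e))
    L <- e - s + 1L
    up <- min(20L, introns$flank_up_len[i])
    dn <- min(20L, introns$flank_down_len[i])
    introns$sequence[i] <- txn_slice(cs, st, s, e, 1L, L)
    introns$donor_pwm_window[i] <- txn_slice(cs, st, s, e, -2L, 6L)
    introns$acceptor_pwm_window[i] <- txn_slice(cs, st, s, e, L - 20L, L + 2L)
    introns$donor_exon_window[i] <-
      if (up >= 1L) txn_slice(cs, st, s, e, 1L - up, 0L) else ""
    introns$donor_intron_window[i] <- txn_slice(cs, st, s, e, 1L, min(20L, L))
    introns$acceptor_intron_window[i] <- txn_slice(cs, st, s, e, max(1L, L - 19L), L)
    introns$acceptor_exon_window[i] <-
      if (dn >= 1L) txn_slice(cs, st, s, e, L + 1L, L + dn) else ""
  }
  introns
}

#' Terminal dinucleotide summary per intron class
#'
#' Fractions of GT-AG, GC-AG and other terminal dinucleotide combinations
#' among each label class.
#'
#' @param introns Intron data frame with `sequence` and `label` columns.
#' @return A data frame with columns `label`, `gt_ag`, `gc_ag`, `other`;
#'   fractions within each class sum to 1.
#' @export
terminal_dinucleotide_summary <- function(introns) {
  first2 <- substr(introns$sequence, 1L, 2L)
  last2 <- substring(introns$sequence, nchar(introns$sequence) - 1L)
  cls <- ifelse(first2 == "gt" & last2 == "ag", "gt_ag",
                ifelse(first2 == "gc" & last2 == "ag", "gc_ag", "other"))
  out <- do.call(rbind, lapply(split(cls, introns$label), function(x) {
    c(gt_ag = mean(x == "gt_ag"), gc_ag = mean(x == "gc_ag"),
      other = mean(x == "other"))
  }))
  data.frame(label = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Extract, label and filter introns from annotation plus genome
#'
#' End-to-end wrapper: parse gene models, keep the requested gene/RNA
#' types, label every intron interval by comparing isoforms, collapse
#' redundant RIs, slice all sequences and windows from the genome, drop
#' records containing ambiguous (non-ACGT) letters, and apply the length
#' filter.
#'
#' @param gff3_file GFF3 annotation path.
#' @param genome_file FASTA genome path (or a `DNAStringSet`).
#' @param min_len,max_len Passed to [filter_by_length()].
#' @param keep_all_rna_types Keep introns of every RNA type and chromosome
#'   (default `FALSE`: mRNA introns on non-organelle chromosomes only;
#'   chromosomes named `ChrC`/`ChrM` are treated as organellar).
#' @param keep_ambiguous Keep introns labeled `"ambiguous"` (default
#'   `FALSE`).
#' @return Intron data frame with sequences and windows, RI rows
#'   deduplicated and length-filtered.
#' @export
extract_introns <- function(gff3_file, genome_file, min_len = 20L,
                            max_len = NA, keep_all_rna_types = FALSE,
                            keep_ambiguous = FALSE) {
  genes <- parse_gene_models(gff3_file)
  genes <- Filter(function(g) g$gene_type != "pseudogene", genes)
  if (!keep_all_rna_types) {
    genes <- Filter(function(g) !g$chromosome %in% c("ChrC", "ChrM"), genes)
    genes <- lapply(genes, function(g) {
      g$isoforms <- Filter(function(tr) tr$rna_type == "mRNA", g$isoforms)
      g
    })
  }
  labeled <- lapply(genes, function(g) {
    if (length(g$isoforms) == 0L) return(NULL)
    tab <- label_introns(g)
    ri <- tab[tab$label == "RI", , drop = FALSE]
    if (nrow(ri) > 1L) {
      tab <- rbind(deduplicate_redundant_ris(ri),
                   tab[tab$label != "RI", , drop = FALSE])
    }
    tab
  })
  introns <- do.call(rbind, labeled)
  if (is.null(introns) || nrow(introns) == 0L)
    stop("no introns derived from the annotation")
  rownames(introns) <- NULL
  if (!keep_ambiguous) introns <- introns[introns$label != "ambiguous", , drop = FALSE]
  introns <- extract_sequences(genome_file, introns)
  clean <- !grepl("[^acgt]", paste0(introns$sequence, introns$donor_pwm_window,
                                    introns$acceptor_pwm_window,
                                    introns$donor_exon_window,
                                    introns$acceptor_exon_window))
  if (any(!clean))
    message(sum(!clean), " intron(s) dropped: non-ACGT letters in sequence or windows")
  introns <- introns[clean, , drop = FALSE]
  filter_by_length(introns, min_len = min_len, max_len = max_len)
}
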