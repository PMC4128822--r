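# In-code fixtures: toy gene models, GFF3 text and genomes.

make_transcript <- function(id, exons, rna_type = "mRNA") {
  ex <- matrix(as.integer(unlist(exons)), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  list(transcript_id = id, rna_type = rna_type, exons = ex)
}

make_gene <- function(gene_id = "g1", chromosome = "Chr1", strand = "+",
                      gene_type = "protein_coding", isoforms = list()) {
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 gene_type = gene_type, isoforms = isoforms),
            class = "gene_model")
}

write_toy_gff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

## deterministic toy chromosome of given length
toy_chromosome <- function(n, seed = 42) {
  set.seed(seed)
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  names(g) <- names(seqs)
  g
}

revcomp_str <- function(s) {
  chartr("acgt", "tgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## minimal intron record table for dedup/filter tests
ri_table <- function(coords, strand = "+", gene_id = "g1") {
  data.frame(gene_id = gene_id, chromosome = "Chr1", strand = strand,
             start = vapply(coords, `[`, 0, 1),
             end = vapply(coords, `[`, 0, 2),
             length = vapply(coords, function(x) x[2] - x[1] + 1, 0),
             label = "RI", transcript_ids = "t1",
             flank_up_len = 50L, flank_down_len = 50L,
             stringsAsFactors = FALSE)
}
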