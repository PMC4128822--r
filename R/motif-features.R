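## Contrastive k-mer motif statistics.  For each k-mer w (2 <= k <= 5):
## Fre  = dataset frequency: total occurrences over total sliding windows;
## Conf = fraction of sequences of the set containing w at least once;
## D    = (fre_csi - fre_ri) / (fre_csi + fre_ri), the signed relative
##        difference (positive = CSI-enriched, bounded in [-1, 1]).
## Frequent motifs are those with high Conf in at least one class and
## |D| above a threshold.

kmer_count_matrix <- function(sequences, k) {
  ss <- Biostrings::DNAStringSet(toupper(sequences))
  cnt <- Biostrings::oligonucleotideFrequency(ss, width = k, step = 1L)
  colnames(cnt) <- tolower(colnames(cnt))
  cnt
}

#' Sliding-window k-mer frequencies of one sequence
#'
#' Counts every k-mer among the `L - k + 1` windows (step 1) and divides
#' by the window count, so the frequencies of the observed k-mers sum
#' to 1.
#'
#' @param sequence Lowercase ACGT string.
#' @param k Word size, 2 to 5.
#' @return Named numeric vector over the k-mers present in the sequence
#'   (absent k-mers are omitted).  A sequence shorter than `k` yields an
#'   empty vector with a warning.
#' @export
kmer_frequencies <- function(sequence, k) {
  if (k < 2L || k > 5L) stop("k must be between 2 and 5")
  L <- nchar(sequence)
  if (L < k) {
    warning("sequence shorter than k; returning empty frequency map")
    return(stats::setNames(numeric(0), character(0)))
  }
  cnt <- kmer_count_matrix(sequence, k)[1, ]
  cnt <- cnt[cnt > 0]
  cnt / (L - k + 1L)
}

#' Contrastive motif statistics over two labeled sequence sets
#'
#' For every k-mer observed in either set (word sizes `k_range`), computes
#' the per-dataset frequency (total occurrences divided by total window
#' count), the per-dataset confidence (fraction of sequences containing
#' the k-mer) and the signed relative difference
#' `D = (fre_csi - fre_ri) / (fre_csi + fre_ri)` (0 when both
#' frequencies are 0).  Positive `D` means the k-mer is more frequent in
#' CSIs.
#'
#' @param ris,csis Character vectors of RI and CSI sequences.
#' @param k_range Word sizes (default `2:5`; the mean frequency of longer
#'   words is too low to be informative).
#' @return Data frame with columns `motif`, `k`, `fre_ri`, `fre_csi`,
#'   `conf_ri`, `conf_csi`, `d`.
#' @export
dataset_motif_stats <- function(ris, csis, k_range = 2:5) {
  if (length(ris) == 0L || length(csis) == 0L)
    stop("both sequence sets must be non-empty")
  one_k <- function(k) {
    r <- ris[nchar(ris) >= k]; c <- csis[nchar(csis) >= k]
    cnt_r <- kmer_count_matrix(r, k)
    cnt_c <- kmer_count_matrix(c, k)
    win_r <- sum(nchar(r) - k + 1L)
    win_c <- sum(nchar(c) - k + 1L)
    fre_r <- colSums(cnt_r) / win_r
    fre_c <- colSums(cnt_c) / win_c
    seen <- fre_r > 0 | fre_c > 0
    d <- ifelse(fre_r + fre_c > 0, (fre_c - fre_r) / (fre_c + fre_r), 0)
    data.frame(motif = colnames(cnt_r)[seen], k = k,
               fre_ri = unname(fre_r[seen]), fre_csi = unname(fre_c[seen]),
               conf_ri = unname(colMeans(cnt_r[, seen, drop = FALSE] > 0)),
               conf_csi = unname(colMeans(cnt_c[, seen, drop = FALSE] > 0)),
               d = unname(d[seen]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(k_range, one_k))
  rownames(out) <- NULL
  out
}

#' Select frequent contrastive motifs
#'
#' Keeps k-mers confidently present in at least one class
#' (`max(conf_ri, conf_csi) >= conf_min`) and with class contrast
#' `|D| >= d_min`, sorted by `|D|` descending (ties alphabetical).
#'
#' @param stats Data frame from [dataset_motif_stats()].
#' @param conf_min Minimum confidence in at least one class (default 0.8).
#' @param d_min Minimum `|D|` (default 0.1).
#' @return Character vector of selected motifs, most contrastive first.
#' @export
select_frequent_motifs <- function(stats, conf_min = 0.8, d_min = 0.1) {
  keep <- pmax(stats$conf_ri, stats$conf_csi) >= conf_min & abs(stats$d) >= d_min
  sel <- stats[keep, , drop = FALSE]
  sel$motif[order(-abs(sel$d), sel$motif)]
}

#' Motif frequency feature values of one sequence
#'
#' The per-sequence sliding-window frequency of each motif in `motifs`
#' (0 when absent), in the given order.  The default is the 19-motif
#' frequent-motif panel of [motif_preset_b()].
#'
#' @param sequence Lowercase ACGT string.
#' @param motifs Ordered character vector of motifs.
#' @return Named numeric vector, one value per motif.
#' @export
motif_feature_vector <- function(sequence, motifs = motif_preset_b()) {
  ks <- nchar(motifs)
  out <- stats::setNames(numeric(length(motifs)), motifs)
  for (k in unique(ks)) {
    freq <- suppressWarnings(kmer_frequencies(sequence, k))
    hit <- motifs[ks == k]
    out[hit] <- ifelse(hit %in% names(freq), freq[hit], 0)
  }
  out
}

#' Mean contrast of a motif family
#'
#' Arithmetic mean of `D` over the motifs selected by a predicate, e.g.
#' all 3-5-mers containing `"ggg"` or all at/ta-rich 4-5-mers.  Used to
#' summarize putative splicing-regulatory families.
#'
#' @param stats Data frame from [dataset_motif_stats()].
#' @param family Either a predicate `function(motif) logical` or a
#'   character vector of motifs.
#' @return The mean `D` of the family.
#' @export
family_mean_d <- function(stats, family) {
  sel <- if (is.function(family)) vapply(stats$motif, family, logical(1))
         else stats$motif %in% family
  if (!any(sel)) stop("family predicate selects no motif")
  mean(stats$d[sel])
}
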