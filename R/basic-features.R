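## Global and segmental nucleotide-composition features (the 14 "A"
## features): length, AT/GC content, the four base probabilities, six
## pairwise segmental correlation factors and one segmental heterogeneity
## factor computed over consecutive 20-bp sections.

BASES <- c("a", "c", "g", "t")

check_acgt <- function(sequence) {
  bad <- regexpr("[^acgt]", sequence)
  if (bad > 0L)
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  invisible(sequence)
}

#' Per-section base probabilities
#'
#' Splits a sequence into consecutive sections of `section_len` bases (the
#' last section keeps the remainder, so `m = ceiling(L / section_len)`)
#' and returns the A/C/G/T probability profile of each section,
#' normalized by the section's true length.
#'
#' @param sequence A lowercase ACGT string of length >= 1.
#' @param section_len Section width in bp; 20 by default, the length of
#'   the shortest intron admitted by the pipeline.
#' @return An object of class `section_profile`: a list with `m` (section
#'   count) and `section_probs`, an `m x 4` matrix with columns
#'   `a`, `c`, `g`, `t`, each row summing to 1.
#' @export
section_probabilities <- function(sequence, section_len = 20L) {
  sequence <- tolower(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence")
  check_acgt(sequence)
  m <- ceiling(L / section_len)
  starts <- (seq_len(m) - 1L) * section_len + 1L
  ends <- pmin(starts + section_len - 1L, L)
  probs <- t(vapply(seq_len(m), function(j) {
    sec <- strsplit(substr(sequence, starts[j], ends[j]), "")[[1]]
    tab <- table(factor(sec, levels = BASES))
    as.numeric(tab) / length(sec)
  }, numeric(4)))
  colnames(probs) <- BASES
  structure(list(m = m, section_probs = probs), class = "section_profile")
}

#' Segmental correlation factors
#'
#' Seven local-composition factors summarizing how base usage varies
#' across 20-bp sections: for each of the six unordered base pairs,
#' `lambda_XY = mean_j |p_X(j) - p_Y(j)|`, and the heterogeneity factor
#' `lambda_H = mean_j (1/2) sum_b |p_b(j) - p_b(global)|` against the
#' whole-sequence base probabilities.  All values lie in `[0, 1]`; a
#' single-section profile has `lambda_H = 0`.
#'
#' @param profile A `section_profile` from [section_probabilities()].
#' @param global_probs Optional length-4 vector of whole-sequence base
#'   probabilities; defaults to the section-length-weighted mean of the
#'   profile rows (exact when all sections have equal length, and
#'   recomputed from the sequence by [basic_feature_vector()]).
#' @return Named vector: `lambda_ac`, `lambda_ag`, `lambda_at`,
#'   `lambda_cg`, `lambda_ct`, `lambda_gt`, `lambda_h`.
#' @export
segmental_factors <- function(profile, global_probs = NULL) {
  p <- profile$section_probs
  m <- profile$m
  if (is.null(global_probs)) global_probs <- colMeans(p)
  pairs <- list(c("a", "c"), c("a", "g"), c("a", "t"),
                c("c", "g"), c("c", "t"), c("g", "t"))
  lam <- vapply(pairs, function(pr) mean(abs(p[, pr[1]] - p[, pr[2]])), numeric(1))
  names(lam) <- vapply(pairs, function(pr) paste0("lambda_", pr[1], pr[2]), "")
  lam_h <- mean(vapply(seq_len(m), function(j) {
    sum(abs(p[j, ] - global_probs)) / 2
  }, numeric(1)))
  c(lam, lambda_h = lam_h)
}

## vectorized basic features for whole record sets; one row per sequence,
## identical to vapply(sequences, basic_feature_vector, numeric(14))
basic_feature_matrix <- function(sequences, section_len = 20L) {
  sequences <- tolower(sequences)
  L <- nchar(sequences)
  ss <- Biostrings::DNAStringSet(toupper(sequences))
  glob_cnt <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  if (any(rowSums(glob_cnt) != L)) {
    bad <- which(rowSums(glob_cnt) != L)[1]
    stop(sprintf("non-ACGT character in sequence %d", bad))
  }
  glob <- glob_cnt / L
  m <- ceiling(L / section_len)
  seq_idx <- rep(seq_along(sequences), m)
  sec_no <- unlist(lapply(m, seq_len), use.names = FALSE)
  starts <- (sec_no - 1L) * section_len + 1L
  ends <- pmin(starts + section_len - 1L, L[seq_idx])
  secs <- Biostrings::DNAStringSet(toupper(substring(sequences[seq_idx], starts, ends)))
  p <- Biostrings::letterFrequency(secs, letters = c("A", "C", "G", "T")) /
    (ends - starts + 1L)
  pairs <- utils::combn(1:4, 2)
  lam <- vapply(seq_len(ncol(pairs)), function(k) {
    rowsum(abs(p[, pairs[1, k]] - p[, pairs[2, k]]), seq_idx)[, 1] / m
  }, numeric(length(sequences)))
  lam_h <- rowsum(rowSums(abs(p - glob[seq_idx, , drop = FALSE])) / 2, seq_idx)[, 1] / m
  out <- cbind(L, glob[, 1] + glob[, 4], glob[, 2] + glob[, 3],
               glob[, 1], glob[, 2], glob[, 3], glob[, 4], lam, lam_h)
  colnames(out) <- basic_feature_names()
  rownames(out) <- NULL
  out
}

#' The 14 basic sequence features
#'
#' Global features (length, AT content, GC content, the four base
#' occurrence probabilities) plus the seven segmental factors of
#' [segmental_factors()], in a fixed documented order.
#'
#' @param sequence Lowercase ACGT string.
#' @param section_len Section width for the segmental factors.
#' @return Named numeric vector of length 14: `length`, `at_content`,
#'   `gc_content`, `p_a`, `p_c`, `p_g`, `p_t`, `lambda_ac` ... `lambda_gt`,
#'   `lambda_h`.
#' @export
basic_feature_vector <- function(sequence, section_len = 20L) {
  sequence <- tolower(sequence)
  L <- nchar(sequence)
  check_acgt(sequence)
  counts <- table(factor(strsplit(sequence, "")[[1]], levels = BASES))
  p <- as.numeric(counts) / L
  names(p) <- BASES
  prof <- section_probabilities(sequence, section_len)
  lam <- segmental_factors(prof, global_probs = p)
  c(length = L,
    at_content = p[["a"]] + p[["t"]],
    gc_content = p[["g"]] + p[["c"]],
    p_a = p[["a"]], p_c = p[["c"]], p_g = p[["g"]], p_t = p[["t"]],
    lam)
}
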