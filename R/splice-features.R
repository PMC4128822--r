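## Splice-site signal strength and intron/exon compositional similarity.
##
## Signal strength: a log2 log-odds position weight matrix (PWM) over the
## 9-nt donor window (-3..+6) or the 23-nt acceptor window (-21..+2),
## trained from aligned windows against a uniform background q = 0.25 with
## additive smoothing eps = 1 / (4 (N + 1)).  Scores are sums of
## per-position entries; larger scores mean stronger canonical sites.
##
## Similarity: the increment of diversity ID(X, Y) = D(X+Y) - D(X) - D(Y)
## over overlapping-trimer counts, with the natural-log diversity measure
## D(X) = N ln N - sum_i n_i ln n_i.  Small ID means the intron boundary
## and its flanking exon share trimer usage.

#' Train a splice-site position weight matrix
#'
#' @param aligned_windows Character vector of equal-length ACGT windows
#'   (9 nt for donor sites, 23 nt for acceptor sites), aligned on the
#'   splice site.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return A `pwm_model`: list with `site_type`, `window_len`, `matrix`
#'   (4 x window_len log2 log-odds, rows `a`,`c`,`g`,`t`), background `q`,
#'   smoothing `eps` and `training_n`.  A position whose training counts
#'   are uniform has all four entries 0.
#' @export
train_pwm <- function(aligned_windows, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (length(aligned_windows) == 0L) stop("no training windows")
  w <- unique(nchar(aligned_windows))
  if (length(w) != 1L) stop("training windows have unequal lengths")
  n <- length(aligned_windows)
  eps <- 1 / (4 * (n + 1))
  q <- 0.25
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(toupper(aligned_windows)))
  cm <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  p <- cm / n
  mat <- log2((p + eps) / (q + eps))
  rownames(mat) <- c("a", "c", "g", "t")
  structure(list(site_type = site_type, window_len = w, matrix = mat,
                 q = q, eps = eps, training_n = n),
            class = "pwm_model")
}

#' Score a window against a PWM
#'
#' The signal-strength value: the sum over positions of the matrix entry
#' of the observed base.
#'
#' @param pwm A `pwm_model` from [train_pwm()].
#' @param window ACGT string of length `pwm$window_len`.
#' @return Numeric score (bits).
#' @export
pwm_score <- function(pwm, window) {
  window <- tolower(window)
  if (nchar(window) != pwm$window_len)
    stop(sprintf("window length %d does not match PWM length %d",
                 nchar(window), pwm$window_len))
  bases <- strsplit(window, "")[[1]]
  row <- match(bases, rownames(pwm$matrix))
  if (anyNA(row))
    stop(sprintf("non-ACGT character in window '%s'", window))
  sum(pwm$matrix[cbind(row, seq_along(bases))])
}

#' Overlapping trimer counts of a window
#'
#' @param window ACGT string.
#' @return A `trimer_counts` object: list with `counts` (named integer
#'   vector over observed trimers) and `n` (total trimers,
#'   `nchar(window) - 2`; 0 for windows shorter than 3 nt).
#' @export
trimer_counts <- function(window) {
  L <- nchar(window)
  if (L < 3L)
    return(structure(list(counts = stats::setNames(integer(0), character(0)), n = 0L),
                     class = "trimer_counts"))
  cnt <- kmer_count_matrix(window, 3L)[1, ]
  cnt <- cnt[cnt > 0]
  structure(list(counts = cnt, n = L - 2L), class = "trimer_counts")
}

#' Diversity measure of a count table
#'
#' `D(X) = N ln N - sum_i n_i ln n_i` (natural log, `0 ln 0 = 0`).
#' Non-negative; 0 iff all counts fall in one category (or `N = 0`).
#'
#' @param x A `trimer_counts` object or a numeric count vector.
#' @return The diversity value.
#' @export
diversity_measure <- function(x) {
  cnt <- if (inherits(x, "trimer_counts")) x$counts else x
  cnt <- cnt[cnt > 0]
  n <- sum(cnt)
  if (n == 0) return(0)
  n * log(n) - sum(cnt * log(cnt))
}

#' Increment of diversity between two count tables
#'
#' `ID(X, Y) = D(X + Y) - D(X) - D(Y)` where `X + Y` adds counts
#' category-wise.  Symmetric and non-negative; 0 when the two tables have
#' proportional composition.  Smaller values mean more similar trimer
#' usage.
#'
#' @param x,y `trimer_counts` objects or named numeric count vectors.
#' @return The ID value.
#' @export
increment_of_diversity <- function(x, y) {
  cx <- if (inherits(x, "trimer_counts")) x$counts else x
  cy <- if (inherits(y, "trimer_counts")) y$counts else y
  keys <- union(names(cx), names(cy))
  mixed <- stats::setNames(numeric(length(keys)), keys)
  mixed[names(cx)] <- mixed[names(cx)] + cx
  mixed[names(cy)] <- mixed[names(cy)] + cy
  diversity_measure(mixed) - diversity_measure(cx) - diversity_measure(cy)
}

#' The four splice-site / flanking-sequence features of one intron
#'
#' `sf_value` and `sf_acc_value` are the PWM scores of the donor and
#' acceptor windows; `id_donv` and `id_acceptv` are the increments of
#' diversity between the 20-nt exon-side and intron-side windows at the
#' donor and acceptor sites.  An exon-side window too short to hold a
#' trimer (< 3 nt) sets the corresponding ID feature to 0 and raises the
#' truncation flag.
#'
#' @param record A one-row intron data frame (or list) carrying the six
#'   window columns populated by [extract_sequences()].
#' @param donor_pwm,acceptor_pwm Trained `pwm_model`s.
#' @return Named numeric vector `sf_value`, `sf_acc_value`, `id_donv`,
#'   `id_acceptv`, with attribute `truncated` (logical).
#' @export
splice_feature_vector <- function(record, donor_pwm, acceptor_pwm) {
  truncated <- FALSE
  id_at <- function(exon_w, intron_w) {
    if (nchar(exon_w) < 3L) {
      truncated <<- TRUE
      return(0)
    }
    increment_of_diversity(trimer_counts(exon_w), trimer_counts(intron_w))
  }
  out <- c(
    sf_value = pwm_score(donor_pwm, record$donor_pwm_window),
    sf_acc_value = pwm_score(acceptor_pwm, record$acceptor_pwm_window),
    id_donv = id_at(record$donor_exon_window, record$donor_intron_window),
    id_acceptv = id_at(record$acceptor_exon_window, record$acceptor_intron_window)
  )
  attr(out, "truncated") <- truncated
  out
}
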