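## Assembles the per-intron feature table (all 52 candidate columns) from
## extracted intron records, and selects preset column sets with optional
## majority-class under-sampling.

vectorized_motif_freqs <- function(sequences, motifs) {
  ks <- nchar(motifs)
  out <- matrix(0, length(sequences), length(motifs),
                dimnames = list(NULL, motifs))
  for (k in unique(ks)) {
    cnt <- kmer_count_matrix(sequences, k)
    win <- pmax(nchar(sequences) - k + 1L, 1L)
    hit <- motifs[ks == k]
    out[, hit] <- cnt[, hit, drop = FALSE] / win
  }
  out
}

#' Compute the full feature table of a set of intron records
#'
#' Builds all 52 candidate feature columns for every intron: the 14 basic
#' composition features, the 19 frequent-motif frequencies, the 4
#' splice-site / flanking-similarity features, and the 15 extra trimer
#' frequencies of the complete set.  The donor and acceptor PWMs are
#' trained on the CSI records (the canonical-signal class); pass
#' `pwm_train_idx` to restrict training to a subset (e.g. a training
#' partition) or `pwm_train = "pooled"` to train on both classes.
#'
#' @param records Intron data frame from [extract_sequences()] /
#'   [extract_introns()] (or [simulate_labeled_introns()]), with `label`
#'   and the six window columns.
#' @param pwm_train_idx Optional integer row indices used for PWM
#'   training (intersected with the CSI rows unless `pwm_train` is
#'   `"pooled"`).
#' @param pwm_train `"csi"` (default) or `"pooled"`.
#' @param donor_pwm,acceptor_pwm Optional pre-trained `pwm_model`s; when
#'   supplied, no PWM training takes place (used when scoring new records
#'   against a fitted model).
#' @return A data frame with 52 feature columns (see [preset_columns()]),
#'   plus `label` (factor `RI`/`CSI`) and `id_truncated` (logical flag for
#'   exon windows too short for a trimer).  The trained PWMs are attached
#'   as attributes `donor_pwm` and `acceptor_pwm`.
#' @export
intron_features <- function(records, pwm_train_idx = NULL,
                            pwm_train = c("csi", "pooled"),
                            donor_pwm = NULL, acceptor_pwm = NULL) {
  pwm_train <- match.arg(pwm_train)
  n <- nrow(records)
  if (is.null(donor_pwm) != is.null(acceptor_pwm))
    stop("supply both PWMs or neither")
  if (is.null(donor_pwm)) {
    if (is.null(pwm_train_idx)) pwm_train_idx <- seq_len(n)
    if (pwm_train == "csi")
      pwm_train_idx <- pwm_train_idx[records$label[pwm_train_idx] == "CSI"]
    if (length(pwm_train_idx) == 0L) stop("no records available for PWM training")
    donor_pwm <- train_pwm(records$donor_pwm_window[pwm_train_idx], "donor")
    acceptor_pwm <- train_pwm(records$acceptor_pwm_window[pwm_train_idx], "acceptor")
  }

  a <- basic_feature_matrix(records$sequence)
  b <- vectorized_motif_freqs(records$sequence, motif_preset_b())
  tri <- vectorized_motif_freqs(records$sequence, trimer_preset_52())
  truncated <- logical(n)
  cc <- t(vapply(seq_len(n), function(i) {
    v <- splice_feature_vector(records[i, ], donor_pwm, acceptor_pwm)
    truncated[i] <<- attr(v, "truncated")
    v
  }, numeric(4)))

  out <- data.frame(a, b, tri, cc, check.names = FALSE)
  colnames(out) <- c(basic_feature_names(), motif_preset_b(),
                     trimer_preset_52(), splice_feature_names())
  out <- out[, preset_columns("complete52")]
  lab <- if ("label" %in% names(records)) records$label else rep(NA_character_, n)
  out$label <- factor(lab, levels = c("RI", "CSI"))
  out$id_truncated <- truncated
  attr(out, "donor_pwm") <- donor_pwm
  attr(out, "acceptor_pwm") <- acceptor_pwm
  out
}

#' Assemble a preset feature table with class balancing
#'
#' Selects the columns of a feature preset and, when `undersample_n` is
#' given, balances the classes by keeping all RIs and sampling that many
#' CSIs without replacement.
#'
#' @param features Feature table from [intron_features()] (must contain
#'   all columns of the chosen preset plus `label`).
#' @param preset One of `"A"`, `"AC"`, `"ABC"`, `"complete52"`,
#'   `"optimized27"`.
#' @param undersample_n Number of CSIs to keep (default `NA`: keep all).
#' @param seed Integer seed driving the CSI sample.
#' @return A data frame with the preset's feature columns and `label`.
#' @export
assemble_dataset <- function(features, preset = "ABC", undersample_n = NA,
                             seed = 1L) {
  cols <- preset_columns(preset)
  missing <- setdiff(cols, colnames(features))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  ri <- which(features$label == "RI")
  csi <- which(features$label == "CSI")
  if (length(ri) == 0L || length(csi) == 0L)
    stop("both classes must be present")
  if (!is.na(undersample_n)) {
    if (undersample_n > length(csi))
      stop(sprintf("undersample_n = %d exceeds the %d available CSIs",
                   undersample_n, length(csi)))
    set.seed(seed)
    csi <- sort(sample(csi, undersample_n))
  }
  out <- features[c(ri, csi), c(cols, "label"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize feature columns by training-row statistics
#'
#' Centers and scales every feature column by the mean and sample
#' standard deviation (n - 1) computed on the training rows only, as done
#' by R's `scale()`.  Zero-variance columns are centered with divisor 1
#' and a warning.
#'
#' @param table Feature table (feature columns plus `label`).
#' @param train_idx Row indices supplying the statistics (default: all
#'   rows).
#' @return The table with standardized feature columns; the statistics
#'   are attached as attributes `center` and `scale`.
#' @export
standardize <- function(table, train_idx = seq_len(nrow(table))) {
  num <- vapply(table, is.numeric, logical(1)) & colnames(table) != "label"
  ctr <- vapply(table[train_idx, num, drop = FALSE], mean, numeric(1))
  scl <- vapply(table[train_idx, num, drop = FALSE], stats::sd, numeric(1))
  if (any(scl == 0 | is.na(scl))) {
    warning("zero-variance feature column(s): ",
            paste(colnames(table)[num][scl == 0 | is.na(scl)], collapse = ", "))
    scl[scl == 0 | is.na(scl)] <- 1
  }
  table[, num] <- sweep(sweep(table[, num, drop = FALSE], 2, ctr), 2, scl, "/")
  attr(table, "center") <- ctr
  attr(table, "scale") <- scl
  table
}
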