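## Published feature presets.  Column widths are structural invariants:
## A = 14, A+C = 18, A+B+C = 37, complete = 52, optimized = 27.

#' The 19-motif frequent-motif panel (feature set B)
#'
#' Ten motifs enriched in retained introns (negative `D`; GC-rich) and
#' nine enriched in constitutively spliced introns (positive `D`;
#' AT/TA-rich).
#'
#' @return Character vector of 19 motifs.
#' @export
motif_preset_b <- function() {
  c("cc", "gg", "cg", "ccg", "cga", "cgg", "ggag", "gggt", "gaag", "ttcg",
    "ta", "at", "atgt", "taat", "tatat", "atatt", "aaata", "ttata", "attat")
}

#' The 15 extra trimers of the complete 52-feature set
#'
#' Trimer frequencies appended to the A+B+C descriptor to form the
#' complete 52-feature set.
#'
#' @return Character vector of 15 trimers.
#' @export
trimer_preset_52 <- function() {
  c("agg", "ata", "atg", "cgc", "cta", "gcg", "gga", "ggg", "gta",
    "taa", "tac", "tag", "tat", "tcg", "tta")
}

basic_feature_names <- function() {
  c("length", "at_content", "gc_content", "p_a", "p_c", "p_g", "p_t",
    "lambda_ac", "lambda_ag", "lambda_at", "lambda_cg", "lambda_ct",
    "lambda_gt", "lambda_h")
}

splice_feature_names <- function() {
  c("sf_value", "sf_acc_value", "id_donv", "id_acceptv")
}

#' Feature column names of a preset
#'
#' @param preset One of `"A"`, `"AC"`, `"ABC"`, `"complete52"`,
#'   `"optimized27"`.
#' @return Character vector of feature column names (14, 18, 37, 52 or 27
#'   names respectively).
#' @export
preset_columns <- function(preset = c("ABC", "A", "AC", "complete52", "optimized27")) {
  preset <- match.arg(preset)
  a <- basic_feature_names()
  b <- motif_preset_b()
  cc <- splice_feature_names()
  switch(preset,
    A = a,
    AC = c(a, cc),
    ABC = c(a, b, cc),
    complete52 = c(a, b, cc, trimer_preset_52()),
    ## 23 named features plus 4 segmental factors (the two the contrast
    ## analysis singles out, lambda_cg and lambda_ct, plus lambda_gt and
    ## lambda_h); all drawn from the complete 52 columns
    optimized27 = c("length", "p_g", "p_t", "at_content",
                    "lambda_cg", "lambda_ct", "lambda_gt", "lambda_h",
                    "cg", "ta", "cga", "cta", "gga", "tac", "tag", "tta",
                    "gaag", "ttcg", "atgt", "taat", "attat", "tatat", "aaata",
                    "sf_value", "sf_acc_value", "id_donv", "id_acceptv"))
}
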