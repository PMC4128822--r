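## The central fitting interface: ri_classifier() takes labeled intron
## records, assembles the requested feature preset, and trains either the
## random forest (90/10 holdout, numTrees grid) or the PSO-tuned RBF SVM
## (10-fold cross-validated evaluation), returning a classed object with
## print / summary / predict / plot methods.

#' Fit an intron-retention classifier
#'
#' From labeled intron records (annotation-derived via
#' [extract_introns()] or simulated via [simulate_labeled_introns()]),
#' computes the chosen feature preset and trains one of the two
#' classifiers:
#'
#' * `"rf"` — random forest on a stratified 90/10 split, `mtry` set by
#'   the square-root rule and the tree count picked from a 30-50 grid by
#'   holdout accuracy; splice-site PWMs are trained on the CSI records of
#'   the training partition only.
#' * `"psosvm"` — RBF-kernel SVM whose cost and kernel width are tuned by
#'   particle swarm optimization with 10-fold cross-validated accuracy as
#'   fitness, then evaluated by stratified 10-fold cross-validation with
#'   pooled out-of-fold probability estimates; PWMs are trained on all
#'   CSI records (class-level canonical-signal model).
#'
#' @param records Intron data frame with `label` and the six window
#'   columns.
#' @param method `"rf"` or `"psosvm"`.
#' @param preset Feature preset (see [preset_columns()]).
#' @param undersample_n CSIs retained by majority-class under-sampling
#'   (`NA` = keep all).
#' @param seed Integer seed driving every random choice.
#' @param pso A [pso_config()] (psosvm only; its seed defaults to
#'   `seed`).
#' @param num_trees_grid,split Random-forest controls (rf only).
#' @return An object of class `ri_classifier` with elements `method`,
#'   `preset`, `report` (an `eval_report`), `fit` (the underlying
#'   `rf_result` or list with `pso`, `cv` and the final `svm` model),
#'   `table` (the standardized feature table), `pwms`, `center`/`scale`
#'   and `seed`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' recs <- simulate_labeled_introns(cfg, n_ri = 120, n_csi = 120)
#' fit <- ri_classifier(recs, method = "rf", seed = 7)
#' fit
#' @export
ri_classifier <- function(records, method = c("rf", "psosvm"),
                          preset = "ABC", undersample_n = NA, seed = 1L,
                          pso = NULL, num_trees_grid = seq(30L, 50L, 2L),
                          split = 0.9) {
  method <- match.arg(method)
  ri <- which(records$label == "RI")
  csi <- which(records$label == "CSI")
  if (length(ri) == 0L || length(csi) == 0L) stop("both classes required")
  if (!is.na(undersample_n)) {
    if (undersample_n > length(csi))
      stop("undersample_n exceeds the available CSIs")
    set.seed(seed)
    csi <- sort(sample(csi, undersample_n))
  }
  records <- records[c(ri, csi), , drop = FALSE]

  if (method == "rf") {
    train_idx <- split_train_test(records$label, split, seed)
    feats <- intron_features(records, pwm_train_idx = train_idx)
    table <- assemble_dataset(feats, preset)
    fit <- train_random_forest(table, num_trees_grid = num_trees_grid,
                               split = split, seed = seed)
    std <- standardize(table, fit$train_idx)
    out <- list(method = method, preset = preset, fit = fit,
                report = fit$report, table = std)
  } else {
    feats <- intron_features(records)
    table <- standardize(assemble_dataset(feats, preset))
    if (is.null(pso)) pso <- pso_config(seed = seed)
    opt <- pso_optimize_svm(table, pso)
    cv <- evaluate_svm_cv(table, opt$best_c, opt$best_gamma, seed = seed)
    feat <- setdiff(colnames(table), c("label", "id_truncated"))
    final <- e1071::svm(as.matrix(table[, feat]), droplevels(table$label),
                        kernel = "radial", cost = opt$best_c,
                        gamma = opt$best_gamma, scale = FALSE,
                        probability = TRUE)
    out <- list(method = method, preset = preset,
                fit = list(pso = opt, cv = cv, svm = final),
                report = cv$report, table = table)
  }
  out$pwms <- list(donor = attr(feats, "donor_pwm"),
                   acceptor = attr(feats, "acceptor_pwm"))
  out$center <- attr(out$table, "center")
  out$scale <- attr(out$table, "scale")
  out$seed <- seed
  class(out) <- "ri_classifier"
  out
}

#' @export
print.ri_classifier <- function(x, ...) {
  cat(sprintf("ri_classifier: %s on preset %s (%d features, %d introns)\n",
              x$method, x$preset,
              length(setdiff(colnames(x$table), c("label", "id_truncated"))),
              nrow(x$table)))
  if (x$method == "rf") {
    cat(sprintf("  numTrees = %d (grid search), mtry = %d; 90/10 holdout:\n",
                x$fit$num_trees, x$fit$mtry))
  } else {
    cat(sprintf("  PSO-tuned C = %.4g, gamma = %.4g (CV fitness %.3f); 10-fold CV:\n",
                x$fit$pso$best_c, x$fit$pso$best_gamma, x$fit$pso$best_fitness))
  }
  cat("  ")
  print(x$report)
  invisible(x)
}

#' @export
summary.ri_classifier <- function(object, n_top = 8L, ...) {
  print(object)
  stats <- feature_group_stats(object$table)
  stats <- stats[order(stats$p_value), , drop = FALSE]
  cat("\nmost class-contrasting features (one-way ANOVA):\n")
  print(utils::head(stats, n_top), row.names = FALSE, digits = 3)
  invisible(list(fit = object, feature_stats = stats))
}

#' Predict intron class probabilities
#'
#' Scores new intron records (or a pre-computed feature table) with a
#' fitted classifier: features are computed with the fitted PWMs,
#' standardized with the training statistics, and passed to the
#' underlying model.
#'
#' @param object A fitted `ri_classifier`.
#' @param newdata Intron records with window columns, or a feature table
#'   already containing the preset columns.
#' @param type `"prob"` (RI probability) or `"class"`.
#' @param ... Unused.
#' @return Numeric RI probabilities or a factor of class labels.
#' @export
predict.ri_classifier <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  cols <- preset_columns(object$preset)
  if (!all(cols %in% colnames(newdata))) {
    newdata <- intron_features(newdata, donor_pwm = object$pwms$donor,
                               acceptor_pwm = object$pwms$acceptor)
  }
  x <- as.matrix(newdata[, cols, drop = FALSE])
  x <- sweep(sweep(x, 2, object$center[cols]), 2, object$scale[cols], "/")
  prob <- if (object$method == "rf") {
    stats::predict(object$fit$model, x, type = "prob")[, "RI"]
  } else {
    pr <- stats::predict(object$fit$svm, x, probability = TRUE)
    attr(pr, "probabilities")[, "RI"]
  }
  if (type == "prob") unname(prob)
  else factor(ifelse(prob >= 0.5, "RI", "CSI"), levels = c("RI", "CSI"))
}

#' Plot the ROC curve of a fitted classifier
#'
#' @param x A fitted `ri_classifier`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ri_classifier <- function(x, ...) {
  roc <- x$report$roc
  if (!is.data.frame(roc)) stop("no ROC available (single-class evaluation)")
  graphics::plot(roc$fpr, roc$tpr, type = "l",
                 xlab = "False positive rate (1 - Specificity)",
                 ylab = "True positive rate (Sensitivity)",
                 main = sprintf("%s, preset %s: AUC = %.3f",
                                x$method, x$preset, x$report$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
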