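## Classifier training and evaluation: random forest with a numTrees grid
## search, RBF-SVM with particle-swarm hyperparameter optimization, and
## confusion-matrix / ROC / AUC reporting.  Tree induction is delegated to
## randomForest and the SVM solver to e1071 (libsvm); the swarm, the
## cross-validation loops and all metrics are implemented here.

#' Random-forest mtry rule
#'
#' The number of candidate features per split: the square root of the
#' feature count, rounded half-up (37 -> 6, 52 -> 7, 27 -> 5, 14 -> 4,
#' 18 -> 4).
#'
#' @param p Feature count (>= 1).
#' @return Integer number of features.
#' @export
rf_num_features <- function(p) {
  stopifnot(p >= 1)
  as.integer(floor(sqrt(p) + 0.5))
}

#' Confusion-matrix metrics, ROC curve and AUC
#'
#' Counts true/false positives and negatives at `threshold` (positive
#' class: RI), and computes Accuracy, Sensitivity (= TP / (TP + FN)),
#' Specificity (= TN / (TN + FP)) and the F-Measure
#' (= 2 x Precision x Sensitivity / (Precision + Sensitivity)).  The ROC
#' curve sweeps all score thresholds; AUC is its trapezoid area.
#'
#' @param scores Numeric class-probability scores in `[0, 1]`, one per
#'   label (probability of RI).
#' @param labels Factor/character labels, `"RI"` positive, or a logical
#'   vector (`TRUE` = RI).
#' @param threshold Score cut for the confusion counts (default 0.5).
#' @return An `eval_report`: list with `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `f_measure`, `roc` (data
#'   frame of `fpr`, `tpr`, starting at (0,0) and ending at (1,1)) and
#'   `auc`.  With single-class labels, `roc` and `auc` are `NA`.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  pos <- if (is.logical(labels)) labels else labels == "RI"
  stopifnot(length(scores) == length(pos))
  tp <- sum(scores >= threshold & pos)
  fp <- sum(scores >= threshold & !pos)
  tn <- sum(scores < threshold & !pos)
  fn <- sum(scores < threshold & pos)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0

  if (all(pos) || !any(pos)) {
    roc <- NA
    auc <- NA_real_
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- pos[ord]
    grp <- cumsum(!duplicated(s))               # tie groups share one point
    tpr <- c(0, cumsum(y)[!duplicated(grp, fromLast = TRUE)] / sum(pos))
    fpr <- c(0, cumsum(!y)[!duplicated(grp, fromLast = TRUE)] / sum(!pos))
    roc <- data.frame(fpr = fpr, tpr = tpr)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(pos),
                 sensitivity = sens, specificity = spec, f_measure = f,
                 roc = roc, auc = auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy=%.3f sensitivity=%.3f specificity=%.3f f_measure=%.3f auc=%s\n",
              x$accuracy, x$sensitivity, x$specificity, x$f_measure,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

## class-stratified fold labels, 1..folds, one per row of y
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (lv in unique(y)) {
    idx <- which(y == lv)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))[sample(length(idx))]
  }
  fold_id
}

split_train_test <- function(labels, split, seed) {
  set.seed(seed)
  train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    sample(idx, round(length(idx) * split))
  }), use.names = FALSE)
  sort(train)
}

#' Train and evaluate a random forest with a numTrees grid search
#'
#' Splits the table into stratified training/holdout parts, standardizes
#' by training statistics, and for each candidate tree count fits a
#' forest with `mtry = rf_num_features(p)`; the tree count maximizing
#' holdout accuracy (ties toward the smallest) is selected and reported
#' with class-probability outputs.
#'
#' @param table Feature table (numeric columns plus `label`).
#' @param num_trees_grid Candidate tree counts (default 30 to 50, step 2).
#' @param split Training fraction (default 0.9).
#' @param seed Integer seed (drives the split and each forest).
#' @return List of class `rf_result`: `model` (the chosen
#'   `randomForest`), `report` (an [evaluate()] report on the holdout),
#'   `num_trees`, `mtry`, `train_idx`, `grid` (data frame of tree count
#'   vs holdout accuracy).
#' @export
train_random_forest <- function(table, num_trees_grid = seq(30L, 50L, 2L),
                                split = 0.9, seed = 1L) {
  if (length(unique(table$label)) < 2L) stop("training data has a single class")
  feat <- setdiff(colnames(table), c("label", "id_truncated"))
  train_idx <- split_train_test(table$label, split, seed)
  table <- standardize(table, train_idx)
  x <- as.matrix(table[, feat]); y <- droplevels(table$label)
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  if (length(unique(y[train_idx])) < 2L) stop("training split has a single class")
  mtry <- rf_num_features(length(feat))
  fit_one <- function(nt) {
    set.seed(seed + nt)
    randomForest::randomForest(x[train_idx, ], y[train_idx],
                               ntree = nt, mtry = mtry)
  }
  acc <- vapply(num_trees_grid, function(nt) {
    pr <- stats::predict(fit_one(nt), x[test_idx, ], type = "prob")[, "RI"]
    mean((pr >= 0.5) == (y[test_idx] == "RI"))
  }, numeric(1))
  best_nt <- num_trees_grid[which.max(acc)]   # which.max takes first = smallest
  model <- fit_one(best_nt)
  prob <- stats::predict(model, x[test_idx, ], type = "prob")[, "RI"]
  structure(list(model = model,
                 report = evaluate(prob, y[test_idx]),
                 num_trees = best_nt, mtry = mtry, train_idx = train_idx,
                 grid = data.frame(num_trees = num_trees_grid, accuracy = acc)),
            class = "rf_result")
}

#' Particle swarm configuration
#'
#' The published swarm constants: 10 iterations, 100 particles, 2
#' dimensions, cognition and social learning factors
#' `c1 = c2 = 1.49618`, inertia `w = 0.7298`, and search bounds
#' `C` in `(2^-8, 2^10)`, `gamma` in `(2^-8, 2^8)` (the swarm moves in
#' log2 space).
#'
#' @param iterations,particles,c1,c2,w Swarm constants.
#' @param c_bounds,gamma_bounds log2-space bounds.
#' @param tune_n Stratified subsample of the table used to evaluate the
#'   cross-validation fitness (keeps each of the swarm's ~1000 fitness
#'   evaluations tractable); `NA` uses all rows.
#' @param seed Integer seed.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(iterations = 10L, particles = 100L,
                       c1 = 1.49618, c2 = 1.49618, w = 0.7298,
                       c_bounds = c(-8, 10), gamma_bounds = c(-8, 8),
                       tune_n = 300L, seed = 1L) {
  structure(list(iterations = iterations, particles = particles,
                 dims = 2L, c1 = c1, c2 = c2, w = w,
                 bounds = rbind(c_bounds, gamma_bounds),
                 tune_n = tune_n, seed = seed),
            class = "pso_config")
}

#' 10-fold cross-validation fitness for the RBF SVM
#'
#' Builds a deterministic fitness closure: mean fold accuracy of an
#' RBF-kernel SVM at `(C, gamma)` over fixed stratified folds of a
#' (sub)sample of the table.  The folds and subsample are drawn once from
#' the seed, so the fitness is a pure function of `(C, gamma)`.
#'
#' @param table Standardized feature table with `label`.
#' @param folds Number of folds (default 10).
#' @param tune_n Stratified subsample size (`NA` = all rows).
#' @param seed Integer seed.
#' @return `function(log2_c, log2_gamma) -> mean CV accuracy`.
#' @export
svm_cv_fitness <- function(table, folds = 10L, tune_n = NA, seed = 1L) {
  feat <- setdiff(colnames(table), c("label", "id_truncated"))
  x <- as.matrix(table[, feat])
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- droplevels(table$label)
  set.seed(seed)
  if (!is.na(tune_n) && tune_n < nrow(x)) {
    keep <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(length(idx) * tune_n / length(y)))
    }), use.names = FALSE)
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  fold_id <- stratified_folds(y, folds)
  function(log2_c, log2_gamma) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = 2^log2_c, gamma = 2^log2_gamma, scale = FALSE)
      mean(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(accs)
  }
}

#' Optimize SVM hyperparameters by particle swarm
#'
#' Runs the swarm in `(log2 C, log2 gamma)` space: positions initialized
#' uniformly within the bounds, velocity update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with `r1`, `r2`
#' uniform per dimension, position update `x <- x + v`, positions clamped
#' to the bounds with the velocity zeroed on the clamped dimension.
#' Fitness defaults to the 10-fold cross-validation accuracy of
#' [svm_cv_fitness()]; any `function(x1, x2)` can be substituted (used by
#' the swarm's own convergence checks).  Personal/global best ties are
#' resolved toward smaller parameter values.
#'
#' @param table Standardized feature table (ignored when `fitness` is
#'   supplied).
#' @param cfg A [pso_config()].
#' @param fitness Optional fitness function of the two log2 coordinates.
#' @return List of class `pso_result`: `best_c`, `best_gamma`,
#'   `best_log2` (position), `best_fitness`, `trace` (global-best fitness
#'   after each iteration, non-decreasing), `cfg`.
#' @export
pso_optimize_svm <- function(table = NULL, cfg = pso_config(), fitness = NULL) {
  if (is.null(fitness)) {
    if (is.null(table)) stop("supply a table or a fitness function")
    fitness <- svm_cv_fitness(table, tune_n = cfg$tune_n, seed = cfg$seed)
  }
  lo <- cfg$bounds[, 1]; hi <- cfg$bounds[, 2]
  S <- cfg$particles
  set.seed(cfg$seed)
  pos <- cbind(stats::runif(S, lo[1], hi[1]), stats::runif(S, lo[2], hi[2]))
  vel <- matrix(0, S, 2)
  fit <- vapply(seq_len(S), function(i) fitness(pos[i, 1], pos[i, 2]), numeric(1))
  pbest <- pos; pbest_fit <- fit
  smaller <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
  gi <- which(fit == max(fit))
  gi <- gi[order(pos[gi, 1], pos[gi, 2])][1]
  gbest <- pos[gi, ]; gbest_fit <- fit[gi]
  trace <- numeric(cfg$iterations)
  for (t in seq_len(cfg$iterations)) {
    r1 <- matrix(stats::runif(S * 2), S, 2)
    r2 <- matrix(stats::runif(S * 2), S, 2)
    vel <- cfg$w * vel + cfg$c1 * r1 * (pbest - pos) +
      cfg$c2 * r2 * (sweep(-pos, 2, gbest, "+"))
    pos <- pos + vel
    for (d in 1:2) {
      clamped <- pos[, d] < lo[d] | pos[, d] > hi[d]
      pos[clamped, d] <- pmin(pmax(pos[clamped, d], lo[d]), hi[d])
      vel[clamped, d] <- 0
    }
    fit <- vapply(seq_len(S), function(i) fitness(pos[i, 1], pos[i, 2]), numeric(1))
    upd <- fit > pbest_fit |
      (fit == pbest_fit & (pos[, 1] < pbest[, 1] |
                             (pos[, 1] == pbest[, 1] & pos[, 2] < pbest[, 2])))
    pbest[upd, ] <- pos[upd, ]; pbest_fit[upd] <- fit[upd]
    bi <- which(pbest_fit == max(pbest_fit))
    bi <- bi[order(pbest[bi, 1], pbest[bi, 2])][1]
    if (pbest_fit[bi] > gbest_fit ||
        (pbest_fit[bi] == gbest_fit && smaller(pbest[bi, ], gbest))) {
      gbest <- pbest[bi, ]; gbest_fit <- pbest_fit[bi]
    }
    trace[t] <- gbest_fit
  }
  structure(list(best_c = 2^gbest[1], best_gamma = 2^gbest[2],
                 best_log2 = gbest, best_fitness = gbest_fit,
                 trace = trace, cfg = cfg),
            class = "pso_result")
}

#' Cross-validated evaluation of an RBF SVM at fixed hyperparameters
#'
#' Stratified k-fold cross-validation on the whole table; out-of-fold
#' class-probability estimates (libsvm's probability calibration) are
#' pooled into a single [evaluate()] report.
#'
#' @param table Standardized feature table with `label`.
#' @param cost,gamma SVM hyperparameters (natural scale).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List: `report` (an `eval_report`), `scores` (out-of-fold RI
#'   probabilities), `fold_id`.
#' @export
evaluate_svm_cv <- function(table, cost, gamma, folds = 10L, seed = 1L) {
  feat <- setdiff(colnames(table), c("label", "id_truncated"))
  x <- as.matrix(table[, feat])
  y <- droplevels(table$label)
  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    probability = TRUE)
    pr <- stats::predict(m, x[!tr, , drop = FALSE], probability = TRUE)
    scores[!tr] <- attr(pr, "probabilities")[, "RI"]
  }
  list(report = evaluate(scores, y), scores = scores, fold_id = fold_id)
}

#' Per-feature class means and one-way ANOVA
#'
#' For every feature column: the RI and CSI means, and the classical
#' one-way ANOVA F statistic and p value of the class contrast (raw,
#' uncorrected).  Constant columns report `F = 0`, `p = 1`.
#'
#' @param table Feature table with `label`.
#' @return Data frame with columns `feature`, `mean_ri`, `mean_csi`,
#'   `f_statistic`, `p_value`.
#' @export
feature_group_stats <- function(table) {
  stopifnot(all(c("RI", "CSI") %in% table$label))
  feat <- setdiff(colnames(table), c("label", "id_truncated"))
  out <- lapply(feat, function(cl) {
    v <- table[[cl]]
    g <- factor(table$label)
    if (stats::var(v) == 0) {
      f <- 0; p <- 1
    } else {
      tst <- stats::oneway.test(v ~ g, var.equal = TRUE)
      f <- unname(tst$statistic); p <- tst$p.value
    }
    data.frame(feature = cl,
               mean_ri = mean(v[table$label == "RI"]),
               mean_csi = mean(v[table$label == "CSI"]),
               f_statistic = f, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
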