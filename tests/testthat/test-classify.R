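# Small separable / null feature tables built directly, plus generator-based
# parameter-recovery checks at reduced problem sizes.

sep_table <- function(n = 120, p = 6, delta = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c("RI", "CSI"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p) + outer(y == "RI", rep(delta / sqrt(p), p))
  tab <- as.data.frame(x)
  colnames(tab) <- paste0("f", seq_len(p))
  tab$label <- factor(y, levels = c("RI", "CSI"))
  tab
}

test_that("preset column widths are the published ones", {
  widths <- c(A = 14L, AC = 18L, ABC = 37L, complete52 = 52L, optimized27 = 27L)
  for (p in names(widths)) {
    cols <- preset_columns(p)
    expect_length(cols, widths[[p]])
    expect_false(anyDuplicated(cols) > 0)
  }
  ## optimized and complete presets draw from the same candidate pool
  expect_true(all(preset_columns("optimized27") %in% preset_columns("complete52")))
  expect_error(preset_columns("XYZ"))
})

test_that("the square-root mtry rule rounds half-up", {
  expect_equal(rf_num_features(37), 6)
  expect_equal(rf_num_features(52), 7)
  expect_equal(rf_num_features(27), 5)
  expect_equal(rf_num_features(14), 4)
  expect_equal(rf_num_features(18), 4)
  expect_equal(rf_num_features(1), 1)
})

test_that("standardization uses training-row statistics", {
  tab <- data.frame(x = c(1, 2, 3, 10), z = c(5, 5, 5, 5),
                    label = factor(c("RI", "RI", "CSI", "CSI"),
                                   levels = c("RI", "CSI")))
  expect_warning(std <- standardize(tab, train_idx = 1:3), "zero-variance")
  expect_equal(std$x[1:3], c(-1, 0, 1))
  expect_equal(std$z, rep(0, 4))
  expect_equal(mean(std$x[1:3]), 0)
  expect_equal(sd(std$x[1:3]), 1)
})

test_that("evaluation metrics match hand-computed confusion tables", {
  ## TP=50 FP=10 TN=40 FN=0: precision 5/6, F = 2*(5/6)/(11/6) = 10/11
  scores <- c(rep(0.9, 50), rep(0.9, 10), rep(0.1, 40))
  labels <- c(rep("RI", 50), rep("CSI", 50))
  rep1 <- evaluate(scores, labels)
  expect_equal(rep1$tp, 50); expect_equal(rep1$fp, 10)
  expect_equal(rep1$tn, 40); expect_equal(rep1$fn, 0)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 0.8)
  expect_equal(rep1$accuracy, 0.9)
  expect_equal(rep1$f_measure, 10 / 11)

  ## 3 of 4 positive/negative pairs concordant
  rep2 <- evaluate(c(0.9, 0.3, 0.5, 0.1), c("RI", "RI", "CSI", "CSI"))
  expect_equal(rep2$auc, 0.75)

  rep3 <- evaluate(c(0.9, 0.8, 0.2, 0.1), c("RI", "RI", "CSI", "CSI"))
  expect_equal(rep3$auc, 1)
  expect_equal(rep3$roc$fpr[1], 0)
  expect_equal(rep3$roc$tpr[nrow(rep3$roc)], 1)

  ## single-class labels: ROC undefined
  rep4 <- evaluate(c(0.9, 0.8), c("RI", "RI"))
  expect_true(is.na(rep4$auc))
})

test_that("ROC/AUC agree with an independent implementation and identities hold", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:5) {
    n <- 60
    y <- sample(c("RI", "CSI"), n, replace = TRUE, prob = c(0.4, 0.6))
    s <- runif(n) + 0.4 * (y == "RI")
    rep <- evaluate(s, y)
    ref <- suppressMessages(pROC::auc(pROC::roc(y == "RI", s)))
    expect_equal(rep$auc, as.numeric(ref))
    expect_true(all(diff(rep$roc$fpr) >= 0) && all(diff(rep$roc$tpr) >= 0))
    P <- sum(y == "RI"); N <- sum(y == "CSI")
    expect_equal(rep$accuracy,
                 (rep$sensitivity * P + rep$specificity * N) / (P + N))
  }
})

test_that("dataset assembly under-samples deterministically and enforces presets", {
  cfg <- sim_config(seed = 23)
  feats <- intron_features(simulate_labeled_introns(cfg, 40, 120))
  tab <- assemble_dataset(feats, "ABC", undersample_n = 60, seed = 5)
  expect_equal(sum(tab$label == "RI"), 40)
  expect_equal(sum(tab$label == "CSI"), 60)
  expect_equal(ncol(tab), 38)  # 37 features + label
  tab2 <- assemble_dataset(feats, "ABC", undersample_n = 60, seed = 5)
  expect_identical(tab, tab2)
  expect_error(assemble_dataset(feats, "ABC", undersample_n = 500, seed = 5),
               "exceeds")
  for (p in c("A", "AC", "complete52", "optimized27"))
    expect_equal(ncol(assemble_dataset(feats, p)) - 1L,
                 length(preset_columns(p)))
})

test_that("random forest separates separable data and stays in the grid", {
  rf <- train_random_forest(sep_table(), seed = 3)
  expect_gte(rf$report$accuracy, 0.95)
  expect_true(rf$num_trees %in% seq(30, 50, 2))
  expect_true(all(rf$grid$num_trees %% 2 == 0))
  expect_equal(rf$mtry, rf_num_features(6))
  one_class <- sep_table()
  one_class$label <- factor("RI", levels = c("RI", "CSI"))
  expect_error(train_random_forest(one_class), "single class")
})

test_that("label shuffling destroys random-forest signal", {
  tab <- sep_table(n = 400, seed = 4)
  set.seed(99)
  aucs <- vapply(1:5, function(i) {
    tab$label <- sample(tab$label)
    train_random_forest(tab, num_trees_grid = 42L, seed = i)$report$auc
  }, numeric(1))
  expect_true(mean(aucs) >= 0.4 && mean(aucs) <= 0.6)
})

test_that("identical seeds reproduce identical forests and reports", {
  tab <- sep_table(n = 100, delta = 1.5, seed = 6)
  r1 <- train_random_forest(tab, seed = 11)
  r2 <- train_random_forest(tab, seed = 11)
  expect_identical(r1$train_idx, r2$train_idx)
  expect_equal(r1$report, r2$report)
  expect_equal(r1$grid, r2$grid)
})

test_that("the swarm respects its configuration and degenerate updates", {
  cfg <- pso_config(seed = 2)
  expect_equal(cfg$c1, 1.49618)
  expect_equal(cfg$w, 0.7298)
  expect_equal(unname(cfg$bounds[1, ]), c(-8, 10))
  expect_equal(unname(cfg$bounds[2, ]), c(-8, 8))

  ## c1 = c2 = 0, w = 1: zero initial velocity never changes, so the
  ## global best equals the best of the initial sample on every iteration
  still <- pso_optimize_svm(cfg = pso_config(c1 = 0, c2 = 0, w = 1, seed = 3,
                                             particles = 30, iterations = 5),
                            fitness = function(a, b) -(a^2 + b^2))
  expect_equal(length(unique(still$trace)), 1)

  opt <- pso_optimize_svm(cfg = pso_config(seed = 4),
                          fitness = function(a, b) -(a^2 + b^2))
  expect_true(all(diff(opt$trace) >= 0))
  expect_lt(sqrt(sum(opt$best_log2^2)), 0.05)
  ## positions stay within bounds
  expect_true(opt$best_log2[1] >= -8 && opt$best_log2[1] <= 10)
  expect_true(opt$best_log2[2] >= -8 && opt$best_log2[2] <= 8)
})

test_that("PSO trajectories are seed-deterministic", {
  f <- function(a, b) sin(a) + cos(b)
  o1 <- pso_optimize_svm(cfg = pso_config(seed = 5, particles = 20,
                                          iterations = 5), fitness = f)
  o2 <- pso_optimize_svm(cfg = pso_config(seed = 5, particles = 20,
                                          iterations = 5), fitness = f)
  expect_identical(o1$trace, o2$trace)
  expect_identical(o1$best_log2, o2$best_log2)
})

test_that("the CV fitness is a deterministic function of the hyperparameters", {
  tab <- sep_table(n = 80, delta = 4, seed = 7)
  f <- svm_cv_fitness(tab, folds = 5, seed = 9)
  expect_equal(f(1, -3), f(1, -3))
  expect_gte(f(1, -3), 0.8)
  tab$f1[1] <- Inf
  expect_error(svm_cv_fitness(tab, seed = 9), "non-finite")
})

test_that("cross-validated SVM evaluation recovers planted separation", {
  tab <- sep_table(n = 120, delta = 5, seed = 8)
  cv <- evaluate_svm_cv(tab, cost = 1, gamma = 1 / 6, seed = 2)
  expect_gte(cv$report$f_measure, 0.9)
  expect_gte(cv$report$auc, 0.95)
  expect_equal(sort(unique(cv$fold_id)), 1:10)
})

test_that("per-feature ANOVA reproduces hand-computed statistics", {
  ## groups (1,2,3) vs (4,5,6): SSB = 13.5, MSW = 1, F = 13.5
  tab <- data.frame(x = c(1, 2, 3, 4, 5, 6), const = 1,
                    label = factor(rep(c("RI", "CSI"), each = 3),
                                   levels = c("RI", "CSI")))
  out <- feature_group_stats(tab)
  expect_equal(out$f_statistic[out$feature == "x"], 13.5)
  expect_equal(out$mean_ri[out$feature == "x"], 2)
  expect_equal(out$mean_csi[out$feature == "x"], 5)
  expect_equal(out$f_statistic[out$feature == "const"], 0)
  expect_equal(out$p_value[out$feature == "const"], 1)
  ## identical groups: no between-group variance
  tab2 <- data.frame(x = c(1, 2, 3, 1, 2, 3),
                     label = factor(rep(c("RI", "CSI"), each = 3),
                                    levels = c("RI", "CSI")))
  out2 <- feature_group_stats(tab2)
  expect_equal(out2$f_statistic, 0)
  expect_equal(out2$p_value, 1)
})

test_that("splice-signal features are strongly class-contrasting on planted data", {
  cfg <- sim_config(seed = 25)
  feats <- intron_features(simulate_labeled_introns(cfg, 150, 150))
  stats <- feature_group_stats(assemble_dataset(feats, "AC"))
  expect_lt(stats$p_value[stats$feature == "sf_value"], 0.01)
  expect_lt(stats$p_value[stats$feature == "sf_acc_value"], 0.01)
})

test_that("the fitted classifier object prints, predicts and plots", {
  cfg <- sim_config(seed = 27)
  recs <- simulate_labeled_introns(cfg, 100, 100)
  fit <- ri_classifier(recs, "rf", seed = 27)
  expect_s3_class(fit, "ri_classifier")
  expect_output(print(fit), "rf on preset ABC")
  newrecs <- simulate_labeled_introns(sim_config(seed = 28), 20, 20)
  pr <- predict(fit, newrecs)
  expect_length(pr, 40)
  expect_true(all(pr >= 0 & pr <= 1))
  cls <- predict(fit, newrecs, type = "class")
  expect_gte(mean(cls == newrecs$label), 0.7)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
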