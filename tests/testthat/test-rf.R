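# Ensemble classifiers: OOB behavior, mtry selection, importance, ROC.

sep_features <- function(n = 240, p = 15, seed = 4, noise = 0) {
  set.seed(seed)
  F <- matrix(rbinom(n * p, 1, 0.2), n,
              dimnames = list(sprintf("S%05d", 1:n),
                              c("GATA3", sprintf("G%02d", 2:p))))
  y <- ifelse(F[, "GATA3"] == 1, "positive", "negative")
  flip <- runif(n) < noise
  y[flip] <- ifelse(y[flip] == "positive", "negative", "positive")
  list(F = F, y = factor(y))
}

test_that("a noiseless separating feature yields near-perfect accuracy and
          tops the importance ranking", {
  d <- sep_features()
  m <- train_ensemble(d$F, d$y, n_trees = 300, cv_trees = 60, seed = 1)
  oob_lab <- colnames(m$oob_probs)[max.col(m$oob_probs, "first")]
  expect_gt(mean(oob_lab == d$y), 0.97)
  expect_true(m$mtry %in% unique(pmin(15, pmax(1, round(c(sqrt(15), 15 / 4,
                                                          15 / 2, 15))))))
  imp <- permutation_importance(m, d$F, d$y, n_rep = 5, seed = 2)
  expect_equal(attr(imp, "sorted")$feature[1], "GATA3")
  # constant/null features carry ~zero importance
  expect_lt(max(abs(imp$importance[imp$feature != "GATA3"])), 0.05)
})

test_that("independent labels give accuracy near the majority rate", {
  set.seed(6)
  n <- 200
  F <- matrix(rbinom(n * 10, 1, 0.3), n,
              dimnames = list(NULL, sprintf("G%02d", 1:10)))
  y <- factor(sample(rep(c("positive", "negative"), c(120, 80))))
  m <- train_ensemble(F, y, n_trees = 200, mtry = 3, seed = 1)
  oob_lab <- colnames(m$oob_probs)[max.col(m$oob_probs, "first")]
  expect_lt(mean(oob_lab == y), 0.68)
})

test_that("per-tree bootstraps are class-rebalanced", {
  d <- sep_features(n = 200)
  # unbalance the classes, then check each tree saw equal counts
  y <- d$y; y[1:60] <- "negative"
  m <- train_ensemble(d$F, y, n_trees = 50, mtry = 3, seed = 3)
  inbag <- m$rf$inbag
  per_class <- rowsum(inbag, y)
  m_min <- min(table(y))
  expect_true(all(colSums(rowsum(inbag, y) > 0) <= 200))
  expect_equal(unname(colSums(inbag[y == "positive", , drop = FALSE])),
               rep(m_min, 50))
  expect_equal(unname(colSums(inbag[y == "negative", , drop = FALSE])),
               rep(m_min, 50))
})

test_that("training samples are scored by out-of-bag votes, not resubstitution", {
  d <- sep_features(n = 300, noise = 0.3, seed = 9)
  fm <- make_features(d$F, group = rep("local", 300))
  labels <- ifelse(d$y == "positive", "positive", "negative")
  m <- train_subtype_classifier(fm, labels, n_trees = 300, mtry = 4,
                                include_tmb = FALSE, seed = 5)
  imp <- impute_er(m, fm)
  # imputed probabilities for training rows equal the stored OOB votes
  expect_equal(imp$er_prob,
               unname(m$oob_probs[imp$sample_id, "positive"]))
  # resubstitution votes are optimistically high on noisy data; OOB are not
  resub <- predict(m$rf, as.data.frame(d$F), type = "prob")[, "positive"]
  acc_resub <- mean((resub > 0.5) == (labels == "positive"))
  acc_oob <- mean((imp$er_prob > 0.5) == (labels == "positive"))
  expect_gt(acc_resub, acc_oob + 0.05)
  # vote fractions are complementary across classes
  expect_equal(rowSums(m$oob_probs), rep(1, nrow(m$oob_probs)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("more trees do not degrade OOB accuracy beyond noise", {
  d <- sep_features(n = 250, noise = 0.15, seed = 12)
  acc <- vapply(c(60, 400), function(nt) {
    m <- train_ensemble(d$F, d$y, n_trees = nt, mtry = 4, seed = 7)
    mean(colnames(m$oob_probs)[max.col(m$oob_probs, "first")] == d$y)
  }, numeric(1))
  expect_gt(acc[2], acc[1] - 0.04)
})

test_that("ER imputation on a simulated cohort beats the majority baseline", {
  cfg <- small_config()
  sim <- simulate_cohort(cfg, seed = 15)
  fm <- build_feature_matrix(sim$cohort, granularity = "gene_by_class")
  truth <- sim$truth$true_er
  labelled <- seq_along(truth) %in% sample(seq_along(truth), 700)
  labels <- ifelse(labelled, truth, NA)
  m <- train_subtype_classifier(fm, labels, n_trees = 300, cv_trees = 0,
                                mtry = 18, seed = 8)
  imp <- impute_er(m, fm)
  acc <- mean(imp$er_imputed[!labelled] == truth[!labelled])
  majority <- max(prop.table(table(truth[!labelled])))
  expect_gt(acc, majority + 0.03)
  expect_true(all(imp$er_prob >= 0 & imp$er_prob <= 1))
  expect_error(train_subtype_classifier(fm, rep("positive", nrow(fm$features))),
               "2 classes")
})

test_that("classifier evaluation matches hand-computed ROC/AUC", {
  probs <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  ev <- evaluate_classifier(probs, truth)
  expect_equal(ev$auc, 8 / 9, tolerance = 1e-12)   # rank-sum enumeration
  expect_equal(ev$accuracy, 4 / 6)                 # hand-enumerated at 0.5
  expect_equal(ev$roc$tpr[1], 0)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
  # perfect and random predictions
  expect_equal(evaluate_classifier(c(.9, .9, .1, .1),
                                   c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(20)
  rand <- evaluate_classifier(runif(4000), rbinom(4000, 1, 0.5) == 1)
  expect_lt(abs(rand$auc - 0.5), 0.04)
  deg <- evaluate_classifier(c(.2, .8), c(TRUE, TRUE))
  expect_true(is.na(deg$auc))
  expect_match(deg$reason, "one class")
})
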