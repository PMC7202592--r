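## Random-forest ensembles with class-rebalanced bootstraps, out-of-bag
## probabilities, cross-validated mtry, and permutation feature importance.

#' Train a class-rebalanced random-forest ensemble
#'
#' Each tree is fit on a bootstrap stratified to equal class sizes (the
#' minority-class count per class). `mtry` is selected by k-fold
#' cross-validation over a grid around the square-root default, and the
#' final model is refit on all data at the chosen value. The fraction of
#' tree votes for a class is that class's predicted probability;
#' out-of-bag votes provide probabilities for the training samples
#' themselves.
#'
#' @param x Numeric feature matrix or data frame (rows = samples).
#' @param y Two-level factor of labels.
#' @param n_trees Trees in the final ensemble (default 500; increase for
#'   production runs).
#' @param mtry Features per split; `NULL` selects by cross-validation.
#' @param mtry_grid Candidate grid; default `{sqrt(p), p/4, p/2, p}`.
#' @param cv_folds Cross-validation folds (default 10).
#' @param cv_trees Trees per cross-validation fit (default 200).
#' @param seed RNG seed.
#' @param target Label describing what is being predicted.
#' @return Object of class `metbc_ensemble`.
#' @export
train_ensemble <- function(x, y, n_trees = 500, mtry = NULL,
                           mtry_grid = NULL, cv_folds = 10, cv_trees = 200,
                           seed = 1, target = "label") {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes, got ", nlevels(y))
  set.seed(seed)
  p <- ncol(x)
  m <- min(table(y))
  sampsize <- setNames(rep(m, nlevels(y)), levels(y))

  if (is.null(mtry)) {
    if (is.null(mtry_grid))
      mtry_grid <- unique(pmin(p, pmax(1, round(c(sqrt(p), p / 4, p / 2, p)))))
    if (length(mtry_grid) > 1) {
      folds <- sample(rep(seq_len(cv_folds), length.out = length(y)))
      acc <- vapply(mtry_grid, function(mt) {
        hits <- 0L
        for (k in seq_len(cv_folds)) {
          tr <- folds != k
          if (length(unique(y[tr])) < 2) next
          ms <- setNames(rep(min(table(y[tr])), nlevels(y)), levels(y))
          rf <- randomForest::randomForest(
            x[tr, , drop = FALSE], y[tr], ntree = cv_trees, mtry = mt,
            strata = y[tr], sampsize = ms)
          hits <- hits + sum(predict(rf, x[!tr, , drop = FALSE]) == y[!tr])
        }
        hits / length(y)
      }, numeric(1))
      mtry <- mtry_grid[which.max(acc)]
    } else mtry <- mtry_grid
  }

  rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                   strata = y, sampsize = sampsize,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  structure(list(target = target, feature_names = colnames(x),
                 n_trees = n_trees, mtry = mtry, rf = rf,
                 classes = levels(y),
                 class_balance = sampsize,
                 oob_probs = rf$votes,       # vote fractions, OOB only
                 train_ids = rownames(x),
                 y_train = y),
            class = "metbc_ensemble")
}

#' @export
print.metbc_ensemble <- function(x, ...) {
  cat("metbc ensemble for", x$target, ":", x$n_trees, "trees, mtry",
      x$mtry, ",", length(x$feature_names), "features\n")
  cat("OOB accuracy:",
      round(mean(colnames(x$oob_probs)[max.col(x$oob_probs, "first")] ==
                   x$y_train), 3), "\n")
  invisible(x)
}

# matrix of per-sample vote fractions; training rows (matched by rowname)
# use out-of-bag votes, everything else the full-ensemble vote
.ensemble_probs <- function(model, x) {
  x <- as.data.frame(x)
  miss <- setdiff(model$feature_names, colnames(x))
  extra <- setdiff(colnames(x), model$feature_names)
  if (length(miss))
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  probs <- predict(model$rf, x, type = "prob")
  if (!is.null(rownames(x)) && !is.null(model$train_ids)) {
    tr <- rownames(x) %in% model$train_ids
    if (any(tr))
      probs[tr, ] <- model$oob_probs[match(rownames(x)[tr],
                                           model$train_ids), , drop = FALSE]
  }
  probs
}

#' Train a molecular- or histological-subtype classifier
#'
#' Trains the ensemble on the labelled rows of a feature matrix: binary
#' alteration flags plus (optionally) mutation load per megabase.
#'
#' @param fm A `metbc_features` matrix.
#' @param labels Character/factor vector aligned with the rows of `fm`;
#'   `NA`/"unknown" rows are excluded from training.
#' @param target Name of the predicted label.
#' @param include_tmb Include mutation load as a feature (default TRUE).
#' @param ... Passed to [train_ensemble()].
#' @return A `metbc_ensemble`.
#' @export
train_subtype_classifier <- function(fm, labels, target = "er_status",
                                     include_tmb = TRUE, ...) {
  stopifnot(inherits(fm, "metbc_features"))
  x <- as.data.frame(fm$features)
  if (include_tmb) x$tmb_per_mb <- fm$tmb_per_mb
  rownames(x) <- fm$samples$sample_id
  labels <- as.character(labels)
  known <- !is.na(labels) & labels != "unknown"
  if (length(unique(labels[known])) < 2)
    stop("need at least 2 classes among labelled samples")
  train_ensemble(x[known, , drop = FALSE], labels[known],
                 target = target, ...)
}

#' Impute ER status from genomic features
#'
#' Training samples receive their out-of-bag vote fraction (never the
#' resubstitution vote); unlabelled samples receive the full-ensemble vote
#' fraction. The hard label is positive when the positive-class probability
#' exceeds 0.5; an exact tie goes to the alphabetically first class.
#'
#' @param model A `metbc_ensemble` trained on ER labels.
#' @param fm A `metbc_features` matrix for the samples to impute.
#' @return Data frame with `sample_id`, `er_prob` (probability of the
#'   "positive" class) and `er_imputed`.
#' @export
impute_er <- function(model, fm) {
  stopifnot(inherits(model, "metbc_ensemble"), inherits(fm, "metbc_features"))
  x <- as.data.frame(fm$features)
  if ("tmb_per_mb" %in% model$feature_names) x$tmb_per_mb <- fm$tmb_per_mb
  rownames(x) <- fm$samples$sample_id
  probs <- .ensemble_probs(model, x)
  pos <- if ("positive" %in% colnames(probs)) "positive"
         else colnames(probs)[ncol(probs)]
  p <- probs[, pos]
  lab <- ifelse(p > 0.5, pos, setdiff(colnames(probs), pos)[1])
  data.frame(sample_id = fm$samples$sample_id, er_prob = unname(p),
             er_imputed = lab, stringsAsFactors = FALSE)
}

#' Permutation feature importance by out-of-bag accuracy decrease
#'
#' For each feature, permutes its column, recomputes per-tree predictions,
#' scores each training sample by the majority vote of the trees that did
#' not see it in their bootstrap, and reports the mean decrease in this
#' out-of-bag accuracy over `n_rep` independent permutations.
#'
#' @param model A `metbc_ensemble` (fit with `keep.inbag`, the default).
#' @param x Training feature matrix (same rows/columns as used to train).
#' @param y True labels.
#' @param n_rep Permutations per feature (default 5).
#' @param seed RNG seed.
#' @return Data frame of class `metbc_importance` with `feature` and
#'   `importance` (mean OOB accuracy drop), in input order;
#'   `attr(, "sorted")` holds the descending view.
#' @export
permutation_importance <- function(model, x, y, n_rep = 5, seed = 1) {
  stopifnot(inherits(model, "metbc_ensemble"))
  x <- as.data.frame(x)[, model$feature_names, drop = FALSE]
  y <- as.character(y)
  set.seed(seed)
  inbag <- model$rf$inbag
  oob <- inbag == 0                     # n x ntree
  if (is.null(inbag)) stop("model was trained without keep.inbag")

  oob_accuracy <- function(xx) {
    ind <- predict(model$rf, xx, predict.all = TRUE)$individual
    votes <- vapply(model$classes, function(cl)
      rowSums((ind == cl) & oob), numeric(nrow(xx)))
    pred <- model$classes[max.col(votes, "first")]
    usable <- rowSums(oob) > 0
    mean(pred[usable] == y[usable])
  }
  base <- oob_accuracy(x)
  imp <- vapply(model$feature_names, function(f) {
    drops <- vapply(seq_len(n_rep), function(r) {
      xp <- x
      xp[[f]] <- sample(xp[[f]])
      base - oob_accuracy(xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = model$feature_names, importance = unname(imp),
                    stringsAsFactors = FALSE)
  attr(out, "baseline_oob_accuracy") <- base
  attr(out, "sorted") <- out[order(-out$importance), , drop = FALSE]
  class(out) <- c("metbc_importance", "data.frame")
  out
}

#' Evaluate probabilistic predictions against binary truth
#'
#' Accuracy at the 0.5 threshold, the full ROC curve by threshold sweep,
#' and the area under it by the trapezoid rule.
#'
#' @param probs Predicted probabilities of the positive class.
#' @param truth Binary truth (logical, 0/1, or factor whose second level is
#'   positive).
#' @return List with `accuracy`, `roc` (data frame of threshold, fpr, tpr)
#'   and `auc` (NA with a reason when truth is degenerate).
#' @export
evaluate_classifier <- function(probs, truth) {
  if (is.factor(truth)) truth <- truth == levels(truth)[2]
  truth <- as.logical(truth)
  stopifnot(length(probs) == length(truth))
  acc <- mean((probs > 0.5) == truth)
  if (length(unique(truth)) < 2)
    return(list(accuracy = acc, roc = NULL, auc = NA_real_,
                reason = "degenerate truth: only one class present"))
  th <- c(Inf, sort(unique(probs), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(probs[truth] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(probs[!truth] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(accuracy = acc,
       roc = data.frame(threshold = th, fpr = fpr, tpr = tpr),
       auc = auc)
}
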