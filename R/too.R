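## Gene-masked tissue-of-origin classification and misdiagnosis inference.

# feature columns belonging to a gene: the mutation flag plus any
# gene-by-class columns ("GENE", "GENE.amplification", ...)
.gene_columns <- function(cols, genes)
  cols[cols %in% genes | sub("\\..*$", "", cols) %in% genes]

#' Train a breast-vs-other-tissue classifier with enriched genes masked
#'
#' Trains the standard rebalanced ensemble to separate breast-derived from
#' other-tissue-derived alteration profiles, after removing every feature
#' column of the masked genes (the alterations whose site enrichment
#' motivated the test, e.g. PTEN deletions for brain). Mutation load is
#' excluded from the feature set. A held-out split reports accuracy and
#' AUC.
#'
#' @param x_breast,x_other Binary feature matrices (samples x features,
#'   same columns) for the two tissues.
#' @param other_tissue Name of the non-breast class (`"lung"`, `"bone"`,
#'   `"brain"`, `"skin"`).
#' @param masked_genes Genes whose feature columns are removed before
#'   training; genes absent from the columns produce a warning only.
#' @param holdout_frac Fraction held out for evaluation (default 0.2).
#' @param seed RNG seed.
#' @param ... Passed to [train_ensemble()].
#' @return Object of class `metbc_too`: the ensemble plus `other_tissue`,
#'   `masked_genes`, `holdout` (accuracy, auc, n).
#' @export
train_too_classifier <- function(x_breast, x_other, other_tissue,
                                 masked_genes = character(),
                                 holdout_frac = 0.2, seed = 1, ...) {
  x_breast <- as.data.frame(x_breast)
  x_other <- as.data.frame(x_other)
  stopifnot(identical(colnames(x_breast), colnames(x_other)),
            nrow(x_breast) > 0, nrow(x_other) > 0)
  drop_cols <- .gene_columns(colnames(x_breast), masked_genes)
  not_found <- setdiff(masked_genes, sub("\\..*$", "", drop_cols))
  if (length(not_found))
    warning("masked gene(s) not among features: ",
            paste(not_found, collapse = ", "))
  keep <- setdiff(colnames(x_breast), drop_cols)
  x <- rbind(x_breast[, keep, drop = FALSE], x_other[, keep, drop = FALSE])
  y <- factor(rep(c("breast", other_tissue),
                  c(nrow(x_breast), nrow(x_other))),
              levels = c("breast", other_tissue))
  rownames(x) <- sprintf("too%05d", seq_len(nrow(x)))

  set.seed(seed)
  n <- nrow(x)
  ho <- sample.int(n, max(2, round(holdout_frac * n)))
  model <- train_ensemble(x[-ho, , drop = FALSE], y[-ho], seed = seed,
                          target = paste0("origin:", other_tissue), ...)
  probs <- predict(model$rf, x[ho, , drop = FALSE],
                   type = "prob")[, other_tissue]
  ev <- evaluate_classifier(probs, y[ho] == other_tissue)
  structure(c(model,
              list(other_tissue = other_tissue, masked_genes = masked_genes,
                   holdout = list(accuracy = ev$accuracy, auc = ev$auc,
                                  n = length(ho)))),
            class = c("metbc_too", "metbc_ensemble"))
}

#' Score samples for non-breast tissue of origin
#'
#' Probability of the other-tissue class from the ensemble vote fraction.
#' Masked-gene columns present in the input are ignored; any other feature
#' mismatch is an error.
#'
#' @param model A `metbc_too` classifier.
#' @param x Feature matrix for the samples to score.
#' @param stratum Optional per-sample stratum labels (e.g.
#'   `"carrier"`/`"background"`) carried into the score set.
#' @return Data frame of class `metbc_tooscores` with `sample_id`,
#'   `prob_other`, `classified_other` (vote fraction > 0.5) and `stratum`.
#' @export
score_samples <- function(model, x, stratum = NULL) {
  stopifnot(inherits(model, "metbc_too"))
  x <- as.data.frame(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("Q%05d", seq_len(nrow(x)))
  x <- x[, intersect(colnames(x), model$feature_names), drop = FALSE]
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "))
  p <- predict(model$rf, x[, model$feature_names, drop = FALSE],
               type = "prob")[, model$other_tissue]
  out <- data.frame(sample_id = ids, prob_other = unname(p),
                    classified_other = unname(p) > 0.5,
                    stratum = if (is.null(stratum)) NA_character_
                              else as.character(stratum),
                    stringsAsFactors = FALSE)
  class(out) <- c("metbc_tooscores", "data.frame")
  out
}

#' Compare tissue-of-origin scores between strata
#'
#' Two-sample Kolmogorov-Smirnov test on the score distributions of the
#' carrier stratum (metastases harboring the site-enriched alteration)
#' versus background, plus the fraction classified as the other tissue
#' (vote fraction above 0.5) per stratum.
#'
#' @param scores A `metbc_tooscores` with a two-level `stratum` column, or
#'   a numeric vector of carrier scores.
#' @param background Numeric vector of background scores (when `scores` is
#'   a vector).
#' @return List with `ks_statistic`, `ks_p`, `frac_classified` (named per
#'   stratum) and group sizes.
#' @export
misdiagnosis_test <- function(scores, background = NULL) {
  if (inherits(scores, "metbc_tooscores")) {
    strata <- split(scores$prob_other, scores$stratum)
    if (length(strata) != 2)
      stop("score set must contain exactly 2 strata")
    a <- strata[[1]]; b <- strata[[2]]
    nm <- names(strata)
  } else {
    a <- scores; b <- background
    nm <- c("carrier", "background")
  }
  if (length(a) < 2 || length(b) < 2)
    return(list(ks_statistic = NA_real_, ks_p = NA_real_,
                frac_classified = NULL, n = c(length(a), length(b))))
  ks <- ks_compare(a, b)
  list(ks_statistic = ks$statistic, ks_p = ks$p,
       frac_classified = setNames(c(mean(a > 0.5), mean(b > 0.5)), nm),
       n = setNames(c(length(a), length(b)), nm))
}

## Beta regression --------------------------------------------------------

#' Beta regression with a logit mean link
#'
#' Maximum-likelihood beta regression: the response mean follows
#' `logit(mu) = X beta` and a common precision `phi` is estimated on the
#' log scale. Standard errors come from the numerically evaluated observed
#' information. Used to compare classifier score distributions while
#' adjusting for covariates.
#'
#' @param y Responses in the open interval (0, 1).
#' @param X Design matrix including an intercept.
#' @return Object of class `metbc_betareg` with `coefficients`, `vcov`,
#'   `phi`, `converged`, `logLik`.
#' @export
beta_regression <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(all(y > 0 & y < 1), nrow(X) == length(y))
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  nll <- function(par) {
    beta <- par[-length(par)]
    phi <- exp(par[length(par)])
    mu <- plogis(pmin(pmax(drop(X %*% beta), -30), 30))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(coef(lm(qlogis(y) ~ X - 1)), log_phi = log(5))
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  k <- ncol(X)
  cf <- setNames(opt$par[seq_len(k)], colnames(X))
  V <- if (!is.null(vc)) vc[seq_len(k), seq_len(k), drop = FALSE]
       else matrix(NA_real_, k, k)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = cf,
                 vcov = V,
                 phi = exp(opt$par[k + 1]),
                 converged = opt$convergence == 0,
                 logLik = -opt$value), class = "metbc_betareg")
}

#' @export
coef.metbc_betareg <- function(object, ...) object$coefficients

#' Covariate-adjusted stratum comparison of classifier scores
#'
#' Beta regression of the (boundary-shrunk) other-tissue probability on a
#' stratum indicator plus covariates, with a Wald test on the stratum
#' coefficient. Scores are transformed by `(p (n - 1) + 1/2) / n` to keep
#' the support open, since ensemble vote fractions can hit 0 and 1 exactly.
#'
#' @param prob Scores in \[0, 1\].
#' @param stratum Two-level factor or logical (carrier vs background).
#' @param covariates Optional data frame of per-sample covariates.
#' @return List with `estimate`, `se`, `z`, `p` for the stratum effect,
#'   `converged`, and the full `fit`.
#' @export
covariate_adjusted_comparison <- function(prob, stratum, covariates = NULL) {
  n <- length(prob)
  y <- (prob * (n - 1) + 0.5) / n
  stratum <- as.numeric(as.factor(stratum)) - 1
  X <- cbind("(Intercept)" = 1, stratum = stratum)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    X <- cbind(X, as.matrix(data.frame(lapply(covariates, as.numeric))))
  }
  fit <- beta_regression(y, X)
  se <- sqrt(diag(fit$vcov))["stratum"]
  b <- coef(fit)["stratum"]
  z <- unname(b / se)
  list(estimate = unname(b), se = unname(se), z = z,
       p = 2 * pnorm(-abs(z)), converged = fit$converged, fit = fit)
}
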