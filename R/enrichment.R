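## Covariate-adjusted enrichment scanning with max-statistic permutation
## control of the family-wise error rate.

# assemble outcome, feature block and covariate block for a scan context
.scan_inputs <- function(fm, group1, group0, covariates, min_count,
                         keep = NULL) {
  stopifnot(inherits(fm, "metbc_features"))
  s <- fm$samples
  sel <- s$group %in% c(group1, group0)
  if (!is.null(keep)) sel <- sel & keep
  y <- as.numeric(s$group[sel] == group1)
  covs <- list(er_prob = s$er_prob[sel],
               her2_amplified = as.numeric(s$her2_amplified[sel]),
               tmb_per_mb = fm$tmb_per_mb[sel])
  C <- do.call(cbind, covs[covariates])
  # constant covariates carry no information and break the design
  keep_cov <- apply(C, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  C <- C[, keep_cov, drop = FALSE]
  ok <- stats::complete.cases(C) & !is.na(y)
  if (any(!ok))
    warning(sum(!ok), " sample(s) dropped for missing covariates")
  F <- fm$features[sel, , drop = FALSE][ok, , drop = FALSE]
  y <- y[ok]; C <- C[ok, , drop = FALSE]
  events <- colSums(F)
  testable <- events >= min_count & events < nrow(F)
  list(y = y, F = F[, testable, drop = FALSE], C = C,
       skipped = colnames(F)[!testable])
}

#' Scan alteration features for group enrichment
#'
#' Fits, per feature, `group ~ feature + covariates` by logistic regression
#' and reports the Wald test on the feature coefficient, together with
#' per-group prevalences and the odds ratio. Samples outside the two
#' compared groups (including the ambiguous group) are excluded; features
#' with fewer than `min_count` events in the tested context are skipped.
#' Per-feature fit failures are recorded and the scan continues.
#'
#' @param fm A `metbc_features` matrix.
#' @param group1,group0 Group labels compared (1 vs 0); defaults
#'   metastasis vs local.
#' @param covariates Covariate set; default ER-positivity probability, HER2
#'   amplification and mutation load per megabase.
#' @param min_count Minimum feature events in the tested context (default 10).
#' @param context Label recorded on each result row.
#' @return Data frame of class `metbc_enrichment`, sorted by raw p, with
#'   columns `feature`, `n1`, `n0`, `rate1`, `rate0`, `odds_ratio`,
#'   `wald_z`, `p_raw`, `p_corrected` (NA until
#'   [maxt_permutation_correct()]), `n_tested`, `context`, `filter`.
#' @export
enrichment_scan <- function(fm, group1 = "metastasis", group0 = "local",
                            covariates = c("er_prob", "her2_amplified",
                                           "tmb_per_mb"),
                            min_count = 10, context = "all_mets") {
  inp <- .scan_inputs(fm, group1, group0, covariates, min_count)
  y <- inp$y; F <- inp$F; C <- inp$C
  m <- ncol(F)
  res <- data.frame(feature = colnames(F), n1 = NA_integer_,
                    n0 = NA_integer_, rate1 = NA_real_, rate0 = NA_real_,
                    odds_ratio = NA_real_, wald_z = NA_real_,
                    p_raw = NA_real_, p_corrected = NA_real_,
                    n_tested = length(y), context = context,
                    filter = fm$filter, fit_error = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- F[, j]
    res$n1[j] <- sum(f[y == 1]); res$n0[j] <- sum(f[y == 0])
    res$rate1[j] <- mean(f[y == 1]); res$rate0[j] <- mean(f[y == 0])
    X <- cbind("(Intercept)" = 1, feature = f, C)
    fit <- tryCatch(fit_logistic(y, X), error = function(e) e)
    if (inherits(fit, "error")) {
      res$fit_error[j] <- conditionMessage(fit)
      next
    }
    wt <- wald_test(fit, "feature")
    res$odds_ratio[j] <- exp(unname(coef(fit)["feature"]))
    res$wald_z[j] <- wt$z
    res$p_raw[j] <- wt$p
  }
  res <- res[order(res$p_raw), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- inp$skipped
  class(res) <- c("metbc_enrichment", "data.frame")
  res
}

#' Family-wise permutation correction by the min-p max-statistic method
#'
#' Permutes the outcome labels (covariates stay attached to their samples),
#' reruns the full feature scan per permutation, and records the most
#' significant raw p. Each feature's corrected p is
#' `(1 + #{permutations with min-p <= p_raw}) / (n_perm + 1)`, floored at
#' its own raw p. This controls the family-wise error rate across the whole
#' alteration family.
#'
#' @param fm A `metbc_features` matrix.
#' @param group1,group0,covariates,min_count As in [enrichment_scan()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param scan Optional precomputed [enrichment_scan()] result to correct;
#'   computed if missing.
#' @param screen_k Per permutation, the number of score-test-ranked
#'   candidate features refit exactly to locate the minimum p (default 20;
#'   raise towards the family size for a fully exhaustive pass).
#' @return The scan data frame with `p_corrected` filled in; permutation
#'   min-p values in `attr(, "perm_min_p")`.
#' @export
maxt_permutation_correct <- function(fm, group1 = "metastasis",
                                     group0 = "local",
                                     covariates = c("er_prob",
                                                    "her2_amplified",
                                                    "tmb_per_mb"),
                                     min_count = 10, n_perm = 1000,
                                     seed = 1, scan = NULL, screen_k = 20) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  inp <- .scan_inputs(fm, group1, group0, covariates, min_count)
  if (is.null(scan))
    scan <- enrichment_scan(fm, group1, group0, covariates, min_count)
  set.seed(seed)
  n <- length(inp$y)
  Y <- vapply(seq_len(n_perm), function(b) inp$y[sample.int(n)],
              numeric(n))
  minp <- cpp_maxt_min_p(inp$F, inp$C, Y, as.integer(screen_k))
  pc <- vapply(scan$p_raw, function(p) {
    if (is.na(p)) return(NA_real_)
    (1 + sum(minp <= p)) / (n_perm + 1)
  }, numeric(1))
  scan$p_corrected <- pmax(pc, scan$p_raw)
  attr(scan, "perm_min_p") <- minp
  scan
}

#' Site-specific enrichment scans
#'
#' Compares metastases from each biopsy site separately against all local
#' samples, with the same model and covariates as the pooled scan. Sites
#' without samples are skipped with a warning.
#'
#' @param fm A `metbc_features` matrix.
#' @param sites Sites to scan; default every metastatic site present.
#' @param covariates,min_count As in [enrichment_scan()].
#' @param n_perm Optional permutation count for per-site correction
#'   (`NULL` skips correction).
#' @param seed RNG seed for the permutation step.
#' @return Named list of `metbc_enrichment` data frames.
#' @export
site_specific_scan <- function(fm, sites = NULL,
                               covariates = c("er_prob", "her2_amplified",
                                              "tmb_per_mb"),
                               min_count = 10, n_perm = NULL, seed = 1) {
  s <- fm$samples
  if (is.null(sites))
    sites <- sort(unique(s$biopsy_site[s$group == "metastasis"]))
  out <- list()
  for (st in sites) {
    keep <- s$group == "local" |
      (s$group == "metastasis" & s$biopsy_site == st)
    if (!any(s$group == "metastasis" & s$biopsy_site == st)) {
      warning("no metastatic samples at site ", st, "; skipped")
      next
    }
    sub <- fm
    sub$features <- fm$features[keep, , drop = FALSE]
    sub$tmb_per_mb <- fm$tmb_per_mb[keep]
    sub$hypermutated <- fm$hypermutated[keep]
    sub$samples <- s[keep, , drop = FALSE]
    ctx <- paste0("site:", st)
    out[[st]] <- if (is.null(n_perm))
      enrichment_scan(sub, covariates = covariates, min_count = min_count,
                      context = ctx)
    else
      maxt_permutation_correct(sub, covariates = covariates,
                               min_count = min_count, n_perm = n_perm,
                               seed = seed)
  }
  out
}
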