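## Exact and nonparametric supporting tests. These delegate to the standard
## stats implementations; the test suite cross-checks them against
## brute-force oracles (hypergeometric enumeration, pairwise win counts).

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than that
#' of the observed table. A table with a zero margin carries no information
#' and returns p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Fisher's exact test for an r x c table
#'
#' Exact (network-algorithm) p for small tables; Monte-Carlo with fixed
#' margins and the (1 + k)/(B + 1) estimator otherwise, or when the exact
#' computation exceeds its workspace.
#'
#' @param tab r x c matrix of nonnegative integer counts.
#' @param n_mc Monte-Carlo replicates for large tables (default 1e4).
#' @param seed RNG seed used for the Monte-Carlo path.
#' @param force_mc Use the Monte-Carlo path regardless of table size.
#' @return p-value.
#' @export
fisher_exact_rxc <- function(tab, n_mc = 1e4, seed = 1, force_mc = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be nonnegative integers")
  if (all(dim(tab) == c(2, 2))) return(fisher_exact_2x2(tab))
  keep <- rowSums(tab) > 0
  tab <- tab[keep, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2)) return(1)
  small <- !force_mc && sum(tab) <= 200 && prod(dim(tab)) <= 20
  if (small) {
    p <- tryCatch(fisher.test(tab, workspace = 2e7)$p.value,
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  set.seed(seed)
  fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
}

#' Compare per-sample alteration counts between groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with normal
#' approximation and tie correction.
#'
#' @param group_a,group_b Numeric vectors of per-sample counts.
#' @return List with `U` (number of (a, b) pairs where a wins, ties counted
#'   half) and `p`.
#' @export
compare_counts <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two sets of classifier probabilities by the maximum gap between
#' their empirical distribution functions.
#'
#' @param x,y Numeric vectors.
#' @return List with `statistic` and `p` (two-sided).
#' @export
ks_compare <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    return(list(statistic = NA_real_, p = NA_real_))
  kt <- suppressWarnings(ks.test(x, y))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
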