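# Enrichment scanning, permutation correction, exact/nonparametric tests.

null_features <- function(n = 1500, m = 60, seed = 1) {
  set.seed(seed)
  F <- vapply(seq_len(m), function(j) rbinom(n, 1, runif(1, 0.03, 0.25)),
              numeric(n))
  colnames(F) <- sprintf("G%03d", seq_len(m))
  make_features(F, group = sample(rep(c("metastasis", "local"),
                                      length.out = n)),
                er_prob = rbinom(n, 1, 0.6), her2 = rbinom(n, 1, 0.1) == 1,
                tmb = rowSums(F) / 1.1 + rnorm(n, 0, 0.3))
}

test_that("raw p-values are near-uniform under the null", {
  fm <- null_features()
  sc <- enrichment_scan(fm, min_count = 10)
  frac <- mean(sc$p_raw < 0.05, na.rm = TRUE)
  expect_lt(frac, 0.12)
  expect_gt(mean(sc$p_raw > 0.5, na.rm = TRUE), 0.3)
})

test_that("planted effects surface in the scan on a default cohort", {
  cfg <- default_generator_config()
  sim <- simulate_cohort(cfg, seed = 1)
  fm <- build_feature_matrix(sim$cohort, granularity = "gene_by_class")
  sc <- as.data.frame(enrichment_scan(fm))
  esr1 <- sc[sc$feature == "ESR1", ]
  expect_lt(esr1$p_raw, 1e-10)
  expect_gt(esr1$odds_ratio, 1)
  ctcf <- sc[sc$feature == "CTCF", ]
  expect_lt(ctcf$p_raw, 0.05)
  cdkn1b <- sc[sc$feature == "CDKN1B.amplification", ]
  expect_lt(cdkn1b$odds_ratio, 1)   # depletion reported as OR < 1
  expect_lt(cdkn1b$p_raw, 1e-6)
})

test_that("scan respects min_count and is equivariant to sample order", {
  set.seed(3)
  n <- 400
  F <- cbind(rare = c(rep(1, 9), rep(0, n - 9)),
             common = rbinom(n, 1, 0.3))
  fm <- make_features(F, group = sample(rep(c("metastasis", "local"),
                                            length.out = n)))
  sc <- enrichment_scan(fm, min_count = 10)
  expect_false("rare" %in% sc$feature)
  expect_true("rare" %in% attr(sc, "skipped"))
  sc9 <- enrichment_scan(fm, min_count = 9)
  expect_true("rare" %in% sc9$feature)

  perm <- sample.int(n)
  fmp <- fm
  fmp$features <- fm$features[perm, , drop = FALSE]
  fmp$tmb_per_mb <- fm$tmb_per_mb[perm]
  fmp$hypermutated <- fm$hypermutated[perm]
  fmp$samples <- fm$samples[perm, ]
  scp <- enrichment_scan(fmp, min_count = 10)
  expect_equal(as.data.frame(sc), as.data.frame(scp), tolerance = 1e-10)
})

test_that("corrected p never falls below raw p and matches the single-feature
          permutation oracle", {
  set.seed(5)
  n <- 300
  grp <- rep(c("metastasis", "local"), each = n / 2)
  f <- rbinom(n, 1, plogis(-1.5 + 0.8 * (grp == "metastasis")))
  fm <- make_features(cbind(only = f), group = grp,
                      er_prob = rbinom(n, 1, 0.5), tmb = rnorm(n, 5))
  n_perm <- 400
  mc <- maxt_permutation_correct(fm, min_count = 5, n_perm = n_perm,
                                 seed = 77)
  expect_true(all(mc$p_corrected >= mc$p_raw))

  # oracle: same permutations scored with glm Wald p
  inp <- metbc:::.scan_inputs(fm, "metastasis", "local",
                              c("er_prob", "her2_amplified", "tmb_per_mb"),
                              min_count = 5)
  set.seed(77)
  Y <- vapply(seq_len(n_perm), function(b) inp$y[sample.int(n)], numeric(n))
  p_perm <- apply(Y, 2, function(yb) {
    g <- glm(yb ~ inp$F[, 1] + inp$C, family = binomial())
    summary(g)$coefficients[2, 4]
  })
  oracle <- (1 + sum(p_perm <= mc$p_raw[1])) / (n_perm + 1)
  expect_equal(mc$p_corrected[1], max(oracle, mc$p_raw[1]),
               tolerance = 0.01)
})

test_that("maxT correction keeps null features non-significant and planted
          effects significant on a simulated cohort", {
  cfg <- small_config()
  sim <- simulate_cohort(cfg, seed = 9)
  fm <- build_feature_matrix(sim$cohort, granularity = "gene_by_class")
  mc <- as.data.frame(maxt_permutation_correct(fm, n_perm = 200, seed = 10))
  expect_true(all(mc$p_corrected >= mc$p_raw, na.rm = TRUE))
  expect_lt(mc$p_corrected[mc$feature == "ESR1"], 0.01)
  bg <- grepl("^BG", mc$feature)
  expect_gt(min(mc$p_corrected[bg], na.rm = TRUE), 0.05)
  expect_error(maxt_permutation_correct(fm, n_perm = 0), "n_perm")
})

test_that("site-specific scans localize planted site effects", {
  cfg <- default_generator_config()
  sim <- simulate_cohort(cfg, seed = 2)
  fm <- build_feature_matrix(sim$cohort, granularity = "gene_by_class")
  sc <- site_specific_scan(fm, sites = c("skin", "liver"), min_count = 5)
  skin <- as.data.frame(sc$skin)
  liver <- as.data.frame(sc$liver)
  # NOTCH1 planted in skin (8.8% vs 4.5%), absent from liver
  expect_lt(skin[skin$feature == "NOTCH1", "p_raw"], 0.05)
  expect_gt(liver[liver$feature == "NOTCH1", "p_raw"], 0.05)
  expect_equal(unique(skin$context), "site:skin")
  # restriction identity: site scan equals pooled scan on the subset
  keep <- fm$samples$group == "local" |
    (fm$samples$group == "metastasis" & fm$samples$biopsy_site == "skin")
  sub <- fm
  sub$features <- fm$features[keep, , drop = FALSE]
  sub$tmb_per_mb <- fm$tmb_per_mb[keep]
  sub$hypermutated <- fm$hypermutated[keep]
  sub$samples <- fm$samples[keep, ]
  direct <- enrichment_scan(sub, min_count = 5, context = "site:skin")
  expect_equal(as.data.frame(direct), as.data.frame(sc$skin),
               tolerance = 1e-10)
})

test_that("Fisher 2x2 equals hypergeometric enumeration on random tables", {
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, sample(2:8, 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum_2x2(tab),
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2)), 1)  # zero margin
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("r x c Fisher reduces to 2x2 and MC agrees with enumeration", {
  tab <- matrix(c(3, 9, 6, 2), 2)
  expect_equal(fisher_exact_rxc(tab), fisher_exact_2x2(tab))
  tab23 <- matrix(c(3, 1, 4, 2, 2, 5), nrow = 2)
  exact <- fisher_exact_rxc(tab23)
  mc <- fisher_exact_rxc(tab23, n_mc = 4e4, seed = 3, force_mc = TRUE)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 4e4) + 1e-3)
  # independence-generated tables give roughly uniform p
  set.seed(13)
  ps <- replicate(40, {
    t45 <- matrix(rpois(20, 5), 4, 5)
    fisher_exact_rxc(t45, n_mc = 2000, seed = sample.int(1e6, 1))
  })
  expect_gt(mean(ps > 0.1), 0.6)
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("Mann-Whitney U equals the brute-force pairwise win count", {
  a <- c(3, 5, 7, 7, 9, 1, 4, 12)
  b <- c(2, 5, 6, 8, 10, 0, 3, 7)
  wins <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  r <- compare_counts(a, b)
  expect_equal(unname(r$U), wins)
  ident <- compare_counts(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p, 0.9)
  # planted mutation-load difference on the default cohort is detected
  cfg <- small_config()
  sim <- simulate_cohort(cfg, seed = 14)
  fmx <- build_feature_matrix(sim$cohort)
  cnt <- fmx$tmb_per_mb * fmx$panel_mb
  grp <- fmx$samples$group
  mw <- compare_counts(cnt[grp == "metastasis"], cnt[grp == "local"])
  expect_lt(mw$p, 1e-4)
  expect_gt(mean(cnt[grp == "metastasis"]), mean(cnt[grp == "local"]))
})
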