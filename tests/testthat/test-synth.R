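# Synthetic-cohort generator: reproducibility, planted-marginal recovery,
# ESR1 mixtures, CHIP model, pathology reports.

test_that("default configuration validates and plants the published sizes", {
  cfg <- default_generator_config()
  expect_equal(cfg$n_local + cfg$n_lymph + cfg$n_met, 10903)
  expect_equal(cfg$n_ambiguous, 713)
  expect_equal(cfg$esr1_model$met_site_rates_er_pos[["liver"]], 0.44)
  expect_equal(cfg$esr1_model$hotspot_mixture[["D538G"]], 0.332)
  expect_equal(sum(cfg$esr1_model$hotspot_mixture), 1, tolerance = 1e-12)
  probs <- c(unlist(cfg$er_by_group), cfg$her2_by_group,
             cfg$baseline$rate_pos, cfg$baseline$rate_neg, cfg$site_freqs)
  expect_true(all(probs >= 0 & probs <= 1))
  # invalid configs are rejected before sampling
  bad <- cfg; bad$site_freqs[1] <- bad$site_freqs[1] + 0.1
  expect_error(simulate_cohort(bad, 1), "sum to 1")
  bad2 <- cfg; bad2$enrichment$odds_multiplier[1] <- -2
  expect_error(validate_config(bad2), "odds multipliers")
})

test_that("identical config and seed give identical cohorts; seeds differ", {
  cfg <- small_config()
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  c <- simulate_cohort(cfg, seed = 12)
  expect_identical(a$cohort$samples, b$cohort$samples)
  expect_identical(a$cohort$alterations, b$cohort$alterations)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$cohort$alterations, c$cohort$alterations))
  # truth completeness: exactly one row per sample
  expect_identical(a$truth$sample_id, a$cohort$samples$sample_id)
})

test_that("a null configuration shows no metastatic enrichment", {
  cfg <- default_generator_config(n_local = 5000, n_lymph = 0,
                                  n_met = 5000, n_ambiguous = 0)
  cfg$enrichment$odds_multiplier[] <- 1
  cfg$background$met_odds_multiplier <- 1
  cfg$contaminant_model$fraction <- 0
  sim <- simulate_cohort(cfg, seed = 5)
  al <- sim$cohort$alterations
  tr <- sim$truth
  m <- tr$group == "metastasis"
  for (g in c("CTCF", "KRAS", "NF1")) {
    carrier <- tr$sample_id %in%
      al$sample_id[al$gene == g & al$alteration_class == "short_variant"]
    p_pool <- mean(carrier)
    se <- sqrt(p_pool * (1 - p_pool) * (1 / sum(m) + 1 / sum(!m)))
    expect_lt(abs(mean(carrier[m]) - mean(carrier[!m])), 4 * se)
  }
})

test_that("planted per-gene rates are recovered within binomial error", {
  cfg <- default_generator_config(n_local = 20000, n_lymph = 0,
                                  n_met = 0, n_ambiguous = 0)
  cfg$background$hypermutated_fraction <- 0
  sim <- simulate_cohort(cfg, seed = 3)
  al <- sim$cohort$alterations
  er_pos <- sim$truth$true_er == "positive"
  # KMT2D planted at 0.095 in both subtypes, no enrichment, local only
  carrier <- sim$truth$sample_id %in%
    al$sample_id[al$gene == "KMT2D" & al$alteration_class == "short_variant"]
  expect_lt(abs(mean(carrier) - 0.095), 4 * sqrt(0.095 * 0.905 / 20000))
  # subtype-split rate for TP53 (0.45 ER+ / 0.85 ER-)
  tp53 <- sim$truth$sample_id %in%
    al$sample_id[al$gene == "TP53" & al$alteration_class == "short_variant"]
  expect_lt(abs(mean(tp53[er_pos]) - 0.45),
            4 * sqrt(0.45 * 0.55 / sum(er_pos)))
  expect_lt(abs(mean(tp53[!er_pos]) - 0.85),
            4 * sqrt(0.85 * 0.15 / sum(!er_pos)))
})

test_that("planted enrichment multiplier is recovered on the log-odds scale", {
  cfg <- default_generator_config(n_local = 15000, n_lymph = 0,
                                  n_met = 15000, n_ambiguous = 0)
  cfg$background$hypermutated_fraction <- 0
  cfg$contaminant_model$fraction <- 0
  # plant a strong, well-powered effect on a mid-prevalence gene
  cfg$baseline$rate_pos[cfg$baseline$gene == "KMT2D"] <- 0.10
  cfg$baseline$rate_neg[cfg$baseline$gene == "KMT2D"] <- 0.10
  cfg$enrichment <- rbind(cfg$enrichment,
                          data.frame(gene = "KMT2D", class = "short_variant",
                                     context = "all_mets",
                                     odds_multiplier = 2,
                                     er_restrict = "both"))
  sim <- simulate_cohort(cfg, seed = 8)
  al <- sim$cohort$alterations
  tr <- sim$truth
  carrier <- tr$sample_id %in%
    al$sample_id[al$gene == "KMT2D" & al$alteration_class == "short_variant"]
  m <- tr$group == "metastasis"
  lo <- function(p) log(p / (1 - p))
  diff_lo <- lo(mean(carrier[m])) - lo(mean(carrier[!m]))
  se <- sqrt(1 / sum(carrier & m) + 1 / sum(!carrier & m) +
               1 / sum(carrier & !m) + 1 / sum(!carrier & !m))
  expect_lt(abs(diff_lo - log(2)), 3 * se)
})

test_that("hotspot mixture draws recover the configured fractions", {
  cfg <- small_config()
  set.seed(21)
  v <- simulate_esr1_variants(10000, cfg$esr1_model)
  frac <- prop.table(table(v$hotspot_label))
  se <- function(p) sqrt(p * (1 - p) / nrow(v))
  expect_lt(abs(frac[["D538G"]] - 0.332), 3 * se(0.332))
  expect_lt(abs(frac[["Y537S"]] - 0.214), 3 * se(0.214))
  # multi-mutation frequency among mutant samples
  per <- table(v$sample)
  multi <- mean(per >= 2)
  expect_lt(abs(multi - 0.089), 3 * sqrt(0.089 * 0.911 / 10000))
  # degenerate mixture: every draw is the single allowed hotspot
  em <- cfg$esr1_model
  em$hotspot_mixture[] <- 0; em$hotspot_mixture["D538G"] <- 1
  em$multi_mut_prob <- 0
  set.seed(1)
  expect_true(all(simulate_esr1_variants(50, em)$hotspot_label == "D538G"))
  # invalid mixture is a hard error
  em$hotspot_mixture["D538G"] <- 0.5
  expect_error(simulate_esr1_variants(5, em), "sum to 1")
})

test_that("site and histology tilts shift the drawn mixtures", {
  cfg <- small_config()
  set.seed(4)
  n <- 4000
  bone <- simulate_esr1_variants(n, cfg$esr1_model, site = rep("bone", n))
  liver <- simulate_esr1_variants(n, cfg$esr1_model, site = rep("liver", n))
  expect_gt(mean(liver$hotspot_label == "D538G"),
            mean(bone$hotspot_label == "D538G"))
  expect_gt(mean(bone$hotspot_label == "Y537S"),
            mean(liver$hotspot_label == "Y537S"))
  ilc <- simulate_esr1_variants(n, cfg$esr1_model,
                                histology = rep("ILC", n))
  expect_gt(mean(ilc$hotspot_label == "E380Q"), 0.15)
})

test_that("CHIP VAF declines with age while tumor VAF does not", {
  cfg <- small_config()
  chm <- cfg$chip_model
  ages <- rep(seq(25, 85, by = 10), each = 1000)
  set.seed(2)
  v <- simulate_chip_vaf(ages, chm)
  expect_true(all(v >= 0 & v <= 1))
  fit <- lm(v ~ ages)
  expect_lt(coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, 4], 1e-10)
  # constant-mean model: means at age 40 vs 80 within 3 SE
  flat <- chm; flat$vaf_logit_slope <- 0
  set.seed(3)
  a40 <- simulate_chip_vaf(rep(40, 2000), flat)
  a80 <- simulate_chip_vaf(rep(80, 2000), flat)
  se <- sqrt(var(a40) / 2000 + var(a80) / 2000)
  expect_lt(abs(mean(a40) - mean(a80)), 3 * se)
})

test_that("pathology-report generation covers templates and negation", {
  r <- simulate_pathology_report("positive", "plain")
  expect_match(r$text, "ER staining was detected", fixed = TRUE)
  r2 <- simulate_pathology_report("negative", "plain")
  expect_match(r2$text, "ER staining was not detected", fixed = TRUE)
  expect_equal(r2$truth, "negative")
  expect_error(simulate_pathology_report("positive",
                                         templates = list(positive = c())),
               "empty template set")
  # report suite carries ground truth for every row
  sim <- simulate_cohort(small_config(), seed = 6)
  expect_true(all(sim$reports$truth %in% c("positive", "negative")))
  expect_true(all(sim$reports$sample_id %in% sim$cohort$samples$sample_id))
})
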