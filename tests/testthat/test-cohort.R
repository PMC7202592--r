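# Cohort data model, tabular I/O, group assignment, feature construction.

test_that("assign_group is total, deterministic, and maps known sites", {
  expect_equal(assign_group("breast"), "local")
  expect_equal(assign_group("chest wall"), "local")
  expect_equal(assign_group("lymph node"), "lymph_node")
  expect_equal(assign_group(c("liver", "bone", "lung", "brain", "skin",
                              "pleura", "pleural fluid", "soft tissue",
                              "ovary", "GI")),
               rep("metastasis", 10))
  expect_equal(assign_group("xyzzy"), "ambiguous")
  expect_equal(assign_group("unknown"), "ambiguous")
  # deterministic over the vocabulary
  vocab <- c(names(site_group_map()), "other", "unknown", "")
  expect_identical(assign_group(vocab), assign_group(vocab))
})

test_that("sample table reading fills groups, validates and warns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tbiopsy_site\tgroup\ter_status",
               "s1\tliver\t.\tpositive",
               "s2\tbreast\t.\tnegative",
               "s3\tweird-site\t.\twhoops"), tmp)
  expect_warning(s <- read_sample_table(tmp), "malformed er_status")
  expect_equal(s$group, c("metastasis", "local", "ambiguous"))
  expect_equal(s$er_status[3], "unknown")

  # empty file with valid header -> empty table
  writeLines("sample_id\tbiopsy_site", tmp)
  expect_equal(nrow(read_sample_table(tmp)), 0)

  # duplicate id is a hard error naming the id
  writeLines(c("sample_id\tbiopsy_site", "s1\tliver", "s2\tbone",
               "s1\tbreast"), tmp)
  expect_error(read_sample_table(tmp), "duplicate sample_id: s1")

  # missing required column named in the error
  writeLines(c("sample_id\ter_status", "s1\tpositive"), tmp)
  expect_error(read_sample_table(tmp), "biopsy_site")
})

test_that("alteration table reading validates class, vaf and sample ids", {
  stmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tbiopsy_site", "s1\tliver"), stmp)
  s <- read_sample_table(stmp)

  atmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene\talteration_class\tprotein_change\tvaf",
               "s1\tESR1\tshort_variant\tD538G\t0.21"), atmp)
  co <- read_alteration_table(atmp, s)
  expect_equal(co$alterations$protein_change, "D538G")
  expect_equal(co$alterations$vaf, 0.21)

  writeLines("sample_id\tgene\talteration_class", atmp)
  expect_equal(nrow(read_alteration_table(atmp, s)$alterations), 0)

  writeLines(c("sample_id\tgene\talteration_class\tvaf",
               "s1\tESR1\tshort_variant\t1.2"), atmp)
  expect_error(read_alteration_table(atmp, s), "vaf")

  writeLines(c("sample_id\tgene\talteration_class",
               "s1\tESR1\tbig_bang"), atmp)
  expect_error(read_alteration_table(atmp, s), "alteration_class")

  writeLines(c("sample_id\tgene\talteration_class",
               "s1\tESR1\tshort_variant",
               "sX\tTP53\tshort_variant"), atmp)
  expect_warning(co <- read_alteration_table(atmp, s), "1 alteration")
  expect_equal(nrow(co$alterations), 1)
})

test_that("write/read round-trip reproduces the cohort field by field", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir, panel = co$panel)
  expect_equal(back$samples, co$samples)
  expect_equal(back$alterations, co$alterations)
  expect_equal(back$panel, co$panel)
})

test_that("feature flags respect the VUS filter and match brute force", {
  co <- tiny_cohort()
  fm_all <- build_feature_matrix(co, filter = "all_variants")
  fm_kl <- build_feature_matrix(co, filter = "known_likely_only")
  # B's TP53 R273C is a VUS: flagged under all_variants only
  expect_equal(fm_all$features["B", "TP53"], 1L)
  expect_equal(fm_kl$features["B", "TP53"], 0L)
  # sample with no calls: all-zero row, zero load, not hypermutated
  expect_equal(sum(fm_all$features["D", ]), 0)
  expect_equal(fm_all$tmb_per_mb[4], 0)
  expect_false(fm_all$hypermutated[4])

  # brute-force recomputation of every flag on a random cohort
  cfg <- small_config()
  sim <- simulate_cohort(cfg, seed = 42)
  fm <- build_feature_matrix(sim$cohort, granularity = "gene_by_class")
  al <- sim$cohort$alterations
  sv <- al[al$alteration_class == "short_variant", ]
  for (g in c("TP53", "ESR1", "CTCF", "BG001")) {
    brute <- as.integer(sim$cohort$samples$sample_id %in%
                          sv$sample_id[sv$gene == g])
    expect_equal(unname(fm$features[, g]), brute, label = g)
  }
  amp <- al[al$alteration_class == "amplification" & al$gene == "CDKN1B", ]
  expect_equal(unname(fm$features[, "CDKN1B.amplification"]),
               as.integer(sim$cohort$samples$sample_id %in% amp$sample_id))
})

test_that("mutation load is linear in qualifying variants; hypermutation at >25 genes", {
  make <- function(n_genes) {
    ids <- "s1"
    panel <- sprintf("G%03d", 1:40)
    alt <- data.frame(sample_id = "s1", gene = panel[seq_len(n_genes)],
                      alteration_class = "short_variant",
                      protein_change = NA, functional_status = "known",
                      vaf = 0.3, stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = ids, biopsy_site = "breast",
                          group = "local", er_status = "unknown",
                          er_source = "unknown", er_prob = NA,
                          her2_amplified = FALSE, histology = "unknown",
                          age_years = 50L, stringsAsFactors = FALSE)
    build_feature_matrix(cohort(samples, alt, panel))
  }
  expect_false(make(25)$hypermutated)
  expect_true(make(26)$hypermutated)
  counts <- c(0, 3, 11, 26)
  tmb <- vapply(counts, function(k) make(max(k, 1))$tmb_per_mb, numeric(1))
  tmb[1] <- 0
  expect_equal(tmb, counts / 1.1, tolerance = 1e-12)
  expect_error(build_feature_matrix(cohort(make(1)$samples,
                                           tiny_cohort()$alterations[0, ],
                                           character(0))),
               "empty gene panel")
})

test_that("cohort summaries match hand computation and are compositional", {
  co <- tiny_cohort()
  sm <- summarize_cohort(co)
  expect_equal(unname(sm$group_counts[c("local", "metastasis")]),
               c(2L, 1L), ignore_attr = TRUE)
  expect_equal(sm$distal_met_fraction, 0.25)
  # one ER+ local sample at breast plus one unknown: hand proportions
  expect_equal(sm$subtype_by_site["breast", "ER+/HER2-"], 0.5)
  expect_equal(sm$subtype_by_site["liver", "HER2amp"], 1)
  expect_true(all(abs(rowSums(sm$subtype_by_site) - 1) < 1e-9))
  expect_true(all(abs(rowSums(sm$histology_by_site) - 1) < 1e-9))
  # prevalence ranking is sorted descending
  expect_true(!is.unsorted(rev(sm$alteration_prevalence$prevalence)))
})
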