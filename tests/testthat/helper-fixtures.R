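# Shared fixtures, built in code.

# minimal hand-enumerable cohort: 4 samples, 3-gene panel
tiny_cohort <- function() {
  samples <- data.frame(
    sample_id = c("A", "B", "C", "D"),
    biopsy_site = c("breast", "liver", "lymph node", "breast"),
    group = c("local", "metastasis", "lymph_node", "local"),
    er_status = c("positive", "negative", "positive", "unknown"),
    er_source = c("pathology_report", "pathology_report",
                  "imputed", "unknown"),
    er_prob = c(1, 0, 0.8, NA),
    her2_amplified = c(FALSE, TRUE, FALSE, FALSE),
    histology = c("IDC", "ILC", "IDC", "unknown"),
    age_years = c(55L, 61L, 48L, NA),
    stringsAsFactors = FALSE)
  alterations <- data.frame(
    sample_id = c("A", "A", "B", "B", "C"),
    gene = c("TP53", "ESR1", "TP53", "CDKN1B", "ESR1"),
    alteration_class = c("short_variant", "short_variant", "short_variant",
                         "amplification", "short_variant"),
    protein_change = c("R175H", "D538G", "R273C", NA, "Y537S"),
    functional_status = c("known", "known", "VUS", "known", "known"),
    vaf = c(0.41, 0.22, 0.35, NA, 0.18),
    stringsAsFactors = FALSE)
  cohort(samples, alterations, panel = c("TP53", "ESR1", "CDKN1B"))
}

# scaled-down generator config for fast simulation tests
small_config <- function(...)
  default_generator_config(n_local = 800, n_lymph = 200, n_met = 1000,
                           n_ambiguous = 50, ...)

# metbc_features built directly from raw pieces (for synthetic-null scans)
make_features <- function(F, group, er_prob = NULL, her2 = NULL,
                          tmb = NULL) {
  n <- nrow(F)
  if (is.null(er_prob)) er_prob <- rep(0.5, n)
  if (is.null(her2)) her2 <- rep(FALSE, n)
  if (is.null(tmb)) tmb <- rowSums(F) / 1.1
  ids <- sprintf("S%05d", seq_len(n))
  rownames(F) <- ids
  structure(list(
    features = F, tmb_per_mb = tmb, hypermutated = rep(FALSE, n),
    samples = data.frame(
      sample_id = ids, biopsy_site = "breast", group = group,
      er_status = ifelse(er_prob > 0.5, "positive", "negative"),
      er_source = "pathology_report", er_prob = er_prob,
      her2_amplified = her2, histology = "IDC", age_years = 55L,
      stringsAsFactors = FALSE),
    granularity = "gene", filter = "all_variants", panel_mb = 1.1),
    class = "metbc_features")
}

# brute-force two-sided Fisher p by hypergeometric enumeration
fisher_enum_2x2 <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
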