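## Generator configuration.
##
## The default configuration plants the published cohort structure: group
## sizes, subtype composition, per-gene alteration rates with metastatic and
## site-specific enrichments, the ESR1 site/subtype model and hotspot
## mixtures, a lung-like contaminant block, age-dependent clonal
## hematopoiesis, and pathology-report templates. Free parameters that the
## published figures do not pin down (e.g. the ER+ rate at unnamed sites)
## are solved at config-build time so that the weighted marginals equal the
## published prevalences exactly.

.met_sites <- c("liver", "bone", "lung", "brain", "skin", "pleura",
                "pleural fluid", "soft tissue", "ovary", "GI")

.default_report_templates <- list(
  positive = c(plain      = "ER staining was detected",
               colon      = "Estrogen receptor: positive",
               expression = "Tumor cells show diffuse ER expression",
               percent    = "Estrogen receptor staining was detected in 90% of nuclei"),
  negative = c(plain      = "ER staining was not detected",
               colon      = "Estrogen receptor: negative",
               rare       = "ER: rare staining",
               negated    = "Tumor was negative for estrogen receptor"),
  boilerplate = paste("Interpretation guide: results are reported as",
                      "positive or negative per standard guidelines."))

# renormalizing tilt of a mixture: named replacements, remainder rescaled
.tilt_mixture <- function(base, changes) {
  m <- base
  m[names(changes)] <- changes
  fixed <- names(changes)
  free <- setdiff(names(m), fixed)
  rem <- 1 - sum(m[fixed])
  if (rem < 0) stop("tilt exceeds unit mass")
  m[free] <- base[free] * rem / sum(base[free])
  m
}

# shift all site logits by a common delta so the weighted mean hits target
.calibrate_logit_shift <- function(p0, w, target) {
  f <- function(d) sum(w * plogis(qlogis(p0) + d)) - target
  uniroot(f, c(-8, 8), tol = 1e-12)$root
}

#' Default synthetic-cohort generator configuration
#'
#' Returns a [generator configuration][simulate_cohort] whose planted
#' parameters reproduce the published cohort: 4,512 local, 1,357 lymph-node,
#' 5,034 metastatic (and 713 ambiguous) samples; ER+/HER2- fractions of 64%
#' among metastases and 48% in local disease; HER2 amplification at
#' 9.4%/8.7%; ESR1 short-variant prevalence 18.3% (metastases) vs 2.2%
#' (local), 44% in ER+ liver metastases; CTCF mutations at 2.0% vs 0.9%;
#' CDKN1B amplification at 1.3% vs 3.6%; the ESR1 hotspot mixture
#' (D538G 33.2%, Y537S 21.4%, E380Q 8.5%, Y537N 8.0%, Y537C 4.3%,
#' L536H 1.9%, V422del 1.4%, remainder pooled by recurrence); site-specific
#' enrichments (NOTCH1 in skin, PTEN deletion and ASXL1 amplification in
#' brain, DNMT3A in bone); a lung-like contaminant mixture with a
#' co-occurring KRAS/KEAP1/STK11 triplet; and age-dependent DNMT3A clonal
#' hematopoiesis with declining variant allele fraction.
#'
#' Quantities the source figures do not pin down (site frequencies among
#' metastases, ER+ rates at unnamed sites, filler-gene background rates)
#' are fixed here once; rates with several constraints are solved
#' analytically so the planted marginals are exact.
#'
#' @param n_local,n_lymph,n_met,n_ambiguous Group sizes.
#' @return Object of class `metbc_config`.
#' @export
default_generator_config <- function(n_local = 4512, n_lymph = 1357,
                                     n_met = 5034, n_ambiguous = 713) {
  site_freqs <- c(liver = 0.28, bone = 0.20, lung = 0.12, brain = 0.08,
                  skin = 0.07, pleura = 0.05, "pleural fluid" = 0.04,
                  "soft tissue" = 0.08, ovary = 0.04, GI = 0.04)

  her2_by_group <- c(local = 0.087, lymph_node = 0.09,
                     metastasis = 0.094, ambiguous = 0.09)

  ## ER+ probability: published ER+/HER2- fractions divided by P(not HER2+),
  ## assuming ER and HER2 amplification independent within group.
  er_target_met   <- 0.64 / (1 - her2_by_group[["metastasis"]])
  er_target_local <- 0.48 / (1 - her2_by_group[["local"]])

  ## per-site ER+ propensities (liver/bone high, brain/lung low, per the
  ## published subtype-by-site pattern), calibrated by a common logit shift
  ## so the metastasis-wide ER+ rate is exact
  er_site_base <- c(liver = 0.78, bone = 0.80, lung = 0.60, brain = 0.50,
                    skin = 0.70, pleura = 0.72, "pleural fluid" = 0.72,
                    "soft tissue" = 0.70, ovary = 0.75, GI = 0.70)
  dlt <- .calibrate_logit_shift(er_site_base[.met_sites],
                                site_freqs[.met_sites], er_target_met)
  er_site_met <- setNames(plogis(qlogis(er_site_base[.met_sites]) + dlt),
                          .met_sites)

  er_by_group <- list(local = unname(er_target_local),
                      lymph_node = 0.55,
                      metastasis = er_site_met,
                      ambiguous = 0.55)

  ## ESR1 model ----------------------------------------------------------
  ## ER+ metastasis rates at the named sites are the published values; the
  ## shared rate at unnamed sites is solved so the metastasis-wide ESR1
  ## prevalence is exactly 18.3%. Local ER+ rate solved for 2.2% overall.
  esr1_named <- c(liver = 0.44, pleura = 0.25, "pleural fluid" = 0.25,
                  lung = 0.24, bone = 0.20, brain = 0.20)
  esr1_er_neg_met <- 0.02
  contam_frac <- 0.15          # lung contaminants never carry ESR1; the
                               # marginal accounts for the diluted lung term
  unnamed <- setdiff(.met_sites, names(esr1_named))
  f <- function(r) {
    rates <- c(esr1_named, setNames(rep(r, length(unnamed)), unnamed))
    per_site <- er_site_met[.met_sites] * rates[.met_sites] +
      (1 - er_site_met[.met_sites]) * esr1_er_neg_met
    per_site["lung"] <- per_site["lung"] * (1 - contam_frac)
    sum(site_freqs[.met_sites] * per_site) - 0.183
  }
  r_unnamed <- uniroot(f, c(1e-4, 0.5), tol = 1e-12)$root
  esr1_site_rates <- c(esr1_named,
                       setNames(rep(r_unnamed, length(unnamed)), unnamed))

  esr1_local_neg <- 0.005
  esr1_local_pos <- (0.022 - (1 - er_target_local) * esr1_local_neg) /
    er_target_local

  hotspot_base <- c(D538G = 0.332, Y537S = 0.214, E380Q = 0.085,
                    Y537N = 0.080, Y537C = 0.043, L536H = 0.019,
                    V422del = 0.014, pooled_2_3 = 0.080, pooled_1 = 0.100,
                    other = 0.033)
  site_mixtures <- list(
    liver  = .tilt_mixture(hotspot_base, c(D538G = 0.44, Y537S = 0.15)),
    pleura = .tilt_mixture(hotspot_base, c(D538G = 0.38, Y537S = 0.17)),
    "pleural fluid" = .tilt_mixture(hotspot_base, c(D538G = 0.38, Y537S = 0.17)),
    lung   = .tilt_mixture(hotspot_base, c(D538G = 0.38, Y537S = 0.17)),
    brain  = .tilt_mixture(hotspot_base, c(D538G = 0.38, Y537S = 0.17)),
    bone   = .tilt_mixture(hotspot_base, c(D538G = 0.22, Y537S = 0.29)),
    breast = .tilt_mixture(hotspot_base, c(D538G = 0.20, Y537S = 0.12,
                                           E380Q = 0.31, other = 0.08,
                                           pooled_1 = 0.13)),
    "chest wall" = .tilt_mixture(hotspot_base, c(D538G = 0.20, Y537S = 0.12,
                                                 E380Q = 0.31, other = 0.08,
                                                 pooled_1 = 0.13)),
    "lymph node" = .tilt_mixture(hotspot_base, c(other = 0.08, pooled_1 = 0.13)))
  ilc_mixture <- .tilt_mixture(hotspot_base, c(E380Q = 0.22, D538G = 0.25))

  esr1_model <- list(
    met_site_rates_er_pos = esr1_site_rates,
    met_rate_er_neg = esr1_er_neg_met,
    local_rate_er_pos = esr1_local_pos,
    local_rate_er_neg = esr1_local_neg,
    lymph_rate_er_pos = 0.155,
    lymph_rate_er_neg = 0.02,
    multi_mut_prob = 0.089,
    hotspot_mixture = hotspot_base,
    site_mixtures = site_mixtures,
    ilc_mixture = ilc_mixture,
    lbd_interval = c(311L, 547L))

  ## per-(gene, class) baseline alteration probabilities in local disease,
  ## split by ER status where the subtype landscape differs
  bl <- function(gene, class, pos, neg = pos)
    data.frame(gene = gene, class = class, rate_pos = pos, rate_neg = neg,
               stringsAsFactors = FALSE)
  baseline <- rbind(
    bl("TP53",   "short_variant", 0.45, 0.85),
    bl("PIK3CA", "short_variant", 0.36, 0.24),
    bl("CDH1",   "short_variant", 0.14, 0.04),
    bl("GATA3",  "short_variant", 0.14, 0.03),
    bl("KMT2D",  "short_variant", 0.095),
    bl("CTCF",   "short_variant", 0.009),
    bl("KRAS",   "short_variant", 0.011),
    bl("NF1",    "short_variant", 0.033),
    bl("NOTCH1", "short_variant", 0.045),
    bl("DNMT3A", "short_variant", 0.025),
    bl("LRP1B",  "short_variant", 0.082),
    bl("BRCA1",  "short_variant", 0.056),
    bl("BRCA2",  "short_variant", 0.072),
    bl("AKT1",   "short_variant", 0.035, 0.015),
    bl("MAP3K1", "short_variant", 0.080, 0.020),
    bl("CBFB",   "short_variant", 0.030, 0.010),
    bl("EGFR",   "short_variant", 0.006),
    bl("KEAP1",  "short_variant", 0.003),
    bl("STK11",  "short_variant", 0.010),
    bl("CDKN1B", "short_variant", 0.011),
    bl("MYC",    "amplification", 0.228),
    bl("CCND1",  "amplification", 0.21, 0.12),
    bl("FGFR1",  "amplification", 0.10),
    bl("FGF3",   "amplification", 0.17, 0.04),
    bl("FGF4",   "amplification", 0.17, 0.04),
    bl("FGF19",  "amplification", 0.17, 0.04),
    bl("CDKN1B", "amplification", 0.036),
    bl("ASXL1",  "amplification", 0.008),
    bl("PTEN",   "deletion",      0.05),
    bl("CDKN2A", "deletion",      0.05),
    bl("CDKN2B", "deletion",      0.05),
    bl("RB1",    "deletion",      0.025),
    bl("CDKN1B", "deletion",      0.001),
    bl("ERBB2",  "rearrangement", 0.015),
    bl("FGFR1",  "rearrangement", 0.013))

  ## planted enrichments as odds multipliers applied on the logit scale;
  ## each multiplier is odds(published context rate) / odds(published local
  ## rate) so the context-wide marginal matches the published rate
  or_from_rates <- function(p1, p0) (p1 / (1 - p1)) / (p0 / (1 - p0))
  en <- function(gene, class, context, om, er = "both")
    data.frame(gene = gene, class = class, context = context,
               odds_multiplier = om, er_restrict = er,
               stringsAsFactors = FALSE)
  enrichment <- rbind(
    en("CTCF",   "short_variant", "all_mets", or_from_rates(0.020, 0.009)),
    en("CDKN1B", "amplification", "all_mets", or_from_rates(0.013, 0.036)),
    en("CDKN1B", "short_variant", "all_mets", or_from_rates(0.019, 0.011)),
    en("CDKN1B", "deletion",      "all_mets", or_from_rates(0.002, 0.001)),
    en("KRAS",   "short_variant", "all_mets", or_from_rates(0.019, 0.011)),
    en("NF1",    "short_variant", "all_mets", or_from_rates(0.047, 0.033)),
    en("FGF3",   "amplification", "all_mets", or_from_rates(0.27, 0.17), "positive"),
    en("FGF4",   "amplification", "all_mets", or_from_rates(0.27, 0.17), "positive"),
    en("FGF19",  "amplification", "all_mets", or_from_rates(0.27, 0.17), "positive"),
    en("FGF3",   "amplification", "all_mets", or_from_rates(0.13, 0.04), "negative"),
    en("FGF4",   "amplification", "all_mets", or_from_rates(0.13, 0.04), "negative"),
    en("FGF19",  "amplification", "all_mets", or_from_rates(0.13, 0.04), "negative"),
    en("NOTCH1", "short_variant", "site:skin",  or_from_rates(0.088, 0.045)),
    en("DNMT3A", "short_variant", "site:bone",  or_from_rates(0.064, 0.025)),
    en("PTEN",   "deletion",      "site:brain", or_from_rates(0.118, 0.050)),
    en("ASXL1",  "amplification", "site:brain", or_from_rates(0.042, 0.008)))

  named_genes <- unique(c(baseline$gene, "ESR1", "ERBB2"))
  n_filler <- 287 - length(named_genes)
  panel <- c(named_genes, sprintf("BG%03d", seq_len(n_filler)))

  contaminant_model <- list(
    fraction = contam_frac,    # share of lung-site "metastases" that are
                               # misdiagnosed lung primaries
    triplet_joint = 0.15,      # P(KRAS & KEAP1 & STK11 jointly)
    rates = c(KRAS = 0.18, KEAP1 = 0.12, STK11 = 0.10, EGFR = 0.14,
              TP53 = 0.60, LRP1B = 0.30, CDKN2A.del = 0.20,
              CDKN2B.del = 0.18, STK11.del = 0.04, KMT2D = 0.12),
    background_rate = 0.02)    # filler-gene rate in the lung profile

  chip_model <- list(
    logit_intercept = -7.6, logit_slope = 0.078,   # P(DNMT3A CHIP | age)
    vaf_logit_intercept = 1.2, vaf_logit_slope = -0.045,  # E[VAF] vs age
    vaf_kappa = 20)

  report_templates <- .default_report_templates

  cfg <- list(
    n_local = n_local, n_lymph = n_lymph, n_met = n_met,
    n_ambiguous = n_ambiguous,
    local_site_freqs = c(breast = 0.90, "chest wall" = 0.10),
    site_freqs = site_freqs,
    her2_by_group = her2_by_group,
    er_by_group = er_by_group,
    histology_given_site = list(
      default = c(IDC = 0.84, ILC = 0.10, other = 0.06),
      ovary   = c(IDC = 0.60, ILC = 0.32, other = 0.08),
      GI      = c(IDC = 0.60, ILC = 0.32, other = 0.08)),
    age_model = list(mean = 55, sd = 13, min = 20, max = 90),
    baseline = baseline,
    enrichment = enrichment,
    background = list(rate = 0.0154, met_odds_multiplier = 1.285,
                      hypermutated_fraction = 0.01,
                      hypermutated_odds_multiplier = 8),
    functional_probs = c(known = 0.45, likely = 0.25, VUS = 0.30),
    tumor_vaf = list(mean = 0.35, kappa = 8),
    esr1_model = esr1_model,
    contaminant_model = contaminant_model,
    chip_model = chip_model,
    report_templates = report_templates,
    panel = panel,
    panel_mb = 1.1)
  class(cfg) <- "metbc_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks probability bounds, positive odds multipliers, nonnegative group
#' sizes and unit-sum mixtures. Called by [simulate_cohort()] before any
#' sampling.
#'
#' @param cfg A `metbc_config`.
#' @return The config, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  chk01 <- function(x, what) {
    if (any(is.na(x)) || any(x < 0 | x > 1))
      stop(what, " outside [0, 1]")
  }
  stopifnot(cfg$n_local >= 0, cfg$n_lymph >= 0, cfg$n_met >= 0,
            cfg$n_ambiguous >= 0)
  chk01(unlist(cfg$er_by_group), "ER+ probability")
  chk01(cfg$her2_by_group, "HER2 probability")
  chk01(cfg$baseline$rate_pos, "baseline rate")
  chk01(cfg$baseline$rate_neg, "baseline rate")
  if (any(cfg$enrichment$odds_multiplier <= 0))
    stop("odds multipliers must be > 0")
  mix_sum <- function(m, what) {
    if (abs(sum(m) - 1) > 1e-9) stop(what, " mixture does not sum to 1")
    chk01(m, what)
  }
  mix_sum(cfg$site_freqs, "site frequency")
  mix_sum(cfg$local_site_freqs, "local site frequency")
  mix_sum(cfg$esr1_model$hotspot_mixture, "hotspot")
  for (m in cfg$esr1_model$site_mixtures) mix_sum(m, "hotspot site")
  mix_sum(cfg$esr1_model$ilc_mixture, "hotspot ILC")
  chk01(unlist(cfg$esr1_model[c("met_site_rates_er_pos", "met_rate_er_neg",
                                "local_rate_er_pos", "local_rate_er_neg",
                                "lymph_rate_er_pos", "lymph_rate_er_neg",
                                "multi_mut_prob")]), "ESR1 rate")
  chk01(cfg$contaminant_model$fraction, "contaminant fraction")
  chk01(cfg$contaminant_model$rates, "contaminant rate")
  if (anyDuplicated(cfg$panel)) stop("panel contains duplicates")
  invisible(cfg)
}

#' @export
print.metbc_config <- function(x, ...) {
  cat("metbc generator config:", x$n_local, "local /", x$n_lymph,
      "lymph node /", x$n_met, "metastatic /", x$n_ambiguous,
      "ambiguous samples;", length(x$panel), "panel genes\n")
  invisible(x)
}
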