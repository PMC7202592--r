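## Synthetic cohort generator.
##
## Samples are drawn hierarchically: group -> biopsy site -> subtype /
## histology / age -> per-feature Bernoulli alteration vector with planted
## enrichments applied on the logit scale -> ESR1 hotspot assignment ->
## lung-contaminant substitution -> CHIP injection. Ground truth is recorded
## for every sample.

.aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
         "T","W","Y","V")

.hotspot_info <- data.frame(
  label = c("D538G", "Y537S", "Y537N", "Y537C", "E380Q", "L536H", "V422del"),
  position = c(538L, 537L, 537L, 537L, 380L, 536L, 422L),
  stringsAsFactors = FALSE)

# fixed pool of recurrent rare LBD substitutions backing the pooled_2_3
# category (drawn uniformly, so each recurs a handful of times in a cohort)
.rare_lbd_pool <- local({
  pos <- seq(315L, 545L, by = 8L)
  paste0(rep(c("L", "S", "E", "V", "P"), length.out = length(pos)), pos,
         rep(c("F", "R", "K", "M", "H"), length.out = length(pos)))
})

#' Draw ESR1 variant calls for mutant samples
#'
#' Each flagged sample draws one hotspot (or a recurrence-pooled long-tail
#' category) from the site/histology-specific mixture; a configured fraction
#' draws a second, independent variant. Invasive lobular histology overrides
#' the site mixture; sites without a dedicated mixture use the cohort-wide
#' default.
#'
#' @param n Number of ESR1-mutant samples to draw for.
#' @param esr1_model The `esr1_model` component of a generator config.
#' @param site,histology Optional per-sample vectors (length `n`); `NULL`
#'   uses the default mixture throughout.
#' @return Data frame with `sample` (index 1..n), `hotspot_label`,
#'   `protein_change`, `position`.
#' @export
simulate_esr1_variants <- function(n, esr1_model, site = NULL,
                                   histology = NULL) {
  labs <- names(esr1_model$hotspot_mixture)
  pick_mixture <- function(i) {
    if (!is.null(histology) && histology[i] == "ILC")
      return(esr1_model$ilc_mixture)
    if (!is.null(site) && site[i] %in% names(esr1_model$site_mixtures))
      return(esr1_model$site_mixtures[[site[i]]])
    esr1_model$hotspot_mixture
  }
  draw_one <- function(mix) {
    if (abs(sum(mix) - 1) > 1e-9) stop("hotspot mixture does not sum to 1")
    sample(labs, 1L, prob = mix[labs])
  }
  out_sample <- integer(0); out_label <- character(0)
  for (i in seq_len(n)) {
    mix <- pick_mixture(i)
    k <- if (runif(1) < esr1_model$multi_mut_prob) 2L else 1L
    for (j in seq_len(k)) {
      out_sample <- c(out_sample, i)
      out_label <- c(out_label, draw_one(mix))
    }
  }
  m <- length(out_label)
  pos <- integer(m); pc <- character(m)
  hs <- match(out_label, .hotspot_info$label)
  named <- !is.na(hs)
  pos[named] <- .hotspot_info$position[hs[named]]
  pc[named] <- out_label[named]
  lbd <- esr1_model$lbd_interval
  for (i in which(!named)) {
    if (out_label[i] == "pooled_2_3") {
      pc[i] <- sample(.rare_lbd_pool, 1L)
      pos[i] <- as.integer(gsub("[^0-9]", "", pc[i]))
    } else if (out_label[i] == "pooled_1") {
      pos[i] <- sample(lbd[1]:lbd[2], 1L)
      pc[i] <- paste0(sample(.aa, 1L), pos[i], sample(.aa, 1L))
    } else {  # non-LBD passenger
      pos[i] <- sample(5:(lbd[1] - 1L), 1L)
      pc[i] <- paste0(sample(.aa, 1L), pos[i], sample(.aa, 1L))
    }
  }
  data.frame(sample = out_sample, hotspot_label = out_label,
             protein_change = pc, position = pos, stringsAsFactors = FALSE)
}

#' Draw clonal-hematopoiesis variant allele fractions
#'
#' CHIP VAFs follow a beta distribution whose mean declines with age on the
#' logit scale (blood-derived clones contribute fewer reads in older,
#' lower-cellularity biopsies); tumor variants draw from an age-independent
#' beta distribution.
#'
#' @param age_years Numeric vector of ages.
#' @param chip_model The `chip_model` component of a generator config.
#' @return Numeric vector of VAFs in \[0, 1\].
#' @export
simulate_chip_vaf <- function(age_years, chip_model) {
  mu <- plogis(chip_model$vaf_logit_intercept +
                 chip_model$vaf_logit_slope * age_years)
  k <- chip_model$vaf_kappa
  rbeta(length(age_years), mu * k, (1 - mu) * k)
}

#' Generate a synthetic pathology-report snippet
#'
#' Renders a status sentence from the configured template set, optionally
#' prefixed by boilerplate (an interpretation guide the parser must filter)
#' and surrounded by neutral report lines.
#'
#' @param er_status `"positive"` or `"negative"`.
#' @param template_id Template name within the status' template set; `NULL`
#'   draws one at random.
#' @param templates The `report_templates` component of a generator config.
#' @param boilerplate Include the distractor boilerplate line.
#' @return List with `text` and `truth`.
#' @export
simulate_pathology_report <- function(er_status = c("positive", "negative"),
                                      template_id = NULL,
                                      templates = .default_report_templates,
                                      boilerplate = FALSE) {
  er_status <- match.arg(er_status)
  set_ <- templates[[er_status]]
  if (!length(set_)) stop("empty template set")
  if (is.null(template_id)) template_id <- sample(names(set_), 1L)
  if (!template_id %in% names(set_)) stop("unknown template: ", template_id)
  lines <- c("SURGICAL PATHOLOGY REPORT",
             "Specimen: breast, core needle biopsy.",
             if (boilerplate) templates$boilerplate,
             "IMMUNOHISTOCHEMISTRY RESULTS:",
             set_[[template_id]],
             "Ki-67 proliferation index: 15%.")
  list(text = paste(lines, collapse = "\n"), truth = er_status,
       template = template_id)
}

## ------------------------------------------------------------------------

# apply an odds multiplier to a probability on the logit scale
.apply_or <- function(p, m) {
  o <- p / (1 - p) * m
  o / (1 + o)
}

#' Simulate a panel-sequencing cohort
#'
#' Draws a full synthetic cohort (samples, alteration calls, pathology-report
#' texts) from a generator configuration, together with per-sample ground
#' truth. Reproducible: identical `(config, seed)` gives identical output.
#'
#' @param cfg A `metbc_config`, e.g. [default_generator_config()].
#' @param seed Integer RNG seed.
#' @return List with `cohort` (a `metbc_cohort`), `truth` (data frame with
#'   per-sample latent labels: `true_er`, `is_contaminant`, `has_chip`,
#'   `esr1_mutant`, `hyper`), and `reports` (data frame of report text and
#'   truth for a labelled subsample).
#' @export
simulate_cohort <- function(cfg, seed) {
  validate_config(cfg)
  set.seed(seed)

  n <- cfg$n_local + cfg$n_lymph + cfg$n_met + cfg$n_ambiguous
  group <- rep(c("local", "lymph_node", "metastasis", "ambiguous"),
               c(cfg$n_local, cfg$n_lymph, cfg$n_met, cfg$n_ambiguous))
  site <- character(n)
  site[group == "local"] <- sample(names(cfg$local_site_freqs),
                                   sum(group == "local"), TRUE,
                                   cfg$local_site_freqs)
  site[group == "lymph_node"] <- "lymph node"
  site[group == "metastasis"] <- sample(names(cfg$site_freqs),
                                        sum(group == "metastasis"), TRUE,
                                        cfg$site_freqs)
  site[group == "ambiguous"] <- sample(c("other", "unknown"),
                                       sum(group == "ambiguous"), TRUE,
                                       c(0.6, 0.4))

  ## subtype
  p_er <- numeric(n)
  p_er[group == "local"] <- cfg$er_by_group$local
  p_er[group == "lymph_node"] <- cfg$er_by_group$lymph_node
  p_er[group == "ambiguous"] <- cfg$er_by_group$ambiguous
  im <- group == "metastasis"
  p_er[im] <- cfg$er_by_group$metastasis[site[im]]
  er_pos <- runif(n) < p_er
  her2 <- runif(n) < cfg$her2_by_group[group]

  ## histology and age
  histology <- character(n)
  for (s in unique(site)) {
    tab <- cfg$histology_given_site[[s]]
    if (is.null(tab)) tab <- cfg$histology_given_site$default
    idx <- site == s
    histology[idx] <- sample(names(tab), sum(idx), TRUE, tab)
  }
  age <- round(rnorm(n, cfg$age_model$mean, cfg$age_model$sd))
  age <- pmin(pmax(age, cfg$age_model$min), cfg$age_model$max)

  ## hypermutation flag (odds multiplier applied to short-variant probs)
  hyper <- runif(n) < cfg$background$hypermutated_fraction

  ## per-(gene, class) Bernoulli draws with enrichments on the logit scale
  bfeat <- cfg$baseline
  E <- matrix(as.numeric(er_pos), n, nrow(bfeat))
  P <- sweep(E, 2, bfeat$rate_pos, "*") +
    sweep(1 - E, 2, bfeat$rate_neg, "*")
  for (k in seq_len(nrow(cfg$enrichment))) {
    e <- cfg$enrichment[k, ]
    j <- which(bfeat$gene == e$gene & bfeat$class == e$class)
    if (!length(j)) next
    rows <- if (e$context == "all_mets") im
            else im & site == sub("^site:", "", e$context)
    if (e$er_restrict == "positive") rows <- rows & er_pos
    if (e$er_restrict == "negative") rows <- rows & !er_pos
    P[rows, j] <- .apply_or(P[rows, j], e$odds_multiplier)
  }
  sv_cols <- bfeat$class == "short_variant"
  P[hyper, sv_cols] <- .apply_or(P[hyper, sv_cols],
                                 cfg$background$hypermutated_odds_multiplier)
  A <- matrix(runif(n * nrow(bfeat)), n) < P

  ## filler background genes (short variants)
  bg_genes <- grep("^BG", cfg$panel, value = TRUE)
  pbg <- matrix(cfg$background$rate, n, length(bg_genes))
  pbg[im, ] <- .apply_or(pbg[im, ], cfg$background$met_odds_multiplier)
  pbg[hyper, ] <- .apply_or(pbg[hyper, ],
                            cfg$background$hypermutated_odds_multiplier)
  B <- matrix(runif(n * length(bg_genes)), n) < pbg

  ## lung-like contaminants among lung-site metastases
  cm <- cfg$contaminant_model
  contam <- im & site == "lung" & runif(n) < cm$fraction
  if (any(contam)) {
    ci <- which(contam)
    A[ci, ] <- FALSE
    triplet <- runif(length(ci)) < cm$triplet_joint
    lung_draw <- function(gene, class) {
      j <- which(bfeat$gene == gene & bfeat$class == class)
      nm <- if (class == "short_variant") gene else paste0(gene, ".del")
      r <- cm$rates[[nm]]
      if (is.null(r) || !length(j)) return(invisible(NULL))
      A[ci, j] <<- runif(length(ci)) < r
      j
    }
    for (g in c("KRAS", "KEAP1", "STK11"))
      lung_draw(g, "short_variant")
    # force the co-occurring triplet
    for (g in c("KRAS", "KEAP1", "STK11")) {
      j <- which(bfeat$gene == g & bfeat$class == "short_variant")
      A[ci[triplet], j] <- TRUE
    }
    for (g in c("EGFR", "TP53", "LRP1B", "KMT2D"))
      lung_draw(g, "short_variant")
    for (g in c("CDKN2A", "CDKN2B", "STK11"))
      lung_draw(g, "deletion")
    B[ci, ] <- matrix(runif(length(ci) * length(bg_genes)),
                      length(ci)) < cm$background_rate
  }

  ## ESR1 model
  em <- cfg$esr1_model
  p_esr1 <- numeric(n)
  p_esr1[group == "local"] <- ifelse(er_pos[group == "local"],
                                     em$local_rate_er_pos, em$local_rate_er_neg)
  p_esr1[group == "lymph_node"] <- ifelse(er_pos[group == "lymph_node"],
                                          em$lymph_rate_er_pos, em$lymph_rate_er_neg)
  p_esr1[group == "ambiguous"] <- ifelse(er_pos[group == "ambiguous"],
                                         em$local_rate_er_pos, em$local_rate_er_neg)
  p_esr1[im] <- ifelse(er_pos[im], em$met_site_rates_er_pos[site[im]],
                       em$met_rate_er_neg)
  p_esr1[contam] <- 0
  esr1_mut <- runif(n) < p_esr1
  esr1_idx <- which(esr1_mut)
  esr1_calls <- simulate_esr1_variants(length(esr1_idx), em,
                                       site = site[esr1_idx],
                                       histology = histology[esr1_idx])

  ## CHIP: age-dependent DNMT3A clones with declining VAF
  chm <- cfg$chip_model
  has_chip <- runif(n) < plogis(chm$logit_intercept + chm$logit_slope * age)
  j_dnmt3a <- which(bfeat$gene == "DNMT3A" & bfeat$class == "short_variant")

  ## assemble the alteration-call table -----------------------------------
  ids <- sprintf("S%05d", seq_len(n))
  hits <- which(A, arr.ind = TRUE)
  calls <- data.frame(
    sample_id = ids[hits[, 1]],
    gene = bfeat$gene[hits[, 2]],
    alteration_class = bfeat$class[hits[, 2]],
    stringsAsFactors = FALSE)
  calls$.age <- age[hits[, 1]]
  calls$.chipvaf <- has_chip[hits[, 1]] & hits[, 2] == j_dnmt3a

  bhits <- which(B, arr.ind = TRUE)
  if (nrow(bhits)) {
    bcalls <- data.frame(sample_id = ids[bhits[, 1]],
                         gene = bg_genes[bhits[, 2]],
                         alteration_class = "short_variant",
                         stringsAsFactors = FALSE)
    bcalls$.age <- age[bhits[, 1]]
    bcalls$.chipvaf <- FALSE
    calls <- rbind(calls, bcalls)
  }
  # CHIP carriers without a tumor DNMT3A draw get an injected call
  inj <- which(has_chip & !A[, j_dnmt3a])
  if (length(inj)) {
    icalls <- data.frame(sample_id = ids[inj], gene = "DNMT3A",
                         alteration_class = "short_variant",
                         stringsAsFactors = FALSE)
    icalls$.age <- age[inj]
    icalls$.chipvaf <- TRUE
    calls <- rbind(calls, icalls)
  }
  calls$protein_change <- NA_character_
  calls$functional_status <- sample(names(cfg$functional_probs), nrow(calls),
                                    TRUE, cfg$functional_probs)
  is_sv <- calls$alteration_class == "short_variant"
  calls$vaf <- NA_real_
  tv <- cfg$tumor_vaf
  calls$vaf[is_sv] <- rbeta(sum(is_sv), tv$mean * tv$kappa,
                            (1 - tv$mean) * tv$kappa)
  cv <- is_sv & calls$.chipvaf
  calls$vaf[cv] <- simulate_chip_vaf(calls$.age[cv], chm)
  calls$.age <- NULL; calls$.chipvaf <- NULL

  if (nrow(esr1_calls)) {
    named <- esr1_calls$hotspot_label %in% .hotspot_info$label
    ecalls <- data.frame(
      sample_id = ids[esr1_idx[esr1_calls$sample]],
      gene = "ESR1", alteration_class = "short_variant",
      protein_change = esr1_calls$protein_change,
      functional_status = ifelse(named, "known",
                                 ifelse(runif(nrow(esr1_calls)) < 0.5,
                                        "likely", "VUS")),
      vaf = rbeta(nrow(esr1_calls), tv$mean * tv$kappa,
                  (1 - tv$mean) * tv$kappa),
      stringsAsFactors = FALSE)
    calls <- rbind(calls, ecalls)
  }

  ## HER2 amplification is carried on the sample and emitted as a call
  if (any(her2)) {
    calls <- rbind(calls, data.frame(
      sample_id = ids[her2], gene = "ERBB2",
      alteration_class = "amplification", protein_change = NA_character_,
      functional_status = "known", vaf = NA_real_,
      stringsAsFactors = FALSE))
  }
  calls <- calls[order(match(calls$sample_id, ids), calls$gene,
                       calls$alteration_class), , drop = FALSE]
  rownames(calls) <- NULL

  samples <- data.frame(
    sample_id = ids, biopsy_site = site, group = group,
    er_status = ifelse(er_pos, "positive", "negative"),
    er_source = "pathology_report",
    er_prob = as.numeric(er_pos),
    her2_amplified = her2, histology = histology,
    age_years = as.integer(age), stringsAsFactors = FALSE)

  ## labelled pathology reports for a subsample
  n_rep <- min(n, 200L)
  rep_idx <- if (n) sort(sample.int(n, n_rep)) else integer(0)
  reports <- do.call(rbind, lapply(rep_idx, function(i) {
    r <- simulate_pathology_report(samples$er_status[i],
                                   templates = cfg$report_templates,
                                   boilerplate = runif(1) < 0.2)
    data.frame(sample_id = ids[i], text = r$text, truth = r$truth,
               template = r$template, stringsAsFactors = FALSE)
  }))

  truth <- data.frame(
    sample_id = ids, group = group, biopsy_site = site,
    true_er = ifelse(er_pos, "positive", "negative"),
    her2_amplified = her2, histology = histology, age_years = age,
    is_contaminant = contam, has_chip = has_chip,
    esr1_mutant = esr1_mut, hyper = hyper, stringsAsFactors = FALSE)

  list(cohort = cohort(samples, calls, cfg$panel), truth = truth,
       reports = reports)
}

#' Simulate per-tissue alteration profiles for classifier training
#'
#' Draws binary feature vectors from a tissue's generative rate profile:
#' the breast profile uses the configured baseline rates (mixed over ER
#' status) and filler-gene background; the lung profile uses the
#' contaminant model's lung-like rates, including the co-occurring
#' KRAS/KEAP1/STK11 triplet. Custom tissues can be drawn by supplying a
#' named rate vector (`"GENE"` for short variants, `"GENE.deletion"` /
#' `"GENE.amplification"` for other classes).
#'
#' @param n Number of tumors to draw.
#' @param tissue `"breast"` or `"lung"` (ignored when `rates` is given).
#' @param cfg A `metbc_config`.
#' @param columns Feature columns of the returned matrix; defaults to the
#'   panel genes plus the configured gene-by-class combinations. Columns
#'   without a configured rate are all-zero.
#' @param rates Optional named per-feature rate vector overriding the
#'   tissue profile.
#' @param er_pos_frac Breast profile only: ER+ mixing fraction.
#' @return Binary integer matrix, `n` rows.
#' @export
simulate_tissue_profile <- function(n, tissue = c("breast", "lung"), cfg,
                                    columns = NULL, rates = NULL,
                                    er_pos_frac = 0.64) {
  tissue <- match.arg(tissue)
  bfeat <- cfg$baseline
  combo <- ifelse(bfeat$class == "short_variant", bfeat$gene,
                  paste(bfeat$gene, bfeat$class, sep = "."))
  if (is.null(columns))
    columns <- unique(c(cfg$panel, combo[bfeat$class != "short_variant"],
                        "ERBB2.amplification"))
  p <- setNames(numeric(length(columns)), columns)
  bg <- grep("^BG", columns, value = TRUE)
  if (is.null(rates)) {
    if (tissue == "breast") {
      r <- er_pos_frac * bfeat$rate_pos + (1 - er_pos_frac) * bfeat$rate_neg
      p[combo[combo %in% columns]] <- r[combo %in% columns]
      p[bg] <- cfg$background$rate
      if ("ERBB2.amplification" %in% columns)
        p["ERBB2.amplification"] <- mean(cfg$her2_by_group)
    } else {
      cm <- cfg$contaminant_model
      nm <- names(cm$rates)
      key <- ifelse(grepl("\\.del$", nm), sub("\\.del$", ".deletion", nm), nm)
      p[key[key %in% columns]] <- cm$rates[key %in% columns]
      p[bg] <- cm$background_rate
    }
  } else {
    p[names(rates)[names(rates) %in% columns]] <-
      rates[names(rates) %in% columns]
  }
  X <- matrix(as.integer(matrix(runif(n * length(columns)), n) <
                           matrix(p, n, length(columns), byrow = TRUE)),
              n, dimnames = list(sprintf("%s%05d", tissue, seq_len(n)),
                                 columns))
  if (is.null(rates) && tissue == "lung") {
    trip <- intersect(c("KRAS", "KEAP1", "STK11"), columns)
    force_rows <- runif(n) < cfg$contaminant_model$triplet_joint
    X[force_rows, trip] <- 1L
  }
  X
}
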