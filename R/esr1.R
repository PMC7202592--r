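## ESR1 variant classification and hotspot contingency analysis.
##
## The recurrent ligand-binding-domain (LBD) hotspots are named; everything
## else is pooled by its recurrence within the analyzed cohort (seen 2-3
## times, or once). The LBD boundary defaults to residues 311-547.

.esr1_hotspots <- c("D538G", "Y537S", "Y537N", "Y537C", "E380Q", "L536H",
                    "V422del")
.esr1_labels <- c(.esr1_hotspots, "pooled_2_3", "pooled_1", "other")

#' Visceral metastatic sites
#'
#' Liver, pleura, pleural fluid, brain and lung.
#' @return Character vector of site names.
#' @export
visceral_sites <- function()
  c("liver", "pleura", "pleural fluid", "brain", "lung")

.parse_position <- function(protein_change) {
  m <- regmatches(protein_change,
                  regexpr("[0-9]+", protein_change))
  ifelse(lengths(regmatches(protein_change,
                            gregexpr("[0-9]+", protein_change))) >= 1,
         suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1",
                                         protein_change))),
         NA_integer_)
}

#' Classify an ESR1 protein change
#'
#' Named hotspots keep their label; other parseable variants are pooled by
#' their cohort-wide recurrence (2-3 observations, or 1); recurrent
#' non-listed variants (seen 4+ times) and unparseable strings fall into
#' `other` (the latter with a warning, never dropped). `in_lbd` is the
#' position test against the ligand-binding-domain interval.
#'
#' @param protein_change Character vector of short-form protein changes.
#' @param recurrence Integer vector: cohort-wide count of each exact change.
#' @param lbd_interval Length-2 integer LBD residue interval.
#' @return Data frame with `protein_change`, `position`, `hotspot_label`,
#'   `in_lbd`, `recurrence`.
#' @export
classify_esr1_variant <- function(protein_change, recurrence,
                                  lbd_interval = c(311L, 547L)) {
  stopifnot(length(protein_change) == length(recurrence))
  pos <- .parse_position(protein_change)
  unparseable <- is.na(pos) & !(protein_change %in% .esr1_hotspots)
  if (any(unparseable))
    warning(sum(unparseable), " unparseable protein change(s) kept as 'other'")
  label <- ifelse(protein_change %in% .esr1_hotspots, protein_change,
           ifelse(is.na(pos), "other",
           ifelse(recurrence >= 4, "other",
           ifelse(recurrence >= 2, "pooled_2_3", "pooled_1"))))
  in_lbd <- !is.na(pos) & pos >= lbd_interval[1] & pos <= lbd_interval[2]
  data.frame(protein_change = protein_change, position = pos,
             hotspot_label = factor(label, levels = .esr1_labels),
             in_lbd = in_lbd, recurrence = recurrence,
             stringsAsFactors = FALSE)
}

#' Extract and classify all ESR1 short variants of a cohort
#'
#' Recurrence is computed cohort-wide on the exact protein change before
#' any grouping, so pooling is stable under sample reordering.
#'
#' @param x A `metbc_cohort`.
#' @param lbd_interval LBD residue interval.
#' @return Data frame: one row per ESR1 short-variant call, with
#'   `sample_id` and the classification columns.
#' @export
esr1_variant_table <- function(x, lbd_interval = c(311L, 547L)) {
  stopifnot(inherits(x, "metbc_cohort"))
  v <- x$alterations
  v <- v[v$gene == "ESR1" & v$alteration_class == "short_variant", ,
         drop = FALSE]
  if (!nrow(v))
    return(cbind(data.frame(sample_id = character(0)),
                 classify_esr1_variant(character(0), integer(0),
                                       lbd_interval)))
  pc <- ifelse(is.na(v$protein_change), "unknown", v$protein_change)
  rec <- as.integer(table(pc)[pc])
  out <- cbind(data.frame(sample_id = v$sample_id,
                          stringsAsFactors = FALSE),
               classify_esr1_variant(pc, rec, lbd_interval))
  rownames(out) <- NULL
  out
}

#' Hotspot-by-stratum contingency analysis
#'
#' Cross-tabulates ESR1 mutations by hotspot label against a stratifier
#' (metastatic site or histology). Cell percentages are each stratum's
#' share of its ESR1 mutations (rows sum to 100); the `sample_fraction`
#' column is the fraction of the stratum's samples carrying at least one
#' ESR1 mutation. Association is tested by the r x c Fisher exact test.
#'
#' @param variants Output of [esr1_variant_table()].
#' @param samples Sample metadata data frame (for stratum assignment and
#'   denominators).
#' @param stratifier `"site"` or `"histology"`.
#' @param min_variants Strata with fewer ESR1 mutations are dropped from
#'   the table (default 1).
#' @return List of class `metbc_hotspot_table` with `counts`, `percent`,
#'   `sample_fraction`, `fisher_p`.
#' @export
hotspot_site_table <- function(variants, samples,
                               stratifier = c("site", "histology"),
                               min_variants = 1) {
  stratifier <- match.arg(stratifier)
  if (!nrow(variants)) stop("no ESR1 variants")
  key <- if (stratifier == "site") samples$biopsy_site else samples$histology
  strat <- key[match(variants$sample_id, samples$sample_id)]
  counts <- table(stratum = strat, hotspot = variants$hotspot_label)
  counts <- counts[rowSums(counts) >= min_variants, , drop = FALSE]
  pct <- prop.table(counts, 1) * 100
  carriers <- tapply(variants$sample_id, strat,
                     function(v) length(unique(v)))
  denom <- table(key)
  sf <- as.numeric(carriers[rownames(counts)]) /
    as.numeric(denom[rownames(counts)])
  p <- if (nrow(counts) >= 2 && sum(colSums(counts) > 0) >= 2)
    fisher_exact_rxc(unclass(counts)) else NA_real_
  structure(list(counts = counts, percent = pct,
                 sample_fraction = setNames(sf, rownames(counts)),
                 fisher_p = p), class = "metbc_hotspot_table")
}

#' @export
print.metbc_hotspot_table <- function(x, ...) {
  cat("ESR1 hotspot table (", nrow(x$counts), " strata); Fisher p = ",
      format(x$fisher_p, digits = 3), "\n", sep = "")
  print(round(x$percent, 1))
  invisible(x)
}

#' D538G versus other hotspots in visceral versus bone metastases
#'
#' 2x2 Fisher exact test comparing D538G counts against the other named
#' hotspots between the visceral sites (liver, pleura, pleural fluid,
#' brain, lung) and bone.
#'
#' @param variants Output of [esr1_variant_table()].
#' @param samples Sample metadata.
#' @param visceral Visceral site set (default [visceral_sites()]).
#' @param reference Non-visceral comparator site (default `"bone"`).
#' @return List with the 2x2 `table` and Fisher `p`.
#' @export
visceral_hotspot_test <- function(variants, samples,
                                  visceral = visceral_sites(),
                                  reference = "bone") {
  site <- samples$biopsy_site[match(variants$sample_id, samples$sample_id)]
  named <- variants$hotspot_label %in% .esr1_hotspots
  use <- named & site %in% c(visceral, reference)
  grp <- ifelse(site[use] %in% visceral, "visceral", reference)
  d538g <- variants$hotspot_label[use] == "D538G"
  tab <- table(factor(grp, levels = c("visceral", reference)),
               factor(ifelse(d538g, "D538G", "other_hotspot"),
                      levels = c("D538G", "other_hotspot")))
  list(table = tab, p = fisher_exact_2x2(unclass(tab)))
}

#' Long-tail ESR1 enrichment by recurrence-defined variant sets
#'
#' Builds per-sample carrier indicators for the sets of ESR1 mutations
#' seen once, seen twice, seen once inside the ligand-binding domain and
#' seen once outside it (recurrence computed cohort-wide before grouping),
#' then runs the covariate-adjusted logistic enrichment model
#' (metastasis vs local) for each set. The LBD vs non-LBD contrast among
#' singletons is a Wald test on the difference of the two set
#' coefficients.
#'
#' @param x A `metbc_cohort`.
#' @param fm Feature matrix for covariates (defaults to
#'   `build_feature_matrix(x)`).
#' @param lbd_interval LBD residue interval.
#' @return List with `sets` (per-set data frame: carriers per group, odds
#'   ratio, z, p; NA rows with a reason for empty sets) and `lbd_contrast`
#'   (z, p).
#' @export
long_tail_enrichment <- function(x, fm = build_feature_matrix(x),
                                 lbd_interval = c(311L, 547L)) {
  v <- esr1_variant_table(x, lbd_interval)
  s <- fm$samples
  use <- s$group %in% c("metastasis", "local")
  y <- as.numeric(s$group[use] == "metastasis")
  C <- cbind(er_prob = s$er_prob[use],
             her2 = as.numeric(s$her2_amplified[use]),
             tmb = fm$tmb_per_mb[use])

  carrier <- function(rows) {
    ids <- unique(v$sample_id[rows])
    as.numeric(s$sample_id[use] %in% ids)
  }
  sets <- list(
    seen_once       = carrier(v$recurrence == 1),
    seen_twice      = carrier(v$recurrence == 2),
    seen_once_lbd   = carrier(v$recurrence == 1 & v$in_lbd),
    seen_once_nonlbd = carrier(v$recurrence == 1 & !v$in_lbd),
    all_variants    = carrier(rep(TRUE, nrow(v))))

  fit_one <- function(ind) {
    if (sum(ind) == 0)
      return(list(n1 = 0, n0 = 0, or = NA, z = NA, p = NA,
                  reason = "no carriers"))
    X <- cbind("(Intercept)" = 1, set = ind, C)
    fit <- tryCatch(fit_logistic(y, X), error = function(e) NULL)
    if (is.null(fit))
      return(list(n1 = sum(ind[y == 1]), n0 = sum(ind[y == 0]), or = NA,
                  z = NA, p = NA, reason = "fit failed"))
    wt <- wald_test(fit, "set")
    list(n1 = sum(ind[y == 1]), n0 = sum(ind[y == 0]),
         or = exp(unname(coef(fit)["set"])), z = wt$z, p = wt$p,
         beta = unname(coef(fit)["set"]),
         se = sqrt(diag(fit$vcov))["set"], reason = NA_character_)
  }
  res <- lapply(sets, fit_one)
  tab <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(set = nm, n_met = r$n1, n_local = r$n0,
               odds_ratio = r$or, z = ifelse(is.null(r$z), NA, r$z),
               p = ifelse(is.null(r$p), NA, r$p), reason = r$reason,
               stringsAsFactors = FALSE)
  }))

  a <- res$seen_once_lbd; b <- res$seen_once_nonlbd
  contrast <- if (!is.null(a$beta) && !is.null(b$beta) &&
                  !is.na(a$beta) && !is.na(b$beta)) {
    z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
    list(z = unname(z), p = unname(2 * pnorm(-abs(z))))
  } else list(z = NA_real_, p = NA_real_)
  list(sets = tab, lbd_contrast = contrast)
}
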