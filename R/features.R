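## Feature-matrix construction and cohort summaries.

#' Build a binary alteration feature matrix
#'
#' A gene counts as "mutated" when it harbors at least one short variant;
#' amplifications, deletions and rearrangements appear as separate
#' gene-by-class features under `granularity = "gene_by_class"`. Under the
#' `known_likely_only` filter, short variants of unknown significance (VUS)
#' are ignored both for the binary flags and for the mutation load.
#'
#' Mutation load per megabase (`tmb_per_mb`) is the qualifying short-variant
#' count divided by the configured panel footprint in megabases. A sample is
#' hypermutated when it carries short variants in more than 25 distinct genes.
#'
#' @param x A `metbc_cohort`.
#' @param granularity `"gene"` (mutation flags only) or `"gene_by_class"`
#'   (mutation flags for every panel gene plus one column per observed
#'   gene-by-class combination for amplification/deletion/rearrangement,
#'   named e.g. `"CDKN1B.amplification"`).
#' @param filter `"all_variants"` or `"known_likely_only"`.
#' @param panel_mb Panel footprint in megabases used as the mutation-load
#'   denominator (default 1.1).
#' @return Object of class `metbc_features`: list with `features` (integer
#'   matrix, samples x features), `tmb_per_mb`, `hypermutated`, `samples`
#'   (the cohort metadata).
#' @export
build_feature_matrix <- function(x, granularity = c("gene", "gene_by_class"),
                                 filter = c("all_variants", "known_likely_only"),
                                 panel_mb = 1.1) {
  stopifnot(inherits(x, "metbc_cohort"))
  granularity <- match.arg(granularity)
  filter <- match.arg(filter)
  if (!length(x$panel)) stop("empty gene panel")
  ids <- x$samples$sample_id
  alt <- x$alterations

  sv <- alt[alt$alteration_class == "short_variant", , drop = FALSE]
  if (filter == "known_likely_only" && nrow(sv))
    sv <- sv[!is.na(sv$functional_status) &
               sv$functional_status %in% c("known", "likely"), , drop = FALSE]

  si <- match(sv$sample_id, ids)
  gi <- match(sv$gene, x$panel)
  mut <- matrix(0L, length(ids), length(x$panel),
                dimnames = list(ids, x$panel))
  if (nrow(sv)) mut[cbind(si, gi)] <- 1L

  if (granularity == "gene_by_class") {
    other <- alt[alt$alteration_class != "short_variant", , drop = FALSE]
    if (nrow(other)) {
      combo <- paste(other$gene, other$alteration_class, sep = ".")
      cols <- sort(unique(combo))
      extra <- matrix(0L, length(ids), length(cols),
                      dimnames = list(ids, cols))
      extra[cbind(match(other$sample_id, ids), match(combo, cols))] <- 1L
      mut <- cbind(mut, extra)
    }
  }

  n_sv <- tabulate(si, nbins = length(ids))          # qualifying short variants
  n_genes_mut <- rowSums(mut[, x$panel, drop = FALSE])
  structure(list(
    features     = mut,
    tmb_per_mb   = n_sv / panel_mb,
    hypermutated = n_genes_mut > 25,
    samples      = x$samples,
    granularity  = granularity,
    filter       = filter,
    panel_mb     = panel_mb), class = "metbc_features")
}

#' @export
print.metbc_features <- function(x, ...) {
  cat("metbc feature matrix:", nrow(x$features), "samples x",
      ncol(x$features), "features (", x$granularity, ",", x$filter, ")\n")
  cat("mean mutation load/Mb:", round(mean(x$tmb_per_mb), 2),
      "; hypermutated:", sum(x$hypermutated), "\n")
  invisible(x)
}

#' Summarize a cohort
#'
#' Produces the standard prevalence tables: molecular subtype (ER/HER2) by
#' biopsy site, histology by site, group sizes, and an alteration-prevalence
#' ranking. Compositional rows sum to 1.
#'
#' @param x A `metbc_cohort`.
#' @return List with `group_counts`, `distal_met_fraction`,
#'   `subtype_by_site`, `histology_by_site`, `alteration_prevalence`.
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "metbc_cohort"), nrow(x$samples) > 0)
  s <- x$samples
  grp <- table(factor(s$group, levels = .groups))
  subtype <- ifelse(s$her2_amplified, "HER2amp",
                    ifelse(s$er_status == "positive", "ER+/HER2-",
                           ifelse(s$er_status == "negative", "ER-/HER2-",
                                  "unknown")))
  subtype_by_site <- prop.table(table(site = s$biopsy_site, subtype), 1)
  histology_by_site <- prop.table(table(site = s$biopsy_site,
                                        histology = s$histology), 1)
  prev <- NULL
  if (nrow(x$alterations)) {
    key <- paste(x$alterations$gene, x$alterations$alteration_class, sep = ".")
    per <- tapply(x$alterations$sample_id, key,
                  function(v) length(unique(v)))
    prev <- data.frame(feature = names(per),
                       n = as.integer(per),
                       prevalence = as.numeric(per) / nrow(s))
    prev <- prev[order(-prev$prevalence), , drop = FALSE]
    rownames(prev) <- NULL
  }
  list(group_counts = grp,
       distal_met_fraction = unname(grp["metastasis"] / sum(grp)),
       subtype_by_site = subtype_by_site,
       histology_by_site = histology_by_site,
       alteration_prevalence = prev)
}
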