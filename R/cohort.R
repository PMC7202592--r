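#' @useDynLib metbc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate anova as.formula binomial coef glm glm.fit
#'   ks.test lm optim p.adjust pbeta pbinom phyper plogis pnorm predict
#'   qlogis quantile rbeta rbinom rnbinom rnorm runif sd setNames uniroot
#'   vcov wilcox.test fisher.test dhyper na.omit
#' @importFrom utils read.delim write.table head
"_PACKAGE"

## Controlled vocabularies -----------------------------------------------

#' Biopsy-site vocabulary and site-to-group mapping
#'
#' Breast and chest-wall biopsies are local disease (primaries and local
#' recurrences), lymph node biopsies form their own group, the named distal
#' organs are metastases, and anything else (including "other"/"unknown")
#' is ambiguous. The mapping is config-overridable because clinical site
#' annotations vary between laboratories.
#'
#' @return Named character vector mapping site to group.
#' @export
site_group_map <- function() {
  c("breast"        = "local",
    "chest wall"    = "local",
    "lymph node"    = "lymph_node",
    "liver"         = "metastasis",
    "bone"          = "metastasis",
    "lung"          = "metastasis",
    "brain"         = "metastasis",
    "skin"          = "metastasis",
    "pleura"        = "metastasis",
    "pleural fluid" = "metastasis",
    "soft tissue"   = "metastasis",
    "ovary"         = "metastasis",
    "GI"            = "metastasis")
}

.groups      <- c("local", "lymph_node", "metastasis", "ambiguous")
.er_levels   <- c("positive", "negative", "unknown")
.er_sources  <- c("pathology_report", "imputed", "unknown")
.histologies <- c("IDC", "ILC", "other", "unknown")
.alt_classes <- c("short_variant", "amplification", "deletion", "rearrangement")
.fn_statuses <- c("known", "likely", "VUS")

#' Map a biopsy site to a disease group
#'
#' Deterministic, total mapping: recognised sites go to local, lymph_node or
#' metastasis per [site_group_map()]; unrecognised sites are ambiguous.
#'
#' @param biopsy_site Character vector of site labels.
#' @param map Optional site-to-group mapping (named character vector).
#' @return Character vector of groups.
#' @export
assign_group <- function(biopsy_site, map = site_group_map()) {
  grp <- unname(map[as.character(biopsy_site)])
  grp[is.na(grp)] <- "ambiguous"
  grp
}

## Cohort constructor ----------------------------------------------------

#' Assemble a cohort object
#'
#' A cohort bundles per-sample clinical metadata, per-call alteration records
#' and the ordered gene panel. Every alteration must refer to a known sample
#' and a panel gene.
#'
#' @param samples Data frame with columns `sample_id`, `biopsy_site`, `group`,
#'   `er_status`, `er_source`, `er_prob`, `her2_amplified`, `histology`,
#'   `age_years`.
#' @param alterations Data frame with columns `sample_id`, `gene`,
#'   `alteration_class`, `protein_change`, `functional_status`, `vaf`.
#' @param panel Character vector of panel gene symbols, no duplicates.
#' @return Object of class `metbc_cohort`.
#' @export
cohort <- function(samples, alterations, panel) {
  if (anyDuplicated(panel)) stop("panel contains duplicate gene symbols")
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  if (nrow(alterations)) {
    bad <- !(alterations$sample_id %in% samples$sample_id)
    if (any(bad)) {
      warning(sum(bad), " alteration call(s) for unknown sample_ids dropped")
      alterations <- alterations[!bad, , drop = FALSE]
    }
    off_panel <- !(alterations$gene %in% panel)
    if (any(off_panel)) {
      warning(sum(off_panel), " alteration call(s) for off-panel genes dropped")
      alterations <- alterations[!off_panel, , drop = FALSE]
    }
    if (any(!is.na(alterations$vaf) &
            (alterations$vaf < 0 | alterations$vaf > 1)))
      stop("vaf outside [0, 1]")
    if (!all(alterations$alteration_class %in% .alt_classes))
      stop("unknown alteration_class: ",
           paste(setdiff(unique(alterations$alteration_class), .alt_classes),
                 collapse = ", "))
  }
  if (any(!is.na(samples$er_prob) &
          (samples$er_prob < 0 | samples$er_prob > 1)))
    stop("er_prob outside [0, 1]")
  structure(list(samples = samples, alterations = alterations,
                 panel = as.character(panel)),
            class = "metbc_cohort")
}

#' @export
print.metbc_cohort <- function(x, ...) {
  cat("metbc cohort:", nrow(x$samples), "samples,",
      nrow(x$alterations), "alteration calls,",
      length(x$panel), "panel genes\n")
  print(table(group = x$samples$group))
  invisible(x)
}

## Tabular I/O ------------------------------------------------------------
## Dialect: UTF-8, tab-separated, "." for missing values.

.required_sample_cols <- c("sample_id", "biopsy_site")

.dot_to_na <- function(x) { x[x == "."] <- NA; x }
.na_to_dot <- function(x) { x <- as.character(x); x[is.na(x)] <- "."; x }

#' Read a sample metadata table
#'
#' Tab-separated, UTF-8, "." for missing. Required columns: `sample_id`,
#' `biopsy_site`. Missing `group` values are filled from the site mapping;
#' malformed enum values are mapped to `unknown` with a warning.
#'
#' @param path Path to a TSV file.
#' @param map Site-to-group mapping, see [assign_group()].
#' @return Data frame of sample records (the metadata part of a cohort).
#' @export
read_sample_table <- function(path, map = site_group_map()) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = character())
  missing_cols <- setdiff(.required_sample_cols, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  n <- nrow(df)
  get_col <- function(nm) if (nm %in% names(df)) .dot_to_na(df[[nm]]) else rep(NA_character_, n)

  out <- data.frame(
    sample_id   = df$sample_id,
    biopsy_site = df$biopsy_site,
    group       = get_col("group"),
    er_status   = get_col("er_status"),
    er_source   = get_col("er_source"),
    er_prob     = suppressWarnings(as.numeric(get_col("er_prob"))),
    her2_amplified = tolower(get_col("her2_amplified")) %in% c("true", "1", "yes"),
    histology   = get_col("histology"),
    age_years   = suppressWarnings(as.integer(get_col("age_years"))),
    stringsAsFactors = FALSE)

  fix_enum <- function(x, levels, name) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      warning(sum(bad), " malformed ", name, " value(s) mapped to unknown")
      x[bad] <- "unknown"
    }
    x[is.na(x)] <- "unknown"
    x
  }
  out$er_status <- fix_enum(out$er_status, .er_levels, "er_status")
  out$er_source <- fix_enum(out$er_source, .er_sources, "er_source")
  out$histology <- fix_enum(out$histology, .histologies, "histology")

  fill <- is.na(out$group)
  out$group[fill] <- assign_group(out$biopsy_site[fill], map)
  bad_grp <- !(out$group %in% .groups)
  if (any(bad_grp)) {
    warning(sum(bad_grp), " malformed group value(s) re-derived from site")
    out$group[bad_grp] <- assign_group(out$biopsy_site[bad_grp], map)
  }
  out
}

#' Read an alteration call table and attach it to sample metadata
#'
#' @param path Path to a TSV file with columns `sample_id`, `gene`,
#'   `alteration_class` and optional `protein_change`, `functional_status`,
#'   `vaf`.
#' @param samples Sample metadata data frame (from [read_sample_table()]).
#' @param panel Gene panel; defaults to the genes observed in the table.
#' @return A `metbc_cohort`.
#' @export
read_alteration_table <- function(path, samples, panel = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = character())
  req <- c("sample_id", "gene", "alteration_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(df)
  get_col <- function(nm) if (nm %in% names(df)) .dot_to_na(df[[nm]]) else rep(NA_character_, n)
  alt <- data.frame(
    sample_id = df$sample_id, gene = df$gene,
    alteration_class  = df$alteration_class,
    protein_change    = get_col("protein_change"),
    functional_status = get_col("functional_status"),
    vaf = suppressWarnings(as.numeric(get_col("vaf"))),
    stringsAsFactors = FALSE)
  if (n) {
    if (!all(alt$alteration_class %in% .alt_classes))
      stop("unknown alteration_class: ",
           paste(setdiff(unique(alt$alteration_class), .alt_classes),
                 collapse = ", "))
    if (any(!is.na(alt$vaf) & (alt$vaf < 0 | alt$vaf > 1)))
      stop("vaf outside [0, 1]")
    # protein changes only make sense for short variants
    alt$protein_change[alt$alteration_class != "short_variant"] <- NA
  }
  if (is.null(panel)) panel <- sort(unique(alt$gene))
  cohort(samples, alt, panel)
}

#' Write cohort tables
#'
#' Writes `samples.tsv` and `alterations.tsv` in the package's tab-separated
#' dialect ("." for missing), such that reading them back reproduces the
#' cohort field by field.
#'
#' @param x A `metbc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- x$samples
  s$her2_amplified <- ifelse(s$her2_amplified, "true", "false")
  s[] <- lapply(s, .na_to_dot)
  a <- x$alterations
  a[] <- lapply(a, .na_to_dot)
  ps <- file.path(dir, "samples.tsv")
  pa <- file.path(dir, "alterations.tsv")
  write.table(s, ps, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(a, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(samples = ps, alterations = pa))
}

#' Read a cohort from a directory written by [write_cohort()]
#' @param dir Directory containing `samples.tsv` and `alterations.tsv`.
#' @param panel Optional gene panel.
#' @return A `metbc_cohort`.
#' @export
read_cohort <- function(dir, panel = NULL) {
  s <- read_sample_table(file.path(dir, "samples.tsv"))
  read_alteration_table(file.path(dir, "alterations.tsv"), s, panel = panel)
}
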