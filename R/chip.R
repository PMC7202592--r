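## Clonal-hematopoiesis diagnostics: age-stratified mutation rates
## normalized to the youngest bin, and VAF-versus-age trend tests.

.default_age_bins <- function()
  list(breaks = c(20, 40, 50, 60, 70, Inf),
       labels = c("20-39", "40-49", "50-59", "60-69", "70+"))

#' Age-normalized mutation rates for a gene
#'
#' Per-age-bin prevalence of short-variant carriers, normalized to the
#' reference (youngest, 20-39) bin, with binomial standard errors. A rising
#' normalized rate in a gene not otherwise age-associated is one line of
#' CHIP evidence.
#'
#' @param x A `metbc_cohort`.
#' @param gene Gene symbol (default `"DNMT3A"`).
#' @param bins List with `breaks` and `labels`; default bins 20-39, 40-49,
#'   50-59, 60-69, 70+.
#' @return Data frame of class `metbc_agetrend`: `bin`, `n`, `events`,
#'   `rate`, `rate_se`, `normalized` (reference bin exactly 1).
#' @export
age_normalized_rates <- function(x, gene = "DNMT3A",
                                 bins = .default_age_bins()) {
  stopifnot(inherits(x, "metbc_cohort"))
  s <- x$samples[!is.na(x$samples$age_years), , drop = FALSE]
  bin <- cut(s$age_years, breaks = bins$breaks, labels = bins$labels,
             right = FALSE, include.lowest = TRUE)
  carriers <- unique(x$alterations$sample_id[
    x$alterations$gene == gene &
      x$alterations$alteration_class == "short_variant"])
  hit <- s$sample_id %in% carriers
  n <- as.integer(table(bin))
  ev <- as.integer(tapply(hit, bin, sum, default = 0L))
  if (n[1] == 0) stop("empty reference age bin ", bins$labels[1])
  rate <- ev / n
  if (rate[1] == 0) stop("no ", gene, " events in the reference bin")
  out <- data.frame(bin = bins$labels, n = n, events = ev, rate = rate,
                    rate_se = sqrt(rate * (1 - rate) / pmax(n, 1)),
                    normalized = rate / rate[1],
                    stringsAsFactors = FALSE)
  class(out) <- c("metbc_agetrend", "data.frame")
  out
}

#' VAF-versus-age trend for a gene
#'
#' Least-squares slope of the variant allele fraction on patient age across
#' the gene's short-variant calls, with a normal-approximation p-value.
#' A negative slope (blood clones dilute with age-related biopsy changes,
#' tumor variants do not) is the second line of CHIP evidence; PIK3CA and
#' TP53 serve as age-flat comparators.
#'
#' @param x A `metbc_cohort`.
#' @param gene Gene symbol.
#' @return List with `gene`, `n`, `slope`, `se`, `p` (NA when fewer than 3
#'   usable calls).
#' @export
vaf_age_trend <- function(x, gene = "DNMT3A") {
  stopifnot(inherits(x, "metbc_cohort"))
  v <- x$alterations
  v <- v[v$gene == gene & v$alteration_class == "short_variant" &
           !is.na(v$vaf), , drop = FALSE]
  age <- x$samples$age_years[match(v$sample_id, x$samples$sample_id)]
  ok <- !is.na(age)
  if (sum(ok) < 3)
    return(list(gene = gene, n = sum(ok), slope = NA_real_, se = NA_real_,
                p = NA_real_))
  fit <- lm(v$vaf[ok] ~ age[ok])
  sm <- suppressWarnings(summary(fit))$coefficients
  list(gene = gene, n = sum(ok), slope = unname(sm[2, 1]),
       se = unname(sm[2, 2]),
       p = unname(2 * pnorm(-abs(sm[2, 1] / sm[2, 2]))))
}

#' Compare VAF-age slopes across genes
#'
#' @param x A `metbc_cohort`.
#' @param genes Genes to profile (default DNMT3A and the age-flat
#'   comparators PIK3CA and TP53).
#' @return Data frame with one row per gene: `n`, `slope`, `se`, `p`.
#' @export
vaf_age_comparison <- function(x, genes = c("DNMT3A", "PIK3CA", "TP53")) {
  do.call(rbind, lapply(genes, function(g) {
    r <- vaf_age_trend(x, g)
    data.frame(gene = g, n = r$n, slope = r$slope, se = r$se, p = r$p,
               stringsAsFactors = FALSE)
  }))
}
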