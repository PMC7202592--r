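## Rule-based extraction of ER status from pathology-report text.
##
## Within a line window of an "ER"/"Estrogen" anchor, the nearest status
## keyword within a character-distance threshold decides the status;
## negation tokens between anchor and keyword flip it; boilerplate lines
## (interpretation guides and the like) are blanked before matching.

#' Parser configuration
#'
#' Keyword stems are matched case-insensitively as word-initial tokens;
#' "ER" is matched only as a standalone token. The distance threshold and
#' window are explicit, auditable defaults.
#'
#' @param positive_keywords,negative_keywords Keyword stems.
#' @param negation_tokens Tokens that flip the status when they occur
#'   between anchor and keyword (applied once per evidence span; double
#'   negation is not resolved).
#' @param window_lines Maximum line distance between anchor and keyword.
#' @param max_distance_chars Maximum character distance.
#' @param boilerplate_patterns Lines matching any of these regular
#'   expressions are excluded before matching.
#' @return List of class `metbc_parser_config`.
#' @export
parser_config <- function(positive_keywords = c("positive", "detect",
                                                "expression"),
                          negative_keywords = c("negative", "rare"),
                          negation_tokens = c("not", "no", "non"),
                          window_lines = 3,
                          max_distance_chars = 130,
                          boilerplate_patterns = c("interpretation guide",
                                                   "reported as",
                                                   "guidelines",
                                                   "bibliograph")) {
  structure(list(positive_keywords = positive_keywords,
                 negative_keywords = negative_keywords,
                 negation_tokens = negation_tokens,
                 window_lines = window_lines,
                 max_distance_chars = max_distance_chars,
                 boilerplate_patterns = boilerplate_patterns),
            class = "metbc_parser_config")
}

# all matches of a regex with offsets, on text lowered beforehand
.find_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(offset = integer(0),
                                    match = character(0)))
  data.frame(offset = as.integer(m),
             match = regmatches(text, list(m))[[1]],
             stringsAsFactors = FALSE)
}

#' Parse ER status from pathology-report text
#'
#' Always returns a result: `unknown` when no qualifying evidence exists
#' within the line window and character threshold. When several
#' anchor-keyword pairs qualify, the closest wins; an exact distance tie
#' goes to the negative reading (conservative clinical default).
#'
#' @param text Report text (plain, possibly multi-line).
#' @param config A [parser_config()].
#' @return List of class `metbc_parse_result`: `status`, `anchor`,
#'   `anchor_offset`, `evidence`, `evidence_offset`, `distance_chars`,
#'   `negated`, `filtered_reason`.
#' @export
parse_er_status <- function(text, config = parser_config()) {
  result <- function(status, anchor = NA, aoff = NA, ev = NA, eoff = NA,
                     dist = NA, negated = FALSE, reason = NULL)
    structure(list(status = status, anchor = anchor, anchor_offset = aoff,
                   evidence = ev, evidence_offset = eoff,
                   distance_chars = dist, negated = negated,
                   filtered_reason = reason),
              class = "metbc_parse_result")
  if (is.null(text) || !nzchar(text)) return(result("unknown"))
  low <- tolower(text)
  lines <- strsplit(low, "\n", fixed = TRUE)[[1]]
  boiler <- vapply(lines, function(l)
    any(vapply(config$boilerplate_patterns, grepl, logical(1), x = l)),
    logical(1))
  lines[boiler] <- strrep(" ", nchar(lines[boiler]))  # keep offsets stable
  low <- paste(lines, collapse = "\n")

  # line number of a character offset
  line_starts <- c(1L, which(strsplit(low, "")[[1]] == "\n") + 1L)
  line_of <- function(off) findInterval(off, line_starts)

  anchors <- .find_all(low, "\\b(er|estrogen)\\b")
  if (!nrow(anchors)) return(result("unknown"))

  find_kw <- function(keys, pol) {
    hits <- do.call(rbind, lapply(keys, function(k)
      .find_all(low, paste0("\\b", k, "\\w*"))))
    if (is.null(hits) || !nrow(hits)) return(NULL)
    hits$polarity <- pol
    hits
  }
  kw <- rbind(find_kw(config$positive_keywords, "positive"),
              find_kw(config$negative_keywords, "negative"))
  if (is.null(kw) || !nrow(kw)) return(result("unknown"))

  best <- NULL
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(kw))) {
      if (anchors$offset[i] == kw$offset[j]) next
      dist <- abs(anchors$offset[i] - kw$offset[j])
      if (dist > config$max_distance_chars) next
      if (abs(line_of(anchors$offset[i]) - line_of(kw$offset[j])) >
          config$window_lines) next
      cand <- list(anchor = anchors$match[i], aoff = anchors$offset[i],
                   ev = kw$match[j], eoff = kw$offset[j], dist = dist,
                   polarity = kw$polarity[j])
      better <- is.null(best) || cand$dist < best$dist ||
        (cand$dist == best$dist && best$polarity == "positive" &&
           cand$polarity == "negative")
      if (better) best <- cand
    }
  }
  if (is.null(best)) return(result("unknown"))

  span <- substr(low, min(best$aoff, best$eoff),
                 max(best$aoff, best$eoff))
  negated <- any(vapply(config$negation_tokens, function(tok)
    grepl(paste0("\\b", tok, "\\b"), span), logical(1)))
  status <- best$polarity
  if (negated) status <- if (status == "positive") "negative" else "positive"
  result(status, best$anchor, best$aoff, best$ev, best$eoff, best$dist,
         negated)
}

#' @export
print.metbc_parse_result <- function(x, ...) {
  cat("ER status:", x$status,
      if (!is.na(x$evidence))
        paste0("(", x$anchor, " ... ", x$evidence, ", ", x$distance_chars,
               " chars", if (x$negated) ", negated", ")"), "\n")
  invisible(x)
}

#' Evaluate the parser against labelled reports
#'
#' @param reports Data frame with `text` and `truth` columns.
#' @param config A [parser_config()].
#' @return List with `accuracy` and the per-report `status` vector
#'   (unknowns count as errors).
#' @export
evaluate_parser <- function(reports, config = parser_config()) {
  stopifnot(nrow(reports) >= 1)
  status <- vapply(reports$text,
                   function(t) parse_er_status(t, config)$status,
                   character(1), USE.NAMES = FALSE)
  list(accuracy = mean(status == reports$truth), status = status)
}
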