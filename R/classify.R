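## classification bands, scorecard assembly and report serialization.

#' Map a point total to the five-tier classification
#'
#' Thresholds reproduce the published bands exactly: pathogenic at 0.99 or
#' more points, likely pathogenic 0.90-0.98, uncertain significance -0.89
#' to 0.89, likely benign -0.90 to -0.98, benign at -0.99 or fewer points.
#' Totals between printed band edges (e.g. 0.985) fall to the lower band by
#' the same thresholds, keeping the mapping total over the reals.
#'
#' @param total Finite point total.
#' @return One of `"PATHOGENIC"`, `"LIKELY_PATHOGENIC"`, `"VUS"`,
#'   `"LIKELY_BENIGN"`, `"BENIGN"`.
#' @export
classify_total <- function(total) {
  if (length(total) != 1L || !is.finite(total))
    cnv_abort("classification requires a single finite total",
              "cnvscore_validation_error")
  if (total >= 0.99) "PATHOGENIC"
  else if (total >= 0.90) "LIKELY_PATHOGENIC"
  else if (total > -0.90) "VUS"
  else if (total > -0.99) "LIKELY_BENIGN"
  else "BENIGN"
}

#' Assemble a scorecard from evidence items
#'
#' Sums contributing points in decimal-safe arithmetic (integer hundredths),
#' honoring the terminal-benign short-circuit: when a terminal benign
#' category fired, the automated total is exactly -1.0 regardless of other
#' sections. Records the pre- (automated-only) and final classification and
#' whether the automated evidence already suffices for classification
#' without manual review (|total| >= 0.99 or terminal benign).
#'
#' @param query A `cnv_query`.
#' @param items Merged evidence data frame (automated + manual).
#' @param terminal Whether a terminal benign category fired.
#' @param conflicts Character vector of conflict flags.
#' @param build Genome build label echoed from the database.
#' @return A `scorecard` object.
#' @export
build_scorecard <- function(query, items, terminal = FALSE,
                            conflicts = character(0), build = NA_character_) {
  auto <- items[items$source == "AUTOMATED" & items$contributes, ,
                drop = FALSE]
  auto_total <- if (terminal) -1 else sum_points(auto$points)
  contributing <- items[items$contributes, , drop = FALSE]
  final_total <- if (terminal) -1 else sum_points(contributing$points)
  pre_class <- classify_total(auto_total)
  final_class <- classify_total(final_total)
  sufficient <- terminal || auto_total >= 0.99 || auto_total <= -0.99
  structure(list(query = query, items = items, auto_total = auto_total,
                 final_total = final_total, pre_classification = pre_class,
                 final_classification = final_class,
                 sufficient_without_manual = sufficient,
                 terminal_benign = terminal, conflicts = conflicts,
                 build = build),
            class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat(write_report(x, format = "text"))
  invisible(x)
}

scorecard_to_list <- function(card) {
  list(query = list(label = card$query$label %||% "",
                    chrom = card$query$chrom, start = card$query$start,
                    end = card$query$end, dosage = card$query$dosage),
       build = card$build,
       items = card$items,
       auto_total = card$auto_total,
       final_total = card$final_total,
       pre_classification = card$pre_classification,
       final_classification = card$final_classification,
       sufficient_without_manual = card$sufficient_without_manual,
       terminal_benign = card$terminal_benign,
       conflicts = as.list(card$conflicts))
}

#' Parse a JSON report back into a scorecard
#'
#' Inverse of `write_report(card, "json")`.
#' @param json JSON string or path.
#' @return A `scorecard`.
#' @export
read_report <- function(json) {
  x <- jsonlite::fromJSON(json)
  q <- cnv_query(x$query$chrom, x$query$start, x$query$end, x$query$dosage,
                 label = if (nzchar(x$query$label %||% "")) x$query$label
                 else NULL)
  build_scorecard(q, x$items, terminal = isTRUE(x$terminal_benign),
                  conflicts = unlist(x$conflicts) %||% character(0),
                  build = x$build)
}

# section ordering for the text narrative
category_section <- function(category) as.integer(substr(category, 1, 1))

tsv_row <- function(card, status = "ok") {
  contributing <- card$items[card$items$contributes, , drop = FALSE]
  cats <- paste(sprintf("%s:%g", contributing$category, contributing$points),
                collapse = ";")
  data.frame(label = card$query$label %||% "",
             chrom = card$query$chrom, start = card$query$start,
             end = card$query$end, dosage = card$query$dosage,
             auto_total = card$auto_total, final_total = card$final_total,
             pre_class = card$pre_classification,
             final_class = card$final_classification,
             categories = cats,
             flags = paste(c(if (card$terminal_benign) "terminal_benign",
                             card$conflicts), collapse = "|"),
             status = status, stringsAsFactors = FALSE)
}

#' Serialize a scorecard
#'
#' `json` round-trips through [read_report()]; `tsv` yields the one-line
#' batch format; `text` mirrors the narrative report ordering (Section 1
#' through 5, then totals and classification).
#'
#' @param card A `scorecard`.
#' @param format `"json"`, `"tsv"` or `"text"`.
#' @param file Optional path; when given, the report is written there.
#' @return The serialized report, invisibly when `file` is given.
#' @export
write_report <- function(card, format = c("json", "tsv", "text"),
                         file = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    json = jsonlite::toJSON(scorecard_to_list(card), auto_unbox = TRUE,
                            digits = NA, pretty = TRUE, na = "null"),
    tsv = {
      row <- tsv_row(card)
      paste(c(paste(names(row), collapse = "\t"),
              paste(unlist(lapply(row, as.character)), collapse = "\t")),
            collapse = "\n")
    },
    text = {
      items <- card$items[order(category_section(card$items$category),
                                card$items$category), , drop = FALSE]
      lines <- c(sprintf("CNV %s (%s)%s  [build %s]", format_cnv(card$query),
                         card$query$dosage,
                         if (is.null(card$query$label)) ""
                         else paste0(" ", card$query$label),
                         card$build),
                 "evidence:")
      for (i in seq_len(nrow(items)))
        lines <- c(lines, sprintf("  %-5s %6.2f %s[%s] %s",
                                  items$category[i], items$points[i],
                                  if (items$contributes[i]) "* " else "  ",
                                  items$source[i], items$rationale[i]))
      lines <- c(lines,
                 sprintf("automated total: %.2f (%s)%s", card$auto_total,
                         card$pre_classification,
                         if (card$sufficient_without_manual)
                           "; sufficient without manual review" else ""),
                 sprintf("final total:     %.2f (%s)", card$final_total,
                         card$final_classification))
      if (length(card$conflicts))
        lines <- c(lines, paste("conflict:", card$conflicts))
      paste0(paste(lines, collapse = "\n"), "\n")
    })
  if (!is.null(file)) {
    writeLines(as.character(out), file)
    return(invisible(out))
  }
  out
}
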