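#' Parse a CNV coordinate string into a query object
#'
#' Accepts the conventional `chrom:start-end` notation, with or without a
#' `chr` prefix and with optional thousands separators (commas) or whitespace
#' inside the integers. Coordinates are 1-based and fully closed.
#'
#' @param text Coordinate string, e.g. `"chr1:1-1000"` or
#'   `"chr22:18,761,827-20,307,561"`.
#' @param dosage `"LOSS"` (deletion) or `"GAIN"` (duplication).
#' @param label Optional free-text identifier carried into reports.
#' @return A `cnv_query` object with fields `chrom`, `start`, `end`,
#'   `dosage`, `label`.
#' @examples
#' parse_cnv("chr1:1-1000", "LOSS")
#' parse_cnv("22:18,761,827-20,307,561", "LOSS")
#' @export
parse_cnv <- function(text, dosage = c("LOSS", "GAIN"), label = NULL) {
  dosage <- match.arg(toupper(dosage), c("LOSS", "GAIN"))
  if (!is.character(text) || length(text) != 1L || is.na(text))
    cnv_abort("coordinate must be a single character string",
              "cnvscore_parse_error")
  cleaned <- gsub("[,[:space:]]", "", text)
  m <- regmatches(cleaned,
                  regexec("^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$", cleaned))[[1]]
  if (length(m) != 4L) {
    bad <- if (!grepl(":", cleaned)) cleaned else sub("^[^:]*:", "", cleaned)
    cnv_abort(sprintf("malformed CNV coordinate %s (offending token: '%s'); expected chrom:start-end",
                      sQuote(text), bad),
              "cnvscore_parse_error")
  }
  cnv_query(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]),
            dosage = dosage, label = label)
}

#' Construct a CNV query
#'
#' @param chrom Chromosome label; `"22"` and `"chr22"` are equivalent.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param dosage `"LOSS"` or `"GAIN"`.
#' @param label Optional identifier.
#' @return A `cnv_query` object.
#' @export
cnv_query <- function(chrom, start, end, dosage = c("LOSS", "GAIN"),
                      label = NULL) {
  dosage <- match.arg(toupper(dosage), c("LOSS", "GAIN"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < 1)
    cnv_abort("CNV coordinates must be positive integers",
              "cnvscore_validation_error")
  if (start > end)
    cnv_abort(sprintf("invalid interval: start (%s) > end (%s)",
                      format(start, big.mark = ","),
                      format(end, big.mark = ",")),
              "cnvscore_validation_error")
  structure(list(chrom = normalize_chrom(chrom), start = start, end = end,
                 dosage = dosage, label = label),
            class = "cnv_query")
}

#' Format a CNV query back to coordinate notation
#'
#' `format_cnv(parse_cnv(s))` is idempotent for well-formed `s`.
#' @param query A `cnv_query`.
#' @return `chrom:start-end` string without separators.
#' @export
format_cnv <- function(query) {
  stopifnot(inherits(query, "cnv_query"))
  sprintf("%s:%s-%s", query$chrom,
          format(query$start, scientific = FALSE, trim = TRUE),
          format(query$end, scientific = FALSE, trim = TRUE))
}

#' @export
print.cnv_query <- function(x, ...) {
  cat(sprintf("<cnv_query> %s %s (%s bp)%s\n", format_cnv(x), x$dosage,
              format(interval_length(x$start, x$end), big.mark = ","),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}
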