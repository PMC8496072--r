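## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Point totals are carried as integer hundredths so that band boundaries
# (0.99, 0.90, ...) are compared exactly, never through floating-point sums.
to_hundredths <- function(x) as.integer(round(x * 100))

from_hundredths <- function(h) h / 100

sum_points <- function(points) {
  if (length(points) == 0L) return(0)
  from_hundredths(sum(to_hundredths(points)))
}

cnv_abort <- function(msg, class = "cnvscore_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# "22" and "chr22" compare equal; the normalized form carries the prefix.
normalize_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  if (any(!nzchar(chrom))) cnv_abort("chromosome label must be non-empty")
  ifelse(grepl("^chr", chrom, ignore.case = TRUE),
         sub("^chr", "chr", chrom, ignore.case = TRUE),
         paste0("chr", chrom))
}

interval_length <- function(start, end) end - start + 1L

# 1-based fully-closed overlap: >= 1 shared bp.
overlaps_1bp <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

shared_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
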