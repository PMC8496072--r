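# Independent oracles for property tests. These deliberately take a
# different computational route from the package internals.

# O(n) linear scan over a record table: every record sharing >= 1 bp.
brute_scan <- function(df, chrom, start, end) {
  hit <- df$chrom == chrom & df$start <= end & df$end >= start
  out <- df[hit, , drop = FALSE]
  id_col <- intersect(c("gene_id", "region_id", "variant_id"), names(out))
  id <- if (length(id_col)) out[[id_col[1]]] else rownames(out)
  out <- out[order(out$chrom, out$start, out$end, id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random multi-exon gene model built directly (not via the package's
# fixture builder): exon and intron lengths drawn freely, strand random,
# CDS trimmed by strand-aware UTRs.
rand_gene_model <- function(id) {
  n <- sample(2:6, 1)
  exon_lens <- sample(30:250, n, replace = TRUE)
  introns <- sample(60:800, max(n - 1, 1), replace = TRUE)
  start <- sample(1e4:1e6, 1)
  es <- numeric(n); ee <- numeric(n); pos <- start
  for (i in seq_len(n)) {
    es[i] <- pos; ee[i] <- pos + exon_lens[i] - 1
    if (i < n) pos <- ee[i] + introns[i] + 1
  }
  strand <- sample(c("+", "-"), 1)
  utr5 <- sample(5:(exon_lens[1] - 5), 1)
  utr3 <- sample(5:(exon_lens[n] - 5), 1)
  if (strand == "+") {
    cds_start <- start + utr5; cds_end <- ee[n] - utr3
  } else {
    cds_start <- start + utr3; cds_end <- ee[n] - utr5
  }
  df <- data.frame(gene_id = id, symbol = id, chrom = "chrT", start = start,
                   end = ee[n], strand = strand, cds_start = cds_start,
                   cds_end = cds_end,
                   exon_starts = paste(es, collapse = ","),
                   exon_ends = paste(ee, collapse = ","),
                   coding = 1L, canonical = 1L, pli = NA_real_,
                   oe_upper = NA_real_, hi_index = NA_real_, relevant = 1L,
                   stringsAsFactors = FALSE)
  cnvscore:::validate_genes(df)
}

# Coding bases of the gene removed by the deletion [ds, de].
deleted_coding_oracle <- function(gene, ds, de) {
  es <- gene$exon_starts_list[[1]]; ee <- gene$exon_ends_list[[1]]
  total <- 0
  for (i in seq_along(es)) {
    s <- max(es[i], gene$cds_start, ds)
    e <- min(ee[i], gene$cds_end, de)
    if (s <= e) total <- total + (e - s + 1)
  }
  total
}

# Brute-force transcript reconstruction for NMD after a genomic deletion:
# shift coordinates past the deletion, collect retained exon pieces, merge
# pieces that became genomically adjacent, then apply the 50-nt rule with
# the premature stop taken at the deletion junction.
nmd_oracle <- function(gene, ds, de) {
  frame_shift <- deleted_coding_oracle(gene, ds, de) %% 3 != 0
  if (!frame_shift) return(FALSE)
  es <- gene$exon_starts_list[[1]]; ee <- gene$exon_ends_list[[1]]
  o <- order(es); es <- es[o]; ee <- ee[o]
  L <- de - ds + 1
  shift <- function(p) ifelse(p > de, p - L, p)
  pieces <- list()
  for (i in seq_along(es)) {
    if (es[i] < ds)
      pieces[[length(pieces) + 1L]] <- c(shift(es[i]), shift(min(ee[i], ds - 1)))
    if (ee[i] > de)
      pieces[[length(pieces) + 1L]] <- c(shift(max(es[i], de + 1)), shift(ee[i]))
  }
  if (length(pieces) == 0L) return(FALSE)
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if (m[i, 1] == last[2] + 1)
      merged[[length(merged)]] <- c(last[1], m[i, 2])
    else merged[[length(merged) + 1L]] <- m[i, ]
  }
  lens <- vapply(merged, function(p) p[2] - p[1] + 1, numeric(1))
  if (gene$strand == "-") lens <- rev(lens)
  if (length(lens) < 2L) return(FALSE)
  last_junction <- sum(lens[-length(lens)])
  # retained spliced bases transcriptionally upstream of the deletion
  up <- if (gene$strand == "+") {
    sum(pmax(0, pmin(ee, ds - 1) - es + 1))
  } else {
    sum(pmax(0, ee - pmax(es, de + 1) + 1))
  }
  (last_junction - up) >= 50
}

# Random contained deletion within a gene span.
rand_deletion <- function(gene) {
  s <- sample(gene$start:gene$end, 1)
  len <- sample(1:min(500, gene$end - s + 1), 1)
  c(s, s + len - 1)
}
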