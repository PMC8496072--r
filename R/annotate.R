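## annotator: turn a CNV query plus the database into the full set of
## overlap facts the scorers consume.

#' Default engine thresholds
#'
#' Commonness thresholds for population variants (frequency >= 1% with
#' >= 1,000 samples for sample-counted sources or >= 2,000 alleles for
#' allele-counted sources), the predicted-haploinsufficiency gene triple
#' (pLI >= 0.9, o/e upper bound < 0.35, HI index <= 10%), the allele
#' frequency below which a known pathogenic variant is counted as
#' "established" (1%), the frequency at which loss-of-function variation in
#' a region counts as frequent in the population (0.1%), and the minimum
#' dosage score treated as an established ClinGen curation (3).
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_frequency = 0.01, min_samples = 1000, min_alleles = 2000,
       pli_min = 0.9, oe_upper_max = 0.35, hi_index_max = 10,
       pathogenic_af_max = 0.01, lof_frequent_af = 0.001,
       min_established_score = 3)
}

region_overlap_class <- function(q_start, q_end, r_start, r_end) {
  if (q_start <= r_start && q_end >= r_end) "CNV_CONTAINS_ELEMENT"
  else if (q_start >= r_start && q_end <= r_end) "CNV_WITHIN_ELEMENT"
  else "OTHER_PARTIAL"
}

# Exon intervals in transcription order (exon 1 = 5'-most).
exons_tx_order <- function(gene) {
  es <- gene$exon_starts_list[[1]]; ee <- gene$exon_ends_list[[1]]
  o <- order(es)
  es <- es[o]; ee <- ee[o]
  if (gene$strand == "-") { es <- rev(es); ee <- rev(ee) }
  list(starts = es, ends = ee)
}

coding_part <- function(es, ee, cds_start, cds_end) {
  s <- pmax(es, cds_start); e <- pmin(ee, cds_end)
  keep <- s <= e
  list(starts = s[keep], ends = e[keep])
}

# Coding bases of the gene intersected by [q_start, q_end].
coding_bases_hit <- function(q_start, q_end, gene) {
  if (is.na(gene$cds_start)) return(0)
  cp <- coding_part(gene$exon_starts_list[[1]], gene$exon_ends_list[[1]],
                    gene$cds_start, gene$cds_end)
  if (length(cp$starts) == 0L) return(0)
  sum(shared_bp(q_start, q_end, cp$starts, cp$ends))
}

#' Classify how a CNV overlaps one gene model
#'
#' The relation is strand-aware: a CNV covering the transcription start but
#' not the transcription end of the gene is a 5'-end partial overlap
#' (`PARTIAL_5PRIME`), and vice versa; for minus-strand genes the genomic
#' sense reverses. Exon ordinals are reported in transcription order, so
#' "last exon" is well defined on both strands.
#'
#' @param query A `cnv_query` (or list with `chrom`, `start`, `end`).
#' @param gene One-row slice of the gene table (a selected transcript).
#' @return List with `relation`, `exons_involved`,
#'   `coding_sequence_involved`, `only_last_exon`, `only_3prime_utr`,
#'   `gene_id`, `symbol`.
#' @export
classify_gene_overlap <- function(query, gene) {
  q_start <- query$start; q_end <- query$end
  if (!overlaps_1bp(q_start, q_end, gene$start, gene$end))
    cnv_abort("classify_gene_overlap requires >= 1 bp overlap",
              "cnvscore_contract_error")
  covers_start <- q_start <= gene$start
  covers_end <- q_end >= gene$end
  relation <- if (covers_start && covers_end) "CNV_CONTAINS_ELEMENT"
  else if (!covers_start && !covers_end) "CNV_WITHIN_ELEMENT"
  else if (covers_start) {
    if (gene$strand == "+") "PARTIAL_5PRIME" else "PARTIAL_3PRIME"
  } else {
    if (gene$strand == "+") "PARTIAL_3PRIME" else "PARTIAL_5PRIME"
  }

  tx <- exons_tx_order(gene)
  hit <- overlaps_1bp(q_start, q_end, tx$starts, tx$ends)
  exons_involved <- which(hit)
  n_exons <- length(tx$starts)
  coding_involved <- coding_bases_hit(q_start, q_end, gene) > 0

  only_last_exon <- length(exons_involved) == 1L &&
    exons_involved[1] == n_exons

  # Intersection with the gene lies entirely 3' (transcription sense) of
  # the CDS end with no coding overlap.
  i_start <- max(q_start, gene$start); i_end <- min(q_end, gene$end)
  only_3prime_utr <- !coding_involved && !is.na(gene$cds_start) &&
    if (gene$strand == "+") i_start > gene$cds_end else i_end < gene$cds_start

  list(gene_id = gene$gene_id, symbol = gene$symbol, relation = relation,
       exons_involved = exons_involved,
       coding_sequence_involved = coding_involved,
       only_last_exon = only_last_exon,
       only_3prime_utr = only_3prime_utr)
}

# Distinct protein-coding gene symbols overlapping an interval.
coding_symbols_in <- function(db, chrom, start, end) {
  g <- db_query(db, chrom, start, end, "genes")
  sort(unique(g$symbol[g$coding]))
}

#' Containment and commonness facts against population CNVs
#'
#' Reports each population variant that passes the commonness test
#' (frequency and cohort-size thresholds for its source kind) and matches
#' the query's dosage, with its containment relation, the fraction of the
#' CNV covered, and the number of protein-coding genes in the CNV that lie
#' outside the variant.
#'
#' @param query A `cnv_query`.
#' @param db An `annotation_db`.
#' @param thresholds See [default_thresholds()].
#' @return Data frame with one row per qualifying variant.
#' @export
common_variant_facts <- function(query, db, thresholds = default_thresholds()) {
  pv <- db_query(db, query, collection = "population_variants")
  empty <- data.frame(variant_id = character(0), containment = character(0),
                      overlap_fraction_of_cnv = numeric(0),
                      extra_protein_genes = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pv) == 0L) return(empty)
  common <- pv$dosage == query$dosage & pv$frequency >= thresholds$min_frequency &
    ifelse(pv$source_kind == "SAMPLE_COUNTED",
           pv$cohort_size >= thresholds$min_samples,
           pv$cohort_size >= thresholds$min_alleles)
  pv <- pv[common, , drop = FALSE]
  if (nrow(pv) == 0L) return(empty)
  cnv_len <- interval_length(query$start, query$end)
  cnv_genes <- coding_symbols_in(db, query$chrom, query$start, query$end)
  out <- lapply(seq_len(nrow(pv)), function(i) {
    within <- pv$start[i] <= query$start && pv$end[i] >= query$end
    frac <- shared_bp(query$start, query$end, pv$start[i], pv$end[i]) / cnv_len
    var_genes <- coding_symbols_in(db, pv$chrom[i], pv$start[i], pv$end[i])
    data.frame(variant_id = pv$variant_id[i],
               containment = if (within) "CNV_WITHIN" else "OVERLAP",
               overlap_fraction_of_cnv = frac,
               extra_protein_genes = length(setdiff(cnv_genes, var_genes)),
               frequency = pv$frequency[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Split transcripts into per-gene loci (by symbol) and pick the transcript
# the effect evaluator would use.
selected_transcripts <- function(genes_df) {
  if (nrow(genes_df) == 0L) return(genes_df[0, , drop = FALSE])
  picked <- lapply(split(seq_len(nrow(genes_df)), genes_df$symbol),
                   function(rows) {
                     tx <- genes_df[rows, , drop = FALSE]
                     select_transcript(tx)
                   })
  out <- do.call(rbind, picked)
  out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
}

#' Annotate a CNV against the database
#'
#' Collects every fact the scoring engine consumes: protein-coding gene
#' content, strand-aware per-gene overlap details (on each gene's selected
#' transcript), overlap taxonomy against curated HI/TS and benign elements
#' (including gene-content identity for benign comparisons), genes passing
#' the predicted-haploinsufficiency thresholds, and containment facts
#' against common population variants.
#'
#' @param query A `cnv_query`.
#' @param db An `annotation_db`.
#' @param thresholds See [default_thresholds()].
#' @return An `annotation_result` object.
#' @export
annotate_cnv <- function(query, db, thresholds = default_thresholds()) {
  genes <- db_query(db, query, collection = "genes")
  coding <- genes[genes$coding, , drop = FALSE]
  sel <- selected_transcripts(coding)
  gene_count <- nrow(sel)
  cnv_gene_set <- sort(unique(coding$symbol))

  dosage <- db_query(db, query, collection = "dosage_regions")
  classify_region <- function(rows) {
    if (nrow(rows) == 0L) return(NULL)
    rel <- vapply(seq_len(nrow(rows)), function(i)
      region_overlap_class(query$start, query$end, rows$start[i],
                           rows$end[i]), character(1))
    cbind(rows, overlap_class = rel, stringsAsFactors = FALSE)
  }
  hi_overlaps <- classify_region(dosage[dosage$kind %in%
                                          c("HI_GENE", "HI_REGION"), ,
                                        drop = FALSE])
  ts_overlaps <- classify_region(dosage[dosage$kind %in%
                                          c("TS_GENE", "TS_REGION"), ,
                                        drop = FALSE])
  benign_overlaps <- classify_region(dosage[dosage$kind %in%
                                              c("BENIGN_LOSS", "BENIGN_GAIN"), ,
                                            drop = FALSE])
  # Benign comparisons also recognise gene-set identity: the protein-coding
  # genes of the CNV equal those of the benign element.
  if (!is.null(benign_overlaps) && nrow(benign_overlaps) > 0L) {
    benign_overlaps$identical_gene_content <-
      vapply(seq_len(nrow(benign_overlaps)), function(i) {
        reg_genes <- coding_symbols_in(db, benign_overlaps$chrom[i],
                                       benign_overlaps$start[i],
                                       benign_overlaps$end[i])
        identical(cnv_gene_set, reg_genes)
      }, logical(1))
    benign_overlaps$overlap_class[benign_overlaps$identical_gene_content &
                                    benign_overlaps$overlap_class !=
                                    "CNV_WITHIN_ELEMENT"] <-
      "IDENTICAL_GENE_CONTENT"
  }

  score_ok <- function(df) !is.null(df) && nrow(df) > 0L &&
    any(!is.na(df$score) & df$score %in% 1:3)
  functionally_important <- score_ok(hi_overlaps) || score_ok(ts_overlaps)

  details <- lapply(seq_len(nrow(sel)), function(i)
    classify_gene_overlap(query, sel[i, , drop = FALSE]))

  predicted_hi <- sel[!is.na(sel$pli) & !is.na(sel$oe_upper) &
                        !is.na(sel$hi_index) &
                        sel$pli >= thresholds$pli_min &
                        sel$oe_upper < thresholds$oe_upper_max &
                        sel$hi_index <= thresholds$hi_index_max, ,
                      drop = FALSE]

  structure(list(query = query,
                 genes = genes,
                 selected_genes = sel,
                 gene_count = gene_count,
                 gene_set = cnv_gene_set,
                 functionally_important = functionally_important,
                 hi_overlaps = hi_overlaps,
                 ts_overlaps = ts_overlaps,
                 benign_overlaps = benign_overlaps,
                 gene_overlap_details = details,
                 predicted_hi_genes = predicted_hi,
                 common_variant_facts = common_variant_facts(query, db,
                                                             thresholds),
                 thresholds = thresholds,
                 build = db$build),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s %s\n", format_cnv(x$query),
              x$query$dosage))
  cat(sprintf("  protein-coding genes: %d; functionally important: %s\n",
              x$gene_count, x$functionally_important))
  cat(sprintf("  HI overlaps: %d; TS overlaps: %d; benign overlaps: %d; common variants: %d\n",
              if (is.null(x$hi_overlaps)) 0L else nrow(x$hi_overlaps),
              if (is.null(x$ts_overlaps)) 0L else nrow(x$ts_overlaps),
              if (is.null(x$benign_overlaps)) 0L else nrow(x$benign_overlaps),
              nrow(x$common_variant_facts)))
  invisible(x)
}
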