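## intragenic effect evaluation: reading-frame, NMD and protein-fraction
## calls for CNVs fully inside an established HI gene, graded as
## PVS1 / PVS1_Strong / PVS1_Moderate.

#' Select the transcript used for effect evaluation
#'
#' For a locus with several transcript models: the transcript flagged
#' canonical wins; failing that, the longest coding sequence; ties broken by
#' the longest transcript span, then lexicographically smallest id.
#'
#' @param transcripts Data frame of transcript rows for one locus.
#' @return The selected one-row data frame.
#' @export
select_transcript <- function(transcripts) {
  if (!is.data.frame(transcripts) || nrow(transcripts) == 0L)
    cnv_abort("select_transcript requires a non-empty transcript set",
              "cnvscore_contract_error")
  cds_len <- vapply(seq_len(nrow(transcripts)), function(i) {
    g <- transcripts[i, , drop = FALSE]
    if (is.na(g$cds_start)) return(0)
    cp <- coding_part(g$exon_starts_list[[1]], g$exon_ends_list[[1]],
                      g$cds_start, g$cds_end)
    sum(cp$ends - cp$starts + 1)
  }, numeric(1))
  span <- transcripts$end - transcripts$start + 1
  o <- order(-as.integer(transcripts$canonical), -cds_len, -span,
             transcripts$gene_id)
  transcripts[o[1], , drop = FALSE]
}

# Map a genomic position to transcription coordinates (1 = transcription
# start of the gene span).
tx_coord <- function(gene, pos) {
  if (gene$strand == "+") pos - gene$start + 1 else gene$end - pos + 1
}

# Gene structure in transcription coordinates: ascending exon intervals.
tx_model <- function(gene) {
  es <- gene$exon_starts_list[[1]]; ee <- gene$exon_ends_list[[1]]
  a <- tx_coord(gene, es); b <- tx_coord(gene, ee)
  starts <- pmin(a, b); ends <- pmax(a, b)
  o <- order(starts)
  list(exon_starts = starts[o], exon_ends = ends[o],
       length = tx_coord(gene, if (gene$strand == "+") gene$end else gene$start))
}

tx_interval <- function(gene, s, e) {
  a <- tx_coord(gene, s); b <- tx_coord(gene, e)
  c(min(a, b), max(a, b))
}

pos_is_exonic <- function(model, p) {
  any(model$exon_starts <= p & model$exon_ends >= p)
}

# Exon pieces intersecting [s, e], as a matrix of (start, end) rows.
exon_pieces <- function(model, s, e) {
  ps <- pmax(model$exon_starts, s); pe <- pmin(model$exon_ends, e)
  keep <- ps <= pe
  cbind(ps[keep], pe[keep])
}

# NMD prediction for a deletion [qs, qe] (transcription coordinates).
# Reconstructs the post-deletion spliced transcript: exon pieces outside the
# deletion, fused where the removed segment made them genomically adjacent.
# The premature termination codon is taken at the deletion junction; NMD is
# predicted iff it lies >= 50 nt upstream of the last exon-exon junction.
nmd_after_deletion <- function(model, qs, qe) {
  pieces <- rbind(exon_pieces(model, 1, qs - 1),
                  exon_pieces(model, qe + 1, model$length))
  if (nrow(pieces) < 2L) return(FALSE)
  pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
  # fuse consecutive pieces whose intervening gap is entirely deleted
  lens <- numeric(0); fused <- pieces[1, 2] - pieces[1, 1] + 1
  for (i in seq_len(nrow(pieces) - 1L)) {
    gap_s <- pieces[i, 2] + 1; gap_e <- pieces[i + 1, 1] - 1
    gap_deleted <- gap_s > gap_e || (gap_s >= qs && gap_e <= qe)
    if (gap_deleted) {
      fused <- fused + pieces[i + 1, 2] - pieces[i + 1, 1] + 1
    } else {
      lens <- c(lens, fused)
      fused <- pieces[i + 1, 2] - pieces[i + 1, 1] + 1
    }
  }
  lens <- c(lens, fused)
  if (length(lens) < 2L) return(FALSE)
  last_junction <- sum(lens[-length(lens)])
  ptc <- sum(shared_bp(1, qs - 1, pieces[, 1], pieces[, 2]))
  (last_junction - ptc) >= 50
}

# NMD prediction for a tandem duplication of [qs, qe]: the new transcript is
# copyA (exonic sequence through qe), the duplicated segment again, then the
# remainder; the PTC is taken at the junction between the two copies.
nmd_after_duplication <- function(model, qs, qe) {
  copyA <- exon_pieces(model, 1, qe)
  copyB <- exon_pieces(model, qs, qe)
  rest <- exon_pieces(model, qe + 1, model$length)
  if (nrow(copyA) == 0L) return(FALSE)
  piece_len <- function(m) if (nrow(m) == 0L) numeric(0)
  else m[, 2] - m[, 1] + 1
  qs_exonic <- pos_is_exonic(model, qs)
  qe_exonic <- pos_is_exonic(model, qe)
  qe1_exonic <- qe < model$length && pos_is_exonic(model, qe + 1)

  # segment lengths with fusion flags at the two copy boundaries
  lens <- piece_len(copyA)
  ab_fused <- qe_exonic && qs_exonic
  lb <- piece_len(copyB)
  if (length(lb)) {
    if (ab_fused && length(lens)) {
      lens[length(lens)] <- lens[length(lens)] + lb[1]
      lb <- lb[-1]
    }
    lens <- c(lens, lb)
  }
  br_fused <- qe_exonic && qe1_exonic
  lr <- piece_len(rest)
  if (length(lr)) {
    if (br_fused && length(lens)) {
      lens[length(lens)] <- lens[length(lens)] + lr[1]
      lr <- lr[-1]
    }
    lens <- c(lens, lr)
  }
  if (length(lens) < 2L) return(FALSE)
  last_junction <- sum(lens[-length(lens)])
  ptc <- sum(piece_len(copyA))
  (last_junction - ptc) >= 50
}

coding_length <- function(gene) {
  if (is.na(gene$cds_start)) return(0)
  cp <- coding_part(gene$exon_starts_list[[1]], gene$exon_ends_list[[1]],
                    gene$cds_start, gene$cds_end)
  sum(cp$ends - cp$starts + 1)
}

effect_call <- function(strength, frame_disrupted, nmd_predicted,
                        fraction_removed, critical_region_hit, lof_frequent,
                        relevant_transcript, tandem_status, rationale) {
  structure(list(strength = strength, frame_disrupted = frame_disrupted,
                 nmd_predicted = nmd_predicted,
                 fraction_protein_removed = fraction_removed,
                 critical_region_hit = critical_region_hit,
                 lof_frequent = lof_frequent,
                 relevant_transcript = relevant_transcript,
                 tandem_status = tandem_status, rationale = rationale),
            class = "effect_call")
}

#' Evaluate an intragenic deletion (loss-of-function grading)
#'
#' For a deletion fully inside a protein-coding gene: computes the deleted
#' coding bases on the selected transcript, reading-frame disruption
#' (deleted coding bases not a multiple of 3), NMD prediction by the 50-nt
#' last-junction rule on the reconstructed transcript, and the fraction of
#' the protein removed; grades the result as `PVS1` (frameshift + NMD on a
#' biologically relevant transcript), `PVS1_STRONG` (curated critical
#' region hit, or >10% of protein removed with function unknown and
#' loss-of-function variation not frequent), `PVS1_MODERATE` (<=10%
#' removed under the same conditions) or `NONE`.
#'
#' @param query A `cnv_query` contained in the gene span.
#' @param gene One-row gene (selected transcript).
#' @param db An `annotation_db` supplying critical regions and known
#'   variants.
#' @param thresholds See [default_thresholds()].
#' @return An `effect_call`.
#' @export
evaluate_deletion <- function(query, gene, db,
                              thresholds = default_thresholds()) {
  if (query$start < gene$start || query$end > gene$end)
    cnv_abort("evaluate_deletion requires the CNV to lie within the gene span",
              "cnvscore_contract_error")
  if (!gene$coding)
    cnv_abort("evaluate_deletion requires a protein-coding gene",
              "cnvscore_contract_error")
  rationale <- character(0)
  del_coding <- coding_bases_hit(query$start, query$end, gene)
  total_cds <- coding_length(gene)
  frame_disrupted <- del_coding %% 3 != 0
  model <- tx_model(gene)
  q_tx <- tx_interval(gene, query$start, query$end)
  nmd <- frame_disrupted && nmd_after_deletion(model, q_tx[1], q_tx[2])
  fraction <- if (total_cds > 0) del_coding / total_cds else 0

  crit <- db_query(db, query, collection = "critical_regions")
  critical_hit <- any(crit$gene_id == gene$gene_id)

  kv <- db_query(db, query, collection = "known_variants")
  lof_frequent <- any(kv$significance %in% c("PATHOGENIC",
                                             "LIKELY_PATHOGENIC") &
                        kv$allele_frequency >= thresholds$lof_frequent_af)
  relevant <- isTRUE(gene$relevant)

  rationale <- c(rationale,
                 sprintf("%d coding bp deleted (%.1f%% of CDS); frame %s",
                         del_coding, 100 * fraction,
                         if (frame_disrupted) "disrupted" else "preserved"),
                 sprintf("NMD %spredicted", if (nmd) "" else "not "))
  strength <- if (frame_disrupted && nmd && relevant) {
    rationale <- c(rationale, "frameshift with NMD on relevant transcript: PVS1")
    "PVS1"
  } else if (critical_hit) {
    rationale <- c(rationale, "curated critical region altered: PVS1_Strong")
    "PVS1_STRONG"
  } else if (!lof_frequent && relevant && total_cds > 0 && del_coding > 0) {
    if (fraction > 0.10) {
      rationale <- c(rationale, ">10% of protein removed: PVS1_Strong")
      "PVS1_STRONG"
    } else {
      rationale <- c(rationale, "<=10% of protein removed: PVS1_Moderate")
      "PVS1_MODERATE"
    }
  } else {
    rationale <- c(rationale, "no loss-of-function evidence applicable")
    "NONE"
  }
  effect_call(strength, frame_disrupted, nmd, fraction, critical_hit,
              lof_frequent, relevant, "UNKNOWN", rationale)
}

#' Evaluate an intragenic duplication (tandem loss-of-function grading)
#'
#' Assuming a tandem insertion of the duplicated segment, computes the
#' duplicated coding bases on the selected transcript, frame disruption and
#' NMD (50-nt rule on the reconstructed tandem transcript, premature stop
#' taken at the junction between the two copies). A frame-disrupting,
#' NMD-predicted duplication grades `PVS1` when tandem status is proven and
#' `PVS1_STRONG` when assumed; any other situation (including unknown
#' tandem status) grades `NONE` and defers to manual review.
#'
#' @param query A `cnv_query` contained in the gene span.
#' @param gene One-row gene (selected transcript).
#' @param tandem_status `"PROVEN"`, `"ASSUMED"` or `"UNKNOWN"`.
#' @return An `effect_call`.
#' @export
evaluate_duplication <- function(query, gene,
                                 tandem_status = c("UNKNOWN", "PROVEN",
                                                   "ASSUMED")) {
  tandem_status <- match.arg(toupper(tandem_status),
                             c("UNKNOWN", "PROVEN", "ASSUMED"))
  if (query$start < gene$start || query$end > gene$end)
    cnv_abort("evaluate_duplication requires the CNV to lie within the gene span",
              "cnvscore_contract_error")
  dup_coding <- coding_bases_hit(query$start, query$end, gene)
  frame_disrupted <- dup_coding %% 3 != 0
  model <- tx_model(gene)
  q_tx <- tx_interval(gene, query$start, query$end)
  nmd <- frame_disrupted && nmd_after_duplication(model, q_tx[1], q_tx[2])
  rationale <- c(sprintf("%d coding bp duplicated; frame %s", dup_coding,
                         if (frame_disrupted) "disrupted" else "preserved"),
                 sprintf("NMD %spredicted (tandem %s)",
                         if (nmd) "" else "not ", tolower(tandem_status)))
  strength <- if (frame_disrupted && nmd && tandem_status == "PROVEN") {
    "PVS1"
  } else if (frame_disrupted && nmd && tandem_status == "ASSUMED") {
    "PVS1_STRONG"
  } else "NONE"
  effect_call(strength, frame_disrupted, nmd, 0, FALSE, FALSE,
              isTRUE(gene$relevant), tandem_status, rationale)
}
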