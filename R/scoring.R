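## scoring engine: the automated parts of the copy-number-loss and
## copy-number-gain decision trees, producing evidence items.

#' Construct an evidence item row
#'
#' @param category Metric category id (e.g. `"2C-1"`).
#' @param points Points carried by the item.
#' @param range_min,range_max Permissible range for the category.
#' @param source `"AUTOMATED"` or `"MANUAL"`.
#' @param contributes Whether the item counts toward the total (the
#'   2-series follows a single-winner rule: all candidates are recorded but
#'   only the highest-scoring one contributes).
#' @param rationale Human-readable justification.
#' @param element_refs Semicolon-joined ids of supporting records.
#' @return One-row data frame.
#' @export
evidence_item <- function(category, points, range_min, range_max,
                          source = "AUTOMATED", contributes = TRUE,
                          rationale = "", element_refs = "") {
  if (points < range_min - 1e-9 || points > range_max + 1e-9)
    cnv_abort(sprintf("points %.2f for %s outside configured range [%.2f, %.2f]",
                      points, category, range_min, range_max),
              "cnvscore_validation_error")
  data.frame(category = category, points = points, range_min = range_min,
             range_max = range_max, source = source, contributes = contributes,
             rationale = rationale, element_refs = element_refs,
             stringsAsFactors = FALSE)
}

empty_items <- function() {
  data.frame(category = character(0), points = numeric(0),
             range_min = numeric(0), range_max = numeric(0),
             source = character(0), contributes = logical(0),
             rationale = character(0), element_refs = character(0),
             stringsAsFactors = FALSE)
}

cfg_item <- function(cfg, dosage, category, points = NULL, contributes = TRUE,
                     rationale = NULL, element_refs = "") {
  row <- metric_row(cfg, dosage, category)
  evidence_item(category = category,
                points = points %||% row$default,
                range_min = row$min, range_max = row$max,
                contributes = contributes,
                rationale = rationale %||% row$description,
                element_refs = element_refs)
}

#' Score Section 1: initial assessment of genomic content
#'
#' Category 1A (0 points) when the CNV contains protein-coding genes or
#' known functionally important elements (curated elements with dosage
#' score 1-3); otherwise 1B (-0.60).
#'
#' @param ann An `annotation_result`.
#' @param cfg A `metric_config`.
#' @return One-row evidence data frame.
#' @export
score_section1 <- function(ann, cfg = load_metric_config()) {
  dosage <- ann$query$dosage
  if (ann$gene_count > 0L || ann$functionally_important) {
    cfg_item(cfg, dosage, "1A",
             rationale = sprintf("contains %d protein-coding gene(s)%s",
                                 ann$gene_count,
                                 if (ann$functionally_important)
                                   " and functionally important element(s)"
                                 else ""))
  } else {
    cfg_item(cfg, dosage, "1B",
             rationale = "no protein-coding genes or functionally important elements")
  }
}

established_rows <- function(df, thresholds) {
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  out <- df[!is.na(df$score) & df$score >= thresholds$min_established_score &
              df$score <= 3, , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}

detail_for_gene <- function(ann, gene_id) {
  for (d in ann$gene_overlap_details)
    if (d$gene_id == gene_id) return(d)
  # the dosage record may reference a non-selected transcript of the locus
  sym <- ann$genes$symbol[ann$genes$gene_id == gene_id]
  if (length(sym)) for (d in ann$gene_overlap_details)
    if (d$symbol == sym[1]) return(d)
  NULL
}

gene_row <- function(ann, gene_id) {
  i <- which(ann$selected_genes$gene_id == gene_id)
  if (!length(i)) {
    sym <- ann$genes$symbol[ann$genes$gene_id == gene_id]
    if (length(sym)) i <- which(ann$selected_genes$symbol == sym[1])
  }
  if (!length(i)) return(NULL)
  ann$selected_genes[i[1], , drop = FALSE]
}

# Resolve the 2-series single-winner rule. All candidates are recorded;
# only the highest-points item contributes. A terminal-benign candidate
# (final -1, evaluation stops) wins only when no positive candidate fired;
# otherwise it is kept as a flagged conflict.
finalize_section2 <- function(candidates, terminal_categories) {
  if (nrow(candidates) == 0L)
    return(list(items = candidates, terminal = FALSE, conflicts = character(0)))
  candidates$contributes <- FALSE
  conflicts <- character(0)
  is_terminal_cand <- candidates$category %in% terminal_categories
  has_positive <- any(candidates$points > 0)
  if (any(is_terminal_cand) && !has_positive) {
    winner <- which(is_terminal_cand)[1]
    terminal <- TRUE
  } else {
    o <- order(-candidates$points, candidates$category)
    winner <- o[1]
    terminal <- FALSE
    if (any(is_terminal_cand)) {
      conflicts <- sprintf(
        "benign evidence (%s) co-fired with positive dosage evidence (%s); benign short-circuit suppressed",
        paste(candidates$category[is_terminal_cand], collapse = ","),
        candidates$category[winner])
      candidates$rationale[is_terminal_cand] <-
        paste0(candidates$rationale[is_terminal_cand],
               " [conflict: positive evidence present; not applied]")
    }
  }
  candidates$contributes[winner] <- TRUE
  list(items = candidates, terminal = terminal, conflicts = conflicts)
}

last_exon_has_pathogenic_variant <- function(ann, db, gene, thresholds) {
  tx <- exons_tx_order(gene)
  n <- length(tx$starts)
  kv <- db_query(db, gene$chrom, tx$starts[n], tx$ends[n], "known_variants")
  if (nrow(kv) == 0L) return(FALSE)
  any(kv$significance %in% c("PATHOGENIC", "LIKELY_PATHOGENIC") &
        kv$allele_frequency < thresholds$pathogenic_af_max)
}

#' Score Section 2 for a copy-number loss
#'
#' Walks the loss decision tree: complete overlap of established HI
#' genes/regions (2A), partial HI-region overlap without HI genes (2B),
#' partial 5'-end gene overlap with/without coding sequence (2C-1/2C-2),
#' 3'-end overlaps by exon content and known pathogenic variants
#' (2D-1..2D-4), intragenic deletions graded by the loss-of-function
#' evaluator (2E), predicted-HI genes when no established element is hit
#' (2H), and established benign relations (2F terminal, 2G). All firing
#' categories are recorded; only the highest-scoring one contributes.
#'
#' @param ann An `annotation_result` for a LOSS query.
#' @param db An `annotation_db`.
#' @param cfg A `metric_config`.
#' @param thresholds See [default_thresholds()].
#' @return List with `items` (evidence data frame), `terminal` (benign
#'   short-circuit fired) and `conflicts`.
#' @export
score_section2_loss <- function(ann, db, cfg = load_metric_config(),
                                thresholds = default_thresholds()) {
  stopifnot(ann$query$dosage == "LOSS")
  cand <- empty_items()
  add <- function(items, ...) rbind(items, cfg_item(cfg, "LOSS", ...))

  est <- established_rows(ann$hi_overlaps, thresholds)
  est_genes <- if (!is.null(est)) est[est$kind == "HI_GENE", , drop = FALSE]
  else NULL
  est_regions <- if (!is.null(est)) est[est$kind == "HI_REGION", , drop = FALSE]
  else NULL
  n_est <- if (is.null(est)) 0L else nrow(est)

  # (i) established HI elements
  if (n_est > 0L) {
    contained <- est$overlap_class == "CNV_CONTAINS_ELEMENT"
    if (any(contained))
      cand <- add(cand, "2A",
                  rationale = "completely spans established HI gene(s)/region(s)",
                  element_refs = paste(est$region_id[contained],
                                       collapse = ";"))
    # region overlap without involvement of established HI genes
    if (!is.null(est_regions) && nrow(est_regions) > 0L) {
      partial_regions <- est_regions[est_regions$overlap_class !=
                                       "CNV_CONTAINS_ELEMENT", , drop = FALSE]
      if (nrow(partial_regions) > 0L &&
          (is.null(est_genes) || nrow(est_genes) == 0L))
        cand <- add(cand, "2B",
                    rationale = "partial overlap of established HI region; no established HI gene involved",
                    element_refs = paste(partial_regions$region_id,
                                         collapse = ";"))
    }
    # per-gene branches for partially overlapped / containing HI genes
    if (!is.null(est_genes) && nrow(est_genes) > 0L) {
      for (i in seq_len(nrow(est_genes))) {
        gid <- est_genes$gene_id[i]
        det <- detail_for_gene(ann, gid)
        g <- gene_row(ann, gid)
        if (is.null(det) || is.null(g)) next
        ref <- est_genes$region_id[i]
        if (det$relation == "PARTIAL_5PRIME") {
          if (det$coding_sequence_involved)
            cand <- add(cand, "2C-1",
                        rationale = sprintf("5' overlap of HI gene %s involving coding sequence",
                                            g$symbol),
                        element_refs = ref)
          else
            cand <- add(cand, "2C-2",
                        rationale = sprintf("5' overlap of HI gene %s without coding sequence",
                                            g$symbol),
                        element_refs = ref)
        } else if (det$relation == "PARTIAL_3PRIME") {
          if (det$only_3prime_utr)
            cand <- add(cand, "2D-1",
                        rationale = sprintf("3' overlap of HI gene %s restricted to the 3' UTR (assumed 0-point branch)",
                                            g$symbol),
                        element_refs = ref)
          else if (det$only_last_exon) {
            if (last_exon_has_pathogenic_variant(ann, db, g, thresholds))
              cand <- add(cand, "2D-2",
                          rationale = sprintf("only last exon of HI gene %s deleted; established pathogenic variants in that exon",
                                              g$symbol),
                          element_refs = ref)
            else
              cand <- add(cand, "2D-3",
                          rationale = sprintf("only last exon of HI gene %s deleted; no established pathogenic variants",
                                              g$symbol),
                          element_refs = ref)
          } else
            cand <- add(cand, "2D-4",
                        rationale = sprintf("3' overlap of HI gene %s involving the last and other exons",
                                            g$symbol),
                        element_refs = ref)
        } else if (det$relation == "CNV_WITHIN_ELEMENT") {
          eff <- evaluate_deletion(ann$query, g, db, thresholds)
          pts <- pvs1_points("LOSS", eff$strength)
          cand <- rbind(cand, evidence_item(
            category = "2E", points = pts$points,
            range_min = pts$range_min, range_max = pts$range_max,
            rationale = sprintf("intragenic deletion in HI gene %s: %s (%s)",
                                g$symbol, eff$strength,
                                paste(eff$rationale, collapse = "; ")),
            element_refs = ref))
        }
      }
    }
  }

  # (ii) predicted HI genes, only when nothing established was hit
  if (n_est == 0L && nrow(ann$predicted_hi_genes) > 0L)
    cand <- add(cand, "2H",
                rationale = sprintf("gene(s) meeting predicted-HI thresholds: %s",
                                    paste(ann$predicted_hi_genes$symbol,
                                          collapse = ", ")),
                element_refs = paste(ann$predicted_hi_genes$gene_id,
                                     collapse = ";"))

  # (iii) established benign relations
  ben <- ann$benign_overlaps
  ben <- if (is.null(ben)) NULL else ben[ben$kind == "BENIGN_LOSS", ,
                                         drop = FALSE]
  if (!is.null(ben) && nrow(ben) > 0L) {
    benign_hit <- ben$overlap_class == "CNV_WITHIN_ELEMENT" |
      ben$identical_gene_content
    if (any(benign_hit))
      cand <- add(cand, "2F",
                  rationale = "within an established benign region / identical protein-coding gene content",
                  element_refs = paste(ben$region_id[benign_hit],
                                       collapse = ";"))
    if (any(!benign_hit))
      cand <- add(cand, "2G",
                  rationale = "overlaps established benign region but includes additional genomic material",
                  element_refs = paste(ben$region_id[!benign_hit],
                                       collapse = ";"))
  }

  finalize_section2(cand, terminal_categories = "2F")
}

#' Score Section 2 for a copy-number gain
#'
#' Walks the gain decision tree: complete overlap of established TS
#' genes/regions (2A), partial TS-region overlap (2B), benign-gain
#' relations (2C identical gene content, 2D contained without interrupted
#' genes, 2E contained with potentially interrupted genes, 2F larger
#' without additional protein-coding genes, 2G additional material), HI
#' genes fully contained (2H), intragenic duplications graded by the tandem
#' loss-of-function evaluator (2I), partial HI-gene overlaps deferred to
#' manual review (2J/2K), and genes of no established significance (2L).
#'
#' @param ann An `annotation_result` for a GAIN query.
#' @param db An `annotation_db`.
#' @param cfg A `metric_config`.
#' @param tandem_status `"PROVEN"`, `"ASSUMED"` or `"UNKNOWN"`.
#' @param thresholds See [default_thresholds()].
#' @return List with `items`, `terminal`, `conflicts`.
#' @export
score_section2_gain <- function(ann, db, cfg = load_metric_config(),
                                tandem_status = "UNKNOWN",
                                thresholds = default_thresholds()) {
  stopifnot(ann$query$dosage == "GAIN")
  cand <- empty_items()
  add <- function(items, ...) rbind(items, cfg_item(cfg, "GAIN", ...))

  # does any protein-coding gene have a CNV breakpoint inside it?
  interrupts <- any(vapply(ann$gene_overlap_details, function(d)
    d$relation %in% c("PARTIAL_5PRIME", "PARTIAL_3PRIME",
                      "CNV_WITHIN_ELEMENT"), logical(1)))

  # (i) established TS elements
  ts <- established_rows(ann$ts_overlaps, thresholds)
  if (!is.null(ts) && nrow(ts) > 0L) {
    contained <- ts$overlap_class == "CNV_CONTAINS_ELEMENT"
    if (any(contained))
      cand <- add(cand, "2A",
                  rationale = "completely spans established TS gene(s)/region(s)",
                  element_refs = paste(ts$region_id[contained],
                                       collapse = ";"))
    if (any(!contained & ts$kind == "TS_REGION"))
      cand <- add(cand, "2B",
                  rationale = "partial overlap of established TS region",
                  element_refs = paste(ts$region_id[!contained &
                                                      ts$kind == "TS_REGION"],
                                       collapse = ";"))
  }

  # (ii) established benign gain relations
  ben <- ann$benign_overlaps
  ben <- if (is.null(ben)) NULL else ben[ben$kind == "BENIGN_GAIN", ,
                                         drop = FALSE]
  if (!is.null(ben) && nrow(ben) > 0L) {
    for (i in seq_len(nrow(ben))) {
      ref <- ben$region_id[i]
      reg_genes <- coding_symbols_in(db, ben$chrom[i], ben$start[i],
                                     ben$end[i])
      extra_genes <- setdiff(ann$gene_set, reg_genes)
      if (ben$identical_gene_content[i]) {
        cand <- add(cand, "2C",
                    rationale = "identical protein-coding gene content to an established benign gain",
                    element_refs = ref)
      } else if (ben$overlap_class[i] == "CNV_WITHIN_ELEMENT") {
        if (interrupts)
          cand <- add(cand, "2E",
                      rationale = "within an established benign gain but potentially interrupts protein-coding gene(s)",
                      element_refs = ref)
        else
          cand <- add(cand, "2D",
                      rationale = "within an established benign gain; no protein-coding gene interrupted",
                      element_refs = ref)
      } else if (ben$overlap_class[i] == "CNV_CONTAINS_ELEMENT") {
        if (length(extra_genes) == 0L)
          cand <- add(cand, "2F",
                      rationale = "larger than an established benign gain without additional protein-coding genes",
                      element_refs = ref)
        else
          cand <- add(cand, "2G",
                      rationale = "overlaps an established benign gain with additional genomic material",
                      element_refs = ref)
      } else {
        # partial overlap: 2E'/2F' scenarios map onto 2E/2F; additional
        # protein-coding genes map onto 2G
        if (length(extra_genes) > 0L)
          cand <- add(cand, "2G",
                      rationale = "overlaps an established benign gain with additional genomic material",
                      element_refs = ref)
        else if (interrupts)
          cand <- add(cand, "2E",
                      rationale = "partial benign-gain overlap potentially interrupting protein-coding gene(s)",
                      element_refs = ref)
        else
          cand <- add(cand, "2F",
                      rationale = "partial benign-gain overlap without additional or interrupted protein-coding genes",
                      element_refs = ref)
      }
    }
  }

  # (iii) established HI genes under a duplication
  hi <- established_rows(ann$hi_overlaps, thresholds)
  hi_genes <- if (!is.null(hi)) hi[hi$kind == "HI_GENE", , drop = FALSE]
  else NULL
  if (!is.null(hi_genes) && nrow(hi_genes) > 0L) {
    for (i in seq_len(nrow(hi_genes))) {
      gid <- hi_genes$gene_id[i]
      det <- detail_for_gene(ann, gid)
      g <- gene_row(ann, gid)
      if (is.null(det) || is.null(g)) next
      ref <- hi_genes$region_id[i]
      if (det$relation == "CNV_CONTAINS_ELEMENT") {
        cand <- add(cand, "2H",
                    rationale = sprintf("HI gene %s fully contained within the gain",
                                        g$symbol),
                    element_refs = ref)
      } else if (det$relation == "CNV_WITHIN_ELEMENT") {
        eff <- evaluate_duplication(ann$query, g, tandem_status)
        pts <- pvs1_points("GAIN", eff$strength)
        cand <- rbind(cand, evidence_item(
          category = "2I", points = pts$points,
          range_min = pts$range_min, range_max = pts$range_max,
          rationale = sprintf("intragenic duplication in HI gene %s: %s (%s)",
                              g$symbol, eff$strength,
                              paste(eff$rationale, collapse = "; ")),
          element_refs = ref))
      } else {
        cand <- add(cand, "2J",
                    rationale = sprintf("one breakpoint within HI gene %s: phenotype-dependent, manual review required (2J/2K)",
                                        g$symbol),
                    element_refs = ref)
      }
    }
  }

  # (iv) genes with no established dosage curation
  if (nrow(cand) == 0L && ann$gene_count > 0L)
    cand <- add(cand, "2L",
                rationale = "overlaps gene(s) without established ClinGen dosage curation; 0 assigned, literature evidence (Section 4) may apply")

  finalize_section2(cand, terminal_categories = c("2C", "2D"))
}

#' Score Section 3: protein-coding gene number
#'
#' Loss: 0-24 genes 3A (0), 25-34 genes 3B (0.45), >=35 genes 3C (0.9).
#' Gain: 0-34 genes 3A (0), 35-49 genes 3B (0.45), >=50 genes 3C (0.9).
#'
#' @param ann An `annotation_result` (or an integer gene count).
#' @param dosage Required when `ann` is a bare count.
#' @param cfg A `metric_config`.
#' @return One-row evidence data frame.
#' @export
score_section3 <- function(ann, dosage = NULL, cfg = load_metric_config()) {
  if (inherits(ann, "annotation_result")) {
    n <- ann$gene_count; dosage <- ann$query$dosage
  } else {
    n <- as.integer(ann)
    if (is.null(dosage)) cnv_abort("dosage required with a bare gene count")
  }
  bands <- if (dosage == "LOSS") c(b = 25, c = 35) else c(b = 35, c = 50)
  category <- if (n >= bands["c"]) "3C" else if (n >= bands["b"]) "3B" else "3A"
  cfg_item(cfg, dosage, category,
           rationale = sprintf("%d protein-coding gene(s)", n))
}

#' Score category 4O: overlap with common population variation
#'
#' Fires (-1) when the CNV is completely within a common variant of the
#' same dosage, or when a same-dosage common variant covers >= 50% of the
#' CNV and the CNV contains no protein-coding genes outside that variant.
#' Returns `NULL` when 4O cannot be used.
#'
#' @param ann An `annotation_result` (with `common_variant_facts`).
#' @param cfg A `metric_config`.
#' @return One-row evidence data frame, or `NULL`.
#' @export
score_section4_auto <- function(ann, cfg = load_metric_config()) {
  facts <- ann$common_variant_facts
  if (is.null(facts) || nrow(facts) == 0L) return(NULL)
  dosage <- ann$query$dosage
  within <- facts$containment == "CNV_WITHIN"
  if (any(within))
    return(cfg_item(cfg, dosage, "4O",
                    rationale = sprintf("completely within common population variant %s (frequency %.2f%%)",
                                        facts$variant_id[which(within)[1]],
                                        100 * facts$frequency[which(within)[1]]),
                    element_refs = paste(facts$variant_id[within],
                                         collapse = ";")))
  half <- facts$extra_protein_genes == 0L &
    facts$overlap_fraction_of_cnv >= 0.5
  if (any(half))
    return(cfg_item(cfg, dosage, "4O",
                    rationale = sprintf("common variant %s covers %.0f%% of the CNV with no additional protein-coding genes",
                                        facts$variant_id[which(half)[1]],
                                        100 * facts$overlap_fraction_of_cnv[which(half)[1]]),
                    element_refs = paste(facts$variant_id[half],
                                         collapse = ";")))
  NULL
}
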