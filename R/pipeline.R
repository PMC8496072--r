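## end-to-end pipeline: annotate -> automated scoring -> manual merge ->
## classification, for single queries and batches.

#' Read a manual-evidence file
#'
#' Accepts a JSON array of `{category, points, note}` objects or a TSV with
#' columns `category`, `points` and optional `note`.
#'
#' @param path File path.
#' @return Data frame with columns `category`, `points`, `note`.
#' @export
read_manual_evidence <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path)
  } else {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (!all(c("category", "points") %in% names(m)))
    cnv_abort(sprintf("%s: manual evidence needs 'category' and 'points' columns",
                      basename(path)),
              "cnvscore_schema_error")
  if (!"note" %in% names(m)) m$note <- ""
  m$points <- as.numeric(m$points)
  m
}

#' Score a single CNV end to end
#'
#' Annotates the query, runs the automated sections (1, 2, 3 and 4O) of the
#' dosage-appropriate decision tree, merges validated manual evidence, and
#' returns the classified scorecard. When a terminal benign category fires
#' (loss 2F; gain 2C/2D with no positive dosage evidence) evaluation stops
#' with a final total of exactly -1.0.
#'
#' @param query A `cnv_query` (or coordinate string, parsed with `dosage`).
#' @param db An `annotation_db`.
#' @param dosage Used only when `query` is a coordinate string.
#' @param manual Optional manual evidence (data frame or path).
#' @param tandem_status Tandem status for intragenic duplications:
#'   `"PROVEN"`, `"ASSUMED"` or `"UNKNOWN"`.
#' @param cfg A `metric_config`.
#' @param thresholds See [default_thresholds()].
#' @param strict Enforce 0.05-step manual adjustments.
#' @return A `scorecard`.
#' @examples
#' dir <- tempfile()
#' generate_fixture_db(dir)
#' db <- load_database(dir)
#' card <- score_cnv(parse_cnv("chr22:18,761,827-20,307,561", "LOSS"), db)
#' card$auto_total
#' @export
score_cnv <- function(query, db, dosage = NULL, manual = NULL,
                      tandem_status = "UNKNOWN",
                      cfg = load_metric_config(),
                      thresholds = default_thresholds(), strict = TRUE) {
  if (is.character(query)) query <- parse_cnv(query, dosage)
  stopifnot(inherits(query, "cnv_query"), inherits(db, "annotation_db"))
  if (is.character(manual)) manual <- read_manual_evidence(manual)

  ann <- annotate_cnv(query, db, thresholds)
  items <- score_section1(ann, cfg)
  sec2 <- if (query$dosage == "LOSS")
    score_section2_loss(ann, db, cfg, thresholds)
  else
    score_section2_gain(ann, db, cfg, tandem_status, thresholds)
  items <- rbind(items, sec2$items)
  conflicts <- sec2$conflicts
  # terminal benign short-circuit: the benign category alone carries the
  # final -1; earlier sections stay in the report but do not contribute
  if (sec2$terminal) items$contributes[1] <- FALSE

  if (!sec2$terminal) {
    items <- rbind(items, score_section3(ann, cfg = cfg))
    item4 <- score_section4_auto(ann, cfg)
    if (!is.null(item4)) {
      items <- rbind(items, item4)
      sec2_positive <- any(sec2$items$points > 0 & sec2$items$contributes)
      if (sec2_positive)
        conflicts <- c(conflicts,
                       "common-variant evidence (4O) fired alongside positive Section-2 evidence")
    }
    items <- merge_manual(items, manual, cfg, query$dosage, strict)
  }

  build_scorecard(query, items, terminal = sec2$terminal,
                  conflicts = conflicts, build = db$build)
}

#' Score a batch of CNVs
#'
#' Input columns: `label`, `coordinate` (`chrom:start-end`), `dosage`
#' (`LOSS`/`GAIN`), optional `tandem` (`proven`/`assumed`/`unknown`).
#' Row-level failures are reported in the `status` column without aborting
#' the batch; input order is preserved.
#'
#' @param input Path to a TSV or a data frame.
#' @param db An `annotation_db`.
#' @param cfg,thresholds,strict As in [score_cnv()].
#' @param manual_dir Optional directory of per-label manual-evidence files
#'   (`<label>.tsv` or `<label>.json`).
#' @param out Optional path for the result TSV.
#' @return Data frame, one row per input row.
#' @export
score_batch <- function(input, db, cfg = load_metric_config(),
                        thresholds = default_thresholds(), strict = TRUE,
                        manual_dir = NULL, out = NULL) {
  suite <- if (is.character(input))
    utils::read.delim(input, stringsAsFactors = FALSE)
  else input
  if (!all(c("coordinate", "dosage") %in% names(suite)))
    cnv_abort("batch input needs 'coordinate' and 'dosage' columns",
              "cnvscore_schema_error")
  if (!"label" %in% names(suite))
    suite$label <- sprintf("cnv_%d", seq_len(nrow(suite)))
  if (!"tandem" %in% names(suite)) suite$tandem <- "unknown"

  rows <- lapply(seq_len(nrow(suite)), function(i) {
    tryCatch({
      q <- parse_cnv(suite$coordinate[i], suite$dosage[i],
                     label = suite$label[i])
      manual <- NULL
      if (!is.null(manual_dir)) {
        for (ext in c("tsv", "json")) {
          p <- file.path(manual_dir, paste0(suite$label[i], ".", ext))
          if (file.exists(p)) { manual <- read_manual_evidence(p); break }
        }
      }
      card <- score_cnv(q, db, manual = manual,
                        tandem_status = toupper(suite$tandem[i]),
                        cfg = cfg, thresholds = thresholds, strict = strict)
      tsv_row(card)
    }, cnvscore_parse_error = function(e) batch_error_row(suite$label[i],
                                                          "parse_error"),
       error = function(e) batch_error_row(suite$label[i],
                                           paste0("error: ",
                                                  conditionMessage(e))))
  })
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}

batch_error_row <- function(label, status) {
  data.frame(label = label, chrom = NA_character_, start = NA_real_,
             end = NA_real_, dosage = NA_character_, auto_total = NA_real_,
             final_total = NA_real_, pre_class = NA_character_,
             final_class = NA_character_, categories = "", flags = "",
             status = status, stringsAsFactors = FALSE)
}
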