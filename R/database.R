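## annotation database: load, validate and interval-index the six local
## annotation tables, and answer >=1 bp overlap queries.

DB_FILES <- list(
  genes = list(file = "genes.tsv", required = TRUE,
               cols = c("gene_id", "symbol", "chrom", "start", "end",
                        "strand", "cds_start", "cds_end", "exon_starts",
                        "exon_ends", "coding", "canonical", "pli", "oe_upper",
                        "hi_index", "relevant")),
  dosage_regions = list(file = "dosage.tsv", required = TRUE,
                        cols = c("region_id", "chrom", "start", "end", "kind",
                                 "score", "gene_id")),
  population_variants = list(file = "popvar.tsv", required = FALSE,
                             cols = c("variant_id", "chrom", "start", "end",
                                      "dosage", "frequency", "cohort_size",
                                      "source_kind")),
  known_variants = list(file = "variants.tsv", required = FALSE,
                        cols = c("chrom", "start", "end", "gene_id",
                                 "significance", "allele_frequency")),
  critical_regions = list(file = "critical.tsv", required = FALSE,
                          cols = c("gene_id", "chrom", "start", "end", "note"))
)

DOSAGE_KINDS <- c("HI_GENE", "HI_REGION", "TS_GENE", "TS_REGION",
                  "BENIGN_LOSS", "BENIGN_GAIN")

read_db_table <- function(directory, spec_entry) {
  path <- file.path(directory, spec_entry$file)
  if (!file.exists(path)) {
    if (spec_entry$required)
      cnv_abort(sprintf("required database file missing: %s", path),
                "cnvscore_schema_error")
    message(sprintf("note: optional database file %s absent; collection left empty",
                    spec_entry$file))
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(spec_entry$cols)), spec_entry$cols))
    return(df)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(spec_entry$cols, names(df))
  if (length(missing_cols))
    cnv_abort(sprintf("%s: missing required column(s): %s", spec_entry$file,
                      paste(missing_cols, collapse = ", ")),
              "cnvscore_schema_error")
  df
}

row_error <- function(file, i, msg) {
  # +1 for the header row so the number matches the text file line.
  cnv_abort(sprintf("%s line %d: %s", file, i + 1L, msg),
            "cnvscore_validation_error")
}

parse_int_list <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

validate_genes <- function(df) {
  if (nrow(df) == 0L) {
    df$exon_starts_list <- list(); df$exon_ends_list <- list()
    return(df)
  }
  df$chrom <- normalize_chrom(df$chrom)
  for (col in c("start", "end", "cds_start", "cds_end", "pli", "oe_upper",
                "hi_index"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in c("coding", "canonical", "relevant"))
    df[[col]] <- as.integer(df[[col]]) == 1L
  df$exon_starts_list <- lapply(df$exon_starts, parse_int_list)
  df$exon_ends_list <- lapply(df$exon_ends, parse_int_list)
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts_list[[i]]; ee <- df$exon_ends_list[[i]]
    if (is.na(df$start[i]) || is.na(df$end[i]) || df$start[i] > df$end[i])
      row_error("genes.tsv", i, "invalid transcript span")
    if (!df$strand[i] %in% c("+", "-"))
      row_error("genes.tsv", i, sprintf("invalid strand '%s'", df$strand[i]))
    if (length(es) != length(ee) || length(es) == 0L)
      row_error("genes.tsv", i, "exon_starts/exon_ends length mismatch")
    if (any(es > ee))
      row_error("genes.tsv", i, "exon start > exon end")
    if (any(es < df$start[i]) || any(ee > df$end[i]))
      row_error("genes.tsv", i, "exon outside transcript span")
    o <- order(es)
    if (length(es) > 1L && any(es[o][-1] <= ee[o][-length(ee)]))
      row_error("genes.tsv", i, "overlapping exons")
    if (!is.na(df$cds_start[i]) &&
        (df$cds_start[i] < df$start[i] || df$cds_end[i] > df$end[i] ||
         df$cds_start[i] > df$cds_end[i]))
      row_error("genes.tsv", i, "CDS bounds outside transcript span")
    if (!is.na(df$pli[i]) && (df$pli[i] < 0 || df$pli[i] > 1))
      row_error("genes.tsv", i, "pli outside [0,1]")
    if (!is.na(df$hi_index[i]) && (df$hi_index[i] < 0 || df$hi_index[i] > 100))
      row_error("genes.tsv", i, "hi_index outside [0,100]")
  }
  df
}

validate_dosage <- function(df) {
  if (nrow(df) == 0L) return(df)
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$score <- suppressWarnings(as.numeric(df$score))
  for (i in seq_len(nrow(df))) {
    if (!df$kind[i] %in% DOSAGE_KINDS)
      row_error("dosage.tsv", i, sprintf("unknown kind '%s'", df$kind[i]))
    if (is.na(df$start[i]) || df$start[i] > df$end[i])
      row_error("dosage.tsv", i, "invalid interval")
    if (grepl("^(HI|TS)_", df$kind[i])) {
      if (is.na(df$score[i]) || !df$score[i] %in% c(0, 1, 2, 3, 30, 40))
        row_error("dosage.tsv", i,
                  "HI/TS entries require a dosage score in {0,1,2,3,30,40}")
    }
  }
  df
}

validate_popvar <- function(df) {
  if (nrow(df) == 0L) return(df)
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$frequency <- as.numeric(df$frequency)
  df$cohort_size <- as.numeric(df$cohort_size)
  for (i in seq_len(nrow(df))) {
    if (!df$dosage[i] %in% c("LOSS", "GAIN"))
      row_error("popvar.tsv", i, sprintf("invalid dosage '%s'", df$dosage[i]))
    if (!df$source_kind[i] %in% c("SAMPLE_COUNTED", "ALLELE_COUNTED"))
      row_error("popvar.tsv", i,
                sprintf("invalid source_kind '%s'", df$source_kind[i]))
    if (is.na(df$frequency[i]) || df$frequency[i] < 0 || df$frequency[i] > 1)
      row_error("popvar.tsv", i, "frequency outside [0,1]")
    if (is.na(df$cohort_size[i]) || df$cohort_size[i] < 0)
      row_error("popvar.tsv", i, "negative cohort_size")
    if (is.na(df$start[i]) || df$start[i] > df$end[i])
      row_error("popvar.tsv", i, "invalid interval")
  }
  df
}

validate_variants <- function(df) {
  if (nrow(df) == 0L) return(df)
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$allele_frequency <- as.numeric(df$allele_frequency)
  for (i in seq_len(nrow(df))) {
    if (!df$significance[i] %in% c("PATHOGENIC", "LIKELY_PATHOGENIC", "OTHER"))
      row_error("variants.tsv", i,
                sprintf("invalid significance '%s'", df$significance[i]))
    if (is.na(df$allele_frequency[i]) || df$allele_frequency[i] < 0 ||
        df$allele_frequency[i] > 1)
      row_error("variants.tsv", i, "allele_frequency outside [0,1]")
    if (is.na(df$start[i]) || df$start[i] > df$end[i])
      row_error("variants.tsv", i, "invalid interval")
  }
  df
}

validate_critical <- function(df, genes) {
  if (nrow(df) == 0L) return(df)
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  for (i in seq_len(nrow(df))) {
    g <- which(genes$gene_id == df$gene_id[i])
    if (length(g) == 0L)
      row_error("critical.tsv", i,
                sprintf("gene_id '%s' not present in genes.tsv", df$gene_id[i]))
    within_any <- any(genes$chrom[g] == df$chrom[i] &
                        genes$start[g] <= df$start[i] &
                        genes$end[g] >= df$end[i])
    if (!within_any)
      row_error("critical.tsv", i, "critical region outside linked gene span")
  }
  df
}

build_index <- function(df) {
  if (nrow(df) == 0L) return(NULL)
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(start = df$start,
                                                   end = df$end))
}

#' Load an annotation database directory
#'
#' Reads the tab-delimited annotation tables (`genes.tsv`, `dosage.tsv`
#' required; `popvar.tsv`, `variants.tsv`, `critical.tsv` optional),
#' validates every record against the type invariants (reporting the file
#' and line of any violation), and builds interval indexes for overlap
#' queries.
#'
#' @param directory Path containing the database files.
#' @param build Genome build label echoed in reports; never validated
#'   against a sequence.
#' @return An `annotation_db` object.
#' @export
load_database <- function(directory, build = "GRCh37") {
  if (!dir.exists(directory))
    cnv_abort(sprintf("database directory not found: %s", directory),
              "cnvscore_schema_error")
  tables <- lapply(DB_FILES, function(sp) read_db_table(directory, sp))
  tables$genes <- validate_genes(tables$genes)
  tables$dosage_regions <- validate_dosage(tables$dosage_regions)
  tables$population_variants <- validate_popvar(tables$population_variants)
  tables$known_variants <- validate_variants(tables$known_variants)
  tables$critical_regions <- validate_critical(tables$critical_regions,
                                               tables$genes)
  for (nm in names(tables)) {
    tables[[nm]]$start <- as.numeric(tables[[nm]]$start)
    tables[[nm]]$end <- as.numeric(tables[[nm]]$end)
  }
  indexes <- lapply(tables, build_index)
  structure(list(tables = tables, indexes = indexes, build = build,
                 directory = directory),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("<annotation_db> build %s (%s)\n", x$build, x$directory))
  for (nm in names(x$tables))
    cat(sprintf("  %-20s %6d records\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Query an annotation collection for overlapping records
#'
#' Returns every record of the named collection sharing at least one base
#' pair with the query interval, in deterministic (chromosome, start, end,
#' id) order. A chromosome absent from the database yields an empty result.
#'
#' @param db An `annotation_db`.
#' @param chrom,start,end Query interval (1-based, fully closed). A
#'   `cnv_query` may be given as `chrom` instead.
#' @param collection One of `"genes"`, `"dosage_regions"`,
#'   `"population_variants"`, `"known_variants"`, `"critical_regions"`.
#' @return Data frame of overlapping records (possibly empty).
#' @export
db_query <- function(db, chrom, start = NULL, end = NULL,
                     collection = names(DB_FILES)) {
  collection <- match.arg(collection)
  if (inherits(chrom, "cnv_query")) {
    start <- chrom$start; end <- chrom$end; chrom <- chrom$chrom
  }
  chrom <- normalize_chrom(chrom)
  df <- db$tables[[collection]]
  idx <- db$indexes[[collection]]
  if (is.null(idx) || nrow(df) == 0L) return(df[0, , drop = FALSE])
  if (!chrom %in% as.character(unique(GenomicRanges::seqnames(idx))))
    return(df[0, , drop = FALSE])
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(start = start,
                                                        end = end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, idx,
                                                       minoverlap = 1L))
  rows <- S4Vectors::subjectHits(hits)
  out <- df[rows, , drop = FALSE]
  if (nrow(out) > 1L) {
    id_col <- intersect(c("gene_id", "region_id", "variant_id"), names(out))
    id <- if (length(id_col)) out[[id_col[1]]] else rownames(out)
    out <- out[order(out$chrom, out$start, out$end, id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a BED track as 1-based dosage/benign regions
#'
#' BED is 0-based half-open; records are converted to the package's 1-based
#' fully-closed convention (`start + 1`, `end` unchanged).
#'
#' @param path BED file with at least chrom/start/end and a name column.
#' @param kind Dosage-region kind assigned to every record.
#' @param score Dosage score assigned to HI/TS records (ignored for benign).
#' @return Data frame in `dosage.tsv` layout.
#' @export
read_bed_track <- function(path, kind, score = NA_real_) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3L)
    cnv_abort(sprintf("%s: BED needs at least 3 columns", basename(path)),
              "cnvscore_schema_error")
  data.frame(region_id = if (ncol(bed) >= 4L) bed[[4]]
             else sprintf("%s_%d", kind, seq_len(nrow(bed))),
             chrom = normalize_chrom(bed[[1]]),
             start = as.numeric(bed[[2]]) + 1,
             end = as.numeric(bed[[3]]),
             kind = kind,
             score = if (grepl("^(HI|TS)_", kind)) score else NA_real_,
             gene_id = "", stringsAsFactors = FALSE)
}
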