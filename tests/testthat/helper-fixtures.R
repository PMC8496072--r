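# Shared fixtures: the synthetic database is generated once per test run.

fixture_db_dir <- function() {
  dir <- file.path(tempdir(), "cnvscore-fixture-db")
  if (!file.exists(file.path(dir, "genes.tsv")))
    generate_fixture_db(dir, seed = 1L)
  dir
}

fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- suppressMessages(load_database(fixture_db_dir()))
    db
  }
})

# A database directory with all tables present but empty.
empty_db <- local({
  db <- NULL
  function() {
    if (!is.null(db)) return(db)
    dir <- file.path(tempdir(), "cnvscore-empty-db")
    dir.create(dir, showWarnings = FALSE)
    headers <- list(
      genes.tsv = c("gene_id", "symbol", "chrom", "start", "end", "strand",
                    "cds_start", "cds_end", "exon_starts", "exon_ends",
                    "coding", "canonical", "pli", "oe_upper", "hi_index",
                    "relevant"),
      dosage.tsv = c("region_id", "chrom", "start", "end", "kind", "score",
                     "gene_id"),
      popvar.tsv = c("variant_id", "chrom", "start", "end", "dosage",
                     "frequency", "cohort_size", "source_kind"),
      variants.tsv = c("chrom", "start", "end", "gene_id", "significance",
                       "allele_frequency"),
      critical.tsv = c("gene_id", "chrom", "start", "end", "note"))
    for (f in names(headers))
      writeLines(paste(headers[[f]], collapse = "\t"), file.path(dir, f))
    db <<- suppressMessages(load_database(dir))
    db
  }
})

# Validated one-row gene model (with parsed exon list columns) for direct
# calls into classify_gene_overlap / evaluate_* in tests.
test_gene <- function(...) {
  cnvscore:::validate_genes(cnvscore:::make_gene(...))
}
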