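test_that("the 1.5-Mb chr22 deletion annotates with 32 genes and a spanned HI region", {
  db <- fixture_db()
  ann <- annotate_cnv(parse_cnv("chr22:18,761,827-20,307,561", "LOSS"), db)
  expect_equal(ann$gene_count, 32L)
  expect_true(ann$functionally_important)
  hi <- ann$hi_overlaps
  expect_true("nssv1184570" %in% hi$region_id)
  expect_equal(hi$overlap_class[hi$region_id == "nssv1184570"],
               "CNV_CONTAINS_ELEMENT")
})

test_that("a gene-desert query has no content and is not functionally important", {
  db <- fixture_db()
  ann <- annotate_cnv(cnv_query("chr7", 1e6, 2e6, "LOSS"), db)
  expect_equal(ann$gene_count, 0L)
  expect_false(ann$functionally_important)
})

test_that("gene counts match a brute-force scan over random queries", {
  db <- fixture_db()
  genes <- db$tables$genes
  set.seed(7)
  for (i in 1:200) {
    chrom <- sample(c("chr1", "chr2", "chr9", "chr22"), 1)
    s <- sample.int(3e7, 1); e <- s + sample.int(2e6, 1)
    ann <- annotate_cnv(cnv_query(chrom, s, e, "LOSS"), db)
    hit <- genes$chrom == chrom & genes$start <= e & genes$end >= s &
      genes$coding
    expect_equal(ann$gene_count, length(unique(genes$symbol[hit])))
  }
})

test_that("intronic CNVs classify as contained with no exons involved", {
  g <- test_gene("T1_tx1", "T1", "chr1", 10000)   # exons 150 bp, introns 1 kb
  det <- classify_gene_overlap(list(chrom = "chr1", start = 10200,
                                    end = 10800), g)
  expect_equal(det$relation, "CNV_WITHIN_ELEMENT")
  expect_false(det$coding_sequence_involved)
  expect_length(det$exons_involved, 0)
})

test_that("5'/3' partial overlap is strand-aware", {
  gp <- test_gene("P_tx1", "P", "chr1", 10000)
  gm <- test_gene("M_tx1", "M", "chr1", 10000, strand = "-")
  # covers genomic left end only
  left <- list(chrom = "chr1", start = 9000, end = 10500)
  expect_equal(classify_gene_overlap(left, gp)$relation, "PARTIAL_5PRIME")
  expect_equal(classify_gene_overlap(left, gm)$relation, "PARTIAL_3PRIME")
  # covers genomic right end only (gene ends 13599)
  right <- list(chrom = "chr1", start = 13000, end = 14000)
  expect_equal(classify_gene_overlap(right, gp)$relation, "PARTIAL_3PRIME")
  expect_equal(classify_gene_overlap(right, gm)$relation, "PARTIAL_5PRIME")
  expect_error(classify_gene_overlap(list(start = 1, end = 2), gp),
               class = "cnvscore_contract_error")
})

test_that("a CNV over the genomic 3' half of a minus-strand gene is a 5' overlap", {
  # 3-exon minus-strand model checked by hand: transcription starts at the
  # genomic right end, so covering that end without the left end is 5'.
  g <- test_gene("N3_tx1", "N3", "chr1", 20000,
                 exon_lens = c(120, 120, 120), strand = "-")
  det <- classify_gene_overlap(list(chrom = "chr1", start = 21200,
                                    end = 23000), g)
  expect_equal(det$relation, "PARTIAL_5PRIME")
  expect_equal(det$exons_involved[1], 1L)  # transcription-order exon 1
})

test_that("covering only the terminal coding exon flags only_last_exon", {
  g <- test_gene("LE_tx1", "LE", "chr1", 10000)  # exon 4: 13450-13599
  det <- classify_gene_overlap(list(chrom = "chr1", start = 13460,
                                    end = 13700), g)
  expect_equal(det$relation, "PARTIAL_3PRIME")
  expect_true(det$only_last_exon)
  expect_true(det$coding_sequence_involved)
  expect_false(det$only_3prime_utr)
  # same but beyond the CDS end (13499): pure 3' UTR
  det2 <- classify_gene_overlap(list(chrom = "chr1", start = 13520,
                                     end = 13700), g)
  expect_true(det2$only_3prime_utr)
  expect_false(det2$coding_sequence_involved)
})

test_that("gene overlap relations are invariant under coordinate mirroring", {
  set.seed(99)
  for (i in 1:40) {
    g <- rand_gene_model(sprintf("S%02d", i))
    qs <- sample(g$start:g$end, 1)
    qe <- min(qs + sample.int(2000, 1), g$end + sample(0:500, 1))
    det <- classify_gene_overlap(list(start = qs, end = qe), g)
    # mirror all coordinates around a pivot and flip strand
    pivot <- 2e6
    mirror <- function(x) pivot - x
    gm <- g
    gm$start <- mirror(g$end); gm$end <- mirror(g$start)
    gm$cds_start <- mirror(g$cds_end); gm$cds_end <- mirror(g$cds_start)
    gm$strand <- if (g$strand == "+") "-" else "+"
    gm$exon_starts_list <- list(rev(mirror(g$exon_ends_list[[1]])))
    gm$exon_ends_list <- list(rev(mirror(g$exon_starts_list[[1]])))
    detm <- classify_gene_overlap(list(start = mirror(qe), end = mirror(qs)),
                                  gm)
    expect_equal(detm$relation, det$relation)
    expect_equal(detm$exons_involved, det$exons_involved)
    expect_equal(detm$coding_sequence_involved, det$coding_sequence_involved)
  }
})

test_that("common-variant facts apply frequency, cohort and dosage filters", {
  db <- fixture_db()
  # inside the 12.45% sample-counted loss variant (chr1 zone 22)
  q <- cnv_query("chr1", 22e6 + 12000, 22e6 + 20000, "LOSS")
  facts <- common_variant_facts(q, db)
  expect_equal(facts$containment, "CNV_WITHIN")
  expect_equal(facts$overlap_fraction_of_cnv, 1)
  # a GAIN query over the same loss variant: dosage mismatch
  qg <- cnv_query("chr1", 22e6 + 12000, 22e6 + 20000, "GAIN")
  expect_equal(nrow(common_variant_facts(qg, db)), 0L)
  # rare (0.2%) and small-cohort variants on chr9 are never common
  expect_equal(nrow(common_variant_facts(
    cnv_query("chr9", 2.1e6, 2.2e6, "LOSS"), db)), 0L)
  expect_equal(nrow(common_variant_facts(
    cnv_query("chr9", 4.1e6, 4.2e6, "LOSS"), db)), 0L)
})

test_that("overlap fraction is 1 exactly when the CNV is contained", {
  db <- fixture_db()
  set.seed(5)
  for (i in 1:50) {
    s <- 22e6 + sample.int(6e4, 1); e <- s + sample.int(5e4, 1)
    facts <- common_variant_facts(cnv_query("chr1", s, e, "LOSS"), db)
    if (nrow(facts) == 0L) next
    expect_equal(facts$containment == "CNV_WITHIN",
                 facts$overlap_fraction_of_cnv == 1)
    expect_true(all(facts$overlap_fraction_of_cnv >= 0 &
                      facts$overlap_fraction_of_cnv <= 1))
  }
})
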