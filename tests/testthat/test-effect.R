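test_that("transcript selection prefers canonical, then CDS length, span and id", {
  # canonical short transcript beats a longer non-canonical one
  a <- test_gene("TXA", "G1", "chr1", 1000, exon_lens = c(100, 100),
                 canonical = 1L)
  b <- test_gene("TXB", "G1", "chr1", 1000, exon_lens = c(300, 300, 300),
                 canonical = 0L)
  expect_equal(select_transcript(rbind(a, b))$gene_id, "TXA")
  # singleton
  expect_equal(select_transcript(b)$gene_id, "TXB")
  # neither canonical: CDS 900-ish vs 600-ish (exon sums 500+500 vs 350+350)
  c1 <- test_gene("TXC", "G2", "chr1", 1000, exon_lens = c(500, 500),
                  canonical = 0L)
  c2 <- test_gene("TXD", "G2", "chr1", 1000, exon_lens = c(350, 350),
                  canonical = 0L)
  expect_equal(select_transcript(rbind(c2, c1))$gene_id, "TXC")
  # full tie: lexicographically smallest id
  c3 <- c1; c3$gene_id <- "TXZ"
  expect_equal(select_transcript(rbind(c3, c1))$gene_id, "TXC")
  expect_error(select_transcript(c1[0, ]), class = "cnvscore_contract_error")
})

test_that("deleting a frame-shifting internal exon predicts PVS1 via NMD", {
  # 4 exons, the 100-bp second exon shifts the frame; the junction stop sits
  # 150 nt upstream of the last remaining exon-exon junction
  g <- test_gene("E1_tx1", "E1", "chr1", 10000,
                 exon_lens = c(150, 100, 150, 150))
  q <- cnv_query("chr1", 11100, 11300, "LOSS")   # removes exon 2 entirely
  eff <- evaluate_deletion(q, g, empty_db())
  expect_true(eff$frame_disrupted)
  expect_true(eff$nmd_predicted)
  expect_equal(eff$strength, "PVS1")
})

test_that("in-frame deletions grade by the fraction of protein removed", {
  # CDS 1200 bp: 150+500+500+50
  g <- test_gene("E2_tx1", "E2", "chr1", 10000,
                 exon_lens = c(250, 500, 500, 150))
  # 144 coding bp = 12% > 10%, in frame -> PVS1_Strong
  q1 <- cnv_query("chr1", 10350 + 1000, 10350 + 1000 + 143, "LOSS")
  eff1 <- evaluate_deletion(q1, g, empty_db())
  expect_false(eff1$frame_disrupted)
  expect_equal(eff1$fraction_protein_removed, 144 / 1200)
  expect_equal(eff1$strength, "PVS1_STRONG")
  # 48 coding bp = 4% < 10% -> PVS1_Moderate
  q2 <- cnv_query("chr1", 10350 + 1000, 10350 + 1000 + 47, "LOSS")
  eff2 <- evaluate_deletion(q2, g, empty_db())
  expect_equal(eff2$fraction_protein_removed, 0.04)
  expect_equal(eff2$strength, "PVS1_MODERATE")
})

test_that("critical-region hits and frequent LoF change the grading", {
  db <- fixture_db()
  # zone 15 on chr1: in-frame deletion inside the curated critical region
  g <- db$tables$genes[db$tables$genes$gene_id == "L2EC_tx1", ]
  eff <- evaluate_deletion(cnv_query("chr1", 15e6 + 12300, 15e6 + 12347,
                                     "LOSS"), g, db)
  expect_true(eff$critical_region_hit)
  expect_equal(eff$strength, "PVS1_STRONG")
  # zone 16: same geometry but pathogenic LoF at 5% allele frequency
  g2 <- db$tables$genes[db$tables$genes$gene_id == "L2EL_tx1", ]
  eff2 <- evaluate_deletion(cnv_query("chr1", 16e6 + 11150, 16e6 + 11197,
                                      "LOSS"), g2, db)
  expect_true(eff2$lof_frequent)
  expect_equal(eff2$strength, "NONE")
})

test_that("fraction removed ignores UTR and intron bases added to the CNV", {
  g <- test_gene("E3_tx1", "E3", "chr1", 10000)
  # exon 2 spans 11150-11299 (fully coding); both CNVs delete the same
  # 12 coding bp, the second also takes flanking intron sequence
  core <- cnv_query("chr1", 11150, 11161, "LOSS")
  e1 <- evaluate_deletion(core, g, empty_db())
  expect_equal(e1$fraction_protein_removed, 12 / 400)
  wide <- cnv_query("chr1", 11100, 11161, "LOSS")
  expect_equal(evaluate_deletion(wide, g, empty_db())$fraction_protein_removed,
               12 / 400)
  # pure 3' UTR removal leaves the protein untouched
  q_utr <- cnv_query("chr1", 13500, 13599, "LOSS")
  expect_equal(evaluate_deletion(q_utr, g,
                                 empty_db())$fraction_protein_removed, 0)
})

test_that("multiples of three coding bases never disrupt the frame", {
  set.seed(21)
  for (i in 1:60) {
    g <- rand_gene_model(sprintf("F%02d", i))
    d <- rand_deletion(g)
    eff <- evaluate_deletion(cnv_query("chrT", d[1], d[2], "LOSS"), g,
                             empty_db())
    del <- deleted_coding_oracle(g, d[1], d[2])
    expect_equal(eff$frame_disrupted, del %% 3 != 0)
    if (del %% 3 == 0) expect_false(eff$frame_disrupted)
  }
})

test_that("NMD calls match brute-force transcript reconstruction", {
  set.seed(1234)
  checked <- 0
  while (checked < 200) {
    g <- rand_gene_model(sprintf("NM%03d", checked))
    d <- rand_deletion(g)
    eff <- evaluate_deletion(cnv_query("chrT", d[1], d[2], "LOSS"), g,
                             empty_db())
    expect_equal(eff$nmd_predicted, nmd_oracle(g, d[1], d[2]),
                 info = sprintf("gene %s strand %s del %d-%d", g$gene_id,
                                g$strand, d[1], d[2]))
    checked <- checked + 1
  }
})

test_that("tandem duplications grade by tandem status, frame and NMD", {
  g <- test_gene("D1_tx1", "D1", "chr1", 10000,
                 exon_lens = c(150, 100, 150, 150))
  q <- cnv_query("chr1", 11150, 11249, "GAIN")   # exactly the 100-bp exon 2
  expect_equal(evaluate_duplication(q, g, "PROVEN")$strength, "PVS1")
  expect_equal(evaluate_duplication(q, g, "ASSUMED")$strength, "PVS1_STRONG")
  expect_equal(evaluate_duplication(q, g, "UNKNOWN")$strength, "NONE")
  # in-frame whole-exon duplication: no frame disruption, no call
  g2 <- test_gene("D2_tx1", "D2", "chr1", 10000)
  q2 <- cnv_query("chr1", 11150, 11299, "GAIN")  # 150-bp exon 2
  eff2 <- evaluate_duplication(q2, g2, "PROVEN")
  expect_false(eff2$frame_disrupted)
  expect_equal(eff2$strength, "NONE")
})

test_that("containment contracts are enforced", {
  g <- test_gene("C1_tx1", "C1", "chr1", 10000)
  expect_error(evaluate_deletion(cnv_query("chr1", 9000, 11000, "LOSS"), g,
                                 empty_db()),
               class = "cnvscore_contract_error")
  expect_error(evaluate_duplication(cnv_query("chr1", 9000, 11000, "GAIN"),
                                    g),
               class = "cnvscore_contract_error")
})
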