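cfg <- load_metric_config()

test_that("Section 1 scores genomic content, counting score-1..3 elements", {
  db <- fixture_db()
  # 32 genes -> 1A
  ann <- annotate_cnv(parse_cnv("chr22:18761827-20307561", "LOSS"), db)
  i1 <- score_section1(ann, cfg)
  expect_equal(i1$category, "1A"); expect_equal(i1$points, 0)
  # desert -> 1B
  ann2 <- annotate_cnv(cnv_query("chr7", 1e6, 1.1e6, "LOSS"), db)
  i2 <- score_section1(ann2, cfg)
  expect_equal(i2$category, "1B"); expect_equal(i2$points, -0.6)
  # zero genes but inside a score-3 HI region -> functionally important -> 1A
  ann3 <- annotate_cnv(cnv_query("chr1", 2e6 + 19200, 2e6 + 19900, "LOSS"),
                       db)
  expect_equal(ann3$gene_count, 0L)
  expect_true(ann3$functionally_important)
  expect_equal(score_section1(ann3, cfg)$category, "1A")
})

test_that("Section 3 bands follow the printed gene-count boundaries", {
  cases <- list(list("LOSS", 0, "3A", 0), list("LOSS", 24, "3A", 0),
                list("LOSS", 25, "3B", 0.45), list("LOSS", 32, "3B", 0.45),
                list("LOSS", 34, "3B", 0.45), list("LOSS", 35, "3C", 0.9),
                list("LOSS", 49, "3C", 0.9),
                list("GAIN", 34, "3A", 0), list("GAIN", 35, "3B", 0.45),
                list("GAIN", 40, "3B", 0.45), list("GAIN", 49, "3B", 0.45),
                list("GAIN", 50, "3C", 0.9))
  for (cs in cases) {
    item <- score_section3(cs[[2]], cs[[1]], cfg)
    expect_equal(item$category, cs[[3]],
                 info = sprintf("%s n=%d", cs[[1]], cs[[2]]))
    expect_equal(item$points, cs[[4]])
  }
  # monotonicity: more genes never decrease the points
  pts <- vapply(0:60, function(n) score_section3(n, "LOSS", cfg)$points,
                numeric(1))
  expect_true(all(diff(pts) >= 0))
})

test_that("4O fires on containment or >= 50% coverage without extra genes", {
  fake_ann <- function(dosage, containment, frac, extra) {
    structure(list(query = cnv_query("chr1", 1, 100, dosage),
                   common_variant_facts = data.frame(
                     variant_id = "v1", containment = containment,
                     overlap_fraction_of_cnv = frac,
                     extra_protein_genes = extra, frequency = 0.1)),
              class = "annotation_result")
  }
  expect_equal(score_section4_auto(fake_ann("LOSS", "CNV_WITHIN", 1, 0),
                                   cfg)$points, -1)
  expect_equal(score_section4_auto(fake_ann("LOSS", "OVERLAP", 0.5, 0),
                                   cfg)$points, -1)
  expect_null(score_section4_auto(fake_ann("LOSS", "OVERLAP", 0.49, 0), cfg))
  expect_null(score_section4_auto(fake_ann("LOSS", "OVERLAP", 0.8, 2), cfg))
})

test_that("the 2-series keeps every candidate but only the winner contributes", {
  db <- fixture_db()
  suite <- generate_cnv_suite()$suite
  for (i in seq_len(nrow(suite))) {
    q <- parse_cnv(suite$coordinate[i], suite$dosage[i])
    card <- score_cnv(q, db, tandem_status = toupper(suite$tandem[i]))
    sec2 <- card$items[cnvscore:::category_section(card$items$category) == 2L, ]
    expect_lte(sum(sec2$contributes), 1L)
    # every emitted item sits inside its configured range
    expect_true(all(card$items$points >= card$items$range_min - 1e-9 &
                      card$items$points <= card$items$range_max + 1e-9))
  }
})

test_that("benign containment short-circuits only without positive evidence", {
  fin <- cnvscore:::finalize_section2
  mk <- function(cat, pts) evidence_item(cat, pts, -1, 1)
  # 2F alone, or with only 0-point company: terminal
  r1 <- fin(rbind(mk("2B", 0), mk("2F", -1)), "2F")
  expect_true(r1$terminal)
  expect_equal(r1$items$category[r1$items$contributes], "2F")
  # positive evidence suppresses the short-circuit and wins
  r2 <- fin(rbind(mk("2A", 1), mk("2F", -1)), "2F")
  expect_false(r2$terminal)
  expect_equal(r2$items$category[r2$items$contributes], "2A")
  expect_match(r2$conflicts, "benign")
  # empty candidate set
  r3 <- fin(cnvscore:::empty_items(), "2F")
  expect_false(r3$terminal)
  expect_equal(nrow(r3$items), 0L)
})

test_that("a terminal benign deletion totals exactly -1 regardless of content", {
  db <- fixture_db()
  card <- score_cnv(cnv_query("chr1", 17e6 + 11000, 17e6 + 16000, "LOSS"), db)
  expect_true(card$terminal_benign)
  expect_equal(card$auto_total, -1)
  expect_equal(card$final_classification, "BENIGN")
  expect_true(card$sufficient_without_manual)
})

test_that("dosage-specific categories never leak across dosage types", {
  db <- fixture_db()
  suite <- generate_cnv_suite()$suite
  loss_only <- c("2C-1", "2C-2", "2D-1", "2D-2", "2D-3", "2D-4")
  gain_only <- c("2C", "2D", "2I", "2J", "2K", "2L")
  for (i in seq_len(nrow(suite))) {
    q <- parse_cnv(suite$coordinate[i], suite$dosage[i])
    card <- score_cnv(q, db, tandem_status = toupper(suite$tandem[i]))
    if (q$dosage == "GAIN")
      expect_length(intersect(card$items$category, loss_only), 0)
    else
      expect_length(intersect(card$items$category, gain_only), 0)
  }
})

test_that("an unknown-tandem intragenic duplication contributes 0 via 2I", {
  db <- fixture_db()
  card <- score_cnv(cnv_query("chr2", 12e6 + 11150, 12e6 + 11249, "GAIN"), db,
                    tandem_status = "UNKNOWN")
  i2 <- card$items[card$items$category == "2I", ]
  expect_equal(nrow(i2), 1L)
  expect_equal(i2$points, 0)
})
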