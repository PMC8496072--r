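test_that("the five published bands map exactly, including boundaries", {
  expect_equal(classify_total(1.45), "PATHOGENIC")
  expect_equal(classify_total(0.99), "PATHOGENIC")
  expect_equal(classify_total(0.98), "LIKELY_PATHOGENIC")
  expect_equal(classify_total(0.90), "LIKELY_PATHOGENIC")
  expect_equal(classify_total(0.89), "VUS")
  expect_equal(classify_total(0), "VUS")
  expect_equal(classify_total(-0.89), "VUS")
  expect_equal(classify_total(-0.90), "LIKELY_BENIGN")
  expect_equal(classify_total(-0.98), "LIKELY_BENIGN")
  expect_equal(classify_total(-0.99), "BENIGN")
  expect_equal(classify_total(-1.2), "BENIGN")
  expect_error(classify_total(NaN), class = "cnvscore_validation_error")
})

test_that("a sweep over totals matches the printed band definition", {
  # independent mapping straight from the printed bands, on hundredths
  printed_band <- function(h) {
    if (h >= 99) "PATHOGENIC"
    else if (h >= 90 && h <= 98) "LIKELY_PATHOGENIC"
    else if (h >= -89 && h <= 89) "VUS"
    else if (h >= -98 && h <= -90) "LIKELY_BENIGN"
    else "BENIGN"
  }
  hs <- -150:150
  got <- vapply(hs, function(h) classify_total(h / 100), character(1))
  want <- vapply(hs, printed_band, character(1))
  expect_identical(got, want)
  # monotone non-decreasing severity as the total increases
  sev <- c(BENIGN = 1, LIKELY_BENIGN = 2, VUS = 3, LIKELY_PATHOGENIC = 4,
           PATHOGENIC = 5)
  expect_true(all(diff(sev[got]) >= 0))
})

test_that("scorecards total the contributing items in exact hundredths", {
  q <- cnv_query("chr22", 18761827, 20307561, "LOSS")
  items <- rbind(evidence_item("1A", 0, 0, 0),
                 evidence_item("2A", 1, 1, 1),
                 evidence_item("3B", 0.45, 0.45, 0.45))
  card <- build_scorecard(q, items)
  expect_equal(card$auto_total, 1.45)
  expect_equal(card$pre_classification, "PATHOGENIC")
  expect_true(card$sufficient_without_manual)
  # repeated summation of decimals stays exact at band edges
  many <- do.call(rbind, rep(list(evidence_item("4B", 0.33, 0, 0.45,
                                                source = "MANUAL")), 3))
  card2 <- build_scorecard(q, rbind(evidence_item("1A", 0, 0, 0), many))
  expect_identical(card2$final_total, 0.99)
  expect_equal(card2$final_classification, "PATHOGENIC")
})

test_that("a 1B-only deletion is a VUS at -0.60", {
  card <- build_scorecard(cnv_query("chr1", 1, 100, "LOSS"),
                          rbind(evidence_item("1B", -0.6, -0.6, -0.6),
                                evidence_item("3A", 0, 0, 0)))
  expect_equal(card$auto_total, -0.6)
  expect_equal(card$pre_classification, "VUS")
  expect_false(card$sufficient_without_manual)
})

test_that("adding positive manual evidence never moves the class toward benign", {
  sev <- c(BENIGN = 1, LIKELY_BENIGN = 2, VUS = 3, LIKELY_PATHOGENIC = 4,
           PATHOGENIC = 5)
  cfg <- load_metric_config()
  set.seed(3)
  for (i in 1:30) {
    base_pts <- sample(seq(-1.2, 1.2, by = 0.05), 3)
    items <- do.call(rbind, lapply(seq_along(base_pts), function(j)
      evidence_item(sprintf("4%s", LETTERS[j]), base_pts[j], -2, 2,
                    source = "MANUAL")))
    before <- build_scorecard(cnv_query("chr1", 1, 2, "LOSS"), items)
    extra <- evidence_item("4H", 0.45, 0, 0.45, source = "MANUAL")
    after <- build_scorecard(cnv_query("chr1", 1, 2, "LOSS"),
                             rbind(items, extra))
    expect_gte(sev[after$final_classification],
               sev[before$final_classification])
  }
})

test_that("JSON reports round-trip and TSV/text forms are well formed", {
  db <- fixture_db()
  card <- score_cnv(parse_cnv("chr22:18761827-20307561", "LOSS",
                              label = "case1"), db)
  js <- write_report(card, "json")
  back <- read_report(js)
  expect_equal(back$final_total, card$final_total)
  expect_equal(back$final_classification, card$final_classification)
  expect_equal(back$items$category, card$items$category)
  expect_equal(back$items$points, card$items$points)

  txt <- write_report(card, "text")
  pos <- vapply(c("1A", "2A", "3B"), function(p)
    regexpr(paste0("\n  ", p), txt, fixed = TRUE)[1], numeric(1))
  expect_true(all(diff(pos) > 0))   # narrative keeps section order

  expect_error(write_report(card, "pdf"))
})

test_that("batch scoring preserves rows, isolates failures and is deterministic", {
  db <- fixture_db()
  suite <- data.frame(label = c("a", "bad", "b"),
                      coordinate = c("chr22:18761827-20307561",
                                     "chr22:oops", "chr7:1000000-1100000"),
                      dosage = c("LOSS", "LOSS", "GAIN"))
  res <- score_batch(suite, db)
  expect_equal(nrow(res), 3L)
  expect_equal(res$label, suite$label)
  expect_equal(res$status[2], "parse_error")
  expect_equal(res$status[c(1, 3)], c("ok", "ok"))
  res2 <- score_batch(suite, db)
  expect_identical(res, res2)
})
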