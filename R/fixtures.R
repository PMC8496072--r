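## fixtures: deterministic synthetic annotation database and companion CNV
## suite. Every automated scoring branch is placed in its own well-separated
## genomic zone with hand-constructed geometry; the expected outcome of each
## suite CNV is written down constructively here, never computed by running
## the scoring engine.

# A standard synthetic gene model. Exons are laid out left to right on the
# genome with fixed intron lengths; the CDS trims `utr5` bases off the
# transcriptional 5' end and `utr3` off the 3' end (strand-aware).
make_gene <- function(gene_id, symbol, chrom, start, strand = "+",
                      exon_lens = c(150, 150, 150, 150), intron_len = 1000,
                      utr5 = 100, utr3 = 100, coding = 1L, canonical = 1L,
                      pli = NA_real_, oe_upper = NA_real_,
                      hi_index = NA_real_, relevant = 1L) {
  n <- length(exon_lens)
  es <- numeric(n); ee <- numeric(n)
  pos <- start
  for (i in seq_len(n)) {
    es[i] <- pos
    ee[i] <- pos + exon_lens[i] - 1
    pos <- ee[i] + intron_len + 1
  }
  gene_end <- ee[n]
  if (coding == 1L) {
    if (strand == "+") {
      cds_start <- start + utr5; cds_end <- gene_end - utr3
    } else {
      cds_start <- start + utr3; cds_end <- gene_end - utr5
    }
  } else {
    cds_start <- NA_real_; cds_end <- NA_real_
  }
  data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
             start = start, end = gene_end, strand = strand,
             cds_start = cds_start, cds_end = cds_end,
             exon_starts = paste(format(es, scientific = FALSE, trim = TRUE),
                                 collapse = ","),
             exon_ends = paste(format(ee, scientific = FALSE, trim = TRUE),
                               collapse = ","),
             coding = coding, canonical = canonical, pli = pli,
             oe_upper = oe_upper, hi_index = hi_index, relevant = relevant,
             stringsAsFactors = FALSE)
}

# Collects database rows, suite CNVs and their constructively derived
# expectations for every scoring-branch zone.
fixture_plan <- function(seed = 1L) {
  genes <- list(); dosage <- list(); popvar <- list(); variants <- list()
  critical <- list(); suite <- list(); expected <- list()

  g <- function(...) genes[[length(genes) + 1L]] <<- make_gene(...)
  d <- function(region_id, chrom, start, end, kind, score = NA_real_,
                gene_id = "")
    dosage[[length(dosage) + 1L]] <<- data.frame(
      region_id = region_id, chrom = chrom, start = start, end = end,
      kind = kind, score = score, gene_id = gene_id, stringsAsFactors = FALSE)
  pv <- function(variant_id, chrom, start, end, dosage_type, frequency,
                 cohort_size, source_kind)
    popvar[[length(popvar) + 1L]] <<- data.frame(
      variant_id = variant_id, chrom = chrom, start = start, end = end,
      dosage = dosage_type, frequency = frequency, cohort_size = cohort_size,
      source_kind = source_kind, stringsAsFactors = FALSE)
  kv <- function(chrom, start, end, gene_id, significance, allele_frequency)
    variants[[length(variants) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, gene_id = gene_id,
      significance = significance, allele_frequency = allele_frequency,
      stringsAsFactors = FALSE)
  cr <- function(gene_id, chrom, start, end, note)
    critical[[length(critical) + 1L]] <<- data.frame(
      gene_id = gene_id, chrom = chrom, start = start, end = end, note = note,
      stringsAsFactors = FALSE)
  cnv <- function(label, chrom, start, end, dosage_type, categories,
                  auto_total, classification, terminal = FALSE,
                  tandem = "unknown") {
    suite[[length(suite) + 1L]] <<- data.frame(
      label = label, coordinate = sprintf("%s:%d-%d", chrom, start, end),
      dosage = dosage_type, tandem = tandem, stringsAsFactors = FALSE)
    expected[[label]] <<- list(categories = categories,
                               auto_total = auto_total,
                               classification = classification,
                               terminal = terminal)
  }

  gene_array <- function(prefix, chrom, base, n, spacing = 5000) {
    for (k in seq_len(n))
      g(sprintf("%s%02d_tx1", prefix, k), sprintf("%s%02d", prefix, k),
        chrom, base + (k - 1) * spacing)
    c(base, base + (n - 1) * spacing + 3599)
  }

  zone <- function(k, chrom) list(b = k * 1e6, chrom = chrom)

  ## ------------------------------------------------------------------ loss
  lz <- function(k) zone(k, "chr1")

  # gene desert -> 1B
  z <- lz(1)
  cnv("L-1B", z$chrom, z$b + 100, z$b + 5000, "LOSS",
      list(`1B` = -0.6, `3A` = 0), -0.6, "VUS")

  # complete overlap of an established HI region -> 2A
  z <- lz(2)
  d("HIR_2A", z$chrom, z$b + 10000, z$b + 20000, "HI_REGION", 3)
  g("L2A_A_tx1", "L2A_A", z$chrom, z$b + 11000)
  g("L2A_B_tx1", "L2A_B", z$chrom, z$b + 15500)
  cnv("L-2A", z$chrom, z$b + 5000, z$b + 25000, "LOSS",
      list(`1A` = 0, `2A` = 1, `3A` = 0), 1.0, "PATHOGENIC")

  # partial overlap of an HI region without HI genes -> 2B
  z <- lz(3)
  d("HIR_2B", z$chrom, z$b + 10000, z$b + 30000, "HI_REGION", 3)
  g("L2B_A_tx1", "L2B_A", z$chrom, z$b + 6000)
  cnv("L-2B", z$chrom, z$b + 5000, z$b + 15000, "LOSS",
      list(`1A` = 0, `2B` = 0, `3A` = 0), 0, "VUS")

  # 5' partial overlap of an HI gene, coding sequence involved -> 2C-1
  z <- lz(4)
  g("L2C1_tx1", "L2C1", z$chrom, z$b + 10000)
  d("HIG_2C1", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2C1_tx1")
  cnv("L-2C1", z$chrom, z$b + 9000, z$b + 11000, "LOSS",
      list(`1A` = 0, `2C-1` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC")

  # 5' partial overlap without coding sequence -> 2C-2
  z <- lz(5)
  g("L2C2_tx1", "L2C2", z$chrom, z$b + 10000)
  d("HIG_2C2", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2C2_tx1")
  cnv("L-2C2", z$chrom, z$b + 9000, z$b + 10050, "LOSS",
      list(`1A` = 0, `2C-2` = 0, `3A` = 0), 0, "VUS")

  # 5' partial overlap of a minus-strand HI gene (genomic 3' side) -> 2C-1
  z <- lz(6)
  g("L2C1N_tx1", "L2C1N", z$chrom, z$b + 10000, strand = "-")
  d("HIG_2C1N", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2C1N_tx1")
  cnv("L-2C1N", z$chrom, z$b + 13400, z$b + 14500, "LOSS",
      list(`1A` = 0, `2C-1` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC")

  # only last exon, established pathogenic variant in it -> 2D-2
  z <- lz(7)
  g("L2D2_tx1", "L2D2", z$chrom, z$b + 10000)
  d("HIG_2D2", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2D2_tx1")
  kv(z$chrom, z$b + 13470, z$b + 13472, "L2D2_tx1", "PATHOGENIC", 1e-4)
  cnv("L-2D2", z$chrom, z$b + 13460, z$b + 13700, "LOSS",
      list(`1A` = 0, `2D-2` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC")

  # only last exon, no established pathogenic variant -> 2D-3
  z <- lz(8)
  g("L2D3_tx1", "L2D3", z$chrom, z$b + 10000)
  d("HIG_2D3", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2D3_tx1")
  cnv("L-2D3", z$chrom, z$b + 13460, z$b + 13700, "LOSS",
      list(`1A` = 0, `2D-3` = 0.3, `3A` = 0), 0.3, "VUS")

  # last exon plus other exons -> 2D-4
  z <- lz(9)
  g("L2D4_tx1", "L2D4", z$chrom, z$b + 10000)
  d("HIG_2D4", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2D4_tx1")
  cnv("L-2D4", z$chrom, z$b + 12350, z$b + 13700, "LOSS",
      list(`1A` = 0, `2D-4` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC")

  # 3'-UTR-only overlap -> 2D-1 (0-point branch)
  z <- lz(10)
  g("L2D1_tx1", "L2D1", z$chrom, z$b + 10000)
  d("HIG_2D1", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2D1_tx1")
  cnv("L-2D1", z$chrom, z$b + 13520, z$b + 13700, "LOSS",
      list(`1A` = 0, `2D-1` = 0, `3A` = 0), 0, "VUS")

  # intragenic deletion, frameshift + NMD -> 2E / PVS1 (0.9)
  # 100-bp second exon: deleting it shifts the frame; the premature stop at
  # the junction lies 150 nt upstream of the last remaining junction.
  z <- lz(11)
  g("L2EP_tx1", "L2EP", z$chrom, z$b + 10000,
    exon_lens = c(150, 100, 150, 150))
  d("HIG_2EP", z$chrom, z$b + 10000, z$b + 13549, "HI_GENE", 3, "L2EP_tx1")
  cnv("L-2E-PVS1", z$chrom, z$b + 11200, z$b + 11400, "LOSS",
      list(`1A` = 0, `2E` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC")

  # minus-strand intragenic deletion of the transcriptional second exon
  z <- lz(12)
  g("L2EPN_tx1", "L2EPN", z$chrom, z$b + 10000, strand = "-",
    exon_lens = c(150, 150, 100, 150))
  d("HIG_2EPN", z$chrom, z$b + 10000, z$b + 13549, "HI_GENE", 3, "L2EPN_tx1")
  cnv("L-2E-PVS1-neg", z$chrom, z$b + 12250, z$b + 12450, "LOSS",
      list(`1A` = 0, `2E` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC")

  # in-frame deletion of 48/400 coding bases (12%) -> PVS1_Strong (0.45)
  z <- lz(13)
  g("L2ES_tx1", "L2ES", z$chrom, z$b + 10000)
  d("HIG_2ES", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2ES_tx1")
  cnv("L-2E-STRONG", z$chrom, z$b + 11150, z$b + 11197, "LOSS",
      list(`1A` = 0, `2E` = 0.45, `3A` = 0), 0.45, "VUS")

  # in-frame deletion of 12/400 coding bases (3%) -> PVS1_Moderate (0.3)
  z <- lz(14)
  g("L2EM_tx1", "L2EM", z$chrom, z$b + 10000)
  d("HIG_2EM", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2EM_tx1")
  cnv("L-2E-MODERATE", z$chrom, z$b + 11150, z$b + 11161, "LOSS",
      list(`1A` = 0, `2E` = 0.3, `3A` = 0), 0.3, "VUS")

  # in-frame deletion hitting a curated critical region -> PVS1_Strong
  z <- lz(15)
  g("L2EC_tx1", "L2EC", z$chrom, z$b + 10000)
  d("HIG_2EC", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2EC_tx1")
  cr("L2EC_tx1", z$chrom, z$b + 12300, z$b + 12449, "essential domain")
  cnv("L-2E-CRIT", z$chrom, z$b + 12300, z$b + 12347, "LOSS",
      list(`1A` = 0, `2E` = 0.45, `3A` = 0), 0.45, "VUS")

  # in-frame deletion in a region with frequent pathogenic LoF -> NONE
  z <- lz(16)
  g("L2EL_tx1", "L2EL", z$chrom, z$b + 10000)
  d("HIG_2EL", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "L2EL_tx1")
  kv(z$chrom, z$b + 11150, z$b + 11160, "L2EL_tx1", "PATHOGENIC", 0.05)
  cnv("L-2E-LOF", z$chrom, z$b + 11150, z$b + 11197, "LOSS",
      list(`1A` = 0, `2E` = 0, `3A` = 0), 0, "VUS")

  # within an established benign region, identical gene content -> 2F
  z <- lz(17)
  d("BEN_2F", z$chrom, z$b + 10000, z$b + 30000, "BENIGN_LOSS")
  g("L2F_A_tx1", "L2F_A", z$chrom, z$b + 12000)
  cnv("L-2F", z$chrom, z$b + 11000, z$b + 16000, "LOSS",
      list(`2F` = -1), -1, "BENIGN", terminal = TRUE)

  # overlaps a benign region with additional genomic material -> 2G
  z <- lz(18)
  d("BEN_2G", z$chrom, z$b + 10000, z$b + 20000, "BENIGN_LOSS")
  g("L2G_A_tx1", "L2G_A", z$chrom, z$b + 12000)
  g("L2G_B_tx1", "L2G_B", z$chrom, z$b + 22000)
  cnv("L-2G", z$chrom, z$b + 15000, z$b + 28000, "LOSS",
      list(`1A` = 0, `2G` = 0, `3A` = 0), 0, "VUS")

  # predicted-HI gene (pLI 0.95, o/e 0.2, HI index 5) -> 2H
  z <- lz(19)
  g("L2H_tx1", "L2H", z$chrom, z$b + 10000, pli = 0.95, oe_upper = 0.2,
    hi_index = 5)
  cnv("L-2H", z$chrom, z$b + 9000, z$b + 15000, "LOSS",
      list(`1A` = 0, `2H` = 0.15, `3A` = 0), 0.15, "VUS")

  # 25 genes -> 3B; 49 genes -> 3C
  z <- lz(20)
  gene_array("L3B", z$chrom, z$b + 10000, 25)
  cnv("L-3B", z$chrom, z$b + 9000, z$b + 10000 + 24 * 5000 + 4000, "LOSS",
      list(`1A` = 0, `3B` = 0.45), 0.45, "VUS")
  z <- lz(21)
  gene_array("L3C", z$chrom, z$b + 10000, 49)
  cnv("L-3C", z$chrom, z$b + 9000, z$b + 10000 + 48 * 5000 + 4000, "LOSS",
      list(`1A` = 0, `3C` = 0.9), 0.9, "LIKELY_PATHOGENIC")

  # completely within a common population loss (12.45%, 1000 samples) -> 4O
  z <- lz(22)
  pv("PV_4OW", z$chrom, z$b + 10000, z$b + 50000, "LOSS", 0.1245, 1000,
     "SAMPLE_COUNTED")
  g("L4OW_tx1", "L4OW", z$chrom, z$b + 13000)
  cnv("L-4O-within", z$chrom, z$b + 12000, z$b + 20000, "LOSS",
      list(`1A` = 0, `3A` = 0, `4O` = -1), -1, "BENIGN")

  # 50% covered by a common loss, no genes outside it -> 4O
  z <- lz(23)
  pv("PV_4OF", z$chrom, z$b + 10000, z$b + 19999, "LOSS", 0.05, 5000,
     "SAMPLE_COUNTED")
  g("L4OF_tx1", "L4OF", z$chrom, z$b + 15200)
  cnv("L-4O-frac", z$chrom, z$b + 15000, z$b + 24999, "LOSS",
      list(`1A` = 0, `3A` = 0, `4O` = -1), -1, "BENIGN")

  # 49% covered -> 4O cannot be used
  z <- lz(24)
  pv("PV_4ON", z$chrom, z$b + 10000, z$b + 19999, "LOSS", 0.05, 5000,
     "SAMPLE_COUNTED")
  g("L4ON_tx1", "L4ON", z$chrom, z$b + 15200)
  cnv("L-4O-none", z$chrom, z$b + 15100, z$b + 25099, "LOSS",
      list(`1A` = 0, `3A` = 0), 0, "VUS")

  ## ------------------------------------------------------------------ gain
  gz <- function(k) zone(k, "chr2")

  z <- gz(1)
  cnv("G-1B", z$chrom, z$b + 100, z$b + 5000, "GAIN",
      list(`1B` = -0.6, `3A` = 0), -0.6, "VUS")

  # complete overlap of an established TS region -> 2A
  z <- gz(2)
  d("TSR_2A", z$chrom, z$b + 10000, z$b + 20000, "TS_REGION", 3)
  g("G2A_A_tx1", "G2A_A", z$chrom, z$b + 11000)
  g("G2A_B_tx1", "G2A_B", z$chrom, z$b + 15500)
  cnv("G-2A", z$chrom, z$b + 5000, z$b + 25000, "GAIN",
      list(`1A` = 0, `2A` = 1, `3A` = 0), 1.0, "PATHOGENIC")

  # partial overlap of an established TS region -> 2B
  z <- gz(3)
  d("TSR_2B", z$chrom, z$b + 10000, z$b + 30000, "TS_REGION", 3)
  g("G2B_A_tx1", "G2B_A", z$chrom, z$b + 6000)
  cnv("G-2B", z$chrom, z$b + 5000, z$b + 15000, "GAIN",
      list(`1A` = 0, `2B` = 0, `3A` = 0), 0, "VUS")

  # identical gene content to a benign gain -> 2C (terminal)
  z <- gz(4)
  d("BEN_2C", z$chrom, z$b + 10000, z$b + 20000, "BENIGN_GAIN")
  g("G2C_A_tx1", "G2C_A", z$chrom, z$b + 12000)
  cnv("G-2C", z$chrom, z$b + 11000, z$b + 16000, "GAIN",
      list(`2C` = -1), -1, "BENIGN", terminal = TRUE)

  # within a benign gain, no interrupted genes -> 2D (terminal)
  z <- gz(5)
  d("BEN_2D", z$chrom, z$b + 10000, z$b + 20000, "BENIGN_GAIN")
  g("G2D_A_tx1", "G2D_A", z$chrom, z$b + 10500)
  g("G2D_B_tx1", "G2D_B", z$chrom, z$b + 15000)
  cnv("G-2D", z$chrom, z$b + 10400, z$b + 14200, "GAIN",
      list(`2D` = -1), -1, "BENIGN", terminal = TRUE)

  # within a benign gain but potentially interrupting a gene -> 2E
  z <- gz(6)
  d("BEN_2E", z$chrom, z$b + 10000, z$b + 20000, "BENIGN_GAIN")
  g("G2E_A_tx1", "G2E_A", z$chrom, z$b + 12000)
  g("G2E_B_tx1", "G2E_B", z$chrom, z$b + 16000)
  cnv("G-2E", z$chrom, z$b + 11000, z$b + 13000, "GAIN",
      list(`1A` = 0, `2E` = 0, `3A` = 0), 0, "VUS")

  # partial benign-gain overlap, no additional coding genes -> 2F
  z <- gz(7)
  d("BEN_2F", z$chrom, z$b + 10000, z$b + 20000, "BENIGN_GAIN")
  g("G2F_B_tx1", "G2F_B", z$chrom, z$b + 10500)
  g("G2F_A_tx1", "G2F_A", z$chrom, z$b + 15500)
  cnv("G-2F", z$chrom, z$b + 15000, z$b + 25000, "GAIN",
      list(`1A` = 0, `2F` = -1, `3A` = 0), -1, "BENIGN")

  # overlaps a benign gain with additional genomic material -> 2G
  z <- gz(8)
  d("BEN_2Gg", z$chrom, z$b + 10000, z$b + 20000, "BENIGN_GAIN")
  g("G2G_A_tx1", "G2G_A", z$chrom, z$b + 16000)
  g("G2G_C_tx1", "G2G_C", z$chrom, z$b + 22000)
  cnv("G-2G", z$chrom, z$b + 15000, z$b + 30000, "GAIN",
      list(`1A` = 0, `2G` = 0, `3A` = 0), 0, "VUS")

  # HI gene fully contained within the gain -> 2H
  z <- gz(9)
  g("G2H_tx1", "G2H", z$chrom, z$b + 10000)
  d("HIG_G2H", z$chrom, z$b + 10000, z$b + 13599, "HI_GENE", 3, "G2H_tx1")
  cnv("G-2H", z$chrom, z$b + 9000, z$b + 15000, "GAIN",
      list(`1A` = 0, `2H` = 0, `3A` = 0), 0, "VUS")

  # tandem-proven duplication of a frame-shifting exon -> 2I / PVS1 (0.9)
  z <- gz(10)
  g("G2IP_tx1", "G2IP", z$chrom, z$b + 10000,
    exon_lens = c(150, 100, 150, 150))
  d("HIG_G2IP", z$chrom, z$b + 10000, z$b + 13549, "HI_GENE", 3, "G2IP_tx1")
  cnv("G-2I-proven", z$chrom, z$b + 11150, z$b + 11249, "GAIN",
      list(`1A` = 0, `2I` = 0.9, `3A` = 0), 0.9, "LIKELY_PATHOGENIC",
      tandem = "proven")

  # same event, tandem assumed -> 2I / PVS1_Strong (0.45)
  z <- gz(11)
  g("G2IA_tx1", "G2IA", z$chrom, z$b + 10000,
    exon_lens = c(150, 100, 150, 150))
  d("HIG_G2IA", z$chrom, z$b + 10000, z$b + 13549, "HI_GENE", 3, "G2IA_tx1")
  cnv("G-2I-assumed", z$chrom, z$b + 11150, z$b + 11249, "GAIN",
      list(`1A` = 0, `2I` = 0.45, `3A` = 0), 0.45, "VUS",
      tandem = "assumed")

  # same event, tandem status unknown -> 2I contributes 0
  z <- gz(12)
  g("G2IU_tx1", "G2IU", z$chrom, z$b + 10000,
    exon_lens = c(150, 100, 150, 150))
  d("HIG_G2IU", z$chrom, z$b + 10000, z$b + 13549, "HI_GENE", 3, "G2IU_tx1")
  cnv("G-2I-unknown", z$chrom, z$b + 11150, z$b + 11249, "GAIN",
      list(`1A` = 0, `2I` = 0, `3A` = 0), 0, "VUS")

  # genes of no established clinical significance -> 2L
  z <- gz(13)
  g("G2L_tx1", "G2L", z$chrom, z$b + 10000)
  cnv("G-2L", z$chrom, z$b + 9000, z$b + 15000, "GAIN",
      list(`1A` = 0, `2L` = 0, `3A` = 0), 0, "VUS")

  # 35 genes -> 3B; 50 genes -> 3C
  z <- gz(14)
  gene_array("G3B", z$chrom, z$b + 10000, 35)
  cnv("G-3B", z$chrom, z$b + 9000, z$b + 10000 + 34 * 5000 + 4000, "GAIN",
      list(`1A` = 0, `2L` = 0, `3B` = 0.45), 0.45, "VUS")
  z <- gz(15)
  gene_array("G3C", z$chrom, z$b + 10000, 50)
  cnv("G-3C", z$chrom, z$b + 9000, z$b + 10000 + 49 * 5000 + 4000, "GAIN",
      list(`1A` = 0, `2L` = 0, `3C` = 0.9), 0.9, "LIKELY_PATHOGENIC")

  # completely within a common population gain -> 4O
  z <- gz(16)
  pv("PV_G4O", z$chrom, z$b + 10000, z$b + 50000, "GAIN", 0.08, 3000,
     "ALLELE_COUNTED")
  g("G4O_tx1", "G4O", z$chrom, z$b + 13000)
  cnv("G-4O", z$chrom, z$b + 12000, z$b + 20000, "GAIN",
      list(`1A` = 0, `2L` = 0, `3A` = 0, `4O` = -1), -1, "BENIGN")

  ## ------------------------------------------------- printed worked example
  # heterozygous 1.5-Mb deletion: an established HI region is completely
  # spanned and 32 protein-coding genes are contained -> 1A + 2A + 3B = 1.45
  d("nssv1184570", "chr22", 18912231, 20287208, "HI_REGION", 3)
  for (k in 0:31)
    g(sprintf("C1G%02d_tx1", k), sprintf("C1G%02d", k), "chr22",
      18920000 + k * 40000)
  cnv("case1", "chr22", 18761827, 20307561, "LOSS",
      list(`1A` = 0, `2A` = 1, `3B` = 0.45), 1.45, "PATHOGENIC")

  ## seeded filler: decoy genes and rare variants on a spectator chromosome;
  ## placement is jittered by the seed, never used by any suite CNV
  set.seed(seed)
  for (k in 1:8) {
    b <- k * 1e6 + sample.int(5e5, 1)
    g(sprintf("DEC%02d_tx1", k), sprintf("DEC%02d", k), "chr9", b,
      strand = sample(c("+", "-"), 1))
  }
  pv("PV_RARE", "chr9", 2e6, 2.5e6, "LOSS", 0.002, 5000, "SAMPLE_COUNTED")
  pv("PV_SMALLN", "chr9", 4e6, 4.5e6, "LOSS", 0.2, 200, "SAMPLE_COUNTED")
  kv("chr9", 2100000, 2100010, "DEC02_tx1", "OTHER", 0.3)

  list(genes = do.call(rbind, genes),
       dosage = do.call(rbind, dosage),
       popvar = do.call(rbind, popvar),
       variants = do.call(rbind, variants),
       critical = do.call(rbind, critical),
       suite = do.call(rbind, suite),
       expected = expected)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate the synthetic annotation database
#'
#' Writes a complete, deterministic annotation database (multi-exon gene
#' models on both strands, HI/TS and benign regions, common and rare
#' population variants, known variants, critical regions) in the exact TSV
#' layout [load_database()] reads, plus `manifest.json` recording which CNV
#' of the companion suite exercises which scoring branch. Ground truth is
#' placed by construction during generation, never computed by the scoring
#' engine.
#'
#' @param directory Output directory (created if needed).
#' @param seed Seed for decoy-record jitter; identical seeds give
#'   byte-identical output.
#' @return The directory path, invisibly.
#' @export
generate_fixture_db <- function(directory, seed = 1L) {
  plan <- fixture_plan(seed)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  genes <- plan$genes[, c("gene_id", "symbol", "chrom", "start", "end",
                          "strand", "cds_start", "cds_end", "exon_starts",
                          "exon_ends", "coding", "canonical", "pli",
                          "oe_upper", "hi_index", "relevant")]
  write_tsv(genes, file.path(directory, "genes.tsv"))
  write_tsv(plan$dosage, file.path(directory, "dosage.tsv"))
  write_tsv(plan$popvar, file.path(directory, "popvar.tsv"))
  write_tsv(plan$variants, file.path(directory, "variants.tsv"))
  write_tsv(plan$critical, file.path(directory, "critical.tsv"))
  jsonlite::write_json(plan$expected, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Generate the companion CNV suite and its expected outcomes
#'
#' Returns (and optionally writes) a batch TSV with at least one CNV per
#' automated scoring branch for both dosage types, together with the
#' constructively derived expectation for each CNV: the contributing
#' categories with their points, the automated total, the classification
#' and whether a terminal benign category fires.
#'
#' @param directory Optional output directory for `suite.tsv` and
#'   `expected.json`.
#' @param seed Must match the seed of the paired [generate_fixture_db()].
#' @return List with `suite` (data frame) and `expected` (named list).
#' @export
generate_cnv_suite <- function(directory = NULL, seed = 1L) {
  plan <- fixture_plan(seed)
  if (!is.null(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    write_tsv(plan$suite, file.path(directory, "suite.tsv"))
    jsonlite::write_json(plan$expected, file.path(directory, "expected.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(suite = plan$suite, expected = plan$expected)
}
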