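# cnvscore

Semiautomated scoring and five-tier classification of constitutional
copy-number variants (CNVs), for clinical scientists and variant analysts who
interpret deletions and duplications under the 2019 ACMG/ClinGen technical
standards.

## What it does

Interpreting a CNV under the ACMG/ClinGen metric means walking a long
decision tree: 40 evidence categories per dosage type (copy-number loss or
gain), each carrying a signed point value, summed into a total that maps to
one of five clinical tiers. Much of that tree is mechanical — it depends only
on what the CNV overlaps — and `cnvscore` automates exactly that part:
18 loss criteria and 16 gain criteria are scored from local annotation
tables, the remaining case-evidence criteria (literature cases, inheritance,
family history) are merged in from a validated manual-evidence file.

The automated walk is:

1. **Annotation.** The query interval (1-based, fully closed, `chrom:start-end`)
   is intersected (≥ 1 bp) with six local tables: protein-coding gene models
   with exon/CDS structure, ClinGen-style haploinsufficiency (HI) and
   triplosensitivity (TS) curations, established benign regions, population
   CNV frequencies, known (ClinVar-style) variants, and curated critical
   regions.
2. **Scoring.**
   - *Section 1* — genomic content: 0 if the CNV contains protein-coding
     genes or functionally important elements (dosage score 1–3), else −0.60.
   - *Section 2* — dosage-sensitivity tree: complete overlap of an
     established HI gene/region scores 1.0 (loss 2A; gain 2A for TS);
     partial gene overlaps are resolved strand-aware into 5′/3′ branches;
     CNVs fully inside an HI gene are graded by an intragenic
     loss-of-function (PVS1-style) evaluator that computes reading-frame
     disruption, nonsense-mediated-decay (NMD) prediction by the 50-nt
     last-junction rule, and the fraction of protein removed
     (PVS1 → 0.9, PVS1_Strong → 0.45, PVS1_Moderate → 0.3). Benign-region
     containment short-circuits to a final −1.0. When several Section-2
     categories fire, all are reported but only the highest contributes.
   - *Section 3* — gene count: loss 25–34 genes → 0.45, ≥ 35 → 0.9;
     gain 35–49 → 0.45, ≥ 50 → 0.9.
   - *Section 4O* — containment in (or ≥ 50% coverage by) a common
     population variant of the same dosage (frequency ≥ 1%, cohort ≥ 1,000
     samples or ≥ 2,000 alleles) scores −1.0.
3. **Classification.** The total maps to: pathogenic ≥ 0.99; likely
   pathogenic 0.90–0.98; uncertain (VUS) −0.89–0.89; likely benign
   −0.90 – −0.98; benign ≤ −0.99.

A deterministic fixture generator (`generate_fixture_db()` /
`generate_cnv_suite()`) builds a complete synthetic annotation database in
which every automated branch is exercisable offline, with constructively
derived expected scorecards.

## Worked example

```r
library(cnvscore)

dir <- tempfile()
generate_fixture_db(dir)            # synthetic annotation database
db  <- load_database(dir)

card <- score_cnv(parse_cnv("chr22:18,761,827-20,307,561", "LOSS"), db)
print(card)
```

```
CNV chr22:18761827-20307561 (LOSS)  [build GRCh37]
evidence:
  1A      0.00 * [AUTOMATED] contains 32 protein-coding gene(s) and functionally important element(s)
  2A      1.00 * [AUTOMATED] completely spans established HI gene(s)/region(s)
  3B      0.45 * [AUTOMATED] 32 protein-coding gene(s)
automated total: 1.45 (PATHOGENIC); sufficient without manual review
final total:     1.45 (PATHOGENIC)
```

The 1.5-Mb deletion spans protein-coding genes (category 1A, 0 points),
completely contains an established HI region (2A, 1.0) and holds 32
protein-coding genes (3B, 0.45); the 1.45 total crosses the 0.99 pathogenic
threshold before any manual review, so the report flags the automated
pre-classification as already sufficient.

Manual evidence merges the same way:

```r
card <- score_cnv(q, db, manual = data.frame(category = "4N", points = -0.9))
```

A command-line wrapper lives at `inst/cli/cnvscore`
(`score`, `batch`, `make-fixtures`, `validate-db`, `show-metric`).

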