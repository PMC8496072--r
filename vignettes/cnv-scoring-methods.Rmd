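---
title: "Methods: automated evidence scoring for copy-number variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated evidence scoring for copy-number variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscore)
```

## The scoring model

`cnvscore` implements the evidence-point framework of the 2019 ACMG/ClinGen
technical standards for constitutional CNVs. Each dosage type (copy-number
loss, copy-number gain) has 40 evidence categories; every category carries a
default point value and a permissible range, the signed points are summed,
and the total maps to a five-tier classification through fixed thresholds:

* pathogenic: total ≥ 0.99
* likely pathogenic: 0.90 ≤ total < 0.99
* uncertain significance: −0.90 < total < 0.90
* likely benign: −0.99 < total ≤ −0.90
* benign: total ≤ −0.99

The published bands are printed at a resolution of 0.01 points
("0.90 to 0.98", "−0.89 to 0.89", …). We state them as thresholds so the
mapping is total over the reals and reproduces every printed value; a total
falling strictly between two printed band edges (possible only with
non-standard manual points) falls to the lower band. Totals are accumulated
as integer hundredths internally, so band-edge comparisons are exact and
never subject to binary floating-point drift (three items of 0.33 sum to
exactly 0.99, not 0.9899…).

The engine automates the 18 loss and 16 gain criteria that depend only on
genomic content: Sections 1 (genomic content), 2 (dosage-sensitivity and
benign-region relations), 3 (protein-coding gene count) and category 4O
(common population variation). The remaining case-evidence categories
(4A–4N, the Section-5 inheritance series, and the gain 2J/2K
phenotype-dependent branches) are accepted as pre-assessed manual evidence,
validated against the shipped metric configuration.

## Assumptions and operationalisations

Several of the standards' criteria are stated qualitatively; the package
fixes them as follows.

**Established versus functionally important elements.** A curated dosage
element with score 1, 2 or 3 counts as a *functionally important element*
for Section 1. For the Section-2 "established" gates (2A, the 2C/2D/2E
branches) only elements at score 3 — the ClinGen "sufficient evidence"
level — qualify; emerging-evidence curations (1, 2) do not trigger
pathogenic point assignment. The cutoff is exposed as
`min_established_score` in `default_thresholds()`.

**5′/3′ partial overlap.** Operationalised on the transcript span,
strand-aware: a CNV covering the transcription start but not the
transcription end is a 5′-end overlap, and vice versa; for minus-strand
genes the genomic sense reverses. Exon ordinals are reported in
transcription order so "the last exon" is well defined on both strands.

**The 3′-UTR-only branch.** The loss tree's 3′-end evaluation distinguishes
last-exon deletions with and without documented pathogenic variants, but is
silent on deletions confined to the 3′ untranslated region. We emit these
as a 0-point category `2D-1` (flagged "assumed" in the rationale) so the
report is explicit rather than silent.

**NMD prediction.** A frameshifting intragenic deletion is predicted to
trigger nonsense-mediated decay iff the premature termination codon lies at
least 50 nt upstream of the last exon–exon junction of the selected
transcript; single-exon (or single-remaining-fragment) transcripts never
NMD. Because no nucleotide sequence is modelled, the premature stop is
approximated at the deletion junction itself — a deliberate, conservative
convention applied identically in the package and in the brute-force
reconstruction oracle used by the tests. Tandem duplications are evaluated
on the reconstructed tandem transcript with the stop taken at the junction
between the two copies; exon fragments made genomically adjacent by the
event are fused (no junction), fragments still separated by retained intron
are not.

**Protein-fraction rule.** For in-frame (or NMD-escaping) intragenic
deletions with unknown functional impact, more than 10% of coding sequence
removed grades PVS1_Strong (0.45), otherwise PVS1_Moderate (0.3); exactly
10% takes the moderate branch. The altered region is the exact coding-base
intersection of the CNV with the selected transcript, so adding UTR or
intron bases to the CNV never changes the fraction.

**Transcript selection.** For loci with several transcript models the
canonical flag wins, then the longest coding sequence, then the longest
span, then the lexicographically smallest identifier.

**Frequent loss-of-function.** "LoF variants in the region are not frequent"
has no published cutoff; we require no known pathogenic/likely-pathogenic
variant with allele frequency ≥ 0.001 inside the altered region
(`lof_frequent_af`).

**Common population variation.** Frequency ≥ 1% with cohort ≥ 1,000 samples
(sample-counted sources) or ≥ 2,000 alleles (allele-counted sources), same
dosage as the query. Category 4O fires on complete containment, or on
≥ 50% coverage of the CNV when no protein-coding gene lies outside the
variant.

**Single winner and terminal benign.** All Section-2 categories that fire
are recorded, but only the highest-scoring one contributes points. Benign
containment (loss 2F; gain 2C and 2D) terminates evaluation with a final
total of exactly −1.0 — but only when no positive Section-2 evidence fired;
a CNV that simultaneously spans an established HI region and sits inside a
curated benign region is contradictory input, so the positive evidence wins
and the benign item is kept as a flagged conflict rather than silently
short-circuiting. The gain tree's 2C/2D wording does not declare finality
the way the loss 2F branch does; we mirror the loss behaviour because a
benign floor of −1 combined with gene-count points would otherwise let a
"same as a benign gain" duplication drift out of the benign band.

**Gain CNVs over uncurated genes.** Duplications overlapping genes with no
ClinGen dosage curation score 0 (category 2L), with a note that Section-4
literature evidence is the intended route to points — this includes
disease-associated genes that simply have not been dosage-curated.

**Overlap convention.** All collections use ≥ 1 bp overlap on 1-based,
fully-closed coordinates; a BED reader converts 0-based half-open input on
load. Chromosome labels are normalised (`22` ≡ `chr22`). The genome build
is an echoed label only; coordinates are never validated against a
sequence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_frequency` | 0.01 | population-variant commonness threshold (fraction) |
| `min_samples` / `min_alleles` | 1000 / 2000 | cohort floors by source kind |
| `pli_min`, `oe_upper_max`, `hi_index_max` | 0.9, 0.35, 10 | predicted-HI gene triple (all three required on one gene) |
| `pathogenic_af_max` | 0.01 | allele-frequency ceiling for an "established" pathogenic variant |
| `lof_frequent_af` | 0.001 | allele frequency at which regional LoF counts as frequent |
| `min_established_score` | 3 | dosage score treated as established curation |
| `adjustment_step` | 0.05 | granularity of manual up/down adjustment from a default |

The full category table (defaults, ranges, automation flags) ships as
`inst/extdata/metric_config.tsv` and is data: reviewable and overridable
without code changes. Manual points must sit inside the category's range
and, in strict mode, differ from the default by a whole multiple of the
adjustment step.

## What the synthetic data emulates

`generate_fixture_db()` lays out a complete annotation database in isolated
1-Mb zones, one per scoring branch: multi-exon genes on both strands with
realistic exon/intron structure (150-bp exons, 1-kb introns, 100-bp UTRs),
curated HI/TS and benign elements, common (12.45%, 5%, 8%) and
disqualified (rare, small-cohort) population variants, known pathogenic
variants and a curated critical region, plus a replica of the published
chr22 worked example (HI region chr22:18,912,231–20,287,208 with 32
contained protein-coding genes). `generate_cnv_suite()` pairs it with 41
CNVs — at least one per automated branch and dosage — whose expected
scorecards are written down constructively from the placed geometry, never
computed by the engine under test.

The generator does **not** emulate: sequence content (so no true stop-codon
location, only the junction convention above), overlapping or nested real
gene architecture, segmental duplications and repeats at breakpoints,
multi-transcript loci in the shipped database (transcript selection is
exercised in unit tests), or realistic genome-wide gene density. Passing
the suite therefore demonstrates that the decision tree, the interval
algebra and the point arithmetic are correct — not that any external
annotation source is faithfully reproduced.

## Numerical and degenerate-input choices

* Totals in integer hundredths; classification thresholds compared exactly.
* Interval queries are served by a GenomicRanges index and are checked
  against a brute-force linear scan (1,000 seeded random queries in the
  test suite); ties are broken by (chromosome, start, end, id) so output is
  deterministic across runs and platforms.
* A query on a chromosome absent from the database returns an empty result,
  not an error; abutting intervals (query end + 1 = record start) do not
  overlap.
* Zero-length problems degrade explicitly: a CNV with no coding-base
  intersection never grades by protein fraction; an empty transcript set is
  a contract violation, not a silent `NA`.
* Batch scoring isolates per-row failures in a status column and preserves
  input order; reruns are byte-identical.

## Problem sizes in the shipped tests

The default test run uses the 41-CNV suite, 1,000 random interval queries
against the fixture database, 200 random intragenic deletions for the
NMD/frame oracle comparison, 40 mirrored gene models for the strand-symmetry
property and a 301-step sweep of the classification bands — sizes chosen so
the whole suite exercises every branch and property in about a minute on a
single core.

## Known limitations

* No sequence-level consequence prediction: splice-site disruption,
  stop-gain position, and protein-domain effects beyond the curated
  critical-region table are out of scope.
* Phenotype matching (gain 2J/2K, Section 4 case evidence, Section 5) is
  the user's judgement; the engine only validates and merges the points.
* Breakpoint-containing duplications with unknown tandem status contribute
  0 through 2I and defer to manual review.
* The genome build is not verified; mixed-build inputs are the user's
  responsibility.
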