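dosage	category	default	min	max	automated	description
LOSS	1A	0	0	0	1	Contains protein-coding genes or known functionally important elements
LOSS	1B	-0.6	-0.6	-0.6	1	Does not contain protein-coding genes or known functionally important elements
LOSS	2A	1	1	1	1	Complete overlap of an established HI gene or genomic region
LOSS	2B	0	0	0	1	Partial overlap of an established HI genomic region not involving known HI genes
LOSS	2C-1	0.9	0.45	1	1	Partial 5' overlap of an established HI gene involving coding sequence
LOSS	2C-2	0	0	0.45	1	Partial 5' overlap of an established HI gene not involving coding sequence
LOSS	2D-1	0	0	0	1	Partial 3' overlap involving only the 3' untranslated region
LOSS	2D-2	0.9	0.45	0.9	1	Partial 3' overlap of only the last exon with established pathogenic variants in that exon
LOSS	2D-3	0.3	0	0.45	1	Partial 3' overlap of only the last exon without established pathogenic variants
LOSS	2D-4	0.9	0.45	0.9	1	Partial 3' overlap involving the last exon and other exons
LOSS	2E	0.9	0	0.9	1	Both breakpoints within the same HI gene; points per loss-of-function (PVS1) evaluation
LOSS	2F	-1	-1	0	1	Completely contained within an established benign region or identical protein-coding gene content
LOSS	2G	0	0	0	1	Overlaps an established benign region but includes additional genomic material
LOSS	2H	0.15	0	0.15	1	Involves at least one gene meeting the predicted-haploinsufficiency thresholds (pLI, o/e, HI index)
LOSS	3A	0	0	0	1	0-24 protein-coding genes
LOSS	3B	0.45	0.45	0.45	1	25-34 protein-coding genes
LOSS	3C	0.9	0.9	0.9	1	35 or more protein-coding genes
LOSS	4A	0.45	0	0.45	0	Confirmed de novo case with highly specific, consistent phenotype (per case)
LOSS	4B	0.3	0	0.45	0	Confirmed de novo case with consistent but nonspecific phenotype (per case)
LOSS	4C	0.15	0	0.45	0	Case with consistent phenotype, inheritance unknown (per case)
LOSS	4D	-0.3	-0.45	0	0	Reported cases with inconsistent phenotypes (per case)
LOSS	4E	0.1	0	0.45	0	Case with unknown phenotype and unknown inheritance (per case)
LOSS	4F	0.15	0	0.45	0	Segregation among 3-4 similarly affected family members
LOSS	4G	0.3	0	0.45	0	Segregation among 5-6 similarly affected family members
LOSS	4H	0.45	0	0.45	0	Segregation among 7 or more similarly affected family members
LOSS	4I	-0.45	-0.9	0	0	Non-segregation with a highly specific phenotype
LOSS	4J	-0.3	-0.9	0	0	Non-segregation with a nonspecific phenotype
LOSS	4K	-0.15	-0.3	0	0	Presence in an unaffected or mildly affected relative
LOSS	4L	0.45	0	0.45	0	Statistically significant excess among cases in case-control studies
LOSS	4M	-0.45	-0.9	0	0	No statistically significant difference between cases and controls
LOSS	4N	-0.9	-0.9	0	0	Statistically significant excess among controls
LOSS	4O	-1	-1	0	1	Overlap with common population variation of the same dosage
LOSS	5A	0	0	0.45	0	De novo observation in the patient; use case-evidence (4A-4D) guidance
LOSS	5B	-0.3	-0.45	0	0	Inherited from an apparently unaffected parent
LOSS	5C	0.15	0	0.45	0	Segregation with a consistent phenotype in the patient's family
LOSS	5D	0.3	0	0.45	0	Segregation with a highly specific phenotype in the patient's family
LOSS	5E	-0.45	-0.45	0	0	Non-segregation in the patient's family
LOSS	5F	0	0	0.15	0	Inheritance information unavailable or uninformative
LOSS	5G	0.1	0	0.45	0	Uninformative inheritance, phenotype consistent with the region
LOSS	5H	0.3	0	0.45	0	Uninformative inheritance, highly specific phenotype
GAIN	1A	0	0	0	1	Contains protein-coding genes or known functionally important elements
GAIN	1B	-0.6	-0.6	-0.6	1	Does not contain protein-coding genes or known functionally important elements
GAIN	2A	1	1	1	1	Complete overlap of an established TS gene or genomic region
GAIN	2B	0	0	0	1	Partial overlap of an established TS genomic region not involving known TS genes
GAIN	2C	-1	-1	0	1	Identical in protein-coding gene content to an established benign copy-number gain
GAIN	2D	-1	-1	0	1	Smaller than an established benign gain, breakpoints not interrupting protein-coding genes
GAIN	2E	0	0	0.45	1	Smaller than an established benign gain, breakpoints potentially interrupting protein-coding genes
GAIN	2F	-1	-1	0	1	Larger than an established benign gain without additional protein-coding genes
GAIN	2G	0	0	0.45	1	Overlaps an established benign gain with additional genomic material
GAIN	2H	0	0	0	1	HI gene fully contained within the gain
GAIN	2I	0	0	0.9	1	Both breakpoints within the same HI gene; points per tandem loss-of-function (PVS1) evaluation
GAIN	2J	0	0	0.45	0	One breakpoint within an established HI gene, patient phenotype inconsistent or nonspecific
GAIN	2K	0.45	0	0.45	0	One breakpoint within an established HI gene, patient phenotype highly specific
GAIN	2L	0	0	0	1	Overlaps gene(s) of no established clinical significance
GAIN	3A	0	0	0	1	0-34 protein-coding genes
GAIN	3B	0.45	0.45	0.45	1	35-49 protein-coding genes
GAIN	3C	0.9	0.9	0.9	1	50 or more protein-coding genes
GAIN	4A	0.45	0	0.45	0	Confirmed de novo case with highly specific, consistent phenotype (per case)
GAIN	4B	0.3	0	0.45	0	Confirmed de novo case with consistent but nonspecific phenotype (per case)
GAIN	4C	0.15	0	0.45	0	Case with consistent phenotype, inheritance unknown (per case)
GAIN	4D	-0.3	-0.45	0	0	Reported cases with inconsistent phenotypes (per case)
GAIN	4E	0.1	0	0.45	0	Case with unknown phenotype and unknown inheritance (per case)
GAIN	4F	0.15	0	0.45	0	Segregation among 3-4 similarly affected family members
GAIN	4G	0.3	0	0.45	0	Segregation among 5-6 similarly affected family members
GAIN	4H	0.45	0	0.45	0	Segregation among 7 or more similarly affected family members
GAIN	4I	-0.45	-0.9	0	0	Non-segregation with a highly specific phenotype
GAIN	4J	-0.3	-0.9	0	0	Non-segregation with a nonspecific phenotype
GAIN	4K	-0.15	-0.3	0	0	Presence in an unaffected or mildly affected relative
GAIN	4L	0.45	0	0.45	0	Statistically significant excess among cases in case-control studies
GAIN	4M	-0.45	-0.9	0	0	No statistically significant difference between cases and controls
GAIN	4N	-0.9	-0.9	0	0	Statistically significant excess among controls
GAIN	4O	-1	-1	0	1	Overlap with common population variation of the same dosage
GAIN	5A	0	0	0.45	0	De novo observation in the patient; use case-evidence (4A-4D) guidance
GAIN	5B	-0.3	-0.45	0	0	Inherited from an apparently unaffected parent
GAIN	5C	0.15	0	0.45	0	Segregation with a consistent phenotype in the patient's family
GAIN	5D	0.3	0	0.45	0	Segregation with a highly specific phenotype in the patient's family
GAIN	5E	-0.45	-0.45	0	0	Non-segregation in the patient's family
GAIN	5F	0	0	0.15	0	Inheritance information unavailable or uninformative
GAIN	5G	0.1	0	0.45	0	Uninformative inheritance, phenotype consistent with the region
GAIN	5H	0.3	0	0.45	0	Uninformative inheritance, highly specific phenotype
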