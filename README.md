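# plascheck

De novo sequence verification of small circular plasmids from Illumina
paired-end reads, with reference-agnostic contamination detection.

plascheck is aimed at labs that sequence-verify plasmid preps (cloning QC,
synthetic-biology part verification, strain construction) and want a
machine-checkable answer to two questions without assuming a reference:

1. Does this library assemble into exactly one circular contig — and, if a
   reference is available, is it the intended sequence?
2. Do the reads themselves suggest a second plasmid is hiding in the prep?

## Method

**Filtering.** Illumina runs give small plasmids enormous coverage
(thousands-fold), which degrades de novo assembly. plascheck keeps a read
pair only when *both* mates have mean Phred quality >= 36 and length >= 125
nt (or, alternatively, keeps the top fraction of pairs ranked by the worse
mate), then caps nominal coverage `n · 2L_read / L_plasmid` at 500x by
random subsampling.

**Assembly.** A de Bruijn graph on canonical k-mers (k = 31, counts >= 3)
is cleaned — tips clipped, bubbles popped in favour of the deeper branch,
whole components with median depth below 0.15x the dominant component's
median discarded — and compacted. A unitig whose end (k-1)-mer links back
to its start is a circular contig, reported with the redundant overlap
removed.

**Verification.** Circular sequences are compared up to rotation and
strand via the canonical form

    canon(s) = min over rotations of { s, revcomp(s) }

(Booth's least-rotation algorithm). The assembly is classified as
CORRECT_PRIMARY / MATCHES_CONTAMINANT / MISMATCH / FRAGMENTED /
NO_ASSEMBLY.

**Contamination statistic.** Every *distinct* filtered read string is
exactly back-mapped to the assembly (either strand, matches across the
circular origin allowed). With the mismatch percentage
`m = 100 · (1 − n_matched / n_distinct)`, the contamination probability is
a logistic calibration

    P(contaminated) = logistic(α + β·m),  β >= 0

trained on clean vs contaminated simulation cohorts (refit with
`plascheck calibrate` for your own error regime).

## Worked example

Simulate a 2521 bp plasmid sequenced at ~500x with 20% of read pairs
spiked in from a contaminant that differs by one SNP, then run the full
pipeline:

```r
library(plascheck)

primary     <- generatePlasmid(2521, gc = 0.5, seed = 1)
contaminant <- applyVariant(primary, variantSpec("snp", nSnps = 1, seed = 2))
em     <- errorModel()   # 150 nt pairs, 300+/-30 bp inserts, 0.1% errors
reads  <- simulateReads(primary, 4200, em, seed = 3)
spike  <- simulateReads(contaminant, 4200, em, seed = 4,
                        provenanceLabel = "contaminant")
sample <- mixReads(reads, spike, fraction = 0.2, totalPairs = 4200, seed = 5)
sample
#> ReadSet 'plasmid_s1+plasmid_s1_snp': 4200 read pairs
#>   provenance: contaminant=840, primary=3360
#>   read lengths: 150-150 nt

res <- runVerifyPipeline(sample,
                         fp = filterParams(plasmidLenEstimate = 2521L),
                         primaryRef = primary, seed = 6)
res$assembly
#> AssemblyResult: 1 contig(s) (k=31, 5894 reads used)
#>   contig_1: 2521 bp, circular, mean depth 271.7
res$report
#> ContaminationReport: 3172/4021 distinct reads matched (mismatch 21.11%)
#>   contamination probability 0.771 (calibration 'default-sim-v1')
res$outcome
#> [1] "CORRECT_PRIMARY"
```

Reading the output: strict filtering kept 2947 of 4200 pairs; the graph
cleanly absorbed the SNP contaminant (its bubble branch has ~25% of the
primary branch's depth and is popped), so the single circular contig is
exactly the primary plasmid. The back-mapping statistic still sees the
contamination: 21.1% of distinct reads fail to map, above the clean
baseline of this error regime (~20.2%), and the calibrated probability
flags the sample at 0.77. The same library without the spike scores a
mismatch of 20.3% and a probability of 0.09.

The same pipeline is available from the shell (see
`inst/scripts/plascheck`): `plascheck verify R1.fastq R2.fastq --reference
ref.fasta` writes `assembly.fasta` plus a JSON report and exits 0 on a
single-contig assembly, 3 on a fragmented one; `plascheck simulate`,
`calibrate` and `generate` drive the experiment harness, calibration
training and fixture generation.

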