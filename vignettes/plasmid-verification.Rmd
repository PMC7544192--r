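---
title: "Verifying plasmid sequences de novo and detecting contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying plasmid sequences de novo and detecting contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Routine cloning and gene-synthesis workflows need to confirm that a plasmid
preparation contains exactly the intended circular sequence — no point
mutations, no indels, and no second plasmid hiding in the prep. Illumina
paired-end sequencing of a small plasmid yields enormous coverage (often
thousands-fold), which paradoxically *hurts* de novo assembly: error k-mers
accumulate until they masquerade as real sequence, and assemblers start
emitting multiple contigs. plascheck implements a verification pipeline
built around that observation:

1. **Strict quality filtering.** Keep only read pairs where *both* mates
   have a mean Phred quality at or above a threshold (default Q36) and a
   minimum length (default 125 nt). On real libraries with broad quality
   distributions this retains only a few percent of raw pairs; the retained
   reads do double duty later as the contamination probe.
2. **Coverage capping.** If nominal coverage still exceeds a target
   (default 500x), pairs are randomly subsampled down to it.
3. **De Bruijn assembly.** A canonical-k-mer graph (default k = 31) is
   cleaned (tips, bubbles, shallow components) and compacted; a unitig that
   closes on itself is a circular contig, reported once with the redundant
   k-1 overlap removed and in canonical rotation.
4. **Verification.** The assembly is compared to an optional reference in a
   rotation- and strand-invariant way, and — reference-free — every
   distinct filtered read is exactly back-mapped to the assembly. The
   percentage of distinct reads that fail to map is the contamination
   statistic, converted to a probability by a logistic calibration.

A correct verification means exactly one circular contig that is
`circularEqual` to the intended sequence; more than one contig
(a *fragmented* assembly) is a machine-checkable QC failure (shell exit
code 3 from `plascheck verify`).

## Circular sequence comparison

Assemblies of circular molecules have arbitrary starting position and
strand. Two circular sequences are considered identical when the
lexicographically smallest rotation over both strands (Booth's
least-rotation algorithm, applied to the sequence and its reverse
complement) coincides:

```{r, eval = FALSE}
canonicalRotation("GAAC")           # "AACG"
circularEqual("ATGGCGTA", "CGTAATGG")  # TRUE (rotation by 4)
```

When a rotation of the sequence ties with a rotation of its reverse
complement, that shared string is the canonical form and no strand flag is
kept; only equality semantics are needed. Sequences containing `N` are
rejected by canonicalization — exact string matching has no ambiguity
logic — and reads containing `N` simply never match in back-mapping.

Back-mapping treats circular contigs as circles: the contig is extended by
the read length minus one so matches spanning the assembly origin count.

## The read simulator: what it emulates, and what it does not

The synthetic-data generator reproduces the experimental regime the
pipeline was validated for: circular plasmids of 2.5–3.3 kb, paired 150 nt
reads at several-hundred-fold coverage, contaminant plasmids differing by
1–4 SNPs, a 608 bp indel, or wholly unrelated sequence, and contaminant
read fractions up to 50%.

* Fragment starts are uniform on the circle (origin coverage unbiased,
  which also exercises circular matching); insert lengths are Gaussian
  (default 300 +/- 30 bp) clamped to `[readLen, plasmidLen]`.
* Per-read quality is a two-class mixture: a pair is "good" (mean Phred 38)
  or "bad" (mean 20) with default bad fraction 0.3; per-base scores are
  drawn around the class mean (sd 3, clamped to [2, 41]). The class is
  drawn **per pair**, not per mate: on real instruments mate qualities are
  strongly correlated, and pair-level filtering then retains approximately
  the good fraction — with a 93% bad fraction, the retained few percent
  reproduce the stringent-filtering regime the pipeline targets.
* Sequencing errors are substitutions only, applied per base with
  probability `max(baseErrorRate, 10^(-q/10))` (default floor 0.1%).
  Setting `baseErrorRate = 0` disables substitutions entirely; this exact
  error-free limit is what reconstruction tests rely on.

Deliberately not emulated: PCR/optical duplicates, adapter read-through,
position-dependent quality decay, indel sequencing errors, and repeat-rich
plasmids. Passing simulation tests therefore demonstrates the pipeline's
behaviour under substitution-dominated Illumina noise on repeat-free
plasmids; plasmids carrying repeats longer than the reads can defeat any
short-read assembler, this one included.

## Assembler internals and numerical choices

* **Single fixed k (31).** Plasmid-scale targets at capped coverage
  assemble reliably at one k; a multi-k scheme would add complexity without
  testable benefit. `autoK()` lowers k for short-read inputs (largest odd
  value below the shortest read, floor 15). k must be odd so no k-mer is
  its own reverse complement.
* **`minKmerCount = 3`.** At a few hundred-fold coverage, genuine k-mers
  appear hundreds of times while almost all error k-mers are singletons or
  doubletons.
* **Tips and bubbles.** Dead-end unitigs up to `2k` bases are clipped.
  Parallel unitigs sharing both endpoints form a bubble; the branch with
  the higher mean depth wins (ties: lexicographically smaller sequence).
  Because bubbles are detected on the *compacted* graph, the same rule
  absorbs both SNP bubbles (branch length about k) and the long/short
  branch pair left by a large indel between primary and contaminant.
* **Erroneous-connection removal.** Recurrent sequencing errors — the same
  substitution drawn several times at one position, expected about once per
  few-hundred-fold-coverage run — can pass the count floor and form
  depth-~3 branches; when two of them interlock within k bases neither is
  a simple bubble and popping deadlocks. A non-cycle unitig whose mean
  depth falls below 5% of the deepest unitig sharing one of its endpoints
  is therefore removed. The 5% ratio sits well below the shallowest branch
  the pipeline must preserve for bubble adjudication (a 10% contaminant
  branch has ~11% relative depth).
* **Component depth floor (`relDepthFloor = 0.15`).** An unrelated
  contaminant forms its own connected component. Its median k-mer depth
  relative to the dominant component's median equals roughly
  `f / (1 - f)` at contaminant fraction `f` — about 0.11 at 10%. The floor
  is set at 0.15 so a 10% unrelated contaminant is reliably discarded
  while a 20% one (relative depth about 0.25) is kept and correctly
  surfaces as a fragmented, QC-failing assembly. A floor at or below 0.11
  would keep the 10% component and misreport clean-looking samples as
  fragmented.
* **Determinism.** All traversal orders and tie-breaks are by lexicographic
  k-mer order, so identical inputs give byte-identical FASTA/JSON/TSV
  outputs under a fixed seed.
* **Degenerate inputs.** A graph that empties after pruning yields a
  zero-contig result (`NO_ASSEMBLY`), not an error; reads shorter than k
  contribute nothing; `N` bases break k-mer windows.

Paired-end information is not used for scaffolding: reads enter the graph
as single-end sequences. At k = 31 this only matters for repeats longer
than k, which are rare in small plasmids and are a documented limitation.

## Filtering design

Whole pairs are kept or dropped; there is no per-base trimming. Mean-read
quality filtering with a pair-level gate reproduces the downstream effect
of conventional trimming pipelines — a small, high-quality, synchronized
read subset — with a fully specified, testable contract. The default
threshold Q36 sits just below the mean-quality range observed for
successfully filtered libraries in the validated regime, and a
`topFraction` mode keeps the best `ceiling(fraction * n)` pairs instead
when an explicit retention rate is wanted.

## Contamination statistic and calibration

The statistic is the percentage of *distinct* filtered read strings (each
mate a separate string; a read and its reverse complement count as distinct
strings, since matching already checks both strands) that fail to map
exactly anywhere on the assembly. Deduplication matters: with a fixed
plasmid and high coverage, correct reads collapse into at most
`plasmidLen` distinct strings while error-bearing reads are almost all
unique, so the statistic responds sharply to anything that should not be in
the library. Against fragmented assemblies reads are matched against the
union of all contigs.

The mapping from mismatch percentage to a contamination *probability* is a
deliberately simple logistic regression on the single statistic, with the
slope constrained non-negative so the probability is monotone in the
statistic. The packaged default model (`defaultCalibration()`, id
`default-sim-v1`) is fitted from a synthetic, simulation-derived training
table shipped as plain text (`inst/extdata/calibration_scores_synthetic.tsv`,
generated by `makeCalibrationScores()` under a fixed seed: 60 clean and 60
20%-single-SNP-contaminated pipeline runs). Absolute mismatch levels depend
on the error regime — the simulator's defaults give clean baselines around
20%, higher than the ~12% typical of real filtered libraries, because the
distinct-read denominator and the error profile differ — so the calibration
should be refitted (`plascheck calibrate`) when read length, error rate or
filtering settings change materially. What is robust across regimes, and
what the tests assert, is the *separation*: contaminated runs score higher
than clean ones (ROC AUC around 0.9 for a 20% single-SNP contaminant).

## Simulation harness and problem sizes

`runContaminationExperiment()` is the machine twin of a contamination
spiking experiment: per replicate it generates a primary plasmid (length
uniform in 2521–3294 bp, GC 0.5), derives the contaminant, simulates both
libraries at 500x nominal coverage, mixes at the requested fraction,
filters, caps coverage, assembles, classifies, and back-maps. The package's
validation suite runs 100 replicates per condition and 100 runs per class
for the ROC — enough for percentage estimates with a few points of binomial
noise while keeping a full run on a laptop-class single core in the
ten-minute range. Replicate failures are tallied separately rather than
being folded into the fragmented count. The harness seeds every stage from
a single base seed, so summaries are bit-reproducible.

## Known limitations

* Repeats longer than k fragment the assembly; there is no repeat
  resolution, scaffolding or polishing.
* The contamination detector reports *that* reads fail to map, not which
  contaminant they came from, and it cannot see contamination once the
  contaminant reads dominate (the assembly then simply becomes the
  contaminant or fragments).
* Calibration transfers poorly across error regimes (see above); the
  probability is only as good as the training cohort.
* Exact matching means a single sequencing error anywhere in a read
  removes it from the matched set; the statistic is a library-level signal,
  not a per-read classifier.
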