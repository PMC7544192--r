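# S4 classes for the plasmid verification pipeline. Sequences are stored as
# plain uppercase character strings over {A,C,G,T,N}; coordinates are never
# exchanged across module boundaries, only sequences.

.valid_dna <- function(x) all(grepl("^[ACGTN]+$", x))

#' PlasmidRecord: a named circular (or linear) DNA sequence
#'
#' Container for a plasmid sequence, typically the simulation ground truth or
#' an optional reference used for assembly classification.
#'
#' @slot id single non-empty identifier.
#' @slot seq uppercase DNA string over \code{A,C,G,T,N}.
#' @slot circular logical; plasmids are circular.
#' @export
setClass("PlasmidRecord",
  representation(id = "character", seq = "character", circular = "logical"),
  prototype(circular = TRUE),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a single non-empty string")
    if (length(object@seq) != 1L || nchar(object@seq) < 1L)
      msg <- c(msg, "seq must be a single string of length >= 1")
    else if (!.valid_dna(object@seq))
      msg <- c(msg, "seq may contain only A,C,G,T,N (uppercase)")
    if (length(object@circular) != 1L || is.na(object@circular))
      msg <- c(msg, "circular must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PlasmidRecord
#'
#' @param id identifier.
#' @param seq DNA sequence (coerced to uppercase).
#' @param circular logical, default \code{TRUE}.
#' @return A [PlasmidRecord-class] object.
#' @examples
#' plasmidRecord("p1", "acgtacgt")
#' @export
plasmidRecord <- function(id, seq, circular = TRUE) {
  new("PlasmidRecord", id = as.character(id), seq = toupper(as.character(seq)),
      circular = as.logical(circular))
}

#' ReadSet: paired reads with qualities and provenance labels
#'
#' Ordered collection of read pairs. Qualities are stored Phred+33 encoded;
#' provenance records whether a pair came from the primary or a contaminant
#' library in simulations (\code{"unknown"} for real data).
#'
#' @slot pairId per-pair identifiers.
#' @slot r1,r2 read sequences (uppercase \code{A,C,G,T,N}).
#' @slot q1,q2 Phred+33 quality strings, same lengths as the sequences.
#' @slot provenance one of \code{"primary"}, \code{"contaminant"},
#'   \code{"unknown"} per pair.
#' @slot sourceId single label for the set's origin.
#' @export
setClass("ReadSet",
  representation(pairId = "character", r1 = "character", r2 = "character",
                 q1 = "character", q2 = "character", provenance = "character",
                 sourceId = "character"),
  prototype(sourceId = "readset"),
  validity = function(object) {
    n <- length(object@pairId)
    msg <- character()
    if (any(lengths(list(object@r1, object@r2, object@q1, object@q2,
                         object@provenance)) != n))
      msg <- c(msg, "all per-pair slots must have equal length")
    else if (n > 0L) {
      if (!.valid_dna(object@r1) || !.valid_dna(object@r2))
        msg <- c(msg, "read sequences may contain only A,C,G,T,N")
      if (any(nchar(object@q1) != nchar(object@r1)) ||
          any(nchar(object@q2) != nchar(object@r2)))
        msg <- c(msg, "quality string length must equal sequence length")
      # Phred values in [0, 41] <=> characters '!'..'J'
      if (!all(grepl("^[!-J]+$", object@q1)) ||
          !all(grepl("^[!-J]+$", object@q2)))
        msg <- c(msg, "Phred qualities must be in [0, 41] (Phred+33 '!'..'J')")
      if (!all(object@provenance %in% c("primary", "contaminant", "unknown")))
        msg <- c(msg, "provenance must be primary/contaminant/unknown")
    }
    if (length(object@sourceId) != 1L)
      msg <- c(msg, "sourceId must be a single string")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ReadSet
#'
#' @param r1,r2 character vectors of read sequences.
#' @param q1,q2 Phred+33 quality strings (same lengths as the sequences).
#' @param pairId optional pair identifiers (defaults to \code{pair_1 ...}).
#' @param provenance per-pair labels, recycled; default \code{"unknown"}.
#' @param sourceId label for the set.
#' @return A [ReadSet-class] object.
#' @export
readSet <- function(r1, r2, q1, q2, pairId = NULL, provenance = "unknown",
                    sourceId = "readset") {
  n <- length(r1)
  if (is.null(pairId)) pairId <- if (n) paste0("pair_", seq_len(n)) else character()
  new("ReadSet", pairId = as.character(pairId),
      r1 = toupper(as.character(r1)), r2 = toupper(as.character(r2)),
      q1 = as.character(q1), q2 = as.character(q2),
      provenance = rep_len(as.character(provenance), n),
      sourceId = as.character(sourceId))
}

#' ErrorModel: Illumina-like sequencing error and quality model
#'
#' Parameters of the paired-end read simulator. Per-read quality classes form
#' a two-class mixture ("good"/"bad" mean Phred), emulating the broad
#' per-read mean-quality distributions seen on real plasmid libraries;
#' sequencing errors are substitutions only.
#'
#' @slot readLen read length in nt.
#' @slot insertMean,insertSd Gaussian insert-size model (bp).
#' @slot baseErrorRate floor substitution rate per base.
#' @slot qualMeanGood,qualMeanBad class means of per-base Phred scores.
#' @slot fracBadReads probability that a pair is drawn from the bad class.
#' @export
setClass("ErrorModel",
  representation(readLen = "integer", insertMean = "integer",
                 insertSd = "numeric", baseErrorRate = "numeric",
                 qualMeanGood = "numeric", qualMeanBad = "numeric",
                 fracBadReads = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@readLen < 1L) msg <- c(msg, "readLen must be >= 1")
    if (object@insertMean < object@readLen)
      msg <- c(msg, "insertMean must be >= readLen")
    if (object@insertSd < 0) msg <- c(msg, "insertSd must be >= 0")
    if (object@baseErrorRate < 0 || object@baseErrorRate >= 1)
      msg <- c(msg, "baseErrorRate must be in [0, 1)")
    if (object@fracBadReads < 0 || object@fracBadReads > 1)
      msg <- c(msg, "fracBadReads must be in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an ErrorModel
#'
#' Defaults emulate a high-coverage plasmid MiSeq-style run: 150 nt reads,
#' 300 +/- 30 bp inserts, 0.1% substitution floor, and a good/bad per-read
#' quality mixture (Phred 38 vs 20, 30% bad).
#'
#' @param readLen,insertMean,insertSd,baseErrorRate,qualMeanGood,qualMeanBad,fracBadReads
#'   see [ErrorModel-class].
#' @return An [ErrorModel-class] object.
#' @export
errorModel <- function(readLen = 150L, insertMean = 300L, insertSd = 30,
                       baseErrorRate = 0.001, qualMeanGood = 38,
                       qualMeanBad = 20, fracBadReads = 0.3) {
  new("ErrorModel", readLen = as.integer(readLen),
      insertMean = as.integer(insertMean), insertSd = as.numeric(insertSd),
      baseErrorRate = as.numeric(baseErrorRate),
      qualMeanGood = as.numeric(qualMeanGood),
      qualMeanBad = as.numeric(qualMeanBad),
      fracBadReads = as.numeric(fracBadReads))
}

#' VariantSpec: how a contaminant plasmid differs from the primary
#'
#' @slot kind one of \code{"snp"}, \code{"deletion"}, \code{"insertion"},
#'   \code{"unrelated"}.
#' @slot nSnps number of SNPs (kind \code{"snp"}, 1--4 in the validated
#'   regime).
#' @slot length indel length in bp (kinds \code{"deletion"}/
#'   \code{"insertion"}); default 608.
#' @slot seed RNG seed making the variant deterministic.
#' @export
setClass("VariantSpec",
  representation(kind = "character", nSnps = "integer", length = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("snp", "deletion", "insertion", "unrelated"))
      msg <- c(msg, "kind must be snp/deletion/insertion/unrelated")
    if (object@kind == "snp" && object@nSnps < 1L)
      msg <- c(msg, "nSnps must be >= 1 for kind 'snp'")
    if (object@kind %in% c("deletion", "insertion") && object@length < 1L)
      msg <- c(msg, "length must be >= 1 for indel kinds")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a VariantSpec
#'
#' @param kind variant kind (see [VariantSpec-class]).
#' @param nSnps number of SNPs for kind \code{"snp"}.
#' @param length indel length for kinds \code{"deletion"}/\code{"insertion"}.
#' @param seed RNG seed.
#' @return A [VariantSpec-class] object.
#' @examples
#' variantSpec("snp", nSnps = 2, seed = 1)
#' variantSpec("deletion", length = 608, seed = 1)
#' @export
variantSpec <- function(kind, nSnps = 1L, length = 608L, seed = 1L) {
  new("VariantSpec", kind = as.character(kind), nSnps = as.integer(nSnps),
      length = as.integer(length), seed = as.integer(seed))
}

#' FilterParams: read filtering and coverage-capping parameters
#'
#' Two mutually exclusive filter modes: threshold mode (keep a pair iff both
#' mates have mean Phred >= \code{minMeanQ} and length >= \code{minLen}) and
#' top-fraction mode (keep the best \code{topFraction} of pairs ranked by the
#' worse mate's mean quality). \code{targetCoverage} with
#' \code{plasmidLenEstimate} drives the coverage-capping subsampler.
#'
#' @slot minMeanQ minimum per-mate mean Phred (threshold mode), default 36.
#' @slot minLen minimum mate length in nt, default 125.
#' @slot topFraction fraction in (0, 1] for top-fraction mode; \code{NA}
#'   selects threshold mode.
#' @slot targetCoverage coverage cap in x for subsampling, default 500.
#' @slot plasmidLenEstimate plasmid length estimate in bp (\code{NA} if
#'   unknown).
#' @export
setClass("FilterParams",
  representation(minMeanQ = "numeric", minLen = "integer",
                 topFraction = "numeric", targetCoverage = "numeric",
                 plasmidLenEstimate = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@topFraction) &&
        (object@topFraction <= 0 || object@topFraction > 1))
      msg <- c(msg, "topFraction must be in (0, 1]")
    if (!is.na(object@targetCoverage) && object@targetCoverage <= 0)
      msg <- c(msg, "targetCoverage must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct FilterParams
#'
#' @param minMeanQ,minLen,topFraction,targetCoverage,plasmidLenEstimate see
#'   [FilterParams-class].
#' @return A [FilterParams-class] object.
#' @export
filterParams <- function(minMeanQ = 36, minLen = 125L, topFraction = NA_real_,
                         targetCoverage = 500, plasmidLenEstimate = NA_integer_) {
  new("FilterParams", minMeanQ = as.numeric(minMeanQ),
      minLen = as.integer(minLen), topFraction = as.numeric(topFraction),
      targetCoverage = as.numeric(targetCoverage),
      plasmidLenEstimate = as.integer(plasmidLenEstimate))
}

#' AssemblyParams: de Bruijn assembler parameters
#'
#' @slot k odd k-mer size in \[15, 31\], default 31.
#' @slot minKmerCount discard k-mers seen fewer times, default 3.
#' @slot relDepthFloor drop graph components whose median k-mer depth falls
#'   below this fraction of the dominant component's median, default 0.15.
#' @slot tipLenMax maximal tip length in bases, default \code{2 * k}.
#' @export
setClass("AssemblyParams",
  representation(k = "integer", minKmerCount = "integer",
                 relDepthFloor = "numeric", tipLenMax = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@k < 3L || object@k > 31L || object@k %% 2L == 0L)
      msg <- c(msg, "k must be odd and in [3, 31]")
    if (object@minKmerCount < 1L) msg <- c(msg, "minKmerCount must be >= 1")
    if (object@relDepthFloor < 0 || object@relDepthFloor >= 1)
      msg <- c(msg, "relDepthFloor must be in [0, 1)")
    if (object@tipLenMax < 0L) msg <- c(msg, "tipLenMax must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct AssemblyParams
#'
#' @param k,minKmerCount,relDepthFloor,tipLenMax see [AssemblyParams-class].
#' @return An [AssemblyParams-class] object.
#' @export
assemblyParams <- function(k = 31L, minKmerCount = 3L, relDepthFloor = 0.15,
                           tipLenMax = 2L * as.integer(k)) {
  new("AssemblyParams", k = as.integer(k), minKmerCount = as.integer(minKmerCount),
      relDepthFloor = as.numeric(relDepthFloor), tipLenMax = as.integer(tipLenMax))
}

#' AssemblyResult: contigs produced by the assembler
#'
#' Circular contigs are reported without the redundant terminal (k-1)-mer
#' overlap (each base appears once) and in canonical rotation; linear contigs
#' on the lexicographically smaller strand.
#'
#' @slot seq contig sequences.
#' @slot circular circularity flag per contig.
#' @slot meanDepth mean k-mer depth per contig.
#' @slot params the [AssemblyParams-class] used.
#' @slot totalReadsUsed number of individual reads given to the assembler.
#' @export
setClass("AssemblyResult",
  representation(seq = "character", circular = "logical",
                 meanDepth = "numeric", params = "AssemblyParams",
                 totalReadsUsed = "integer"),
  validity = function(object) {
    n <- length(object@seq)
    msg <- character()
    if (length(object@circular) != n || length(object@meanDepth) != n)
      msg <- c(msg, "seq, circular and meanDepth must have equal length")
    if (n > 0L && any(!object@circular & nchar(object@seq) < object@params@k))
      msg <- c(msg, "every linear contig must be at least k bases long")
    if (n > 0L && any(object@meanDepth < 0))
      msg <- c(msg, "meanDepth must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' CalibrationModel: logistic mapping from mismatch % to contamination
#' probability
#'
#' @slot intercept,slope logistic coefficients on the mismatch percentage;
#'   the slope is constrained to be non-negative so a higher mismatch
#'   percentage never lowers the contamination probability.
#' @slot cleanMean,cleanSd,contamMean,contamSd training score summaries.
#' @slot nTrain total number of training scores.
#' @slot id identifier echoed into reports.
#' @export
setClass("CalibrationModel",
  representation(intercept = "numeric", slope = "numeric",
                 cleanMean = "numeric", cleanSd = "numeric",
                 contamMean = "numeric", contamSd = "numeric",
                 nTrain = "integer", id = "character"),
  validity = function(object) {
    if (object@slope < 0) "slope must be >= 0" else TRUE
  }
)

#' ContaminationReport: exact back-mapping statistic for one sample
#'
#' @slot nDistinct number of distinct filtered read strings (mates counted
#'   separately).
#' @slot nMatched how many of them match the assembly exactly (either strand,
#'   origin-spanning allowed).
#' @slot mismatchPct \code{100 * (1 - nMatched / nDistinct)}.
#' @slot probability calibrated contamination probability in \[0, 1\]
#'   (\code{NA} if no calibration applied).
#' @slot calibrationId identifier of the calibration used.
#' @export
setClass("ContaminationReport",
  representation(nDistinct = "integer", nMatched = "integer",
                 mismatchPct = "numeric", probability = "numeric",
                 calibrationId = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nMatched > object@nDistinct)
      msg <- c(msg, "nMatched must be <= nDistinct")
    expected <- 100 * (1 - object@nMatched / object@nDistinct)
    if (object@nDistinct > 0L && abs(object@mismatchPct - expected) > 1e-9)
      msg <- c(msg, "mismatchPct inconsistent with counts")
    if (length(msg)) msg else TRUE
  }
)
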