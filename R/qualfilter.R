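# Strict read-pair quality filtering and coverage-capping subsampling.
# Whole reads are kept or dropped (no trimming); gating is at the pair level
# so R1/R2 stay synchronized.

#' Mean Phred quality of a read
#'
#' Arithmetic mean of the per-base Phred integers (not error-probability
#' averaging).
#'
#' @param qual an integer vector of Phred scores, or a character vector of
#'   Phred+33 quality strings.
#' @return Numeric mean(s).
#' @examples
#' meanPhred(c(30L, 40L))  # 35
#' @export
meanPhred <- function(qual) {
  if (is.character(qual)) {
    if (any(!nzchar(qual))) stop("empty quality string")
    return(.phred_means_cpp(qual))
  }
  qual <- as.numeric(qual)
  if (length(qual) == 0L) stop("empty quality vector")
  mean(qual)
}

#' Filter read pairs by quality
#'
#' Threshold mode (default): a pair is kept iff \emph{both} mates have mean
#' Phred >= \code{minMeanQ} and length >= \code{minLen}. Top-fraction mode
#' (when \code{topFraction} is set): pairs are ranked by the worse mate's
#' mean quality, descending, and the best \code{ceiling(topFraction * n)}
#' pairs are kept (ties broken by input order). Either way the surviving
#' pairs keep their original relative order and provenance labels.
#'
#' Very stringent settings are deliberate: on raw plasmid libraries with
#' extremely high coverage, retaining only the best few percent of pairs
#' both caps coverage and concentrates signal for downstream contamination
#' detection.
#'
#' @param rs a [ReadSet-class].
#' @param fp a [FilterParams-class].
#' @return The filtered [ReadSet-class] (possibly empty).
#' @export
filterReads <- function(rs, fp = filterParams()) {
  stopifnot(is(rs, "ReadSet"), is(fp, "FilterParams"))
  n <- nPairs(rs)
  if (n == 0L) return(rs)
  m1 <- meanPhred(rs@q1)
  m2 <- meanPhred(rs@q2)
  if (!is.na(fp@topFraction)) {
    keepN <- min(n, as.integer(ceiling(fp@topFraction * n)))
    score <- pmin(m1, m2)
    ord <- order(-score, seq_len(n))   # ties by input order
    keep <- sort(ord[seq_len(keepN)])  # restore original order
  } else {
    keep <- which(m1 >= fp@minMeanQ & m2 >= fp@minMeanQ &
                  nchar(rs@r1) >= fp@minLen & nchar(rs@r2) >= fp@minLen)
  }
  rs[keep]
}

#' Cap coverage by random subsampling of read pairs
#'
#' If the nominal coverage \code{n * 2 * meanReadLen / plasmidLenEstimate}
#' exceeds \code{targetCoverage}, pairs are sampled without replacement down
#' to \code{floor(targetCoverage * plasmidLenEstimate / (2 * meanReadLen))};
#' otherwise the input is returned unchanged. Very high coverage actively
#' hurts de novo assembly of short plasmids, hence the cap (the empirically
#' favourable band is roughly 113x--1030x).
#'
#' @param rs a [ReadSet-class].
#' @param fp a [FilterParams-class] with \code{targetCoverage} and
#'   \code{plasmidLenEstimate} set, unless \code{nPairsTarget} is given.
#' @param seed RNG seed; identical seeds give identical samples.
#' @param nPairsTarget optional explicit pair count overriding the coverage
#'   computation.
#' @return A [ReadSet-class]; a subset of the input pairs in original order.
#' @export
subsampleReads <- function(rs, fp = filterParams(), seed = 1L,
                           nPairsTarget = NULL) {
  stopifnot(is(rs, "ReadSet"))
  n <- nPairs(rs)
  if (n == 0L) return(rs)
  if (is.null(nPairsTarget)) {
    if (is.na(fp@targetCoverage) || is.na(fp@plasmidLenEstimate))
      stop("targetCoverage and plasmidLenEstimate (or nPairsTarget) required")
    if (fp@targetCoverage <= 0 || fp@plasmidLenEstimate <= 0)
      stop("coverage target and plasmid length must be positive")
    meanLen <- mean(c(nchar(rs@r1), nchar(rs@r2)))
    cov <- n * 2 * meanLen / fp@plasmidLenEstimate
    if (cov <= fp@targetCoverage) return(rs)
    nPairsTarget <- floor(fp@targetCoverage * fp@plasmidLenEstimate /
                          (2 * meanLen))
  }
  nPairsTarget <- as.integer(nPairsTarget)
  if (nPairsTarget <= 0L) stop("subsampling target must be positive")
  if (nPairsTarget >= n) return(rs)
  keep <- withr::with_seed(seed, sort(sample.int(n, nPairsTarget)))
  rs[keep]
}

#' Summarize a filtering step
#'
#' @param before,after the [ReadSet-class] before and after filtering.
#' @return A list with input/retained pair counts, retained percentage, and
#'   mean per-read quality before and after (as written into JSON reports).
#' @export
filterSummary <- function(before, after) {
  mq <- function(x) if (nPairs(x) == 0L) NA_real_ else
    mean(c(meanPhred(x@q1), meanPhred(x@q2)))
  list(input_pairs = nPairs(before),
       retained_pairs = nPairs(after),
       retained_pct = if (nPairs(before) == 0L) NA_real_ else
         100 * nPairs(after) / nPairs(before),
       mean_quality_before = mq(before),
       mean_quality_after = mq(after))
}
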