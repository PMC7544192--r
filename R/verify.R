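# Assembly evaluation and reference-agnostic contamination detection.
#
# The contamination statistic is the percentage of distinct filtered reads
# (each mate a separate string, strands not merged) that fail to map exactly
# to any contig, allowing matches across the circular origin and on either
# strand. Clean samples have a characteristic low mismatch percentage driven
# by residual sequencing errors; contaminated samples score higher, and a
# logistic calibration turns the score into a contamination probability.

.OUTCOMES <- c("CORRECT_PRIMARY", "MATCHES_CONTAMINANT", "MISMATCH",
               "FRAGMENTED", "NO_ASSEMBLY")

#' Classify an assembly against references (four-outcome scheme)
#'
#' Zero contigs is \code{NO_ASSEMBLY}; more than one contig is
#' \code{FRAGMENTED}; a single contig is compared (rotation- and
#' strand-invariantly) first to the primary reference
#' (\code{CORRECT_PRIMARY}), then to the contaminant reference if given
#' (\code{MATCHES_CONTAMINANT}), else \code{MISMATCH}.
#'
#' @param ar an [AssemblyResult-class].
#' @param primaryRef the primary [PlasmidRecord-class].
#' @param contaminantRef optional contaminant [PlasmidRecord-class].
#' @return A single outcome string.
#' @export
classifyAssembly <- function(ar, primaryRef, contaminantRef = NULL) {
  stopifnot(is(ar, "AssemblyResult"), is(primaryRef, "PlasmidRecord"))
  n <- nContigs(ar)
  if (n == 0L) return("NO_ASSEMBLY")
  if (n >= 2L) return("FRAGMENTED")
  ctg <- ar@seq[1L]
  if (circularEqual(ctg, primaryRef@seq)) return("CORRECT_PRIMARY")
  if (!is.null(contaminantRef) && circularEqual(ctg, contaminantRef@seq))
    return("MATCHES_CONTAMINANT")
  "MISMATCH"
}

#' Exact back-mapping statistic of reads against an assembly
#'
#' The multiset of individual read sequences (each mate separately) is
#' deduplicated to distinct strings; each distinct string is tested for an
#' exact occurrence in any contig (either strand; origin-spanning matches
#' count on circular contigs). Fragmented assemblies are matched against the
#' union of all contigs.
#'
#' @param ar an [AssemblyResult-class] with at least one contig.
#' @param filtered the non-empty [ReadSet-class] the assembly was built from.
#' @param calibration optional [CalibrationModel-class]; if supplied, the
#'   report carries a calibrated contamination probability.
#' @return A [ContaminationReport-class].
#' @examples
#' \dontrun{
#' rep <- exactMatchStats(asm, filtered)
#' mismatchPct(rep)
#' }
#' @export
exactMatchStats <- function(ar, filtered, calibration = NULL) {
  stopifnot(is(ar, "AssemblyResult"), is(filtered, "ReadSet"))
  if (nContigs(ar) == 0L) stop("assembly has no contigs")
  if (nPairs(filtered) == 0L) stop("empty read set")
  distinct <- unique(c(filtered@r1, filtered@r2))
  hits <- .match_reads_cpp(distinct, ar@seq, ar@circular)
  nD <- length(distinct)
  nM <- sum(hits)
  mm <- 100 * (1 - nM / nD)
  prob <- NA_real_
  calId <- "none"
  if (!is.null(calibration)) {
    prob <- contaminationProbability(mm, calibration)
    calId <- calibration@id
  }
  new("ContaminationReport", nDistinct = as.integer(nD),
      nMatched = as.integer(nM), mismatchPct = mm, probability = prob,
      calibrationId = calId)
}

#' Fit a logistic calibration of contamination probability on mismatch %
#'
#' Maximum-likelihood logistic regression of class (contaminated = 1) on the
#' mismatch percentage, with the slope constrained to be non-negative (a
#' higher mismatch percentage never lowers the contamination probability).
#' If the unconstrained fit has a negative slope the model degrades to an
#' intercept-only fit. Training score summaries are stored for reporting.
#'
#' @param cleanScores,contamScores numeric mismatch percentages from clean
#'   and contaminated runs; at least 20 scores per class.
#' @param id model identifier.
#' @return A [CalibrationModel-class].
#' @export
fitCalibration <- function(cleanScores, contamScores, id = "custom") {
  cleanScores <- as.numeric(cleanScores)
  contamScores <- as.numeric(contamScores)
  if (length(cleanScores) < 20L || length(contamScores) < 20L)
    stop("calibration needs at least 20 scores per class")
  if (anyNA(cleanScores) || anyNA(contamScores))
    stop("calibration scores must not contain NA")
  x <- c(cleanScores, contamScores)
  y <- c(rep(0L, length(cleanScores)), rep(1L, length(contamScores)))
  if (length(unique(x)) == 1L)
    stop("degenerate calibration: all scores identical across classes")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  co <- coef(fit)
  if (anyNA(co)) stop("calibration failed: singular fit")
  intercept <- unname(co[1L])
  slope <- unname(co[2L])
  if (slope < 0) {  # constrained MLE lies on the boundary
    slope <- 0
    intercept <- qlogis(mean(y))
  }
  new("CalibrationModel", intercept = intercept, slope = slope,
      cleanMean = mean(cleanScores), cleanSd = stats::sd(cleanScores),
      contamMean = mean(contamScores), contamSd = stats::sd(contamScores),
      nTrain = length(x), id = id)
}

#' Calibrated contamination probability for a mismatch percentage
#'
#' \code{plogis(intercept + slope * mismatchPct)}; monotone non-decreasing
#' in the mismatch percentage.
#'
#' @param mismatchPct numeric mismatch percentage(s).
#' @param cm a [CalibrationModel-class].
#' @return Probabilities in \[0, 1\].
#' @export
contaminationProbability <- function(mismatchPct, cm) {
  stopifnot(is(cm, "CalibrationModel"))
  plogis(cm@intercept + cm@slope * as.numeric(mismatchPct))
}

#' ROC AUC by the rank statistic
#'
#' The probability that a randomly chosen contaminated score exceeds a
#' randomly chosen clean score, ties counting one half (the Mann-Whitney
#' statistic).
#'
#' @param cleanScores,contamScores non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(10, 20), c(15, 25))  # 0.75
#' @export
rocAuc <- function(cleanScores, contamScores) {
  cleanScores <- as.numeric(cleanScores)
  contamScores <- as.numeric(contamScores)
  n0 <- length(cleanScores)
  n1 <- length(contamScores)
  if (n0 == 0L || n1 == 0L) stop("both score vectors must be non-empty")
  r <- rank(c(cleanScores, contamScores), ties.method = "average")
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Run a contamination-spiking simulation experiment
#'
#' For each replicate: generate a random primary plasmid (length uniform in
#' \code{lengthRange}), derive a contaminant via \code{variant} (if any),
#' simulate both read sets at \code{coverage}, mix at \code{fraction},
#' filter, cap coverage, assemble, classify against the truth, and compute
#' the exact back-mapping statistic. Aggregates the percentage of
#' \code{CORRECT_PRIMARY} and \code{FRAGMENTED} replicates and the
#' unweighted mean mismatch percentage across replicates. Replicate-level
#' errors are tallied separately (counted as neither correct nor
#' fragmented). Fully deterministic under \code{baseSeed}.
#'
#' @param variant a [VariantSpec-class], or \code{NULL} for the clean
#'   (uncontaminated) condition. The spec's seed is ignored; each replicate
#'   derives its own variant seed.
#' @param fraction contaminant read-pair fraction in \[0, 0.5\].
#' @param nReps number of replicates.
#' @param baseSeed master seed.
#' @param em an [ErrorModel-class].
#' @param fp a [FilterParams-class]; the plasmid length estimate is set per
#'   replicate from the simulated truth.
#' @param ap an [AssemblyParams-class].
#' @param lengthRange plasmid length range in bp, default 2521--3294.
#' @param gc plasmid GC fraction.
#' @param coverage nominal raw coverage before filtering, default 500x.
#' @return A one-row \code{data.frame} with columns \code{variant_type},
#'   \code{contamination_pct}, \code{n_reps}, \code{pct_correct},
#'   \code{pct_fragmented}, \code{pct_mismatch}, \code{pct_no_assembly},
#'   \code{mean_mismatch_pct} and \code{n_error}; per-replicate outcomes and
#'   scores are attached as attribute \code{"replicates"}.
#' @export
runContaminationExperiment <- function(variant = NULL, fraction = 0,
                                       nReps = 10L, baseSeed = 1L,
                                       em = errorModel(),
                                       fp = filterParams(),
                                       ap = assemblyParams(),
                                       lengthRange = c(2521L, 3294L),
                                       gc = 0.5, coverage = 500) {
  if (fraction < 0 || fraction > 0.5)
    stop("fraction must be in [0, 0.5]")
  nReps <- as.integer(nReps)
  if (nReps < 1L) stop("nReps must be >= 1")
  if (fraction > 0 && is.null(variant))
    stop("a VariantSpec is required when fraction > 0")
  repSeeds <- withr::with_seed(baseSeed, sample.int(1000000000L, nReps))
  outcomes <- character(nReps)
  scores <- rep(NA_real_, nReps)
  for (i in seq_len(nReps)) {
    s <- repSeeds[i]
    res <- tryCatch({
      L <- withr::with_seed(s, sample(lengthRange[1L]:lengthRange[2L], 1L))
      primary <- generatePlasmid(L, gc, seed = s + 1L)
      np <- as.integer(round(coverage * L / (2 * em@readLen)))
      prs <- simulateReads(primary, np, em, seed = s + 2L,
                           provenanceLabel = "primary")
      contaminant <- NULL
      if (fraction > 0) {
        v <- new("VariantSpec", kind = variant@kind, nSnps = variant@nSnps,
                 length = variant@length, seed = s + 3L)
        contaminant <- applyVariant(primary, v)
        crs <- simulateReads(contaminant, np, em, seed = s + 4L,
                             provenanceLabel = "contaminant")
        prs <- mixReads(prs, crs, fraction, np, seed = s + 5L)
      }
      fpr <- new("FilterParams", minMeanQ = fp@minMeanQ, minLen = fp@minLen,
                 topFraction = fp@topFraction,
                 targetCoverage = fp@targetCoverage,
                 plasmidLenEstimate = L)
      filt <- filterReads(prs, fpr)
      filt <- subsampleReads(filt, fpr, seed = s + 6L)
      ar <- assembleReads(filt, ap)
      out <- classifyAssembly(ar, primary, contaminant)
      mm <- if (nContigs(ar) >= 1L && nPairs(filt) >= 1L)
        mismatchPct(exactMatchStats(ar, filt)) else NA_real_
      list(outcome = out, mm = mm)
    }, error = function(e) list(outcome = "ERROR", mm = NA_real_))
    outcomes[i] <- res$outcome
    scores[i] <- res$mm
  }
  vt <- if (is.null(variant)) "none"
        else if (variant@kind == "snp") sprintf("%d SNP", variant@nSnps)
        else if (variant@kind %in% c("deletion", "insertion"))
          sprintf("%d bp %s", variant@length, variant@kind)
        else variant@kind
  summary <- data.frame(
    variant_type = vt,
    contamination_pct = 100 * fraction,
    n_reps = nReps,
    pct_correct = 100 * mean(outcomes == "CORRECT_PRIMARY"),
    pct_fragmented = 100 * mean(outcomes == "FRAGMENTED"),
    pct_mismatch = 100 * mean(outcomes %in% c("MISMATCH",
                                              "MATCHES_CONTAMINANT")),
    pct_no_assembly = 100 * mean(outcomes == "NO_ASSEMBLY"),
    mean_mismatch_pct = mean(scores, na.rm = TRUE),
    n_error = sum(outcomes == "ERROR"),
    stringsAsFactors = FALSE)
  attr(summary, "replicates") <- data.frame(
    seed = repSeeds, outcome = outcomes, mismatch_pct = scores,
    stringsAsFactors = FALSE)
  summary
}
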