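# Pipeline orchestration: filter -> cap coverage -> assemble -> back-map ->
# calibrated contamination probability (-> classification if a reference is
# given). This is the function behind the command-line `verify` subcommand.

#' Run the full verification pipeline on a read set
#'
#' @param rs a [ReadSet-class] of raw read pairs.
#' @param fp a [FilterParams-class].
#' @param ap an [AssemblyParams-class].
#' @param calibration a [CalibrationModel-class], or \code{NULL} to skip the
#'   probability (default: the packaged simulation-trained model).
#' @param primaryRef,contaminantRef optional [PlasmidRecord-class]
#'   references; when \code{primaryRef} is given the assembly is classified.
#' @param seed RNG seed (used by coverage-capping subsampling).
#' @return A list with elements \code{filtered} (the retained
#'   [ReadSet-class]), \code{filter_summary}, \code{assembly}
#'   ([AssemblyResult-class]), \code{report} ([ContaminationReport-class] or
#'   \code{NULL} when nothing assembled) and \code{outcome} (classification
#'   string or \code{NA}).
#' @export
runVerifyPipeline <- function(rs, fp = filterParams(), ap = assemblyParams(),
                              calibration = defaultCalibration(),
                              primaryRef = NULL, contaminantRef = NULL,
                              seed = 1L) {
  stopifnot(is(rs, "ReadSet"))
  filt <- filterReads(rs, fp)
  if (!is.na(fp@targetCoverage) && !is.na(fp@plasmidLenEstimate))
    filt <- subsampleReads(filt, fp, seed = seed)
  if (nPairs(filt) == 0L)
    stop("no read pairs survive filtering; relax FilterParams")
  ar <- assembleReads(filt, ap)
  report <- NULL
  if (nContigs(ar) >= 1L)
    report <- exactMatchStats(ar, filt, calibration = calibration)
  outcome <- NA_character_
  if (!is.null(primaryRef))
    outcome <- classifyAssembly(ar, primaryRef, contaminantRef)
  list(filtered = filt,
       filter_summary = filterSummary(rs, filt),
       assembly = ar, report = report, outcome = outcome)
}

#' JSON-ready verification report
#'
#' @param res result list from [runVerifyPipeline()].
#' @param sampleId sample identifier echoed into the report.
#' @param config optional effective configuration list echoed for
#'   provenance.
#' @return A named list serializable with \code{jsonlite::write_json}.
#' @export
verificationReport <- function(res, sampleId = "sample", config = NULL) {
  ar <- res$assembly
  rep <- res$report
  out <- list(
    sample_id = sampleId,
    n_contigs = nContigs(ar),
    contig_lengths = as.integer(nchar(ar@seq)),
    circular = ar@circular,
    mean_depth = ar@meanDepth,
    outcome = res$outcome,
    filter = res$filter_summary,
    n_distinct = if (is.null(rep)) NA_integer_ else rep@nDistinct,
    n_matched = if (is.null(rep)) NA_integer_ else rep@nMatched,
    mismatch_pct = if (is.null(rep)) NA_real_ else rep@mismatchPct,
    contamination_probability = if (is.null(rep)) NA_real_ else rep@probability,
    calibration_id = if (is.null(rep)) "none" else rep@calibrationId)
  if (!is.null(config)) out$config <- config
  out
}
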