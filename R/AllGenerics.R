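# Generics and basic methods (accessors, show, subsetting).

#' Number of read pairs in a ReadSet
#' @param x a [ReadSet-class].
#' @return Integer pair count.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "ReadSet", function(x) length(x@pairId))

#' Provenance labels of a ReadSet
#' @param x a [ReadSet-class].
#' @param value replacement labels (recycled).
#' @return Character vector of per-pair labels.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "ReadSet", function(x) x@provenance)

#' @rdname provenance
#' @export
setGeneric("provenance<-", function(x, value) standardGeneric("provenance<-"))

#' @rdname provenance
#' @export
setMethod("provenance<-", "ReadSet", function(x, value) {
  x@provenance <- rep_len(as.character(value), nPairs(x))
  validObject(x)
  x
})

#' Pair identifiers
#' @param x a [ReadSet-class].
#' @return Character vector of pair ids.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname pairIds
#' @export
setMethod("pairIds", "ReadSet", function(x) x@pairId)

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.logical(i)) i <- which(rep_len(i, nPairs(x)))
  new("ReadSet", pairId = x@pairId[i], r1 = x@r1[i], r2 = x@r2[i],
      q1 = x@q1[i], q2 = x@q2[i], provenance = x@provenance[i],
      sourceId = x@sourceId)
})

#' Number of contigs in an assembly
#' @param x an [AssemblyResult-class].
#' @return Integer contig count.
#' @export
setGeneric("nContigs", function(x) standardGeneric("nContigs"))

#' @rdname nContigs
#' @export
setMethod("nContigs", "AssemblyResult", function(x) length(x@seq))

#' Contig sequences
#' @param x an [AssemblyResult-class].
#' @return Named character vector of contig sequences.
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))

#' @rdname contigSeqs
#' @export
setMethod("contigSeqs", "AssemblyResult", function(x) {
  if (nContigs(x) == 0L) return(setNames(character(), character()))
  setNames(x@seq, paste0("contig_", seq_along(x@seq)))
})

#' Contig circularity flags
#' @param x an [AssemblyResult-class].
#' @return Logical vector, one flag per contig.
#' @export
setGeneric("contigCircular", function(x) standardGeneric("contigCircular"))

#' @rdname contigCircular
#' @export
setMethod("contigCircular", "AssemblyResult", function(x) x@circular)

#' Mean k-mer depth per contig
#' @param x an [AssemblyResult-class].
#' @return Numeric vector of mean depths.
#' @export
setGeneric("contigDepths", function(x) standardGeneric("contigDepths"))

#' @rdname contigDepths
#' @export
setMethod("contigDepths", "AssemblyResult", function(x) x@meanDepth)

#' Mismatch percentage of a contamination report
#' @param x a [ContaminationReport-class].
#' @return Percentage of distinct reads that do not match the assembly.
#' @export
setGeneric("mismatchPct", function(x) standardGeneric("mismatchPct"))

#' @rdname mismatchPct
#' @export
setMethod("mismatchPct", "ContaminationReport", function(x) x@mismatchPct)

setMethod("show", "PlasmidRecord", function(object) {
  cat(sprintf("PlasmidRecord '%s': %d bp, %s\n", object@id,
              nchar(object@seq),
              if (object@circular) "circular" else "linear"))
})

setMethod("show", "ReadSet", function(object) {
  n <- nPairs(object)
  cat(sprintf("ReadSet '%s': %d read pairs\n", object@sourceId, n))
  if (n > 0L) {
    tab <- table(object@provenance)
    cat("  provenance:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    cat(sprintf("  read lengths: %d-%d nt\n",
                min(nchar(object@r1), nchar(object@r2)),
                max(nchar(object@r1), nchar(object@r2))))
  }
})

setMethod("show", "AssemblyResult", function(object) {
  cat(sprintf("AssemblyResult: %d contig(s) (k=%d, %d reads used)\n",
              nContigs(object), object@params@k, object@totalReadsUsed))
  if (nContigs(object) > 0L) {
    for (i in seq_along(object@seq))
      cat(sprintf("  contig_%d: %d bp, %s, mean depth %.1f\n", i,
                  nchar(object@seq[i]),
                  if (object@circular[i]) "circular" else "linear",
                  object@meanDepth[i]))
  }
})

setMethod("show", "ContaminationReport", function(object) {
  cat(sprintf(
    "ContaminationReport: %d/%d distinct reads matched (mismatch %.2f%%)\n",
    object@nMatched, object@nDistinct, object@mismatchPct))
  if (!is.na(object@probability))
    cat(sprintf("  contamination probability %.3f (calibration '%s')\n",
                object@probability, object@calibrationId))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel '%s': logit(p) = %.3f + %.3f * mismatch%% (n=%d)\n",
    object@id, object@intercept, object@slope, object@nTrain))
  cat(sprintf("  training scores: clean %.2f +/- %.2f, contaminated %.2f +/- %.2f\n",
              object@cleanMean, object@cleanSd, object@contamMean,
              object@contamSd))
})
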