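# Default contamination calibration. The probability mapping is a logistic
# regression of contamination status on the mismatch percentage, trained on
# this package's own simulations (clean vs 20% single-SNP contamination).
# The packaged training scores are synthetic, produced by
# makeCalibrationScores() under a fixed seed, and shipped as a plain-text
# table so the default model is reproducible; users analysing a different
# error regime should refit with fitCalibration()/cmdCalibrate.

#' Simulate training scores for contamination calibration
#'
#' Runs the full pipeline on clean replicates and on replicates contaminated
#' at \code{fraction} with a single-SNP variant, and collects the mismatch
#' percentages of every replicate that assembled.
#'
#' @param nPerClass replicates per class.
#' @param seed master seed.
#' @param fraction contaminant fraction for the contaminated class.
#' @param nSnps SNPs distinguishing the contaminant.
#' @param ... passed to [runContaminationExperiment()].
#' @return A \code{data.frame} with columns \code{class}
#'   (\code{"clean"}/\code{"contaminated"}) and \code{mismatch_pct}.
#' @export
makeCalibrationScores <- function(nPerClass = 60L, seed = 20260901L,
                                  fraction = 0.2, nSnps = 1L, ...) {
  clean <- runContaminationExperiment(NULL, 0, nReps = nPerClass,
                                      baseSeed = seed, ...)
  cont <- runContaminationExperiment(variantSpec("snp", nSnps = nSnps),
                                     fraction, nReps = nPerClass,
                                     baseSeed = seed + 1L, ...)
  sc <- function(x, cls) {
    r <- attr(x, "replicates")
    data.frame(class = cls, mismatch_pct = r$mismatch_pct[!is.na(r$mismatch_pct)],
               stringsAsFactors = FALSE)
  }
  rbind(sc(clean, "clean"), sc(cont, "contaminated"))
}

#' The packaged default calibration model
#'
#' Fitted (and cached for the session) from the synthetic simulation-derived
#' training scores shipped with the package.
#'
#' @return A [CalibrationModel-class] with id \code{"default-sim-v1"}.
#' @export
defaultCalibration <- function() {
  if (!is.null(.pkg_env$default_calibration))
    return(.pkg_env$default_calibration)
  path <- system.file("extdata", "calibration_scores_synthetic.tsv",
                      package = "plascheck", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  cm <- fitCalibration(tab$mismatch_pct[tab$class == "clean"],
                       tab$mismatch_pct[tab$class == "contaminated"],
                       id = "default-sim-v1")
  .pkg_env$default_calibration <- cm
  cm
}

#' Write / read a calibration model as JSON
#'
#' @param cm a [CalibrationModel-class].
#' @param path JSON file path.
#' @return \code{writeCalibration} returns \code{path} invisibly;
#'   \code{readCalibration} returns the model.
#' @export
writeCalibration <- function(cm, path) {
  stopifnot(is(cm, "CalibrationModel"))
  jsonlite::write_json(list(
    id = cm@id, intercept = cm@intercept, slope = cm@slope,
    clean_mean = cm@cleanMean, clean_sd = cm@cleanSd,
    contam_mean = cm@contamMean, contam_sd = cm@contamSd,
    n_train = cm@nTrain), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationModel", intercept = as.numeric(x$intercept),
      slope = as.numeric(x$slope), cleanMean = as.numeric(x$clean_mean),
      cleanSd = as.numeric(x$clean_sd), contamMean = as.numeric(x$contam_mean),
      contamSd = as.numeric(x$contam_sd), nTrain = as.integer(x$n_train),
      id = as.character(x$id))
}
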