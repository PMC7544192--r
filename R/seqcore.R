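# Sequence primitives and FASTA/FASTQ I/O. Circular sequences are compared
# via a canonical form: the lexicographically smallest rotation over both
# strands (Booth's least-rotation algorithm in C++).

#' Reverse complement
#'
#' Watson-Crick reverse complement; \code{N} maps to \code{N}.
#'
#' @param x character vector of DNA sequences over \code{A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @examples
#' revComp(c("AACG", "AN"))
#' @export
revComp <- function(x) .revcomp_cpp(toupper(as.character(x)))

#' Canonical rotation of a circular sequence
#'
#' The lexicographically smallest string among all rotations of \code{x} and
#' all rotations of its reverse complement. Assemblies of circular plasmids
#' have arbitrary start and strand; this canonical form makes them
#' comparable. Sequences containing \code{N} are rejected (the canonical
#' form is undefined under ambiguity).
#'
#' @param x character vector of non-empty DNA sequences over \code{A,C,G,T}.
#' @return Character vector of canonical rotations.
#' @examples
#' canonicalRotation("GAAC")  # "AACG"
#' @export
canonicalRotation <- function(x) .canonical_rotation_cpp(toupper(as.character(x)))

#' Equality of circular sequences up to rotation and strand
#'
#' @param a,b non-empty DNA sequences without \code{N}.
#' @return \code{TRUE} iff \code{a} and \code{b} describe the same circular
#'   molecule (any rotation, either strand).
#' @examples
#' circularEqual("ATGGCGTA", "CGTAATGG")
#' @export
circularEqual <- function(a, b) {
  canonicalRotation(a) == canonicalRotation(b)
}

#' Exact occurrence of a read in a contig
#'
#' A read matches if it, or its reverse complement, occurs as an exact
#' substring of the contig; for circular contigs the contig is extended by
#' the read length minus one so origin-spanning matches count. Reads
#' containing \code{N} never match (matching is exact, with no ambiguity
#' logic). Reads longer than the contig do not match.
#'
#' @param reads character vector of read sequences.
#' @param contig a single contig sequence.
#' @param circular is the contig circular? Default \code{TRUE}.
#' @return Logical vector, one element per read.
#' @examples
#' circularMatch("CACG", "ACGTAC")  # TRUE: spans the origin
#' @export
circularMatch <- function(reads, contig, circular = TRUE) {
  stopifnot(length(contig) == 1L, nchar(contig) >= 1L)
  reads <- toupper(as.character(reads))
  .match_reads_cpp(reads, toupper(as.character(contig)), as.logical(circular))
}

#' Read plasmid records from a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @param circular circularity flag applied to all records (FASTA does not
#'   encode it); default \code{TRUE}.
#' @return List of [PlasmidRecord-class] objects.
#' @export
readFasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    plasmidRecord(id, as.character(ss[[i]]), circular = circular)
  })
}

#' Write plasmid records (or named sequences) to FASTA
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param records list of [PlasmidRecord-class] objects, or a named character
#'   vector of sequences.
#' @param path output file; a \code{.gz} suffix triggers compression.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records)) {
    seqs <- records
    if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  } else {
    seqs <- vapply(records, function(p) p@seq, character(1))
    names(seqs) <- vapply(records, function(p) p@id, character(1))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a pair of FASTQ files into a ReadSet
#'
#' Phred+33 encoding; gzipped input is handled transparently by filename
#' suffix. R1 and R2 must contain the same number of records in matching
#' order.
#'
#' @param pathR1,pathR2 FASTQ files for the two mates.
#' @param sourceId label for the resulting set (default: R1 file name).
#' @return A [ReadSet-class]; provenance is \code{"unknown"}.
#' @export
readFastqPair <- function(pathR1, pathR2,
                          sourceId = sub("\\.(fastq|fq)(\\.gz)?$", "",
                                         basename(pathR1))) {
  for (p in c(pathR1, pathR2))
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
  rd <- function(p) {
    tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
      error = function(e)
        stop("malformed FASTQ in '", p, "': ", conditionMessage(e),
             call. = FALSE))
  }
  s1 <- rd(pathR1)
  s2 <- rd(pathR2)
  if (length(s1) != length(s2))
    stop(sprintf("R1/R2 record counts differ (%d vs %d): %s, %s",
                 length(s1), length(s2), pathR1, pathR2))
  q1 <- as.character(S4Vectors::mcols(s1)$qualities)
  q2 <- as.character(S4Vectors::mcols(s2)$qualities)
  if (any(nchar(q1) != Biostrings::width(s1)) ||
      any(nchar(q2) != Biostrings::width(s2)))
    stop("quality/sequence length mismatch in FASTQ input")
  readSet(r1 = as.character(s1), r2 = as.character(s2), q1 = q1, q2 = q2,
          pairId = sub("\\s.*$", "", names(s1)), sourceId = sourceId)
}

#' Write a ReadSet to a pair of FASTQ files
#'
#' Write-then-read round-trips preserve ids, sequences and qualities exactly;
#' a \code{.gz} suffix triggers compression.
#'
#' @param rs a [ReadSet-class].
#' @param pathR1,pathR2 output FASTQ files.
#' @return Invisibly, \code{c(pathR1, pathR2)}.
#' @export
writeFastqPair <- function(rs, pathR1, pathR2) {
  stopifnot(is(rs, "ReadSet"))
  wr <- function(seqs, quals, ids, p) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    Biostrings::writeXStringSet(
      ss, filepath = p, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", p))
  }
  wr(rs@r1, rs@q1, rs@pairId, pathR1)
  wr(rs@r2, rs@q2, rs@pairId, pathR2)
  invisible(c(pathR1, pathR2))
}

#' Write ground-truth provenance labels as a sidecar TSV
#'
#' @param rs a [ReadSet-class].
#' @param path output TSV with columns \code{read_id}, \code{provenance}.
#' @return Invisibly, \code{path}.
#' @export
writeProvenance <- function(rs, path) {
  write.table(data.frame(read_id = rs@pairId, provenance = rs@provenance,
                         stringsAsFactors = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
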