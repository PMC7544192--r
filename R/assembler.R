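# De novo assembly of plasmid-scale circular sequences via a de Bruijn graph
# on canonical k-mers. Reads are treated as single-end for graph building
# (paired-end information is not used for scaffolding); tips are clipped,
# simple bubbles popped in favour of the deeper branch, and whole graph
# components far below the dominant component's depth are discarded as
# likely contamination. A unitig closing on itself is emitted as a circular
# contig without the redundant (k-1)-mer overlap, in canonical rotation.

.reads_of <- function(rs) {
  if (is(rs, "ReadSet")) c(rs@r1, rs@r2) else as.character(rs)
}

#' Count canonical k-mers
#'
#' k-mers are counted on the canonical strand (the lexicographic minimum of
#' the k-mer and its reverse complement); windows containing \code{N} are
#' skipped, and reads shorter than \code{k} contribute nothing. \code{k}
#' must be odd so no k-mer equals its own reverse complement.
#'
#' @param rs a [ReadSet-class] (both mates are counted) or a character
#'   vector of sequences.
#' @param k odd k-mer size, at most 31.
#' @return Named integer vector of canonical k-mer counts, in lexicographic
#'   k-mer order.
#' @examples
#' countKmers("ACGTA", 3)  # ACG:2 (ACG + canonical CGT), GTA:1
#' @export
countKmers <- function(rs, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (canonical strand ambiguity)")
  if (k < 1L || k > 31L) stop("k must be in [1, 31]")
  res <- .count_kmers_cpp(.reads_of(rs), k)
  setNames(res$count, res$kmer)
}

#' Choose a k-mer size from read lengths
#'
#' Returns the default \code{k} (31) when the shortest read is longer than
#' it; otherwise the largest odd k at most (shortest read length - 1),
#' bounded below by 15. Read sets whose shortest read is under 16 nt cannot
#' support a usable k.
#'
#' @param rs a [ReadSet-class] or character vector of reads.
#' @param default default k-mer size.
#' @return An odd integer k.
#' @export
autoK <- function(rs, default = 31L) {
  reads <- .reads_of(rs)
  if (length(reads) == 0L) stop("empty read set")
  minLen <- min(nchar(reads))
  if (minLen < 16L) stop("shortest read (", minLen, " nt) is too short for assembly")
  if (minLen > default) return(as.integer(default))
  k <- minLen - 1L
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 15L)
}

#' Assemble reads into circular plasmid contigs
#'
#' Builds the de Bruijn graph on canonical k-mers with count >=
#' \code{minKmerCount}, clips tips (dead-end unitigs up to
#' \code{tipLenMax} bases), pops simple bubbles keeping the higher-depth
#' branch (ties: lexicographically smaller sequence), drops whole components
#' whose median k-mer depth is below \code{relDepthFloor} times the dominant
#' component's median, compacts maximal non-branching paths, and emits
#' unitigs that close into a simple cycle as circular contigs (overlap
#' trimmed, canonical rotation). Remaining unitigs are emitted as linear
#' contigs on the lexicographically smaller strand. Contigs are sorted by
#' length descending; the whole procedure is deterministic (all tie-breaks
#' are by lexicographic k-mer order).
#'
#' An empty graph after pruning yields an [AssemblyResult-class] with zero
#' contigs (a NO_ASSEMBLY outcome), not an error.
#'
#' @param rs a [ReadSet-class] (mates are used as single-end reads) or a
#'   character vector of read sequences.
#' @param ap an [AssemblyParams-class].
#' @return An [AssemblyResult-class].
#' @examples
#' # a toy 8 bp circular plasmid covered by its eight circular 6-mers
#' p <- "ATGGCGTA"
#' reads <- substring(paste0(p, p), 1:8, 6:13)
#' asm <- assembleReads(reads, assemblyParams(k = 15)) # k too big for toy; see tests
#' @export
assembleReads <- function(rs, ap = assemblyParams()) {
  stopifnot(is(ap, "AssemblyParams"))
  reads <- .reads_of(rs)
  if (length(reads) == 0L) stop("empty read set")
  res <- .assemble_cpp(reads, ap@k, ap@minKmerCount, ap@tipLenMax,
                       ap@relDepthFloor)
  new("AssemblyResult", seq = as.character(res$seq),
      circular = as.logical(res$circular),
      meanDepth = as.numeric(res$mean_depth),
      params = ap, totalReadsUsed = length(reads))
}

#' Write contigs to FASTA
#'
#' Headers carry the contig id, length, circularity flag and mean k-mer
#' depth; output is byte-identical across runs for identical inputs.
#'
#' @param ar an [AssemblyResult-class].
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
writeAssemblyFasta <- function(ar, path) {
  stopifnot(is(ar, "AssemblyResult"))
  seqs <- ar@seq
  names(seqs) <- sprintf("contig_%d length=%d circular=%s mean_depth=%.2f",
                         seq_along(seqs), nchar(seqs),
                         ifelse(ar@circular, "true", "false"), ar@meanDepth)
  writeFasta(seqs, path)
}
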