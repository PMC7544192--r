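# Synthetic plasmids, sequence variants, Illumina-like paired-end read
# simulation, and contamination spiking. Everything is deterministic under
# the supplied seed (withr::with_seed isolates the RNG state).

.circular_substr <- function(s, start, len) {
  # 1-based circular substring of length len starting at start
  substring(paste0(s, s), start, start + len - 1L)
}

#' Generate a random circular plasmid
#'
#' Bases are drawn i.i.d. with expected GC fraction \code{gc}. Plasmid-scale
#' lengths (the validated regime is roughly 2.5--3.3 kb) are expected;
#' lengths below 200 bp are rejected as too short to assemble meaningfully.
#'
#' @param length plasmid length in bp (>= 200); default 2521.
#' @param gc expected GC fraction in (0, 1).
#' @param seed RNG seed.
#' @param id record id.
#' @return A circular [PlasmidRecord-class].
#' @examples
#' generatePlasmid(2521, 0.5, seed = 1)
#' @export
generatePlasmid <- function(length = 2521L, gc = 0.5, seed = 1L,
                            id = sprintf("plasmid_s%d", seed)) {
  length <- as.integer(length)
  if (length < 200L) stop("plasmid length must be >= 200 bp")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  bases <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  plasmidRecord(id, paste(bases, collapse = ""), circular = TRUE)
}

.gc_of <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / n
}

#' Derive a contaminant variant from a plasmid
#'
#' \code{"snp"} substitutes exactly \code{nSnps} positions (uniform without
#' replacement) with a different base; \code{"deletion"} removes a contiguous
#' circular block; \code{"insertion"} inserts a random block;
#' \code{"unrelated"} generates a fresh random plasmid of the same length and
#' GC content. Deterministic under the spec's seed.
#'
#' @param p a [PlasmidRecord-class].
#' @param v a [VariantSpec-class].
#' @return A new circular [PlasmidRecord-class].
#' @examples
#' p <- generatePlasmid(2521, 0.5, seed = 1)
#' applyVariant(p, variantSpec("snp", nSnps = 4, seed = 7))
#' @export
applyVariant <- function(p, v) {
  stopifnot(is(p, "PlasmidRecord"), is(v, "VariantSpec"))
  L <- nchar(p@seq)
  newid <- paste0(p@id, "_", v@kind)
  if (v@kind == "snp") {
    seq <- withr::with_seed(v@seed, {
      pos <- sample.int(L, v@nSnps)
      s <- strsplit(p@seq, "", fixed = TRUE)[[1]]
      for (i in pos) {
        alt <- setdiff(c("A", "C", "G", "T"), s[i])
        s[i] <- sample(alt, 1L)
      }
      paste(s, collapse = "")
    })
  } else if (v@kind == "deletion") {
    if (v@length >= L) stop("deletion length must be smaller than the plasmid")
    seq <- withr::with_seed(v@seed, {
      start <- sample.int(L, 1L)
      # circular removal of [start, start+length-1]: keep the complementary arc
      .circular_substr(p@seq, (start + v@length - 1L) %% L + 1L, L - v@length)
    })
  } else if (v@kind == "insertion") {
    seq <- withr::with_seed(v@seed, {
      pos <- sample.int(L, 1L)
      block <- paste(sample(c("A", "C", "G", "T"), v@length, replace = TRUE),
                     collapse = "")
      paste0(substr(p@seq, 1L, pos), block,
             substr(p@seq, pos + 1L, L))
    })
  } else {  # unrelated
    return(generatePlasmid(L, .gc_of(p@seq), seed = v@seed, id = newid))
  }
  plasmidRecord(newid, seq, circular = TRUE)
}

#' Simulate Illumina-like paired-end reads from a circular plasmid
#'
#' Fragments start uniformly on the circle (so origin coverage is unbiased)
#' with Gaussian insert lengths clamped to \code{[readLen, length(p)]}. R1 is
#' the fragment 5' prefix, R2 the reverse complement of its 3' suffix (FR
#' orientation). Each pair is assigned a "good" or "bad" quality class (both
#' mates share the class; mate qualities are strongly correlated on real
#' instruments); per-base Phred scores are drawn around the class mean (sd 3,
#' clamped to \[2, 41\]) and substitution errors are applied per base with
#' probability \code{max(baseErrorRate, 10^(-q/10))}. Setting
#' \code{baseErrorRate = 0} disables substitutions entirely (the exact
#' error-free limit used by reconstruction tests).
#'
#' @param p a circular [PlasmidRecord-class].
#' @param nPairs number of read pairs (>= 1).
#' @param m an [ErrorModel-class].
#' @param seed RNG seed; identical seeds give identical ReadSets.
#' @param provenanceLabel label recorded on every pair (default
#'   \code{"primary"}).
#' @return A [ReadSet-class] of \code{nPairs} pairs.
#' @examples
#' p <- generatePlasmid(2521, 0.5, seed = 1)
#' rs <- simulateReads(p, 100, errorModel(), seed = 2)
#' @export
simulateReads <- function(p, nPairs, m = errorModel(), seed = 1L,
                          provenanceLabel = "primary") {
  stopifnot(is(p, "PlasmidRecord"), is(m, "ErrorModel"))
  nPairs <- as.integer(nPairs)
  if (nPairs < 1L) stop("nPairs must be >= 1")
  L <- nchar(p@seq)
  if (m@readLen > L) stop("readLen exceeds plasmid length")
  withr::with_seed(seed, {
    starts <- sample.int(L, nPairs, replace = TRUE)          # 1-based
    ins <- as.integer(pmin(pmax(round(rnorm(nPairs, m@insertMean, m@insertSd)),
                                m@readLen), L))
    r1f <- .circular_substr(p@seq, starts, m@readLen)
    r2f <- revComp(.circular_substr(
      p@seq, (starts + ins - m@readLen - 1L) %% L + 1L, m@readLen))
    good <- runif(nPairs) >= m@fracBadReads                  # per-pair class
    qmean <- ifelse(good, m@qualMeanGood, m@qualMeanBad)
    b1 <- .sim_block_cpp(r1f, qmean, 3, 2L, 41L, m@baseErrorRate)
    b2 <- .sim_block_cpp(r2f, qmean, 3, 2L, 41L, m@baseErrorRate)
    readSet(r1 = b1$seq, r2 = b2$seq, q1 = b1$qual, q2 = b2$qual,
            pairId = sprintf("%s:%d", p@id, seq_len(nPairs)),
            provenance = provenanceLabel, sourceId = p@id)
  })
}

#' Spike contaminant read pairs into a primary read set
#'
#' Draws \code{round(fraction * totalPairs)} pairs (round-half-even) without
#' replacement from the contaminant set and the remainder from the primary
#' set, then shuffles the order. Provenance labels are preserved, so the
#' mixture carries its own ground truth. Contaminant fractions above 50% are
#' outside the validated regime and rejected.
#'
#' @param primary,contaminant [ReadSet-class] inputs.
#' @param fraction contaminant fraction of the output, in \[0, 0.5\].
#' @param totalPairs number of pairs in the output.
#' @param seed RNG seed.
#' @return A shuffled [ReadSet-class] with exactly \code{totalPairs} pairs.
#' @export
mixReads <- function(primary, contaminant, fraction, totalPairs, seed = 1L) {
  stopifnot(is(primary, "ReadSet"))
  if (fraction < 0 || fraction > 0.5)
    stop("contaminant fraction must be in [0, 0.5]")
  totalPairs <- as.integer(totalPairs)
  nc <- as.integer(round(fraction * totalPairs))  # round-half-even
  np <- totalPairs - nc
  if (np > nPairs(primary))
    stop("primary ReadSet too small: need ", np, " pairs")
  if (nc > 0L) {
    stopifnot(is(contaminant, "ReadSet"))
    if (nc > nPairs(contaminant))
      stop("contaminant ReadSet too small: need ", nc, " pairs")
  }
  withr::with_seed(seed, {
    ip <- sample.int(nPairs(primary), np)
    sub <- primary[ip]
    if (nc > 0L) {
      ic <- sample.int(nPairs(contaminant), nc)
      cc <- contaminant[ic]
      sub <- new("ReadSet",
                 pairId = c(sub@pairId, cc@pairId),
                 r1 = c(sub@r1, cc@r1), r2 = c(sub@r2, cc@r2),
                 q1 = c(sub@q1, cc@q1), q2 = c(sub@q2, cc@q2),
                 provenance = c(sub@provenance, cc@provenance),
                 sourceId = paste0(primary@sourceId, "+", contaminant@sourceId))
    }
    sub[sample.int(nPairs(sub))]
  })
}
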