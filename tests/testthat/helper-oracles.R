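# Brute-force oracles (kept deliberately naive and independent of the
# package's C++ implementations) plus small fixture builders.

rotate_str <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1, n), substr(s, 1, r))
}

# canonical rotation by exhaustive enumeration of all rotations, both strands
brute_canonical <- function(s) {
  n <- nchar(s)
  rc <- revComp(s)
  min(c(vapply(0:(n - 1), rotate_str, "", s = s),
        vapply(0:(n - 1), rotate_str, "", s = rc)))
}

# circular read matching by trying every rotation of the contig, both strands
brute_circular_match <- function(read, contig, circular = TRUE) {
  if (grepl("N", read, fixed = TRUE)) return(FALSE)
  if (nchar(read) > nchar(contig)) return(FALSE)
  rots <- if (circular) 0:(nchar(contig) - 1) else 0
  for (r in rots) {
    d <- rotate_str(contig, r)
    if (grepl(read, d, fixed = TRUE) || grepl(revComp(read), d, fixed = TRUE))
      return(TRUE)
  }
  FALSE
}

# AUC by pairwise enumeration (ties count one half)
brute_auc <- function(clean, contam) {
  cmp <- outer(contam, clean, ">") + 0.5 * outer(contam, clean, "==")
  mean(cmp)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# quality string with constant Phred value
qstr <- function(q, len) strrep(intToUtf8(33L + q), len)

# tiny ReadSet with given per-mate constant qualities
toy_readset <- function(r1, r2, q1 = 38L, q2 = 38L, ...) {
  readSet(r1 = r1, r2 = r2,
          q1 = mapply(qstr, rep_len(q1, length(r1)), nchar(r1)),
          q2 = mapply(qstr, rep_len(q2, length(r2)), nchar(r2)), ...)
}

# error model for the exact error-free limit
clean_error_model <- function(readLen = 150L, insertMean = 300L, ...) {
  errorModel(readLen = readLen, insertMean = insertMean, baseErrorRate = 0,
             fracBadReads = 0, qualMeanGood = 41, ...)
}
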