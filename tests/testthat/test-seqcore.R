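test_that("reverse complement is correct and involutive", {
  expect_identical(revComp("ACGT"), "ACGT")  # palindrome
  expect_identical(revComp("AACG"), "CGTT")
  expect_identical(revComp("AN"), "NT")
  expect_error(revComp("ACGX"), "invalid character")
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(sample(1:80, 1))
    expect_identical(revComp(revComp(s)), s)
  }
})

test_that("canonical rotation matches the brute-force oracle and is idempotent", {
  expect_identical(canonicalRotation("AACG"), "AACG")
  expect_identical(canonicalRotation("GAAC"), "AACG")
  expect_identical(canonicalRotation("T"), "A")
  expect_error(canonicalRotation(""), "empty")
  expect_error(canonicalRotation("ACN"), "N")
  set.seed(21)
  for (i in 1:60) {
    s <- random_dna(sample(1:100, 1))
    cs <- canonicalRotation(s)
    expect_identical(cs, brute_canonical(s))
    expect_identical(canonicalRotation(cs), cs)  # idempotent
  }
})

test_that("circular equality is rotation/strand invariant and an equivalence relation", {
  expect_true(circularEqual("ATGGCGTA", "CGTAATGG"))
  expect_true(circularEqual("ATGGCGTA", revComp("ATGGCGTA")))
  expect_false(circularEqual("ATGGCGTA", "ATGGCGTT"))
  set.seed(31)
  for (i in 1:30) {
    s <- random_dna(sample(2:60, 1))
    r <- sample(0:(nchar(s) - 1), 1)
    expect_true(circularEqual(s, s))                      # reflexive
    expect_true(circularEqual(s, rotate_str(s, r)))       # rotation
    expect_true(circularEqual(s, revComp(s)))             # strand
    expect_true(circularEqual(rotate_str(s, r), s))       # symmetric
    # transitivity through rotation and strand flip
    expect_true(circularEqual(rotate_str(s, r), revComp(s)))
  }
})

test_that("circular matching agrees with the all-rotations brute-force oracle", {
  expect_true(circularMatch("CACG", "ACGTAC"))   # spans the origin
  expect_false(circularMatch("GGGG", "ACGTAC"))
  expect_true(circularMatch("ACGTAC", "ACGTAC")) # full-length self-match
  expect_false(circularMatch("ACGTACA", "ACGTAC"))  # longer than contig
  expect_false(circularMatch("ACNT", "ACGTACNT"))   # N never matches
  set.seed(41)
  for (i in 1:120) {
    contig <- random_dna(sample(5:50, 1))
    circ <- sample(c(TRUE, FALSE), 1)
    read <- if (runif(1) < 0.6) {
      # a true circular substring (possibly rc) to exercise hits
      len <- sample(1:nchar(contig), 1)
      start <- sample(1:nchar(contig), 1)
      x <- substr(rotate_str(contig, start - 1), 1, len)
      if (runif(1) < 0.5) revComp(x) else x
    } else random_dna(sample(1:12, 1))
    expect_identical(circularMatch(read, contig, circular = circ),
                     brute_circular_match(read, contig, circular = circ),
                     label = sprintf("read=%s contig=%s circ=%s", read, contig, circ))
  }
})

test_that("FASTA round-trips records and wraps at 70 columns", {
  d <- withr::local_tempdir()
  p1 <- plasmidRecord("pA", random_dna(151))
  p2 <- plasmidRecord("pB", random_dna(70))
  f <- file.path(d, "p.fasta")
  writeFasta(list(p1, p2), f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 70))
  back <- readFasta(f)
  expect_identical(vapply(back, function(p) p@id, ""), c("pA", "pB"))
  expect_identical(back[[1]]@seq, p1@seq)
  expect_identical(back[[2]]@seq, p2@seq)
  expect_error(readFasta(file.path(d, "absent.fasta")), "not found")
})

test_that("FASTQ pair round-trip is exact, supports gzip, and rejects bad input", {
  d <- withr::local_tempdir()
  rs <- toy_readset(r1 = c("ACGTACGT", "TTTTACGT"), r2 = c("GGGGACGT", "ACACACAC"),
                    q1 = c(0L, 40L), q2 = c(40L, 12L), sourceId = "toy")
  f1 <- file.path(d, "t_R1.fastq"); f2 <- file.path(d, "t_R2.fastq")
  writeFastqPair(rs, f1, f2)
  back <- readFastqPair(f1, f2)
  expect_identical(back@r1, rs@r1)
  expect_identical(back@r2, rs@r2)
  expect_identical(back@q1, rs@q1)
  expect_identical(back@q2, rs@q2)
  expect_identical(pairIds(back), pairIds(rs))
  # byte-identical re-write (uncompressed)
  g1 <- file.path(d, "u_R1.fastq"); g2 <- file.path(d, "u_R2.fastq")
  writeFastqPair(back, g1, g2)
  expect_identical(readLines(g1), readLines(f1))
  expect_identical(readLines(g2), readLines(f2))
  # gzip by suffix
  z1 <- file.path(d, "z_R1.fastq.gz"); z2 <- file.path(d, "z_R2.fastq.gz")
  writeFastqPair(rs, z1, z2)
  expect_identical(readFastqPair(z1, z2)@r1, rs@r1)
  # Phred+33: '!' is Q0, 'I' is Q40
  expect_identical(meanPhred("!"), 0)
  expect_identical(meanPhred("I"), 40)
  # mismatched record counts
  writeLines(readLines(f1)[1:4], file.path(d, "short_R1.fastq"))
  expect_error(readFastqPair(file.path(d, "short_R1.fastq"), f2),
               "record counts differ")
  expect_error(readFastqPair(file.path(d, "absent.fastq"), f2), "not found")
})

test_that("ReadSet validity enforces quality/sequence consistency", {
  expect_error(readSet("ACGT", "ACGT", "III", "IIII"), "length")
  expect_error(readSet("ACGT", "ACGT", "IIII", "IIIK"), "41")
  expect_error(readSet("ACGU", "ACGT", "IIII", "IIII"), "A,C,G,T,N")
  rs <- readSet("ACGT", "ACGT", "IIII", "IIII", provenance = "primary")
  expect_identical(nPairs(rs), 1L)
  expect_error(provenance(rs) <- "weird", "provenance")
})
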