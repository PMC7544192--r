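test_that("plasmid generation is deterministic with the requested length and GC", {
  p <- generatePlasmid(2521, 0.5, seed = 1)
  expect_identical(nchar(p@seq), 2521L)
  expect_true(p@circular)
  expect_identical(generatePlasmid(2521, 0.5, seed = 1)@seq, p@seq)
  expect_false(generatePlasmid(2521, 0.5, seed = 2)@seq == p@seq)
  expect_error(generatePlasmid(150, 0.5, seed = 1), ">= 200")
  # empirical GC within 3 binomial standard errors of the target
  q <- generatePlasmid(6000, 0.62, seed = 9)
  gc <- nchar(gsub("[AT]", "", q@seq)) / 6000
  expect_lt(abs(gc - 0.62), 3 * sqrt(0.62 * 0.38 / 6000))
})

test_that("variants change the plasmid exactly as specified", {
  p <- generatePlasmid(2521, 0.5, seed = 3)
  # SNPs: length preserved, Hamming distance exactly nSnps
  v4 <- applyVariant(p, variantSpec("snp", nSnps = 4, seed = 5))
  expect_identical(nchar(v4@seq), nchar(p@seq))
  hamming <- sum(strsplit(p@seq, "")[[1]] != strsplit(v4@seq, "")[[1]])
  expect_identical(hamming, 4L)
  # determinism
  expect_identical(applyVariant(p, variantSpec("snp", nSnps = 1, seed = 8))@seq,
                   applyVariant(p, variantSpec("snp", nSnps = 1, seed = 8))@seq)
  # deletion: length reduced by exactly the block size, circularly
  dl <- applyVariant(p, variantSpec("deletion", length = 608, seed = 6))
  expect_identical(nchar(dl@seq), 2521L - 608L)
  # insertion adds the block
  ins <- applyVariant(p, variantSpec("insertion", length = 608, seed = 6))
  expect_identical(nchar(ins@seq), 2521L + 608L)
  # unrelated keeps length but shares no circular identity
  un <- applyVariant(p, variantSpec("unrelated", seed = 7))
  expect_identical(nchar(un@seq), nchar(p@seq))
  expect_false(circularEqual(un@seq, p@seq))
  expect_error(applyVariant(p, variantSpec("deletion", length = 3000, seed = 1)),
               "smaller")
})

test_that("error-free simulated reads all match the source plasmid, including across the origin", {
  p <- generatePlasmid(400, 0.5, seed = 12)
  rs <- simulateReads(p, 300, clean_error_model(readLen = 120, insertMean = 200),
                      seed = 13)
  expect_identical(nPairs(rs), 300L)
  expect_true(all(circularMatch(rs@r1, p@seq)))
  expect_true(all(circularMatch(rs@r2, p@seq)))
  # with only 400 bp and 300 fragments, many spanned the origin: confirm some
  # reads are absent from the *linearized* sequence yet match circularly
  lin1 <- circularMatch(rs@r1, p@seq, circular = FALSE)
  expect_gt(sum(!lin1), 0)
  expect_identical(provenance(rs), rep("primary", 300))
  # determinism
  rs2 <- simulateReads(p, 300, clean_error_model(readLen = 120, insertMean = 200),
                       seed = 13)
  expect_identical(rs2@r1, rs@r1)
  expect_identical(rs2@q2, rs@q2)
  expect_error(simulateReads(p, 10, errorModel(readLen = 500, insertMean = 500)),
               "readLen exceeds")
})

test_that("empirical substitution rate approaches the configured rate", {
  p <- generatePlasmid(2000, 0.5, seed = 22)
  em <- errorModel(baseErrorRate = 0.004, fracBadReads = 0, qualMeanGood = 41)
  rs <- simulateReads(p, 2000, em, seed = 23)
  ref <- simulateReads(p, 2000, clean_error_model(), seed = 23)
  nbases <- sum(nchar(rs@r1)) + sum(nchar(rs@r2))
  nerr <- sum(strsplit(paste0(rs@r1, collapse = ""), "")[[1]] !=
              strsplit(paste0(ref@r1, collapse = ""), "")[[1]]) +
          sum(strsplit(paste0(rs@r2, collapse = ""), "")[[1]] !=
              strsplit(paste0(ref@r2, collapse = ""), "")[[1]])
  rate <- nerr / nbases
  se <- sqrt(0.004 * 0.996 / nbases)
  expect_lt(abs(rate - 0.004), 3 * se)
})

test_that("read mixing conserves counts, labels and the requested fraction", {
  p <- generatePlasmid(500, 0.5, seed = 31)
  q <- generatePlasmid(500, 0.5, seed = 32)
  a <- simulateReads(p, 900, clean_error_model(readLen = 50, insertMean = 100),
                     seed = 33, provenanceLabel = "primary")
  b <- simulateReads(q, 900, clean_error_model(readLen = 50, insertMean = 100),
                     seed = 34, provenanceLabel = "contaminant")
  mx <- mixReads(a, b, 0.2, 1000, seed = 35)
  expect_identical(nPairs(mx), 1000L)
  expect_identical(sum(provenance(mx) == "contaminant"), 200L)
  expect_identical(sum(provenance(mx) == "primary"), 800L)
  # fraction 0: all primary, no contaminant set touched
  mx0 <- mixReads(a, b, 0, 800, seed = 36)
  expect_true(all(provenance(mx0) == "primary"))
  # round-half-even: 0.5 * 1001 = 500.5 rounds to 500
  p2 <- simulateReads(p, 600, clean_error_model(readLen = 50, insertMean = 100),
                      seed = 37)
  b2 <- simulateReads(q, 600, clean_error_model(readLen = 50, insertMean = 100),
                      seed = 38, provenanceLabel = "contaminant")
  mx5 <- mixReads(p2, b2, 0.5, 1001, seed = 39)
  expect_identical(sum(provenance(mx5) == "contaminant"), 500L)
  # realized fraction within 1/total of the request, generally
  set.seed(40)
  for (f in c(0.1, 0.33, 0.5)) {
    m <- mixReads(a, b, f, 700, seed = sample.int(1e6, 1))
    expect_lte(abs(mean(provenance(m) == "contaminant") - f), 1 / 700)
  }
  # determinism and error paths
  expect_identical(pairIds(mixReads(a, b, 0.2, 1000, seed = 35)), pairIds(mx))
  expect_error(mixReads(a, b, 0.6, 100), "0.5")
  expect_error(mixReads(a, b, 0.5, 5000), "too small")
})
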