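test_that("mean Phred is the arithmetic mean of the integer scores", {
  expect_identical(meanPhred(c(30L, 40L)), 35)
  expect_identical(meanPhred(38L), 38)
  expect_identical(meanPhred(c(2L, 2L, 2L, 2L)), 2)
  expect_error(meanPhred(integer()), "empty")
  expect_error(meanPhred(""), "empty")
  expect_identical(meanPhred(c("!I", "II")), c(20, 40))
})

test_that("threshold filtering requires both mates to pass quality and length", {
  rs <- toy_readset(
    r1 = c(strrep("A", 130), strrep("C", 130), strrep("G", 130), strrep("T", 100)),
    r2 = c(strrep("T", 130), strrep("G", 130), strrep("C", 130), strrep("A", 130)),
    q1 = c(38L, 38L, 38L, 38L),
    q2 = c(37L, 30L, 36L, 38L))
  kept <- filterReads(rs, filterParams(minMeanQ = 36, minLen = 125))
  # pair 2 fails on the R2 mate quality, pair 4 on R1 length
  expect_identical(pairIds(kept), c("pair_1", "pair_3"))
  # empty output is allowed
  none <- filterReads(rs, filterParams(minMeanQ = 40, minLen = 125))
  expect_identical(nPairs(none), 0L)
})

test_that("top-fraction filtering keeps ceil(fraction*n) pairs, ties by input order", {
  n <- 100L
  quals <- rep(c(30L, 35L), 50)  # two tie groups
  rs <- toy_readset(r1 = replicate(n, random_dna(60)),
                    r2 = replicate(n, random_dna(60)),
                    q1 = quals, q2 = quals)
  kept <- filterReads(rs, filterParams(topFraction = 0.071))
  expect_identical(nPairs(kept), 8L)  # ceil(7.1)
  # all kept pairs come from the Q35 group, earliest input positions first
  expect_identical(pairIds(kept), paste0("pair_", seq(2, 16, by = 2)))
  # survivors keep original relative order
  expect_false(is.unsorted(as.integer(sub("pair_", "", pairIds(kept)))))
})

test_that("filtering is monotone in the threshold and idempotent", {
  p <- generatePlasmid(800, 0.5, seed = 51)
  rs <- simulateReads(p, 600, errorModel(readLen = 100, insertMean = 200),
                      seed = 52)
  nkept <- vapply(c(10, 25, 30, 36, 39), function(q)
    nPairs(filterReads(rs, filterParams(minMeanQ = q, minLen = 50))), 0L)
  expect_false(is.unsorted(rev(nkept)))  # non-increasing in minMeanQ
  fp <- filterParams(minMeanQ = 36, minLen = 50)
  once <- filterReads(rs, fp)
  twice <- filterReads(once, fp)
  expect_identical(pairIds(twice), pairIds(once))
  expect_identical(twice@q1, once@q1)
})

test_that("a 93%-bad-quality library lands in the few-percent retained regime", {
  p <- generatePlasmid(2521, 0.5, seed = 61)
  rs <- simulateReads(p, 2000, errorModel(fracBadReads = 0.93), seed = 62)
  kept <- filterReads(rs, filterParams())
  retained_pct <- 100 * nPairs(kept) / nPairs(rs)
  expect_gte(retained_pct, 3)
  expect_lte(retained_pct, 11)
  s <- filterSummary(rs, kept)
  expect_identical(s$retained_pairs, nPairs(kept))
  expect_gt(s$mean_quality_after, s$mean_quality_before)
})

test_that("coverage capping subsamples to the documented pair count", {
  r <- strrep("A", 150)
  q <- qstr(38L, 150L)
  n <- 50000L
  rs <- readSet(r1 = rep(r, n), r2 = rep(r, n), q1 = rep(q, n), q2 = rep(q, n),
                provenance = rep(c("primary", "contaminant"), length.out = n))
  fp <- filterParams(targetCoverage = 500, plasmidLenEstimate = 3000L)
  sub <- subsampleReads(rs, fp, seed = 71)
  expect_identical(nPairs(sub), 5000L)  # floor(500*3000/300)
  # subset of the input, order preserved, provenance intact
  idx <- as.integer(sub("pair_", "", pairIds(sub)))
  expect_false(is.unsorted(idx))
  expect_identical(provenance(sub),
                   rep(c("primary", "contaminant"), length.out = n)[idx])
  # deterministic
  expect_identical(pairIds(subsampleReads(rs, fp, seed = 71)), pairIds(sub))
  # below-target input is returned unchanged
  small <- rs[1:1000]
  expect_identical(pairIds(subsampleReads(small, fp, seed = 72)),
                   pairIds(small))
  expect_error(subsampleReads(rs, filterParams(targetCoverage = 500)), "required")
  expect_error(subsampleReads(rs, fp, nPairsTarget = 0), "positive")
})
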