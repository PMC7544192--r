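.mk_asm <- function(seqs, circular = TRUE) {
  new("AssemblyResult", seq = as.character(seqs),
      circular = rep_len(circular, length(seqs)),
      meanDepth = rep_len(100, length(seqs)),
      params = assemblyParams(), totalReadsUsed = 0L)
}

test_that("assembly classification follows the four-outcome scheme, rotation/strand invariant", {
  p <- generatePlasmid(400, 0.5, seed = 101)
  q <- generatePlasmid(400, 0.5, seed = 102)
  rot <- paste0(substr(p@seq, 101, 400), substr(p@seq, 1, 100))
  expect_identical(classifyAssembly(.mk_asm(character()), p), "NO_ASSEMBLY")
  expect_identical(classifyAssembly(.mk_asm(c(p@seq, q@seq)), p), "FRAGMENTED")
  expect_identical(classifyAssembly(.mk_asm(rot), p), "CORRECT_PRIMARY")
  expect_identical(classifyAssembly(.mk_asm(revComp(rot)), p), "CORRECT_PRIMARY")
  expect_identical(classifyAssembly(.mk_asm(revComp(q@seq)), p, q),
                   "MATCHES_CONTAMINANT")
  expect_identical(classifyAssembly(.mk_asm(q@seq), p), "MISMATCH")
})

test_that("exact back-mapping counts distinct reads, both mates, either strand", {
  contig <- generatePlasmid(300, 0.5, seed = 111)@seq
  asm <- .mk_asm(contig)
  rs <- readSet(
    r1 = c(substr(contig, 1, 40), revComp(substr(contig, 51, 90))),
    r2 = c(substr(contig, 101, 140), strrep("A", 40)),
    q1 = rep(qstr(38L, 40L), 2), q2 = rep(qstr(38L, 40L), 2))
  rep <- exactMatchStats(asm, rs)
  expect_identical(rep@nDistinct, 4L)
  expect_identical(rep@nMatched, 3L)
  expect_identical(mismatchPct(rep), 25)
  # duplicated read strings collapse before counting
  rs2 <- rs[c(1, 1, 2, 2)]
  expect_identical(exactMatchStats(asm, rs2)@nDistinct, 4L)
  # error-free self-reads give mismatch 0, despite origin-spanning fragments
  p <- generatePlasmid(500, 0.5, seed = 112)
  selfrs <- simulateReads(p, 400, clean_error_model(readLen = 100,
                                                    insertMean = 200),
                          seed = 113)
  expect_identical(mismatchPct(exactMatchStats(.mk_asm(p@seq), selfrs)), 0)
  expect_error(exactMatchStats(.mk_asm(character()), rs), "no contigs")
})

test_that("mismatch percentage rises with the contaminant fraction", {
  p <- generatePlasmid(2000, 0.5, seed = 121)
  cont <- applyVariant(p, variantSpec("unrelated", seed = 122))
  a <- simulateReads(p, 2400, errorModel(fracBadReads = 0), seed = 123)
  b <- simulateReads(cont, 2400, errorModel(fracBadReads = 0), seed = 124,
                     provenanceLabel = "contaminant")
  asm <- .mk_asm(p@seq)  # back-map against the primary truth
  mm <- vapply(c(0, 0.1, 0.2, 0.35, 0.5), function(f) {
    mx <- mixReads(a, b, f, 2000, seed = 125)
    mismatchPct(exactMatchStats(asm, mx))
  }, 0)
  expect_false(is.unsorted(mm, strictly = TRUE))
})

test_that("logistic calibration separates classes, stays monotone, and handles degeneracy", {
  cm <- fitCalibration(rep(10, 25), rep(20, 25), id = "sep")
  expect_gte(cm@slope, 0)
  expect_lt(contaminationProbability(10, cm), 0.5)
  expect_gt(contaminationProbability(20, cm), 0.5)
  # monotone non-decreasing on a grid
  grid <- contaminationProbability(seq(0, 40, by = 0.5), cm)
  expect_false(is.unsorted(grid))
  # identical class distributions: uninformative, p ~ 0.5 everywhere
  x <- rep(c(10, 12, 14), length.out = 30)
  cm0 <- fitCalibration(x, x, id = "flat")
  expect_lt(max(abs(contaminationProbability(c(5, 15, 25), cm0) - 0.5)), 0.05)
  # noisy overlapping classes around the validated regime:
  # boundary lies between the class means
  set.seed(131)
  clean <- rnorm(200, 11.7, 1.2)
  contam <- rnorm(200, 15.9, 1.8)
  cm2 <- fitCalibration(clean, contam, id = "regime")
  expect_lt(contaminationProbability(11.7, cm2), 0.5)
  expect_gt(contaminationProbability(15.9, cm2), 0.5)
  expect_error(fitCalibration(rep(10, 5), rep(20, 25)), "20 scores")
  expect_error(fitCalibration(rep(10, 25), rep(10, 25)), "degenerate")
})

test_that("ROC AUC equals the pairwise enumeration oracle", {
  expect_identical(rocAuc(c(10, 11), c(15, 16)), 1)
  expect_identical(rocAuc(10, 10), 0.5)
  expect_identical(rocAuc(c(10, 20), c(15, 25)), 0.75)
  set.seed(141)
  for (i in 1:40) {
    clean <- sample(0:30, sample(1:20, 1), replace = TRUE)
    contam <- sample(0:30, sample(1:20, 1), replace = TRUE)
    expect_equal(rocAuc(clean, contam), brute_auc(clean, contam))
  }
  expect_error(rocAuc(numeric(), 1), "non-empty")
})

test_that("the experiment harness is deterministic and validates its inputs", {
  s1 <- runContaminationExperiment(variantSpec("snp", 1), 0.2, nReps = 2,
                                   baseSeed = 151)
  s2 <- runContaminationExperiment(variantSpec("snp", 1), 0.2, nReps = 2,
                                   baseSeed = 151)
  expect_identical(s1, s2)
  expect_identical(s1$n_reps, 2L)
  expect_identical(nrow(attr(s1, "replicates")), 2L)
  expect_error(runContaminationExperiment(NULL, 0.2, nReps = 2), "VariantSpec")
  expect_error(runContaminationExperiment(NULL, 0.7, nReps = 2), "0.5")
})
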