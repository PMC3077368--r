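test_that("simulators are deterministic in the seed", {
  tree <- theTree()
  a1 <- simulateCodonAlignment(tree, nCodons = 40, seed = 7)
  a2 <- simulateCodonAlignment(tree, nCodons = 40, seed = 7)
  a3 <- simulateCodonAlignment(tree, nCodons = 40, seed = 8)
  expect_identical(stateMatrix(a1), stateMatrix(a2))
  expect_false(identical(stateMatrix(a1), stateMatrix(a3)))
  expect_identical(splitSeed(42, 3), splitSeed(42, 3))
  expect_true(splitSeed(42, 3) != splitSeed(42, 4))
  expect_lt(splitSeed(.Machine$integer.max, 10), 2^31)
})

test_that("zero-length branches copy the root state everywhere", {
  tree <- theTree()
  ids <- accelscreen:::branchIds(tree)
  z <- setNames(rep(0, length(ids)), ids)
  a <- simulateCodonAlignment(tree, dSr = z, aScale = z + 1, nCodons = 30,
                              seed = 2)
  expect_equal(length(unique(apply(stateMatrix(a), 2, function(col)
    length(unique(col))))), 1)
  expect_true(all(apply(stateMatrix(a), 2, function(col)
    length(unique(col)) == 1)))
  n <- simulateNtAlignment(tree, branchLengths = z, nSites = 30, seed = 2)
  expect_true(all(apply(stateMatrix(n), 2, function(col)
    length(unique(col)) == 1)))
  expect_error(simulateCodonAlignment(tree, nCodons = 0), "nCodons")
})

test_that("omega = 0 yields synonymous-only divergence at the expected rate", {
  tr2 <- readNewick("(A,B);")
  ids <- accelscreen:::branchIds(tr2)
  bl <- setNames(c(0.1, 0), ids)[ids]
  bl["A"] <- 0.1; bl["B"] <- 0
  ones <- setNames(rep(1, 2), ids)
  aln <- simulateCodonAlignment(tr2, dSr = bl, aScale = ones, omega = 0,
                                nCodons = 10000, seed = 13)
  st <- stateMatrix(aln)
  aa <- accelscreen:::.codonTable()$aa
  diffs <- st["A", ] != st["B", ]
  # no nonsynonymous differences at all
  expect_true(all(aa[st["A", diffs]] == aa[st["B", diffs]]))
  # observed divergence matches the transition-matrix expectation within 3 SE
  cp <- accelscreen:::.mg94Components(2, matrix(0.25, 3, 4))
  P <- accelscreen:::.transMatCpp(0.1 * cp$A, cp$pi)
  pDiff <- 1 - sum(cp$pi * diag(P))
  se <- sqrt(pDiff * (1 - pDiff) / 10000)
  expect_lt(abs(mean(diffs) - pDiff), 3 * se)
})

test_that("HKY simulation matches closed-form divergence and kappa structure", {
  tr2 <- readNewick("(A,B);")
  ids <- accelscreen:::branchIds(readNewick("(A,B);"))
  bl <- setNames(c(0.15, 0.05), c("A", "B"))
  aln <- simulateNtAlignment(tr2, branchLengths = bl, kappa = 3,
                             nSites = 50000, seed = 17)
  st <- stateMatrix(aln)
  Q <- hkyMatrix(3, rep(0.25, 4))@Q
  P <- accelscreen:::.transMatCpp(Q * 0.2, rep(0.25, 4))  # total path length
  pDiff <- 1 - sum(0.25 * diag(P))
  se <- sqrt(pDiff * (1 - pDiff) / 50000)
  expect_lt(abs(mean(st["A", ] != st["B", ]) - pDiff), 3 * se)
  # kappa = 1, equal frequencies: transitions:transversions ~ 1:2
  aln2 <- simulateNtAlignment(tr2, branchLengths = bl, kappa = 1,
                              nSites = 50000, seed = 18)
  s2 <- stateMatrix(aln2)
  d <- which(s2["A", ] != s2["B", ])
  isTs <- accelscreen:::.isTransition(c("A", "C", "G", "T")[s2["A", d]],
                                      c("A", "C", "G", "T")[s2["B", d]])
  expect_equal(mean(isTs), 1 / 3, tolerance = 0.05)
})

test_that("Brownian traits have the BM variance and covariance structure", {
  tr <- readNewick("((A:1,B:1):3,(C:3,D:3):1);")
  tips <- vapply(1:300, function(i)
    simulateTraitsBM(tr, sigma2 = 2, rootValue = 5, seed = i), numeric(4))
  expect_equal(mean(tips), 5, tolerance = 0.3)
  expect_equal(var(tips["A", ]), 2 * 4, tolerance = 1.6)  # sigma2 * depth
  # cherries share more path: cor(A,B) > cor(A,C)
  expect_gt(cor(tips["A", ], tips["B", ]), cor(tips["A", ], tips["C", ]))
  z <- simulateTraitsBM(tr, sigma2 = 0, rootValue = 1.5, seed = 3)
  expect_true(all(z == 1.5))
})

test_that("genotype simulator plants the odds ratio and LD structure", {
  ors <- vapply(1:60, function(i) {
    gm <- simulateGenotypes(list(nSnp = 1, blockSize = 1, missingRate = 0),
                            seed = 200 + i)
    st <- phenotypes(gm)$status
    allelicChisq(alleleCounts(dosage(gm)[st == 1, 1]),
                 alleleCounts(dosage(gm)[st == 0, 1]))$OR
  }, numeric(1))
  expect_gt(median(ors), 1.4)
  expect_lt(median(ors), 2.2)
  # an r2 = 1 LD block (blockRho = 1: identical haplotype alleles within
  # the block) is counted once by simpleM
  gm <- simulateGenotypes(list(nSnp = 4, blockSize = 4, blockRho = 1,
                               mafRange = c(0.3, 0.3), plantedOR = 1,
                               missingRate = 0), seed = 33)
  expect_equal(simpleMMeff(dosage(gm)), 1L)
  expect_error(simulateGenotypes(list(plantedOR = -1)), "OR")
})

test_that("locus neighborhoods are valid inputs for every downstream reader", {
  out <- simulateLocusNeighborhood(
    list(nNeighbors = 3, neighborCodons = 30, geneCodons = 30, nElements = 4,
         elementBp = 100, flankBp = 2000, scoreHighFraction = 0.5),
    seed = 5, outDir = od <- withr::local_tempdir())
  expect_true(all(file.exists(out$files)))
  # round-trip through the on-disk formats
  g <- readAlignment(file.path(od, "gene1.fasta"), "fasta", "codon")
  expect_identical(stateMatrix(g)[taxa(out$gene), ], stateMatrix(out$gene))
  els <- readBed(file.path(od, "gene1_elements.bed"))
  expect_equal(length(els), 4)
  expect_equal(S4Vectors::mcols(els)$score,
               S4Vectors::mcols(out$elements)$score)
  expect_equal(GenomicRanges::start(els), GenomicRanges::start(out$elements))
  tree <- readNewick(readLines(file.path(od, "tree.nwk")))
  expect_setequal(tree$tip.label, taxa(out$gene))
  man <- read.table(file.path(od, "gene1_manifest.tsv"), header = TRUE)
  expect_equal(nrow(man), 3)
  truth <- jsonlite::read_json(file.path(od, "gene1_truth.json"))
  expect_equal(truth$seed, 5)
  # downstream fits accept the simulated pieces
  ctx <- fitNoncodingRegional(out$flankAlignments, theTree(), spanBp = 2000,
                              maxit = 40)
  expect_s4_class(ctx, "RegionalContext")
})
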