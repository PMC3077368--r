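mkGr <- function(starts, ends, names, chrom = "chr1", scores = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1L, ends))
  S4Vectors::mcols(gr)$name <- names
  if (!is.null(scores)) S4Vectors::mcols(gr)$score <- scores
  gr
}

test_that("conservation-score filter is inclusive at the threshold", {
  gr <- mkGr(c(0, 100, 200), c(50, 150, 250), c("a", "b", "c"),
             scores = c(400, 399.9, 700))
  kept <- filterElements(gr, 400)
  expect_setequal(S4Vectors::mcols(kept)$name, c("a", "c"))
  expect_length(filterElements(gr[0], 400), 0)
  expect_error(filterElements(mkGr(0, 10, "x"), 400), "no conservation score")
})

test_that("interval distance is symmetric and zero only on contact", {
  expect_equal(intervalDistance(0, 10, 5, 20), 0)    # overlap
  expect_equal(intervalDistance(0, 10, 10, 20), 0)   # bookended
  expect_equal(intervalDistance(0, 10, 15, 20), 5)
  expect_equal(intervalDistance(15, 20, 0, 10), 5)   # symmetric
  set.seed(2)
  for (i in 1:50) {
    s1 <- sample(1000, 1); e1 <- s1 + sample(100, 1)
    s2 <- sample(1000, 1); e2 <- s2 + sample(100, 1)
    d12 <- intervalDistance(s1, e1, s2, e2)
    expect_identical(d12, intervalDistance(s2, e2, s1, e1))
    overlapOrTouch <- s1 <= e2 && s2 <= e1
    expect_identical(d12 == 0, overlapOrTouch)
  }
})

test_that("nearest-gene assignment: containment, ties, and flags", {
  genes <- mkGr(c(1000, 10000), c(2000, 12000), c("A", "B"))
  els <- mkGr(c(1500, 3000, 2500), c(1600, 3100, 2600),
              c("inA", "midway", "nearA"))
  # midway: gap to A = 3000-2000 = 1000; gap to B = 10000-3100 = 6900 -> A
  out <- assignNearestGene(els, genes)
  expect_equal(out$gene[out$element == "inA"], "A")
  expect_equal(out$distance[out$element == "inA"], 0)
  expect_equal(out$gene[out$element == "nearA"], "A")
  # exact tie: element equidistant -> lower-coordinate gene, tie recorded
  tieEl <- mkGr(5500, 6500, "tie")  # gap to A = 3500, gap to B = 3500
  outT <- assignNearestGene(tieEl, genes)
  expect_equal(outT$gene, "A")
  expect_true(outT$tie)
  # chromosome without genes
  orphan <- mkGr(100, 200, "orphan", chrom = "chrX")
  outO <- assignNearestGene(orphan, genes)
  expect_true(is.na(outO$gene))
  expect_equal(outO$flag, "no_gene_on_chromosome")
})

test_that("nearest-gene assignment agrees with a brute-force scan", {
  set.seed(11)
  gs <- sort(sample(100000, 40))
  genes <- mkGr(gs, gs + sample(50:2000, 40, TRUE), paste0("g", 1:40))
  es <- sample(100000, 120)
  els <- mkGr(es, es + sample(10:500, 120, TRUE), paste0("e", 1:120))
  out <- assignNearestGene(els, genes)
  eS <- GenomicRanges::start(els) - 1L; eE <- GenomicRanges::end(els)
  gS <- GenomicRanges::start(genes) - 1L; gE <- GenomicRanges::end(genes)
  for (i in seq_along(els)) {
    d <- intervalDistance(eS[i], eE[i], gS, gE)
    best <- which(d == min(d))
    pick <- best[order(gS[best])][1]
    expect_equal(out$gene[i], paste0("g", pick))
    expect_equal(out$distance[i], min(d))
  }
})

test_that("flanking-sequence selection honors the span rule", {
  tree <- theTree()
  mkFlank <- function(n, seed) simulateNtAlignment(tree, nSites = n, seed = seed)
  flanks <- list(mkFlank(800, 1), mkFlank(900, 2), mkFlank(700, 3),
                 mkFlank(1000, 4))
  ctx <- fitNoncodingRegional(flanks, tree, spanBp = 2000, maxit = 50)
  expect_length(ctx@neighborIds, 3)  # 800 + 900 + 700 >= 2000, 4th ignored
  expect_false("short_flank" %in% ctx@flags)
  ctxShort <- fitNoncodingRegional(flanks[1:2], tree, spanBp = 5000, maxit = 50)
  expect_true("short_flank" %in% ctxShort@flags)
  expect_error(fitNoncodingRegional(flanks, tree, spanBp = 0), "positive")
  expect_error(fitNoncodingRegional(list(), tree), "zero flanking")
})

test_that("noncoding regional fit recovers planted branch lengths", {
  tree <- theTree()
  ids <- accelscreen:::branchIds(tree)
  bl <- setNames(rep(0.1, length(ids)), ids)
  flanks <- lapply(1:5, function(i)
    simulateNtAlignment(tree, branchLengths = bl, nSites = 5000,
                        seed = 700 + i))
  ctx <- fitNoncodingRegional(flanks, tree, spanBp = 25000)
  expect_lt(mean(abs(ctx@dSr / bl - 1)), 0.1)
  expect_equal(ctx@kappa, 2, tolerance = 0.15)
})

test_that("element acceleration LRT: null behavior and power", {
  tree <- theTree()
  ctx <- calibNtContext()
  # element evolving exactly at the regional rate: r_hat near 1
  aln <- simulateNtAlignment(tree, branchLengths = ctx@dSr, nSites = 2000,
                             rate = 1, seed = 55)
  res <- lrtAccelElement(aln, ctx, tree)
  expect_equal(omegaHat(res), 1, tolerance = 0.15)
  expect_gte(lrtStat(res), 0)
  expect_equal(pValue(res), pchisq(lrtStat(res), 1, lower.tail = FALSE))
  # planted 5x focal acceleration on 500-bp elements: strong power
  ps <- vapply(1:40, function(i) {
    a <- simulateNtAlignment(tree, branchLengths = ctx@dSr, nSites = 500,
                             rate = 1, focal = "Human", focalRate = 5,
                             seed = 800 + i)
    pValue(lrtAccelElement(a, ctx, tree))
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.5)
  # all-missing element alignment is flagged, not an error
  blank <- phyloAlignment(setNames(rep(strrep("N", 30), 7),
                                   mammalTree()$tip.label), "nucleotide")
  r0 <- lrtAccelElement(blank, ctx, tree)
  expect_true("all_missing" %in% flags(r0))
  expect_equal(pValue(r0), 1)
})
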