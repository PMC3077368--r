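test_that("Hardy-Weinberg chi-square matches hand computations", {
  expect_equal(hweChisq(25, 50, 25)$chi2, 0)
  expect_equal(hweChisq(25, 50, 25)$p, 1)
  expect_equal(hweChisq(50, 0, 50)$chi2, 100)  # expected 25/50/25
  lt <- hweChisq(0, 0, 100)
  expect_equal(lt$p, 1)
  expect_equal(lt$flag, "monomorphic")
  expect_error(hweChisq(0, 0, 0), "positive")
})

test_that("allelic chi-square equals the 2x2 closed form with cross-product OR", {
  r <- allelicChisq(c(30, 70), c(10, 90))
  expect_equal(r$chi2, 12.5)
  expect_equal(r$OR, 3.857143, tolerance = 1e-6)
  expect_true(r$CI95[1] < r$OR && r$OR < r$CI95[2])
  # identical frequencies
  r0 <- allelicChisq(c(20, 80), c(20, 80))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$OR, 1)
  # swapping case and control inverts OR, preserves chi2
  rs <- allelicChisq(c(10, 90), c(30, 70))
  expect_equal(rs$chi2, r$chi2)
  expect_equal(rs$OR, 1 / r$OR, tolerance = 1e-12)
  # random tables vs textbook formula and stats::chisq.test
  set.seed(14)
  for (i in 1:25) {
    tab <- matrix(sample(5:100, 4), 2)
    r1 <- allelicChisq(tab[1, ], tab[2, ])
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    expect_equal(r1$chi2,
                 n * (a * d - b * c_)^2 /
                   ((a + b) * (c_ + d) * (a + c_) * (b + d)),
                 tolerance = 1e-10)
    expect_equal(r1$chi2,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE))$statistic),
                 tolerance = 1e-10)
  }
  # zero cell: Haldane-Anscombe for the OR only, flagged
  rz <- allelicChisq(c(0, 100), c(10, 90))
  expect_equal(rz$flag, "haldane_correction")
  expect_true(is.finite(rz$OR) && rz$OR > 0)
})

test_that("genotypic chi-square matches stats::chisq.test", {
  ca <- c(30, 50, 20); co <- c(45, 40, 15)
  g <- genotypicChisq(ca, co)
  ref <- chisq.test(rbind(ca, co), correct = FALSE)
  expect_equal(g$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(g$df, 2)
  degenerate <- genotypicChisq(c(10, 0, 0), c(20, 0, 0))
  expect_equal(degenerate$p, 1)
})

test_that("quantitative Wald test: perfect fit and null behavior", {
  g <- rep(0:2, each = 20)
  w <- waldQuant(g, as.numeric(g))
  expect_equal(w$beta, 1, tolerance = 1e-12)
  expect_lt(w$p, 1e-12)
  expect_equal(waldQuant(rep(1, 30), rnorm(30))$flag, "constant_genotype")
  # permuting the phenotype destroys the association
  set.seed(26)
  y <- g + rnorm(60, 0, 0.5)
  expect_lt(waldQuant(g, scale(y)[, 1])$p, 1e-6)
  pPerm <- vapply(1:100, function(i) waldQuant(g, sample(scale(y)[, 1]))$p,
                  numeric(1))
  expect_gt(mean(pPerm < 0.05), 0.0)   # sanity: a few by chance at most
  expect_lt(mean(pPerm < 0.05), 0.15)
  expect_gt(ks.test(pPerm, "punif")$p.value, 0.01)
})

test_that("covariate-adjusted logistic test tracks the unadjusted one", {
  set.seed(61)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  cv <- rnorm(n)  # orthogonal covariate
  st <- rbinom(n, 1, plogis(-0.5 + 0.5 * g))
  la <- logisticAdjusted(st, g, cv)
  un <- summary(glm(st ~ g, family = binomial()))$coefficients["g", ]
  expect_equal(la$beta, unname(un["Estimate"]), tolerance = 0.1)
  expect_lt(abs(log(la$p) - log(un["Pr(>|z|)"])), 1)
  expect_equal(logisticAdjusted(st, g, g)$flag, "collinear")
})

test_that("simpleM effective tests from correlation eigenvalues", {
  set.seed(71)
  base <- matrix(rbinom(200 * 2, 2, 0.3), 200, 2)
  dup <- base[, c(1, 1, 2, 2)]
  expect_equal(simpleMMeff(dup), 2L)  # eigenvalues {2,2,0,0}
  ident <- matrix(rbinom(500 * 20, 2, 0.4), 500, 20)
  m <- simpleMMeff(ident)
  expect_lte(m, 20L)
  expect_gte(m, 18L)  # near-identity correlation: M_eff ~ M
  expect_equal(simpleMMeff(ident[, 1, drop = FALSE]), 1L)
  # blocks of fewer than 2 SNPs contribute their count
  expect_equal(simpleMMeff(ident, window = 1), 20L)
})

test_that("QC filtering applies the stated thresholds in order, idempotently", {
  set.seed(81)
  n <- 120; m <- 40
  d <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("i%03d", 1:n), paste0("s", 1:m)))
  status <- rep(0:1, each = n / 2)
  # s2: HWE failure in controls (all hets)
  d[status == 0, 2] <- 1
  # s3: low SNP call rate (individuals keep 39/40 = 97.5%)
  d[1:10, 3] <- NA
  # s4: MAF below threshold
  d[, 4] <- c(1, rep(0, n - 1))
  # s5: MAF exactly at the 0.05 boundary is retained (12 carriers / 240)
  d[, 5] <- 0; d[20:31, 5] <- 1
  gm <- genotypeMatrix(d, data.frame(status = status))
  out <- qcFilter(gm, snpCallRate = 0.95, mafMin = 0.05, hwePmin = 0.001)
  kept <- colnames(dosage(out$genotypes))
  expect_false("s2" %in% kept)
  expect_false("s3" %in% kept)
  expect_false("s4" %in% kept)
  expect_true("s5" %in% kept)  # MAF exactly 0.05 retained
  expect_equal(out$report$individualsRemoved, 0)
  # an individual below the 95% call rate is removed first
  d2 <- d; d2[11, 1:3] <- NA  # 37/40 = 92.5%
  out2 <- qcFilter(genotypeMatrix(d2, data.frame(status = status)))
  expect_equal(out2$report$individualsRemoved, 1)
  expect_false("i011" %in% rownames(dosage(out2$genotypes)))
  expect_true(all(c("hwe_controls", "call_rate", "maf") %in%
                  qcLog(out$genotypes)$reason))
  # idempotence
  again <- qcFilter(out$genotypes)
  expect_equal(dim(dosage(again$genotypes)), dim(dosage(out$genotypes)))
  expect_equal(sum(again$report$snpsRemoved), 0)
  expect_equal(again$report$individualsRemoved, 0)
})

test_that("duplicate probes collapse to the best call rate", {
  set.seed(82)
  d <- matrix(rbinom(200 * 30, 2, 0.4), 200, 30,
              dimnames = list(NULL, paste0("p", 1:30)))
  colnames(d)[1:3] <- c("a", "b", "c")
  d[1:8, "a"] <- NA  # "a" has the worse call rate of the duplicated pair
  si <- data.frame(id = colnames(d), chr = "chr1",
                   pos = c(500L, 500L, 900L, seq(2000L, by = 100L,
                                                 length.out = 27)),
                   alleleMinor = "A", alleleMajor = "G")
  gm <- genotypeMatrix(d, data.frame(status = rep(0:1, 100)), si)
  out <- qcFilter(gm)
  keptNames <- colnames(dosage(out$genotypes))
  expect_true("b" %in% keptNames)
  expect_false("a" %in% keptNames)
  expect_equal(out$report$snpsRemoved[["duplicate_probe"]], 1)
})

test_that("PLINK-text and dosage-TSV I/O round-trip", {
  gm <- simulateGenotypes(list(nSnp = 10, missingRate = 0.05,
                               mafRange = c(0.15, 0.4)), seed = 91)
  pre <- withr::local_tempfile()
  writePedMap(gm, pre)
  rt <- readPedMap(paste0(pre, ".ped"), paste0(pre, ".map"))
  expect_equal(dim(dosage(rt)), dim(dosage(gm)))
  expect_equal(phenotypes(rt)$status, phenotypes(gm)$status)
  expect_true(mean(dosage(rt) == dosage(gm), na.rm = TRUE) > 0.99)
  expect_identical(is.na(dosage(rt)), is.na(dosage(gm)))

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeDosageTsv(gm, tf)
  rt2 <- readDosageTsv(tf)
  expect_identical(unname(dosage(rt2)), unname(dosage(gm)))
  expect_equal(phenotypes(rt2)$gestAge, phenotypes(gm)$gestAge,
               tolerance = 1e-9)
})

test_that("association scan reports per-SNP tests and the study-wide correction", {
  gm <- simulateGenotypes(list(nSnp = 20, plantedOR = 2.2), seed = 101)
  qc <- qcFilter(gm)
  sc <- assocScan(qc$genotypes)
  expect_equal(nrow(sc$perSnp), ncol(dosage(qc$genotypes)))
  expect_true(all(c("pAllelic", "pGenotypic", "OR", "pAdjusted") %in%
                  names(sc$perSnp)))
  expect_true(all(sc$perSnp$pAllelic >= 0 & sc$perSnp$pAllelic <= 1,
                  na.rm = TRUE))
  expect_lte(sc$mEff, ncol(dosage(qc$genotypes)))
  expect_equal(sc$bonferroni, 0.05 / sc$mEff)
  # phenotypes standardized on construction
  expect_equal(mean(phenotypes(gm)$gestAge), 0, tolerance = 1e-6)
  expect_equal(sd(phenotypes(gm)$gestAge), 1, tolerance = 1e-6)
})
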