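# Candidate-gene case-control association stage: QC, single-SNP tests,
# covariate adjustment, simpleM effective-test correction.

#' Construct a GenotypeMatrix
#'
#' @param dosage individuals x SNPs minor-allele dosage matrix (0/1/2/NA).
#' @param pheno data.frame with at least a `status` column (1 case, 0
#'   control); quantitative phenotype columns are Z-standardized on
#'   construction when `standardize = TRUE`.
#' @param snpInfo data.frame (`id`, `chr`, `pos`, `alleleMinor`,
#'   `alleleMajor`); minimal defaults are filled in when omitted.
#' @param standardize Z-standardize quantitative phenotype columns
#'   (`gestAge`, `bwZ`) to mean 0, sd 1.
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosage, pheno, snpInfo = NULL, standardize = TRUE) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(snpInfo))
    snpInfo <- data.frame(id = colnames(dosage), chr = "chr1",
                          pos = seq_len(ncol(dosage)) * 1000L,
                          alleleMinor = "A", alleleMajor = "G",
                          stringsAsFactors = FALSE)
  if (standardize) {
    for (col in intersect(c("gestAge", "bwZ"), names(pheno))) {
      v <- pheno[[col]]
      if (sd(v, na.rm = TRUE) > 0)
        pheno[[col]] <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    }
  }
  new("GenotypeMatrix", dosage = dosage, pheno = pheno, snpInfo = snpInfo,
      qcLog = data.frame(unit = character(), type = character(),
                         reason = character(), stringsAsFactors = FALSE))
}

#' Hardy-Weinberg equilibrium chi-square
#'
#' 1-df chi-square of observed genotype counts against Hardy-Weinberg
#' expectations from the sample allele frequency.  Monomorphic SNPs return
#' p = 1 by convention, flagged.
#'
#' @param nAA,nAa,naa genotype counts (AA homozygote, heterozygote, aa
#'   homozygote).
#' @return list with `chi2`, `p`, `flag`.
#' @examples
#' hweChisq(50, 0, 50)  # chi2 = 100
#' @export
hweChisq <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n <= 0) stop("total genotype count must be positive")
  pA <- (2 * nAA + nAa) / (2 * n)
  if (pA == 0 || pA == 1)
    return(list(chi2 = 0, p = 1, flag = "monomorphic"))
  E <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  chi2 <- sum((c(nAA, nAa, naa) - E)^2 / E)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE), flag = "")
}

#' Allelic case-control chi-square with odds ratio
#'
#' 1-df chi-square on the 2x2 allele-count table (no continuity correction
#' unless `correct = TRUE`); odds ratio by cross-product with Woolf 95% CI.
#' A zero cell triggers the Haldane--Anscombe 0.5 correction for the OR/CI
#' only (flagged); the chi-square uses the raw counts.
#'
#' @param caseAlleles,controlAlleles length-2 counts `c(minor, major)`.
#' @param correct apply the Yates continuity correction to the chi-square.
#' @return list with `chi2`, `p`, `OR`, `CI95`, `flag`.
#' @examples
#' allelicChisq(c(30, 70), c(10, 90))  # chi2 12.5, OR ~ 3.857
#' @export
allelicChisq <- function(caseAlleles, controlAlleles, correct = FALSE) {
  a <- caseAlleles[1]; b <- caseAlleles[2]
  c_ <- controlAlleles[1]; d <- controlAlleles[2]
  n <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- if (denom == 0) NA_real_ else n * num^2 / denom
  flag <- ""
  if (any(c(a, b, c_, d) == 0)) {
    flag <- "haldane_correction"
    aa <- a + 0.5; bb <- b + 0.5; cc <- c_ + 0.5; dd <- d + 0.5
  } else {
    aa <- a; bb <- b; cc <- c_; dd <- d
  }
  OR <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  CI95 <- exp(log(OR) + c(-1, 1) * 1.96 * se)
  p <- if (is.na(chi2)) NA_real_ else pchisq(chi2, 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, OR = OR, CI95 = CI95, flag = flag)
}

#' Genotypic case-control chi-square
#'
#' Chi-square on the 2 x (genotype classes present) contingency table,
#' df = classes - 1.
#'
#' @param caseCounts,controlCounts length-3 genotype counts (0/1/2 minor
#'   dosage).
#' @return list with `chi2`, `p`, `df`.
#' @export
genotypicChisq <- function(caseCounts, controlCounts) {
  tab <- rbind(caseCounts, controlCounts)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) return(list(chi2 = 0, p = 1, df = 0))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  df <- ncol(tab) - 1
  list(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE), df = df)
}

#' Wald test for a quantitative phenotype on allele dosage
#'
#' Additive-dosage linear regression of a Z-standardized phenotype; the
#' Wald statistic beta/se is referred to the standard normal.
#'
#' @param genotypes dosage vector (0/1/2/NA).
#' @param phenotype standardized quantitative phenotype.
#' @return list with `beta`, `se`, `z`, `p`, `flag`.
#' @export
waldQuant <- function(genotypes, phenotype) {
  ok <- !is.na(genotypes) & !is.na(phenotype)
  g <- genotypes[ok]; y <- phenotype[ok]
  if (length(unique(g)) < 2)
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                flag = "constant_genotype"))
  fm <- lm(y ~ g)
  sm <- suppressWarnings(summary(fm))$coefficients
  beta <- sm["g", "Estimate"]; se <- sm["g", "Std. Error"]
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)), flag = "")
}

#' Logistic association with an ancestry covariate
#'
#' Two-predictor logistic regression (IRLS via `glm`) of case status on
#' allele dosage and a quantitative ancestry covariate (e.g. CEU cluster
#' proportion supplied externally); reports the Wald p for the genotype
#' term.  Collinearity and separation are flagged.
#'
#' @param status binary 0/1 case status.
#' @param genotypes dosage vector.
#' @param covariate numeric covariate.
#' @return list with `beta`, `se`, `p`, `betaCovariate`, `pCovariate`,
#'   `flag`.
#' @export
logisticAdjusted <- function(status, genotypes, covariate) {
  ok <- complete.cases(status, genotypes, covariate)
  st <- status[ok]; g <- genotypes[ok]; cv <- covariate[ok]
  if (sd(g) == 0 || sd(cv) == 0 || abs(cor(g, cv)) > 1 - 1e-10)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                betaCovariate = NA_real_, pCovariate = NA_real_,
                flag = "collinear"))
  fm <- suppressWarnings(glm(st ~ g + cv, family = binomial()))
  flag <- ""
  fitted <- fm$fitted.values
  if (!fm$converged || any(fitted < 1e-8) || any(fitted > 1 - 1e-8) ||
      any(abs(coef(fm)[-1]) > 15))
    flag <- "separation"
  sm <- summary(fm)$coefficients
  list(beta = sm["g", "Estimate"], se = sm["g", "Std. Error"],
       p = sm["g", "Pr(>|z|)"],
       betaCovariate = sm["cv", "Estimate"], pCovariate = sm["cv", "Pr(>|z|)"],
       flag = flag)
}

#' simpleM effective number of independent tests
#'
#' Composite-correlation eigenvalue method: within blocks of at most
#' `window` SNPs, M_eff is the smallest k such that the top-k eigenvalues
#' of the SNP correlation matrix (pairwise-complete dosages) explain at
#' least `varExplained` of the total variance; block contributions are
#' summed.  Blocks with fewer than 2 SNPs contribute their SNP count.
#'
#' @param dosage individuals x SNPs dosage matrix.
#' @param window block size (default 200 SNPs).
#' @param varExplained variance threshold (default 0.995).
#' @return integer M_eff.
#' @examples
#' g <- matrix(rbinom(400, 2, 0.3), 100, 4)[, c(1, 1, 2, 2)]
#' simpleMMeff(g)  # two duplicated pairs -> 2
#' @export
simpleMMeff <- function(dosage, window = 200, varExplained = 0.995) {
  m <- ncol(dosage)
  if (m == 0) return(0L)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / window))
  meff <- 0L
  for (b in blocks) {
    if (length(b) < 2) { meff <- meff + length(b); next }
    cc <- suppressWarnings(cor(dosage[, b, drop = FALSE],
                               use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0; diag(cc) <- 1
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) / sum(ev) >= varExplained)[1]
    meff <- meff + k
  }
  as.integer(meff)
}

#' Quality-control filtering of a GenotypeMatrix
#'
#' Individuals are filtered first (call rate), then SNP filters apply in
#' order: Hardy-Weinberg disequilibrium in controls, SNP call rate, minor
#' allele frequency, duplicate probes (identical chromosome + position;
#' the copy with the highest call rate is kept).  Every removal is logged
#' with a reason code; the returned report tallies them.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param indCallRate minimum individual call rate (default 0.95).
#' @param snpCallRate minimum SNP call rate (default 0.95).
#' @param mafMin SNPs with MAF strictly below this are removed (default
#'   0.05; MAF exactly at the threshold is retained).
#' @param hwePmin SNPs with control-group HWE p strictly below this are
#'   removed (default 0.001).
#' @return list with `genotypes` (filtered [GenotypeMatrix-class], QC log
#'   populated) and `report` (counts per filter + thresholds).
#' @export
qcFilter <- function(gm, indCallRate = 0.95, snpCallRate = 0.95,
                     mafMin = 0.05, hwePmin = 0.001) {
  d <- gm@dosage; ph <- gm@pheno; si <- gm@snpInfo
  log <- gm@qcLog
  addLog <- function(units, type, reason) {
    if (length(units))
      log <<- rbind(log, data.frame(unit = units, type = type, reason = reason,
                                    stringsAsFactors = FALSE))
  }
  # individuals first
  icr <- rowMeans(!is.na(d))
  dropInd <- icr < indCallRate
  addLog(rownames(d)[dropInd], "individual", "call_rate")
  d <- d[!dropInd, , drop = FALSE]; ph <- ph[!dropInd, , drop = FALSE]
  if (nrow(d) == 0) stop("all individuals removed by call-rate filter")

  ctrl <- which(ph$status == 0)
  # 1. HWE in controls
  hweP <- apply(d[ctrl, , drop = FALSE], 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hweChisq(sum(g == 0), sum(g == 1), sum(g == 2))$p
  })
  drop1 <- hweP < hwePmin
  addLog(colnames(d)[drop1], "snp", "hwe_controls")
  d <- d[, !drop1, drop = FALSE]; si <- si[!drop1, , drop = FALSE]
  # 2. SNP call rate
  scr <- colMeans(!is.na(d))
  drop2 <- scr < snpCallRate
  addLog(colnames(d)[drop2], "snp", "call_rate")
  d <- d[, !drop2, drop = FALSE]; si <- si[!drop2, , drop = FALSE]
  # 3. MAF
  maf <- apply(d, 2, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  drop3 <- maf < mafMin
  addLog(colnames(d)[drop3], "snp", "maf")
  d <- d[, !drop3, drop = FALSE]; si <- si[!drop3, , drop = FALSE]
  # 4. duplicate probes: keep highest call rate per (chr, pos)
  key <- paste(si$chr, si$pos)
  scr <- colMeans(!is.na(d))
  keep <- unlist(lapply(split(seq_along(key), key), function(ix) {
    ix[order(-scr[ix], ix)][1]
  }), use.names = FALSE)
  drop4 <- setdiff(seq_along(key), keep)
  addLog(colnames(d)[drop4], "snp", "duplicate_probe")
  keep <- sort(keep)
  d <- d[, keep, drop = FALSE]; si <- si[keep, , drop = FALSE]

  out <- new("GenotypeMatrix", dosage = d, pheno = ph, snpInfo = si, qcLog = log)
  report <- list(
    thresholds = c(indCallRate = indCallRate, snpCallRate = snpCallRate,
                   mafMin = mafMin, hwePmin = hwePmin),
    individualsRemoved = sum(dropInd),
    snpsRemoved = c(hwe_controls = sum(drop1), call_rate = sum(drop2),
                    maf = sum(drop3), duplicate_probe = length(drop4)),
    individualsKept = nrow(d), snpsKept = ncol(d))
  list(genotypes = out, report = report)
}

#' Per-SNP association scan
#'
#' Runs the allelic and genotypic chi-square tests, Wald tests for any
#' quantitative phenotypes present, and (when an `ancestry` column exists)
#' the covariate-adjusted logistic test, for every SNP of a QC-filtered
#' [GenotypeMatrix-class]; appends the study-wide simpleM M_eff and
#' Bonferroni threshold.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param window simpleM block size.
#' @return list with `perSnp` (data.frame) and `mEff`, `bonferroni`.
#' @export
assocScan <- function(gm, alpha = 0.05, window = 200) {
  d <- gm@dosage; ph <- gm@pheno
  case <- ph$status == 1; ctrl <- ph$status == 0
  rows <- lapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    gc <- g[case & !is.na(g)]; gt <- g[ctrl & !is.na(g)]
    al <- allelicChisq(c(sum(gc), 2 * length(gc) - sum(gc)),
                       c(sum(gt), 2 * length(gt) - sum(gt)))
    ge <- genotypicChisq(tabulate(gc + 1, 3), tabulate(gt + 1, 3))
    row <- data.frame(snp = colnames(d)[j], chi2Allelic = al$chi2,
                      pAllelic = al$p, OR = al$OR,
                      ORlo = al$CI95[1], ORhi = al$CI95[2],
                      chi2Genotypic = ge$chi2, pGenotypic = ge$p,
                      stringsAsFactors = FALSE)
    for (q in intersect(c("gestAge", "bwZ"), names(ph))) {
      wq <- waldQuant(g, ph[[q]])
      row[[paste0("beta_", q)]] <- wq$beta
      row[[paste0("p_", q)]] <- wq$p
    }
    if ("ancestry" %in% names(ph)) {
      la <- logisticAdjusted(ph$status, g, ph$ancestry)
      row$pAdjusted <- la$p
    }
    row
  })
  perSnp <- do.call(rbind, rows)
  mEff <- simpleMMeff(d, window = window)
  list(perSnp = perSnp, mEff = mEff,
       bonferroni = as.numeric(bonferroniThreshold(alpha, max(1, mEff))))
}

#' PLINK text and dosage-TSV genotype I/O
#'
#' `readPedMap` reads PLINK-text `.ped`/`.map` pairs (first six ped columns
#' FID, IID, PAT, MAT, SEX, PHENO with 1=control/2=case, then two allele
#' columns per SNP, `0` missing); the minor allele is determined per SNP
#' from the data.  `readDosageTsv` reads the package's dosage dialect: a
#' TSV with an `id` column, a `status` column, optional phenotype columns
#' (`gestAge`, `bwZ`, `ancestry`), and one 0/1/2/NA column per SNP.
#'
#' @param pedPath,mapPath PLINK text file paths.
#' @return a [GenotypeMatrix-class].
#' @export
readPedMap <- function(pedPath, mapPath) {
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chr", "id", "cm", "pos")[seq_len(min(4, ncol(map)))]
  ped <- read.table(pedPath, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nsnp <- nrow(map)
  if (ncol(ped) != 6 + 2 * nsnp)
    stop("ped/map mismatch: expected ", 6 + 2 * nsnp, " ped columns, got ",
         ncol(ped))
  ids <- ped[[2]]
  status <- ifelse(ped[[6]] == "2", 1L, ifelse(ped[[6]] == "1", 0L, NA_integer_))
  dosage <- matrix(NA_integer_, nrow(ped), nsnp,
                   dimnames = list(ids, map$id))
  minor <- major <- character(nsnp)
  for (j in seq_len(nsnp)) {
    a1 <- ped[[6 + 2 * j - 1]]; a2 <- ped[[6 + 2 * j]]
    alleles <- c(a1, a2)
    obs <- alleles[alleles != "0"]
    if (!length(obs)) { minor[j] <- major[j] <- NA_character_; next }
    tb <- sort(table(obs))
    minor[j] <- names(tb)[1]
    major[j] <- names(tb)[length(tb)]
    ok <- a1 != "0" & a2 != "0"
    dosage[ok, j] <- (a1[ok] == minor[j]) + (a2[ok] == minor[j])
  }
  snpInfo <- data.frame(id = map$id, chr = map$chr,
                        pos = if ("pos" %in% names(map)) map$pos else seq_len(nsnp),
                        alleleMinor = minor, alleleMajor = major,
                        stringsAsFactors = FALSE)
  genotypeMatrix(dosage, data.frame(status = status, row.names = ids),
                 snpInfo, standardize = FALSE)
}

#' @rdname readPedMap
#' @param gm a [GenotypeMatrix-class] to write.
#' @param prefix output path prefix (`prefix.ped`, `prefix.map`).
#' @export
writePedMap <- function(gm, prefix) {
  d <- gm@dosage; si <- gm@snpInfo; ph <- gm@pheno
  map <- data.frame(chr = sub("^chr", "", si$chr), id = si$id, cm = 0,
                    pos = si$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(d)
  al <- function(j, g) {
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, si$alleleMinor[j], si$alleleMajor[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, si$alleleMinor[j], si$alleleMajor[j]))
    cbind(a1, a2)
  }
  cols <- vector("list", ncol(d))
  for (j in seq_len(ncol(d))) cols[[j]] <- al(j, d[, j])
  ped <- cbind("FAM", rownames(d), "0", "0", "0",
               ifelse(is.na(ph$status), "0", ifelse(ph$status == 1, "2", "1")),
               do.call(cbind, cols))
  write.table(ped, paste0(prefix, ".ped"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname readPedMap
#' @param path dosage TSV path.
#' @export
readDosageTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  phenoCols <- intersect(c("status", "gestAge", "bwZ", "ancestry"), names(df))
  snpCols <- setdiff(names(df), c("id", phenoCols))
  dosage <- as.matrix(df[snpCols])
  rownames(dosage) <- df$id
  genotypeMatrix(dosage, df[phenoCols], standardize = FALSE)
}

#' @rdname readPedMap
#' @export
writeDosageTsv <- function(gm, path) {
  df <- cbind(data.frame(id = rownames(gm@dosage)), gm@pheno,
              as.data.frame(gm@dosage))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
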