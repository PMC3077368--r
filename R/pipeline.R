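# End-to-end orchestration: simulate -> coding screen -> noncoding screen
# -> gene-wise combination -> FDR -> association -> allometry -> report,
# with a machine-readable run manifest.

#' Default pipeline configuration
#'
#' All screen thresholds default to the analysis constants (FDR level 0.05,
#' conservation score 400, MAF 0.05, HWE p 0.001, call rate 0.95, 10+10
#' neighbor genes, 25 kb flanking span); simulation sizes default to a
#' small but realistic desk-scale study.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    fdrLevel = 0.05,
    minScore = 400,
    focalTip = "Human",
    loci = list(nLoci = 4, nNeighbors = 20, neighborCodons = 120,
                geneCodons = 300, omega = 0.3, kappa = 2,
                acceleratedFraction = 0.25, focalR = 1.5,
                nElements = 4, elementBp = 400, flankBp = 25000,
                elementFocalRate = 4, scoreHighFraction = 0.7),
    assoc = list(nCase = 165, nControl = 163, nSnp = 40, blockSize = 4,
                 blockRho = 0.9, plantedOR = 1.8, causalIndex = 1,
                 causalMaf = 0.3, missingRate = 0.02,
                 indCallRate = 0.95, snpCallRate = 0.95,
                 mafMin = 0.05, hwePmin = 0.001, simpleMWindow = 200,
                 alpha = 0.05),
    allometry = list(
      tree = "((((Human:6,Chimpanzee:6):2,Gorilla:8):8,Macaque:16):14,Marmoset:30);",
      sigma2 = 0.01, rootGestBrain = 1.5, rootGestBody = -1.5,
      pairs = rbind(c("Human", "Gorilla"), c("Human", "Chimpanzee")))
  )
}

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-data pipeline
#'
#' Executes every stage in dependency order on data simulated from the
#' configuration; per-locus failures are logged and skipped, not fatal.
#' Writes per-stage TSVs, a JSON summary and a run manifest (config hash,
#' seeds, file digests, per-stage row counts) under `outDir`.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]), a
#'   YAML file path, or `NULL` for the defaults.
#' @param outDir output directory.
#' @return the run manifest (list), invisibly alongside `stages` with the
#'   in-memory stage outputs.
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("accelrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- defaultPipelineConfig()
  if (!is.null(config)) cfg <- utils::modifyList(cfg, config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tree <- mammalTree()
  seed <- cfg$seed
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  ## stage 1-3: simulate loci, coding + noncoding screens
  nLoci <- cfg$loci$nLoci
  nAccel <- round(cfg$loci$acceleratedFraction * nLoci)
  codingRows <- list(); elementRows <- list()
  geneLoci <- NULL; allElements <- NULL
  for (i in seq_len(nLoci)) {
    accelerated <- i <= nAccel
    lcfg <- cfg$loci
    lcfg$geneId <- sprintf("gene%02d", i)
    lcfg$chrom <- "chrS"
    lcfg$focalTip <- cfg$focalTip
    lcfg$focalR <- if (accelerated) cfg$loci$focalR else NULL
    lcfg$elementFocalRate <- if (accelerated) cfg$loci$elementFocalRate else NULL
    lcfg <- lcfg[setdiff(names(lcfg), c("nLoci", "acceleratedFraction"))]
    locus <- simulateLocusNeighborhood(lcfg, seed = splitSeed(seed, 1000 + i))
    # shift locus coordinates so loci do not overlap
    off <- (i - 1) * 2000000L
    locus$elements <- GenomicRanges::shift(locus$elements, off)
    locus$geneLocus <- GenomicRanges::shift(locus$geneLocus, off)
    res <- tryCatch({
      ctx <- fitRegional(locus$neighbors, tree, kappaInit = cfg$loci$kappa)
      tH <- lrtAccelCoding(locus$gene, ctx, tree, focalTip = cfg$focalTip)
      tA <- lrtAccelCoding(locus$gene, ctx, tree, focalTip = cfg$focalTip,
                           includeAncestor = TRUE)
      aH <- ctx@a[cfg$focalTip]
      data.frame(gene = lcfg$geneId,
                 expectedRatio = unname(aH * omegaHat(tH)),
                 observedRatio = unname(aH * focalRate(tH)),
                 lnL0 = tH@lnL0, lnL1 = tH@lnL1,
                 wHat = omegaHat(tH), RHat = focalRate(tH),
                 lrt = lrtStat(tH), pHuman = pValue(tH),
                 pAncestor = pValue(tA),
                 flags = paste(unique(c(flags(tH), flags(tA))), collapse = ";"),
                 accelerated = accelerated, stringsAsFactors = FALSE)
    }, error = function(e) {
      note("coding_screen skip ", lcfg$geneId, ": ", conditionMessage(e))
      NULL
    })
    codingRows[[i]] <- res

    elRes <- tryCatch({
      kept <- filterElements(locus$elements, cfg$minScore)
      if (!length(kept)) NULL else {
        ectx <- fitNoncodingRegional(locus$flankAlignments, tree,
                                     spanBp = cfg$loci$flankBp,
                                     kappaInit = cfg$loci$kappa)
        do.call(rbind, lapply(seq_along(kept), function(k) {
          nm <- S4Vectors::mcols(kept)$name[k]
          tE <- lrtAccelElement(locus$elementAlignments[[nm]], ectx, tree,
                                focalTip = cfg$focalTip)
          data.frame(element = nm, gene = NA_character_,
                     rHat = omegaHat(tE), focalRate = focalRate(tE),
                     lrt = lrtStat(tE), p = pValue(tE),
                     flags = paste(flags(tE), collapse = ";"),
                     stringsAsFactors = FALSE)
        }))
      }
    }, error = function(e) {
      note("noncoding_screen skip ", lcfg$geneId, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(elRes)) {
      keptGr <- filterElements(locus$elements, cfg$minScore)
      allElements <- if (is.null(allElements)) keptGr else c(allElements, keptGr)
      elementRows[[i]] <- elRes
    }
    geneLoci <- if (is.null(geneLoci)) locus$geneLocus else c(geneLoci, locus$geneLocus)
  }
  coding <- do.call(rbind, codingRows)
  elementTab <- do.call(rbind, elementRows)

  ## stage 4: assign elements to nearest gene, Fisher-combine per gene
  geneWise <- NULL
  if (!is.null(elementTab) && nrow(elementTab)) {
    assign <- assignNearestGene(allElements, geneLoci)
    elementTab$gene <- assign$gene[match(elementTab$element, assign$element)]
    byGene <- split(elementTab$p, elementTab$gene)
    geneWise <- data.frame(gene = names(byGene),
                           nElements = lengths(byGene),
                           pCombined = vapply(byGene, fisherCombine, numeric(1)),
                           stringsAsFactors = FALSE)
  }

  ## stage 5: FDR over the coding screen (gene-level p-values)
  if (!is.null(coding) && nrow(coding)) {
    qv <- suppressWarnings(qvalueStorey(coding$pHuman))
    coding$qHuman <- qv$qvalues
    coding$significant <- coding$qHuman < cfg$fdrLevel
  }

  ## stage 6: association
  assocOut <- tryCatch({
    gm <- simulateGenotypes(cfg$assoc[c("nCase", "nControl", "nSnp",
                                        "blockSize", "blockRho", "plantedOR",
                                        "causalIndex", "causalMaf",
                                        "missingRate")],
                            seed = splitSeed(seed, 5000))
    qc <- qcFilter(gm, cfg$assoc$indCallRate, cfg$assoc$snpCallRate,
                   cfg$assoc$mafMin, cfg$assoc$hwePmin)
    scan <- assocScan(qc$genotypes, alpha = cfg$assoc$alpha,
                      window = cfg$assoc$simpleMWindow)
    list(qcReport = qc$report, scan = scan, qcLog = qcLog(qc$genotypes))
  }, error = function(e) { note("assoc stage failed: ", conditionMessage(e)); NULL })

  ## stage 7: allometry
  allomOut <- tryCatch({
    ptree <- readNewick(cfg$allometry$tree)
    s1 <- splitSeed(seed, 6000); s2 <- splitSeed(seed, 6001)
    lnGB <- simulateTraitsBM(ptree, cfg$allometry$sigma2,
                             cfg$allometry$rootGestBrain, seed = s1)
    lnBo <- simulateTraitsBM(ptree, cfg$allometry$sigma2,
                             cfg$allometry$rootGestBody, seed = s2)
    tt <- data.frame(species = ptree$tip.label, group = "higher_primate",
                     adultBrainG = 100, adultBodyG = 10000,
                     neonatalBrainG = exp(-lnGB) * 180,
                     neonatalBodyG = exp(-lnBo) * 180,
                     gestationDays = 180)
    rp <- ratioProfiles(tt, ptree, pairs = cfg$allometry$pairs)
    fit <- allometricFit(log(tt$neonatalBodyG), log(tt$neonatalBrainG))
    list(traits = tt, profiles = rp, allometricFit = fit)
  }, error = function(e) { note("allometry stage failed: ", conditionMessage(e)); NULL })

  ## stage 8: report + manifest
  files <- character()
  writeTsv <- function(df, name) {
    f <- file.path(outDir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
    f
  }
  if (!is.null(coding)) writeTsv(coding, "coding_screen.tsv")
  if (!is.null(elementTab)) writeTsv(elementTab, "noncoding_screen.tsv")
  if (!is.null(geneWise)) writeTsv(geneWise, "genewise_combined.tsv")
  if (!is.null(assocOut)) writeTsv(assocOut$scan$perSnp, "assoc_scan.tsv")
  rep <- report(list(coding = coding, elements = elementTab,
                     geneWise = geneWise, assoc = assocOut,
                     allometry = allomOut))
  writeTsv(rep$geneTable, "report_genes.tsv")
  sj <- file.path(outDir, "summary.json")
  jsonlite::write_json(rep$summary, sj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sj)
  if (length(log)) {
    lf <- file.path(outDir, "pipeline_log.txt")
    writeLines(log, lf)
    files <- c(files, lf)
  }

  manifest <- list(
    version = as.character(utils::packageVersion("accelscreen")),
    configHash = .configHash(cfg),
    seed = seed,
    fileDigests = as.list(tools::md5sum(files)),
    counts = list(
      genesTested = if (is.null(coding)) 0L else nrow(coding),
      elementsTested = if (is.null(elementTab)) 0L else nrow(elementTab),
      genesAtFdr = if (is.null(coding)) 0L else sum(coding$significant),
      genesCombined = if (is.null(geneWise)) 0L else nrow(geneWise),
      snpsPassingQc = if (is.null(assocOut)) 0L else
        assocOut$qcReport$snpsKept,
      mEff = if (is.null(assocOut)) NA_integer_ else assocOut$scan$mEff))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, outDir = outDir,
                 stages = list(coding = coding, elements = elementTab,
                               geneWise = geneWise, assoc = assocOut,
                               allometry = allomOut),
                 log = log))
}

#' Summarize pipeline stage outputs
#'
#' Builds the human-readable report tables: a per-gene table with expected
#' vs observed rate ratio and the p-values for both focal configurations,
#' and a per-SNP association table; numeric content is identical between
#' the TSV and JSON forms.
#'
#' @param stageOutputs list with any of `coding`, `elements`, `geneWise`,
#'   `assoc`, `allometry` stage outputs (missing stages yield empty but
#'   well-formed tables).
#' @return list with `geneTable`, `snpTable`, `summary`.
#' @export
report <- function(stageOutputs) {
  emptyGene <- data.frame(gene = character(), expectedRatio = numeric(),
                          observedRatio = numeric(), pHuman = numeric(),
                          pAncestor = numeric(), stringsAsFactors = FALSE)
  co <- stageOutputs$coding
  geneTable <- if (is.null(co) || !nrow(co)) emptyGene else
    co[, c("gene", "expectedRatio", "observedRatio", "pHuman", "pAncestor")]
  snpTable <- if (is.null(stageOutputs$assoc)) data.frame(snp = character()) else
    stageOutputs$assoc$scan$perSnp
  summary <- list(
    genes = if (nrow(geneTable)) lapply(seq_len(nrow(geneTable)), function(i)
      as.list(geneTable[i, ])) else list(),
    nSnp = nrow(snpTable),
    mEff = if (is.null(stageOutputs$assoc)) NA else stageOutputs$assoc$scan$mEff)
  list(geneTable = geneTable, snpTable = snpTable, summary = summary)
}
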