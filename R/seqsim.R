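# Seeded forward simulators for every input the screens assume: codon and
# nucleotide alignments on the species tree, locus neighborhoods (focal
# gene + flanking genes + conserved elements), Brownian trait values, and
# LD-structured case-control genotypes with a planted risk allele.
#
# One master seed deterministically derives per-component seeds
# (counter-based splitting), so identical configurations reproduce
# byte-identical outputs.

#' Derive a component seed from a master seed
#'
#' @param master master seed (integer).
#' @param index component counter.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
splitSeed <- function(master, index = 0) {
  as.integer((as.double(master) %% 2147483647 * 48271 + index * 7919) %%
               2147483646 + 1)
}

# default per-branch regional parameters for the seven-taxon tree:
# synonymous lengths loosely mirroring mammalian divergence (short ape
# branches, longer rodent/laurasiatherian branches) and per-branch
# constraint scalings spread around a typical mammalian dN/dS of ~0.2.
.defaultBranchParams <- function(tree) {
  ids <- branchIds(.unrootIfNeeded(tree))
  dSr <- setNames(rep(0.08, length(ids)), ids)
  known <- c(Human = 0.012, Chimpanzee = 0.012, "Chimpanzee+Human" = 0.025,
             Macaque = 0.06, "Chimpanzee+Human+Macaque" = 0.08,
             Mouse = 0.12, Rat = 0.12, "Mouse+Rat" = 0.1,
             Dog = 0.1, Cow = 0.12, "Cow+Dog" = 0.05)
  hit <- intersect(names(known), ids)
  dSr[hit] <- known[hit]
  a <- setNames(rep(0.2, length(ids)), ids)
  a[] <- 0.2 * exp(seq(-0.4, 0.4, length.out = length(ids)))
  list(dSr = dSr, a = a)
}

# sample child states given parent states and a transition matrix
.evolveStates <- function(parentStates, P) {
  k <- nrow(P)
  child <- integer(length(parentStates))
  for (s in seq_len(k)) {
    ix <- which(parentStates == s)
    if (length(ix))
      child[ix] <- sample.int(k, length(ix), replace = TRUE, prob = P[s, ])
  }
  child
}

# generic forward simulation: per-edge generator matrices on a rooted or
# unrooted (trifurcating-root) tree
.simulateOnTree <- function(tree, Glist, pi, nSites) {
  idx <- treeIndex(tree)
  k <- length(pi)
  nodeStates <- vector("list", idx$nnode)
  nodeStates[[idx$root]] <- sample.int(k, nSites, replace = TRUE, prob = pi)
  # preorder = reverse postorder of edges
  for (e in rev(seq_len(nrow(idx$edge)))) {
    par <- idx$edge[e, 1]; ch <- idx$edge[e, 2]
    P <- .transMatCpp(Glist[[e]], pi)
    nodeStates[[ch]] <- .evolveStates(nodeStates[[par]], P)
  }
  states <- do.call(rbind, nodeStates[seq_len(idx$ntip)])
  rownames(states) <- idx$tipLabels
  states
}

#' Simulate a codon alignment under the regional acceleration model
#'
#' Root codons are drawn from the MG94xHKY85 stationary distribution and
#' evolved along each branch with synonymous length `dSr_i` and
#' nonsynonymous length `a_i * m * dSr_i`, where `m` is `omega` on
#' background branches and `focalR` on the focal branch(es).
#'
#' @param tree species tree (a degree-2 root is collapsed, matching the
#'   fitting convention).
#' @param dSr,aScale named per-branch synonymous lengths and constraint
#'   scalings (defaults: realistic mammalian values, see
#'   `accelscreen:::.defaultBranchParams`).
#' @param omega gene-wise rate multiplier.
#' @param kappa transition/transversion ratio.
#' @param freqs3x4 position-specific nucleotide frequencies.
#' @param nCodons number of codon sites (>= 1).
#' @param focal branch identifiers carrying `focalR` instead of `omega`
#'   (e.g. `focalBranches(tree, "Human")`).
#' @param focalR focal rate multiplier (default `omega`: null model).
#' @param seed RNG seed.
#' @return a codon [PhyloAlignment-class] with attribute `"truth"`
#'   recording the generating parameters.
#' @export
simulateCodonAlignment <- function(tree, dSr = NULL, aScale = NULL,
                                   omega = 0.3, kappa = 2,
                                   freqs3x4 = matrix(0.25, 3, 4),
                                   nCodons = 300, focal = character(),
                                   focalR = NULL, seed = 1) {
  if (nCodons < 1) stop("nCodons must be >= 1")
  tree <- .unrootIfNeeded(tree)
  bp <- .defaultBranchParams(tree)
  if (is.null(dSr)) dSr <- bp$dSr
  if (is.null(aScale)) aScale <- bp$a
  ids <- branchIds(tree)
  idx <- treeIndex(tree)
  cp <- .mg94Components(kappa, freqs3x4)
  if (is.null(focalR)) focalR <- omega
  set.seed(seed)
  G <- lapply(seq_along(idx$branchIds), function(e) {
    id <- idx$branchIds[e]
    m <- if (id %in% focal) focalR else omega
    dSr[id] * cp$A + aScale[id] * m * dSr[id] * cp$B
  })
  states <- .simulateOnTree(tree, G, cp$pi, nCodons)
  aln <- new("PhyloAlignment", taxa = rownames(states), states = states,
             alphabet = "codon")
  attr(aln, "truth") <- list(dSr = dSr, a = aScale, omega = omega,
                             kappa = kappa, focal = focal, focalR = focalR,
                             seed = seed)
  aln
}

#' Simulate a nucleotide alignment under HKY85
#'
#' @param tree species tree.
#' @param branchLengths named per-branch lengths (expected
#'   substitutions/site); default: the regional synonymous lengths scaled
#'   by `rate`.
#' @param kappa,freqs HKY85 parameters.
#' @param nSites number of sites.
#' @param rate overall rate multiplier applied to `branchLengths`.
#' @param focal,focalRate optionally accelerate the focal branches by
#'   `focalRate` instead of `rate`.
#' @param seed RNG seed.
#' @return a nucleotide [PhyloAlignment-class] with a `"truth"` attribute.
#' @export
simulateNtAlignment <- function(tree, branchLengths = NULL, kappa = 2,
                                freqs = rep(0.25, 4), nSites = 500,
                                rate = 1, focal = character(),
                                focalRate = NULL, seed = 1) {
  if (nSites < 1) stop("nSites must be >= 1")
  tree <- .unrootIfNeeded(tree)
  if (is.null(branchLengths)) branchLengths <- .defaultBranchParams(tree)$dSr
  if (is.null(focalRate)) focalRate <- rate
  Q <- hkyMatrix(kappa, freqs)@Q
  idx <- treeIndex(tree)
  set.seed(seed)
  G <- lapply(seq_along(idx$branchIds), function(e) {
    id <- idx$branchIds[e]
    r <- if (id %in% focal) focalRate else rate
    Q * (r * branchLengths[id])
  })
  states <- .simulateOnTree(tree, G, freqs, nSites)
  aln <- new("PhyloAlignment", taxa = rownames(states), states = states,
             alphabet = "nucleotide")
  attr(aln, "truth") <- list(branchLengths = branchLengths, kappa = kappa,
                             rate = rate, focal = focal,
                             focalRate = focalRate, seed = seed)
  aln
}

#' Simulate a focal locus with its genomic neighborhood
#'
#' Emulates the unit of the screens: a focal gene with flanking neighbor
#' genes sharing the regional per-branch rates, plus conserved noncoding
#' elements (with conservation scores and coordinates on a synthetic
#' chromosome) and flanking conserved sequence for the noncoding rate
#' context.
#'
#' @param config list overriding any of: `nNeighbors` (total, default 20 =
#'   10 upstream + 10 downstream), `neighborCodons` (300), `geneCodons`
#'   (300), `omega` (0.3), `focalR` (`NULL` = null model), `focalTip`,
#'   `includeAncestor`, `kappa` (2), `dSr`, `aScale`, `nElements` (6),
#'   `elementBp` (500), `elementRate` (1), `elementFocalRate` (`NULL`),
#'   `scoreHighFraction` (0.7), `flankBp` (25000 span of flanking
#'   conserved sequence), `chrom`, `geneId`.
#' @param seed master seed; component seeds are split from it.
#' @param outDir optional directory: writes per-locus FASTAs, a neighbor
#'   manifest TSV, element/gene BED files and a ground-truth JSON.
#' @return list with `gene`, `neighbors`, `elements` (`GRanges`),
#'   `elementAlignments`, `flankAlignments`, `geneLocus` (`GRanges`),
#'   `truth`, and (if written) `files`.
#' @export
simulateLocusNeighborhood <- function(config = list(), seed = 1,
                                      outDir = NULL) {
  cfg <- utils::modifyList(list(
    nNeighbors = 20, neighborCodons = 300, geneCodons = 300, omega = 0.3,
    focalR = NULL, focalTip = "Human", includeAncestor = FALSE, kappa = 2,
    dSr = NULL, aScale = NULL, nElements = 6, elementBp = 500,
    elementRate = 1, elementFocalRate = NULL, scoreHighFraction = 0.7,
    flankBp = 25000, chrom = "chrS", geneId = "gene1"), config)
  tree <- .unrootIfNeeded(mammalTree())
  bp <- .defaultBranchParams(tree)
  if (is.null(cfg$dSr)) cfg$dSr <- bp$dSr
  if (is.null(cfg$aScale)) cfg$aScale <- bp$a
  foc <- focalBranches(tree, cfg$focalTip, cfg$includeAncestor)

  neighbors <- lapply(seq_len(cfg$nNeighbors), function(i) {
    simulateCodonAlignment(tree, cfg$dSr, cfg$aScale, omega = cfg$omega,
                           kappa = cfg$kappa, nCodons = cfg$neighborCodons,
                           seed = splitSeed(seed, i))
  })
  names(neighbors) <- paste0(cfg$geneId, "_nb", seq_len(cfg$nNeighbors))
  gene <- simulateCodonAlignment(tree, cfg$dSr, cfg$aScale, omega = cfg$omega,
                                 kappa = cfg$kappa, nCodons = cfg$geneCodons,
                                 focal = if (is.null(cfg$focalR)) character() else foc,
                                 focalR = cfg$focalR,
                                 seed = splitSeed(seed, 101))

  # conserved elements on a synthetic chromosome around the gene body
  set.seed(splitSeed(seed, 102))
  geneStart <- 1000000L
  geneEnd <- geneStart + 3L * cfg$geneCodons
  elStarts <- sort(sample.int(200000L, cfg$nElements)) + geneEnd + 5000L
  high <- runif(cfg$nElements) < cfg$scoreHighFraction
  scores <- ifelse(high, round(runif(cfg$nElements, 400, 700)),
                   round(runif(cfg$nElements, 100, 399)))
  elements <- GenomicRanges::GRanges(
    cfg$chrom, IRanges::IRanges(elStarts + 1L, elStarts + cfg$elementBp))
  S4Vectors::mcols(elements)$name <- paste0(cfg$geneId, "_el", seq_len(cfg$nElements))
  S4Vectors::mcols(elements)$score <- scores
  elementAlignments <- lapply(seq_len(cfg$nElements), function(i) {
    simulateNtAlignment(tree, cfg$dSr, kappa = cfg$kappa,
                        nSites = cfg$elementBp, rate = cfg$elementRate,
                        focal = if (is.null(cfg$elementFocalRate)) character() else foc,
                        focalRate = cfg$elementFocalRate,
                        seed = splitSeed(seed, 200 + i))
  })
  names(elementAlignments) <- S4Vectors::mcols(elements)$name

  nFlank <- ceiling(cfg$flankBp / 1000)
  flankAlignments <- lapply(seq_len(nFlank), function(i) {
    simulateNtAlignment(tree, cfg$dSr, kappa = cfg$kappa, nSites = 1000,
                        rate = 1, seed = splitSeed(seed, 400 + i))
  })
  names(flankAlignments) <- paste0(cfg$geneId, "_flank", seq_len(nFlank))

  geneLocus <- GenomicRanges::GRanges(cfg$chrom,
                                      IRanges::IRanges(geneStart + 1L, geneEnd))
  S4Vectors::mcols(geneLocus)$name <- cfg$geneId

  truth <- list(config = cfg[setdiff(names(cfg), c("dSr", "aScale"))],
                dSr = as.list(cfg$dSr), aScale = as.list(cfg$aScale),
                focalBranches = foc, seed = seed)
  out <- list(gene = gene, neighbors = neighbors, elements = elements,
              elementAlignments = elementAlignments,
              flankAlignments = flankAlignments, geneLocus = geneLocus,
              truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- c()
    gf <- file.path(outDir, paste0(cfg$geneId, ".fasta"))
    writeAlignmentFasta(gene, gf); files <- c(files, gf)
    for (nm in names(neighbors)) {
      f <- file.path(outDir, paste0(nm, ".fasta"))
      writeAlignmentFasta(neighbors[[nm]], f); files <- c(files, f)
    }
    for (nm in names(elementAlignments)) {
      f <- file.path(outDir, paste0(nm, ".fasta"))
      writeAlignmentFasta(elementAlignments[[nm]], f); files <- c(files, f)
    }
    manifest <- data.frame(gene = cfg$geneId, neighbor = names(neighbors),
                           order = seq_along(neighbors))
    mf <- file.path(outDir, paste0(cfg$geneId, "_manifest.tsv"))
    write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    eb <- file.path(outDir, paste0(cfg$geneId, "_elements.bed"))
    writeBed(elements, eb)
    gb <- file.path(outDir, paste0(cfg$geneId, "_locus.bed"))
    writeBed(geneLocus, gb)
    tj <- file.path(outDir, paste0(cfg$geneId, "_truth.json"))
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
    tf <- file.path(outDir, "tree.nwk")
    writeLines(writeNewick(tree), tf)
    out$files <- c(files, mf, eb, gb, tj, tf)
  }
  out
}

#' Simulate Brownian-motion trait values on a tree
#'
#' @param tree phylogeny with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length, > 0).
#' @param rootValue trait value at the root.
#' @param seed RNG seed.
#' @return named numeric vector of tip values.
#' @export
simulateTraitsBM <- function(tree, sigma2, rootValue = 0, seed = 1) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  idx <- treeIndex(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  set.seed(seed)
  vals <- numeric(idx$nnode)
  vals[idx$root] <- rootValue
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    vals[ch] <- vals[par] + rnorm(1, 0, sqrt(sigma2 * tr$edge.length[e]))
  }
  setNames(vals[seq_len(idx$ntip)], tr$tip.label)
}

#' Simulate LD-structured case-control genotypes with a planted risk allele
#'
#' Control genotypes are drawn at Hardy-Weinberg equilibrium from
#' block-correlated haplotypes (latent Gaussian AR(rho) within blocks);
#' cases and controls are rejection-sampled against the logistic
#' penetrance implied by the planted per-allele odds ratio at the causal
#' SNP (baseline prevalence `prevalence`).
#'
#' @param spec list overriding any of: `nCase` (165), `nControl` (163),
#'   `nSnp` (60), `mafRange` (c(0.1, 0.5)), `blockSize` (4), `blockRho`
#'   (0.9), `plantedOR` (1.8), `causalIndex` (1), `causalMaf` (0.3),
#'   `missingRate` (0.02), `prevalence` (0.05), `quantBeta` (0) effect of
#'   causal dosage on the gestational-age phenotype before
#'   standardization.
#' @param seed RNG seed.
#' @return a [GenotypeMatrix-class] with `status`, `gestAge`, `bwZ` and
#'   `ancestry` phenotypes; attribute `"truth"` records the spec.
#' @export
simulateGenotypes <- function(spec = list(), seed = 1) {
  sp <- utils::modifyList(list(
    nCase = 165, nControl = 163, nSnp = 60, mafRange = c(0.1, 0.5),
    blockSize = 4, blockRho = 0.9, plantedOR = 1.8, causalIndex = 1,
    causalMaf = 0.3, missingRate = 0.02, prevalence = 0.05,
    quantBeta = 0), spec)
  if (sp$plantedOR <= 0) stop("OR must be positive")
  set.seed(seed)
  maf <- runif(sp$nSnp, sp$mafRange[1], sp$mafRange[2])
  maf[sp$causalIndex] <- sp$causalMaf
  block <- ceiling(seq_len(sp$nSnp) / sp$blockSize)
  thr <- qnorm(maf)
  alpha <- qlogis(sp$prevalence)
  lor <- log(sp$plantedOR)

  oneHaplotype <- function() {
    z <- numeric(sp$nSnp)
    for (b in unique(block)) {
      ix <- which(block == b)
      zz <- numeric(length(ix))
      zz[1] <- rnorm(1)
      if (length(ix) > 1)
        for (j in 2:length(ix))
          zz[j] <- sp$blockRho * zz[j - 1] +
            sqrt(1 - sp$blockRho^2) * rnorm(1)
      z[ix] <- zz
    }
    as.integer(z < thr)
  }
  drawIndividual <- function(wantCase) {
    repeat {
      g <- oneHaplotype() + oneHaplotype()
      pen <- plogis(alpha + lor * g[sp$causalIndex])
      if (wantCase && runif(1) < pen) return(g)
      if (!wantCase && runif(1) < 1 - pen) return(g)
    }
  }
  n <- sp$nCase + sp$nControl
  status <- c(rep(1L, sp$nCase), rep(0L, sp$nControl))
  dosage <- matrix(NA_integer_, n, sp$nSnp)
  for (i in seq_len(n)) dosage[i, ] <- drawIndividual(status[i] == 1L)
  # missingness
  nmiss <- rbinom(1, length(dosage), sp$missingRate)
  if (nmiss > 0) dosage[sample.int(length(dosage), nmiss)] <- NA_integer_
  dimnames(dosage) <- list(sprintf("ind%03d", seq_len(n)),
                           sprintf("snp%04d", seq_len(sp$nSnp)))
  gest <- 280 - 35 * status + rnorm(n, 0, 8) +
    sp$quantBeta * ifelse(is.na(dosage[, sp$causalIndex]), 0,
                          dosage[, sp$causalIndex])
  bw <- rnorm(n, -0.8 * status, 1)
  pheno <- data.frame(status = status, gestAge = gest, bwZ = bw,
                      ancestry = rbeta(n, 1, 9))
  snpInfo <- data.frame(id = colnames(dosage), chr = "chr2",
                        pos = seq_len(sp$nSnp) * 2500L,
                        alleleMinor = "A", alleleMajor = "G",
                        stringsAsFactors = FALSE)
  gm <- genotypeMatrix(dosage, pheno, snpInfo, standardize = TRUE)
  attr(gm, "truth") <- c(sp, list(seed = seed))
  gm
}
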