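# HKY85 acceleration test for conserved noncoding elements, adjacent-
# sequence rate context, and element-to-gene assignment.
#
# Elements and gene loci travel as GRanges (0-based half-open on disk, the
# BED convention; 1-based closed in memory, the GRanges convention); each
# element's alignment is a nucleotide PhyloAlignment keyed by element id.

#' Conservation-score filter for noncoding elements
#'
#' @param elements a `GRanges` with a numeric `score` metadata column.
#' @param minScore inclusive threshold (default 400): elements with
#'   `score >= minScore` are kept.
#' @return the filtered `GRanges` (possibly empty).
#' @export
filterElements <- function(elements, minScore = 400) {
  stopifnot(is(elements, "GRanges"))
  sc <- S4Vectors::mcols(elements)$score
  if (is.null(sc)) stop("elements carry no conservation score")
  elements[!is.na(sc) & sc >= minScore]
}

#' Adjacent-noncoding rate context from flanking conserved sequence
#'
#' Concatenates the nearest flanking conserved elements (already ordered by
#' genomic distance from the focal element, focal element excluded) until
#' at least `spanBp` of sequence is accumulated, then fits per-branch HKY85
#' lengths and a shared kappa by maximum likelihood.
#'
#' @param flankingAlignments list of nucleotide [PhyloAlignment-class]
#'   objects ordered by distance from the focal element.
#' @param tree the species tree.
#' @param spanBp target flanking span in bp (default 25000).
#' @param kappaInit,maxit,factr optimizer controls.
#' @return a [RegionalContext-class] with empty `a`; `flags` gains
#'   `"short_flank"` if less than `spanBp` was available.
#' @export
fitNoncodingRegional <- function(flankingAlignments, tree, spanBp = 25000,
                                 kappaInit = 2, maxit = 300, factr = 1e9) {
  if (is(flankingAlignments, "PhyloAlignment"))
    flankingAlignments <- list(flankingAlignments)
  if (spanBp <= 0) stop("spanBp must be positive")
  if (!length(flankingAlignments)) stop("zero flanking sequence supplied")
  widths <- vapply(flankingAlignments, nSites, numeric(1))
  cum <- cumsum(widths)
  take <- seq_len(min(which(cum >= spanBp), length(widths)))
  if (max(cum) < spanBp) take <- seq_along(widths)
  used <- flankingAlignments[take]
  flags <- if (sum(widths[take]) < spanBp) "short_flank" else character()

  tree <- .unrootIfNeeded(tree)
  idx <- treeIndex(tree)
  states <- do.call(cbind, lapply(used, function(a) {
    stopifnot(a@alphabet == "nucleotide")
    .statesForTree(a, idx$tipLabels, allowMissingTaxa = TRUE)
  }))
  if (!any(!is.na(states))) stop("zero flanking sequence after masking")
  counts <- .ntFreqCounts(used)
  freqs <- .ntFreqs(counts)
  eng <- .likEngine(tree, states, freqs, hkyMatrix(kappaInit, freqs)@Q)
  ne <- nrow(idx$edge)

  kappaLast <- kappaInit
  obj <- function(th) {
    t_e <- exp(th[1:ne]); kappa <- exp(th[ne + 1])
    if (kappa != kappaLast) {
      eng$setModel(hkyMatrix(kappa, freqs)@Q)
      kappaLast <<- kappa
    }
    -eng$lnL(t_e)
  }
  th0 <- c(rep(log(0.05), ne), log(kappaInit))
  lo <- c(rep(log(.RATE_FLOOR), ne), log(.KAPPA_BOUNDS[1]))
  hi <- c(rep(log(10), ne), log(.KAPPA_BOUNDS[2]))
  fit <- optim(th0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = maxit, factr = factr))
  if (fit$convergence != 0) flags <- c(flags, "non_convergence")
  dNC <- setNames(exp(fit$par[1:ne]), idx$branchIds)
  if (any(dNC <= .RATE_FLOOR * 1.05)) flags <- c(flags, "rate_floor")
  nm <- names(used)
  if (is.null(nm)) nm <- paste0("flank", seq_along(used))
  new("RegionalContext", branchIds = idx$branchIds, dSr = dNC,
      a = numeric(0), kappa = exp(fit$par[ne + 1]), ntCounts = counts,
      neighborIds = nm, logLik = -fit$value, flags = flags)
}

#' Focal-lineage acceleration test for a conserved noncoding element
#'
#' Null: a single free element rate multiplier `r` scales every branch's
#' adjacent-noncoding length (`r * dNCadj_i`).  Alternative: the focal
#' lineage's multiplier is additionally freed (one parameter, shared across
#' both focal branches in the combined configuration).  1-df chi-squared
#' LRT; base frequencies are estimated empirically from the element.
#'
#' @param elementAlignment nucleotide [PhyloAlignment-class] of the
#'   element.
#' @param context [RegionalContext-class] from [fitNoncodingRegional()].
#' @param tree the species tree.
#' @param focalTip,includeAncestor focal-lineage configuration.
#' @param nStarts,tol optimizer controls.
#' @return an [AccelTestResult-class] (`omegaHat` is the element rate
#'   multiplier r; `RHat` the focal multiplier).
#' @export
lrtAccelElement <- function(elementAlignment, context, tree,
                            focalTip = "Human", includeAncestor = FALSE,
                            nStarts = 3, tol = 1e-4) {
  tree <- .unrootIfNeeded(tree)
  idx <- treeIndex(tree)
  if (!setequal(idx$branchIds, context@branchIds))
    stop("regional context branches do not match the tree")
  states <- .statesForTree(elementAlignment, idx$tipLabels,
                           allowMissingTaxa = TRUE)
  if (!any(!is.na(states)))
    return(new("AccelTestResult", lnL0 = NA_real_, lnL1 = NA_real_,
               omegaHat = NA_real_, omegaAlt = NA_real_, RHat = NA_real_,
               lrt = 0, pValue = 1, focal = focalTip, flags = "all_missing"))
  freqs <- .ntFreqs(.ntFreqCounts(elementAlignment))
  Q <- hkyMatrix(context@kappa, freqs)@Q
  eng <- .likEngine(tree, states, freqs, Q)
  ne <- nrow(idx$edge)
  dNC <- pmax(context@dSr[idx$branchIds], .RATE_FLOOR)
  foc <- idx$branchIds %in% focalBranches(tree, focalTip, includeAncestor)

  lnL <- function(r, f) {
    m <- ifelse(foc, f, r)
    eng$lnL(m * dNC)
  }
  rBounds <- c(1e-4, 1000)
  nullFit <- .brentMax(function(r) lnL(r, r), rBounds, tol)
  r0 <- nullFit$par; lnL0 <- nullFit$value
  descend <- function(r, f) {
    val <- lnL(r, f)
    for (round in 1:8) {
      fF <- .brentMax(function(x) lnL(r, x), rBounds, tol)
      f <- fF$par
      fR <- .brentMax(function(x) lnL(x, f), rBounds, tol)
      r <- fR$par
      if (fR$value - val < 1e-7) { val <- fR$value; break }
      val <- fR$value
    }
    list(r = r, f = f, value = val)
  }
  atBound <- function(x, b) min(abs(log(x) - log(b))) < 1e-3
  best <- descend(r0, r0)
  if (nStarts > 1 && (atBound(best$r, rBounds) || atBound(best$f, rBounds))) {
    for (f0 in utils::head(c(min(5 * r0, rBounds[2]),
                             max(r0 / 5, rBounds[1])), nStarts - 1)) {
      cand <- descend(r0, f0)
      if (cand$value > best$value) best <- cand
    }
  }
  lnL1 <- max(best$value, lnL0)
  lrt <- max(0, 2 * (lnL1 - lnL0))
  flags <- character()
  if (atBound(best$r, rBounds) || atBound(best$f, rBounds))
    flags <- c(flags, "boundary")
  new("AccelTestResult", lnL0 = lnL0, lnL1 = lnL1, omegaHat = r0,
      omegaAlt = best$r, RHat = best$f, lrt = lrt,
      pValue = pchisq(lrt, 1, lower.tail = FALSE),
      focal = paste0(focalTip, if (includeAncestor) "+ancestor" else ""),
      flags = flags)
}

#' Boundary-to-boundary distance between genomic intervals
#'
#' Gap length in bases between two intervals on the same chromosome: 0 for
#' overlapping (or bookended) intervals, otherwise the number of bases
#' strictly between them.
#'
#' @param start1,end1,start2,end2 0-based half-open coordinates.
#' @return nonnegative integer distance (vectorized).
#' @export
intervalDistance <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start2 - end1, start1 - end2))
}

#' Assign each conserved element to its nearest gene
#'
#' An element overlapping a gene body is assigned to that gene; otherwise
#' to the gene minimizing boundary-to-boundary distance.  Ties go to the
#' gene with the lower start coordinate (recorded in the `tie` column).
#' Strand is ignored.
#'
#' @param elements `GRanges` of elements with a `name` (or `id`) metadata
#'   column.
#' @param geneLoci `GRanges` of gene bodies with a `name` (or `id`) column.
#' @return data.frame: `element`, `gene` (`NA` if the chromosome has no
#'   genes, flagged), `distance`, `tie`, `flag`.
#' @export
assignNearestGene <- function(elements, geneLoci) {
  stopifnot(is(elements, "GRanges"), is(geneLoci, "GRanges"))
  getName <- function(gr, prefix) {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) nm <- S4Vectors::mcols(gr)$id
    if (is.null(nm)) nm <- paste0(prefix, seq_along(gr))
    as.character(nm)
  }
  eName <- getName(elements, "element"); gName <- getName(geneLoci, "gene")
  eChr <- as.character(GenomicRanges::seqnames(elements))
  gChr <- as.character(GenomicRanges::seqnames(geneLoci))
  # 0-based half-open coordinates for the distance computation
  eS <- GenomicRanges::start(elements) - 1L; eE <- GenomicRanges::end(elements)
  gS <- GenomicRanges::start(geneLoci) - 1L; gE <- GenomicRanges::end(geneLoci)
  out <- data.frame(element = eName, gene = NA_character_,
                    distance = NA_integer_, tie = FALSE, flag = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(elements)) {
    cand <- which(gChr == eChr[i])
    if (!length(cand)) { out$flag[i] <- "no_gene_on_chromosome"; next }
    d <- intervalDistance(eS[i], eE[i], gS[cand], gE[cand])
    dmin <- min(d)
    hits <- cand[d == dmin]
    if (length(hits) > 1) {
      out$tie[i] <- TRUE
      hits <- hits[order(gS[hits])]
    }
    out$gene[i] <- gName[hits[1]]
    out$distance[i] <- dmin
  }
  out
}

#' Read/write BED intervals
#'
#' BED5 I/O (chrom, start, end, name, score) via \pkg{rtracklayer}: 0-based
#' half-open on disk, `GRanges` (1-based closed) with `name` and `score`
#' metadata in memory.
#'
#' @param path BED file path.
#' @return `readBed`: a `GRanges`.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname readBed
#' @param gr a `GRanges` with optional `name` and `score` columns.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
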