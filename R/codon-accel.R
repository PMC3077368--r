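# Regional-context estimation and the focal-lineage acceleration LRT for
# protein-coding sequences.
#
# Branch parameterization: the synonymous length of branch i is the
# regional dSr_i; its nonsynonymous length is a_i * m * dSr_i, where a_i is
# the regional per-branch constraint scaling (the regional omega is
# absorbed into a_i, so a_i reads as the regional dN/dS scale on branch i)
# and m is the gene-wise rate multiplier: a single omega under the null,
# or the focal-lineage free parameter R on the focal branch(es) under the
# alternative.  R is on the same scale as omega, so R = omega recovers the
# null and the test has exactly one extra degree of freedom.

.W_BOUNDS <- c(1e-6, 100)
.KAPPA_BOUNDS <- c(0.1, 20)
.DSR_BOUNDS <- c(1e-6, 10)
.A_BOUNDS <- c(1e-6, 100)
.RATE_FLOOR <- 1e-6

#' Build a regional context from known per-branch values
#'
#' Constructs a [RegionalContext-class] directly from supplied per-branch
#' rates instead of estimating them from neighbor data -- used to carry
#' simulation ground truth into the tests (calibration and power studies
#' condition on the true regional context) or externally estimated rates.
#'
#' @param tree the species tree (degree-2 root collapsed).
#' @param dSr per-branch synonymous (or adjacent-noncoding) lengths: a
#'   scalar recycled to every branch or a named vector keyed by branch id.
#' @param a per-branch constraint scalings (same conventions); use
#'   `numeric(0)` for noncoding contexts.
#' @param kappa transition/transversion ratio.
#' @param freqs3x4 3 x 4 position-specific nucleotide frequencies (or a
#'   length-4 vector for nucleotide contexts), converted to pseudo-counts.
#' @return a [RegionalContext-class].
#' @export
regionalContext <- function(tree, dSr, a = numeric(0), kappa = 2,
                            freqs3x4 = matrix(0.25, 3, 4)) {
  tree <- .unrootIfNeeded(tree)
  ids <- branchIds(tree)
  expand <- function(v) {
    if (length(v) == 1 && is.null(names(v))) return(setNames(rep(v, length(ids)), ids))
    if (length(v) == 0) return(v)
    miss <- setdiff(ids, names(v))
    if (length(miss)) stop("missing branch value(s): ", paste(miss, collapse = ", "))
    v[ids]
  }
  fq <- if (is.matrix(freqs3x4)) freqs3x4 else matrix(freqs3x4, 1, 4)
  new("RegionalContext", branchIds = ids, dSr = expand(dSr), a = expand(a),
      kappa = kappa, ntCounts = fq * 1000, neighborIds = "supplied",
      logLik = NA_real_, flags = character())
}

# memoized MG94 components: rebuilt only when kappa changes
.mg94Memo <- function(freqs3x4) {
  lastKappa <- NA_real_
  cp <- NULL
  function(kappa) {
    if (is.na(lastKappa) || kappa != lastKappa) {
      cp <<- .mg94Components(kappa, freqs3x4)
      lastKappa <<- kappa
    }
    cp
  }
}

#' Estimate the regional rate context from neighboring genes
#'
#' Maximizes the concatenated likelihood of a window of neighbor genes
#' (default usage: the 10 upstream and 10 downstream genes of a focal
#' locus) over per-branch regional synonymous lengths `dSr_i`, per-branch
#' constraint scalings `a_i` (regional omega absorbed), and a shared
#' `kappa`, under the MG94xHKY85 codon model with F3x4 frequencies
#' estimated from the neighbors.
#'
#' @param neighborAlignments named list of codon [PhyloAlignment-class]
#'   objects (loci that passed [filterOrthologPresence()]).
#' @param tree the species tree (`phylo`); a degree-2 root is collapsed
#'   and the unrooted tree is fitted.
#' @param kappaInit starting transition/transversion ratio.
#' @param maxit,factr L-BFGS-B controls.
#' @return a [RegionalContext-class]; `flags` may contain
#'   `"non_convergence"` and/or `"rate_floor"` (some `dSr_i` at the 1e-6
#'   floor, e.g. for invariant neighbor data).
#' @export
fitRegional <- function(neighborAlignments, tree, kappaInit = 2,
                        maxit = 300, factr = 1e9) {
  if (is(neighborAlignments, "PhyloAlignment"))
    neighborAlignments <- list(neighborAlignments)
  if (!length(neighborAlignments)) stop("at least one neighbor alignment required")
  tree <- .unrootIfNeeded(tree)
  idx <- treeIndex(tree)
  stateList <- lapply(neighborAlignments, function(a) {
    stopifnot(a@alphabet == "codon")
    .statesForTree(a, idx$tipLabels, allowMissingTaxa = TRUE)
  })
  states <- do.call(cbind, stateList)
  if (!any(!is.na(states))) stop("zero aligned codons after masking")
  counts <- .f3x4Counts(neighborAlignments)
  freqs <- .f3x4Freqs(counts)
  mg <- .mg94Memo(freqs)
  cp0 <- mg(kappaInit)
  eng <- .likEngine(tree, states, cp0$pi, cp0$A, cp0$B)
  ne <- nrow(idx$edge)

  kappaLast <- kappaInit
  obj <- function(th) {
    dSr <- exp(th[1:ne]); a <- exp(th[ne + (1:ne)]); kappa <- exp(th[2 * ne + 1])
    if (kappa != kappaLast) {
      cp <- mg(kappa)
      eng$setModel(cp$A, cp$B)
      kappaLast <<- kappa
    }
    -eng$lnL(dSr, a * dSr)
  }
  th0 <- c(rep(log(0.05), ne), rep(log(0.2), ne), log(kappaInit))
  lo <- c(rep(log(.DSR_BOUNDS[1]), ne), rep(log(.A_BOUNDS[1]), ne),
          log(.KAPPA_BOUNDS[1]))
  hi <- c(rep(log(.DSR_BOUNDS[2]), ne), rep(log(.A_BOUNDS[2]), ne),
          log(.KAPPA_BOUNDS[2]))
  fit <- optim(th0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = maxit, factr = factr))
  dSr <- setNames(exp(fit$par[1:ne]), idx$branchIds)
  a <- setNames(exp(fit$par[ne + (1:ne)]), idx$branchIds)
  flags <- character()
  if (fit$convergence != 0) flags <- c(flags, "non_convergence")
  if (any(dSr <= .RATE_FLOOR * 1.05)) flags <- c(flags, "rate_floor")
  nm <- names(neighborAlignments)
  if (is.null(nm)) nm <- paste0("neighbor", seq_along(neighborAlignments))
  new("RegionalContext", branchIds = idx$branchIds, dSr = dSr, a = a,
      kappa = exp(fit$par[2 * ne + 1]), ntCounts = counts,
      neighborIds = nm, logLik = -fit$value, flags = flags)
}

# 1-D Brent maximization over a log-scaled rate parameter
.brentMax <- function(f, bounds, tol = 1e-4) {
  opt <- optimize(function(lg) f(exp(lg)), interval = log(bounds),
                  maximum = TRUE, tol = tol)
  list(par = exp(opt$maximum), value = opt$objective)
}

#' Focal-lineage acceleration test for a coding gene
#'
#' Likelihood-ratio test of whether the focal lineage's nonsynonymous rate
#' exceeds its regional expectation.  Under the null a single gene-wise
#' omega multiplies every branch's regional nonsynonymous expectation
#' (`a_i * omega * dSr_i`, synonymous lengths fixed at `dSr_i`); the
#' alternative frees the focal lineage's multiplier to R (one parameter,
#' shared across the terminal and ancestor branches in the combined
#' configuration), giving a 1-df chi-squared test.
#'
#' @param geneAlignment codon [PhyloAlignment-class] of the focal gene.
#' @param context the [RegionalContext-class] fitted from the gene's
#'   neighbors.
#' @param tree the species tree.
#' @param focalTip focal terminal branch label (default `"Human"`).
#' @param includeAncestor also free the focal tip's parent branch, sharing
#'   the single R (the "human + human-chimpanzee ancestor" configuration).
#' @param nStarts number of alternative-model starts (perturbed R inits).
#' @param tol Brent tolerance on the log-rate scale.
#' @return an [AccelTestResult-class].
#' @export
lrtAccelCoding <- function(geneAlignment, context, tree, focalTip = "Human",
                           includeAncestor = FALSE, nStarts = 3, tol = 2e-3) {
  tree <- .unrootIfNeeded(tree)
  idx <- treeIndex(tree)
  if (!setequal(idx$branchIds, context@branchIds))
    stop("regional context branches do not match the tree")
  states <- .statesForTree(geneAlignment, idx$tipLabels, allowMissingTaxa = TRUE)
  freqs <- .f3x4Freqs(context@ntCounts + .f3x4Counts(geneAlignment))
  cp <- .mg94Components(context@kappa, freqs)
  eng <- .likEngine(tree, states, cp$pi, cp$A, cp$B)
  ne <- nrow(idx$edge)
  dSr <- pmax(context@dSr[idx$branchIds], .RATE_FLOOR)
  a <- context@a[idx$branchIds]
  foc <- idx$branchIds %in% focalBranches(tree, focalTip, includeAncestor)
  if (!any(foc)) stop("no focal branch found")

  lnL <- function(w, R) {
    m <- ifelse(foc, R, w)
    eng$lnL(dSr, a * m * dSr)
  }

  nullFit <- .brentMax(function(w) lnL(w, w), .W_BOUNDS, tol)
  w0 <- nullFit$par
  lnL0 <- nullFit$value

  # coordinate descent over (omega, R); each 1-D subproblem is a global
  # Brent search over the whole bound interval, so additional perturbed
  # starts are only launched when a descent ends on a parameter bound
  descend <- function(w, R) {
    val <- lnL(w, R)
    for (round in 1:8) {
      fR <- .brentMax(function(r) lnL(w, r), .W_BOUNDS, tol)
      R <- fR$par
      fW <- .brentMax(function(x) lnL(x, R), .W_BOUNDS, tol)
      w <- fW$par
      if (fW$value - val < 1e-7) { val <- fW$value; break }
      val <- fW$value
    }
    list(w = w, R = R, value = val)
  }
  atBound <- function(x, b) min(abs(log(x) - log(b))) < 1e-3
  best <- descend(w0, w0)
  if (nStarts > 1 && (atBound(best$R, .W_BOUNDS) || atBound(best$w, .W_BOUNDS))) {
    for (R0 in utils::head(c(min(3 * w0, .W_BOUNDS[2]),
                             max(w0 / 3, .W_BOUNDS[1])), nStarts - 1)) {
      cand <- descend(w0, R0)
      if (cand$value > best$value) best <- cand
    }
  }
  lnL1 <- max(best$value, lnL0)

  flags <- character()
  lrt <- 2 * (lnL1 - lnL0)
  if (lrt < 0) lrt <- 0
  if (atBound(best$w, .W_BOUNDS) || atBound(best$R, .W_BOUNDS))
    flags <- c(flags, "boundary")
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  new("AccelTestResult", lnL0 = lnL0, lnL1 = lnL1, omegaHat = w0,
      omegaAlt = best$w, RHat = best$R, lrt = lrt, pValue = p,
      focal = paste0(focalTip, if (includeAncestor) "+ancestor" else ""),
      flags = flags)
}

#' Stand-alone two-ratio branch test of dN/dS
#'
#' Unadjusted variant for single-gene analyses on an arbitrary taxon set
#' (no regional context): estimates per-branch synonymous lengths, shared
#' kappa, and a background omega; the alternative adds a separate omega on
#' the focal branch(es).  1-df LRT.
#'
#' @param geneAlignment codon [PhyloAlignment-class].
#' @param tree species tree containing the focal tip.
#' @param focalTip focal terminal branch label.
#' @param includeAncestor share the focal omega with the parent branch.
#' @param kappaInit,maxit,factr optimizer controls.
#' @return list with `omegaFocal`, `omegaBackground`, `p`, `lrt`, `lnL0`,
#'   `lnL1`, `flags`.
#' @export
humanDnds <- function(geneAlignment, tree, focalTip = "Human",
                      includeAncestor = FALSE, kappaInit = 2,
                      maxit = 300, factr = 1e9) {
  tree <- .unrootIfNeeded(tree)
  idx <- treeIndex(tree)
  states <- .statesForTree(geneAlignment, idx$tipLabels, allowMissingTaxa = TRUE)
  variable <- apply(states, 2, function(col) {
    v <- unique(col[!is.na(col)]); length(v) > 1
  })
  if (!any(variable))
    return(list(omegaFocal = NA_real_, omegaBackground = NA_real_,
                p = NA_real_, lrt = NA_real_, lnL0 = NA_real_, lnL1 = NA_real_,
                flags = "inestimable"))
  freqs <- .f3x4Freqs(.f3x4Counts(geneAlignment))
  mg <- .mg94Memo(freqs)
  cp0 <- mg(kappaInit)
  eng <- .likEngine(tree, states, cp0$pi, cp0$A, cp0$B)
  ne <- nrow(idx$edge)
  foc <- idx$branchIds %in% focalBranches(tree, focalTip, includeAncestor)

  kappaLast <- kappaInit
  objFactory <- function(twoRatio) {
    function(th) {
      t_e <- exp(th[1:ne]); kappa <- exp(th[ne + 1]); w <- exp(th[ne + 2])
      wf <- if (twoRatio) exp(th[ne + 3]) else w
      if (kappa != kappaLast) {
        cp <- mg(kappa)
        eng$setModel(cp$A, cp$B)
        kappaLast <<- kappa
      }
      m <- ifelse(foc, wf, w)
      -eng$lnL(t_e, m * t_e)
    }
  }
  lo0 <- c(rep(log(.DSR_BOUNDS[1]), ne), log(.KAPPA_BOUNDS[1]), log(.W_BOUNDS[1]))
  hi0 <- c(rep(log(.DSR_BOUNDS[2]), ne), log(.KAPPA_BOUNDS[2]), log(.W_BOUNDS[2]))
  th0 <- c(rep(log(0.05), ne), log(kappaInit), log(0.2))
  fit0 <- optim(th0, objFactory(FALSE), method = "L-BFGS-B",
                lower = lo0, upper = hi0,
                control = list(maxit = maxit, factr = factr))
  th1 <- c(fit0$par, fit0$par[ne + 2])
  fit1 <- optim(th1, objFactory(TRUE), method = "L-BFGS-B",
                lower = c(lo0, log(.W_BOUNDS[1])), upper = c(hi0, log(.W_BOUNDS[2])),
                control = list(maxit = maxit, factr = factr))
  flags <- character()
  if (fit0$convergence != 0 || fit1$convergence != 0)
    flags <- c(flags, "non_convergence")
  lnL0 <- -fit0$value; lnL1 <- max(-fit1$value, lnL0)
  lrt <- max(0, 2 * (lnL1 - lnL0))
  list(omegaFocal = exp(fit1$par[ne + 3]),
       omegaBackground = exp(fit1$par[ne + 2]),
       p = pchisq(lrt, 1, lower.tail = FALSE), lrt = lrt,
       lnL0 = lnL0, lnL1 = lnL1, flags = flags)
}
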