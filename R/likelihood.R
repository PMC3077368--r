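#' Transition probability matrix of a reversible model
#'
#' `exp(Q t)` computed from the eigendecomposition of the pi-symmetrized
#' generator, with scaling-and-squaring as a fallback for ill-conditioned
#' inputs.
#'
#' @param model a [SubstitutionModel-class].
#' @param t branch length (>= 0) in the model's normalization units.
#' @return a stochastic matrix (rows sum to 1).
#' @export
transitionMatrix <- function(model, t) {
  if (t < 0) stop("negative branch length")
  .transMatCpp(model@Q * t, model@pi)
}

#' Felsenstein pruning log-likelihood
#'
#' Exact phylogenetic log-likelihood of an alignment on a tree under a
#' reversible substitution model, with missing states marginalized and
#' identical site patterns collapsed.  Branch lengths are supplied per
#' branch, either as a named numeric vector keyed by branch identifier
#' (child tip label, or sorted child-clade tip labels joined by `"+"`) or
#' as a function mapping a branch identifier to a length.
#'
#' @param tree a `phylo` object.
#' @param alignment a [PhyloAlignment-class] whose alphabet matches the
#'   model's state space.
#' @param model a [SubstitutionModel-class].
#' @param branchLengths named numeric vector or `function(branchId)`.
#' @param allowMissingTaxa treat tree taxa absent from the alignment as
#'   all-missing rows (default `FALSE`: error).
#' @return the log-likelihood (numeric scalar).
#' @examples
#' tr <- readNewick("(A:1,B:1);")
#' aln <- phyloAlignment(c(A = "A", B = "A"), "nucleotide")
#' m <- hkyMatrix(2, rep(0.25, 4))
#' pruneLoglik(tr, aln, m, c(A = 0, B = 0))  # log(1/4)
#' @export
pruneLoglik <- function(tree, alignment, model, branchLengths,
                        allowMissingTaxa = FALSE) {
  idx <- treeIndex(tree)
  if (is.function(branchLengths)) {
    bl <- vapply(idx$branchIds, branchLengths, numeric(1))
  } else {
    miss <- setdiff(idx$branchIds, names(branchLengths))
    if (length(miss)) stop("no branch length for: ", paste(miss, collapse = ", "))
    bl <- branchLengths[idx$branchIds]
  }
  if (any(bl < 0)) stop("negative branch length")
  states <- .statesForTree(alignment, idx$tipLabels, allowMissingTaxa)
  pat <- .compressPatterns(states)
  k <- length(model@pi)
  P <- array(0, c(k, k, nrow(idx$edge)))
  for (e in seq_len(nrow(idx$edge)))
    P[, , e] <- .transMatCpp(model@Q * bl[e], model@pi)
  .pruneLoglikCpp(pat$states, idx$edge, P, model@pi, pat$weights,
                  idx$nnode, idx$root)
}

# ---- internal fast-path engine used by the fitting routines ----
#
# Precomputes the traversal and site patterns once; lnL(s, n, version) is
# the log-likelihood with branch-e generator s[e]*A + n[e]*B, where A/B are
# bound at construction or refreshed via setModel() (bump `version` when
# they change).  Transition matrices are cached per branch and recomputed
# only for branches whose (s, n) changed.

.likEngine <- function(tree, statesMatrix, pi, A, B = matrix(0, 0, 0)) {
  idx <- treeIndex(tree)
  stopifnot(identical(rownames(statesMatrix), idx$tipLabels))
  pat <- .compressPatterns(statesMatrix)
  k <- length(pi)
  ne <- nrow(idx$edge)
  env <- new.env(parent = emptyenv())
  env$P <- array(0, c(k, k, ne))
  env$s <- rep(NA_real_, ne); env$n <- rep(NA_real_, ne)
  env$A <- A; env$B <- B; env$version <- 0L
  setModel <- function(A, B = matrix(0, 0, 0)) {
    env$A <- A; env$B <- B
    env$s[] <- NA_real_  # invalidate every branch
  }
  lnL <- function(s, n = rep(0, ne)) {
    changed <- which(is.na(env$s) | env$s != s | env$n != n)
    if (length(changed)) {
      env$P[, , changed] <- .batchTransMatCpp(env$A, env$B, s[changed],
                                              n[changed], pi)
      env$s[changed] <- s[changed]; env$n[changed] <- n[changed]
    }
    .pruneLoglikCpp(pat$states, idx$edge, env$P, pi, pat$weights,
                    idx$nnode, idx$root)
  }
  list(lnL = lnL, setModel = setModel, idx = idx,
       npat = ncol(pat$states), nsite = sum(pat$weights))
}
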