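#' HKY85 nucleotide substitution model
#'
#' Transition/transversion-weighted reversible model with arbitrary base
#' frequencies, normalized so the expected substitution rate at
#' stationarity is 1 (branch lengths in expected substitutions/site).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param freqs stationary base frequencies in A,C,G,T order (sum to 1).
#' @return a [SubstitutionModel-class] with 4 states.
#' @examples
#' m <- hkyMatrix(2, rep(0.25, 4))
#' rowSums(m@Q)  # ~ 0
#' @export
hkyMatrix <- function(kappa = 2, freqs = rep(0.25, 4)) {
  stopifnot(kappa > 0, length(freqs) == 4)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  Q <- matrix(0, 4, 4, dimnames = list(.ntLevels, .ntLevels))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- freqs[j] * if (.isTransition(.ntLevels[i], .ntLevels[j])) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q <- Q / rate
  new("SubstitutionModel", states = .ntLevels, Q = Q, pi = as.numeric(freqs),
      normalization = "total", rateInfo = c(kappa = kappa))
}

# MG94xHKY85 building blocks: separately normalized synonymous (A) and
# nonsynonymous (B) generator parts sharing the stationary distribution, so
# a branch generator s*A + n*B accumulates s expected synonymous and n
# expected nonsynonymous substitutions per codon site.
#
# freqs3x4: 3 x 4 matrix of position-specific nucleotide frequencies.
.mg94Components <- function(kappa, freqs3x4) {
  stopifnot(kappa > 0, all(dim(freqs3x4) == c(3, 4)))
  if (max(abs(rowSums(freqs3x4) - 1)) > 1e-8)
    stop("position-specific frequencies must each sum to 1")
  tab <- .codonTable()
  cm <- tab$cmat
  piC <- freqs3x4[1, match(cm[, 1], .ntLevels)] *
         freqs3x4[2, match(cm[, 2], .ntLevels)] *
         freqs3x4[3, match(cm[, 3], .ntLevels)]
  piC <- piC / sum(piC)
  pr <- tab$pairs
  rate <- freqs3x4[cbind(pr$pos, pr$targetNt)] * ifelse(pr$transition, kappa, 1)
  A <- matrix(0, 61, 61, dimnames = list(tab$codons, tab$codons))
  B <- A
  syn <- pr$synonymous
  A[cbind(pr$i[syn], pr$j[syn])] <- rate[syn]
  B[cbind(pr$i[!syn], pr$j[!syn])] <- rate[!syn]
  fluxA <- sum(piC * rowSums(A))
  fluxB <- sum(piC * rowSums(B))
  A <- A / fluxA; B <- B / fluxB
  diag(A) <- -rowSums(A); diag(B) <- -rowSums(B)
  list(A = A, B = B, pi = piC, kappa = kappa)
}

#' MG94xHKY85 codon substitution model
#'
#' Muse--Gaut codon structure with HKY85 nucleotide exchangeabilities:
#' codons differing at more than one position do not interchange directly;
#' single-nucleotide changes are weighted by the target nucleotide's
#' (position-specific, F3x4) frequency, by `kappa` for transitions, and by
#' `omega` if the change is nonsynonymous.  The generator is normalized so
#' branch lengths are in expected synonymous substitutions per codon site;
#' `rateInfo["nonsynFluxPerUnit"]` records the accompanying nonsynonymous
#' flux.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs3x4 3 x 4 matrix of position-specific nucleotide
#'   frequencies (rows = codon positions, columns = A,C,G,T); defaults to
#'   uniform.
#' @return a [SubstitutionModel-class] with 61 states.
#' @examples
#' m <- mg94Matrix(kappa = 2, omega = 0.2)
#' m@Q["AAA", "ACG"]  # two positions differ -> 0
#' @export
mg94Matrix <- function(kappa = 2, omega = 0.2,
                       freqs3x4 = matrix(0.25, 3, 4)) {
  if (omega < 0) stop("omega must be >= 0")
  cp <- .mg94Components(kappa, freqs3x4)
  Q <- cp$A + omega * cp$B
  new("SubstitutionModel", states = .codonTable()$codons, Q = Q, pi = cp$pi,
      normalization = "synonymous",
      rateInfo = c(kappa = kappa, omega = omega, nonsynFluxPerUnit = omega))
}

# Position-specific nucleotide counts (3 x 4) from one or more codon
# alignments; the F3x4 frequencies are the row-normalized counts with a
# half-count floor so no frequency is exactly zero.
.f3x4Counts <- function(alignments) {
  if (is(alignments, "PhyloAlignment")) alignments <- list(alignments)
  counts <- matrix(0, 3, 4, dimnames = list(NULL, .ntLevels))
  cm <- .codonTable()$cmat
  for (aln in alignments) {
    stopifnot(aln@alphabet == "codon")
    st <- aln@states[!is.na(aln@states)]
    if (!length(st)) next
    tb <- tabulate(st, nbins = 61)
    for (p in 1:3)
      counts[p, ] <- counts[p, ] +
        as.numeric(tapply(tb, factor(cm[, p], levels = .ntLevels), sum))
  }
  counts[is.na(counts)] <- 0
  counts
}

.f3x4Freqs <- function(counts) {
  counts <- counts + 0.5  # avoid zero frequencies
  counts / rowSums(counts)
}

# Pooled base frequencies (length 4) from nucleotide alignments, with the
# same half-count floor.
.ntFreqCounts <- function(alignments) {
  if (is(alignments, "PhyloAlignment")) alignments <- list(alignments)
  counts <- setNames(numeric(4), .ntLevels)
  for (aln in alignments) {
    stopifnot(aln@alphabet == "nucleotide")
    st <- aln@states[!is.na(aln@states)]
    counts <- counts + tabulate(st, nbins = 4)
  }
  matrix(counts, nrow = 1, dimnames = list(NULL, .ntLevels))
}

.ntFreqs <- function(counts) {
  counts <- counts + 0.5
  as.numeric(counts / sum(counts))
}
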