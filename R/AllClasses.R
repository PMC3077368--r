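#' Multiple sequence alignment tied to a state alphabet
#'
#' Sequences are stored as an integer state matrix (taxa x sites); `NA`
#' encodes missing data (gaps, ambiguity codes, and -- for the codon
#' alphabet -- any codon containing an ambiguous base, which is masked
#' whole).  For the codon alphabet the states index the 61 sense codons of
#' the universal code; stop codons are masked as missing.
#'
#' @slot taxa character vector of unique taxon names (row order of `states`).
#' @slot states integer matrix, taxa x sites, values in `1:length(alphabet
#'   states)` or `NA`.
#' @slot alphabet `"nucleotide"` (A,C,G,T) or `"codon"` (61 sense codons).
#' @export
setClass("PhyloAlignment",
  representation(taxa = "character", states = "matrix", alphabet = "character"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicate taxon names")
    if (nrow(object@states) != length(object@taxa))
      msg <- c(msg, "states row count != number of taxa")
    if (!object@alphabet %in% c("nucleotide", "codon"))
      msg <- c(msg, "alphabet must be 'nucleotide' or 'codon'")
    k <- if (identical(object@alphabet, "codon")) 61L else 4L
    v <- object@states[!is.na(object@states)]
    if (length(v) && (min(v) < 1L || max(v) > k))
      msg <- c(msg, "state indices out of range for alphabet")
    if (length(msg)) msg else TRUE
  }
)

#' Reversible substitution model
#'
#' @slot states state labels (4 nucleotides or 61 sense codons).
#' @slot Q instantaneous rate matrix, rows summing to zero.
#' @slot pi stationary frequencies.
#' @slot normalization `"total"` (expected substitutions/site/unit = 1) or
#'   `"synonymous"` (expected synonymous substitutions/site/unit = 1, the
#'   codon-model convention so branch lengths read in synonymous units).
#' @slot rateInfo named numeric bookkeeping (e.g. nonsynonymous flux per
#'   unit synonymous length).
#' @export
setClass("SubstitutionModel",
  representation(states = "character", Q = "matrix", pi = "numeric",
                 normalization = "character", rateInfo = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- length(object@states)
    if (!all(dim(object@Q) == k)) msg <- c(msg, "Q dimension != state count")
    if (length(object@pi) != k) msg <- c(msg, "pi length != state count")
    if (abs(sum(object@pi) - 1) > 1e-8) msg <- c(msg, "pi does not sum to 1")
    if (max(abs(rowSums(object@Q))) > 1e-8) msg <- c(msg, "Q rows do not sum to 0")
    db <- object@pi * object@Q
    if (max(abs(db - t(db))) > 1e-6 * max(abs(object@Q)))
      msg <- c(msg, "detailed balance violated (model not reversible)")
    if (length(msg)) msg else TRUE
  }
)

#' Regional rate context for a focal locus
#'
#' Per-branch expected rates estimated from a locus's genomic neighborhood:
#' for coding screens, regional synonymous lengths `dSr` and constraint
#' scalings `a` (the regional dN/dS scale, regional omega absorbed) from the
#' flanking genes; for noncoding screens `a` is empty and `dSr` holds the
#' adjacent conserved-sequence branch lengths.
#'
#' @slot branchIds stable branch identifiers (child-clade labels).
#' @slot dSr named per-branch synonymous (or adjacent-noncoding) lengths.
#' @slot a named per-branch constraint scaling factors (coding only).
#' @slot kappa shared transition/transversion ratio.
#' @slot ntCounts position x nucleotide count matrix behind the F3x4
#'   frequencies (3 x 4 for codon contexts, 1 x 4 for nucleotide contexts).
#' @slot neighborIds identifiers of the contributing neighbor loci.
#' @slot logLik maximized log-likelihood of the neighbor data.
#' @slot flags character vector of condition flags (e.g. "non_convergence",
#'   "rate_floor", "short_flank").
#' @export
setClass("RegionalContext",
  representation(branchIds = "character", dSr = "numeric", a = "numeric",
                 kappa = "numeric", ntCounts = "matrix",
                 neighborIds = "character", logLik = "numeric",
                 flags = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@dSr) != length(object@branchIds))
      msg <- c(msg, "one dSr per branch required")
    if (length(object@a) && length(object@a) != length(object@branchIds))
      msg <- c(msg, "a must be empty or one per branch")
    if (any(object@dSr < 0) || any(object@a < 0))
      msg <- c(msg, "rates must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' Result of a lineage-acceleration likelihood-ratio test
#'
#' @slot lnL0,lnL1 maximized log-likelihoods of the null (single omega) and
#'   alternative (focal rate freed) models.
#' @slot omegaHat shared rate multiplier under the null (gene-wise omega for
#'   coding tests, element rate multiplier r for noncoding tests).
#' @slot omegaAlt background rate multiplier under the alternative.
#' @slot RHat focal-lineage rate multiplier under the alternative, on the
#'   same scale as `omegaHat` (R = omega recovers the null).
#' @slot lrt 2*(lnL1 - lnL0), clamped at 0.
#' @slot pValue chi-squared (1 df) survival probability of `lrt`.
#' @slot focal label of the focal configuration.
#' @slot flags condition flags ("boundary", "non_convergence", ...).
#' @export
setClass("AccelTestResult",
  representation(lnL0 = "numeric", lnL1 = "numeric", omegaHat = "numeric",
                 omegaAlt = "numeric", RHat = "numeric", lrt = "numeric",
                 pValue = "numeric", focal = "character", flags = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "p-value outside [0,1]")
    if (length(object@lrt) && object@lrt < 0) msg <- c(msg, "negative LRT")
    if (length(msg)) msg else TRUE
  }
)

#' Case-control genotype container
#'
#' @slot dosage individuals x SNPs minor-allele dosage matrix (0/1/2, `NA`
#'   missing), dimnames individual and SNP identifiers.
#' @slot pheno data.frame, one row per individual: `status` (1 case, 0
#'   control), optional quantitative phenotypes (`gestAge`, `bwZ`), optional
#'   `ancestry` covariate.
#' @slot snpInfo data.frame, one row per SNP: `id`, `chr`, `pos`, `alleleMinor`,
#'   `alleleMajor`.
#' @slot qcLog data.frame of filter decisions (unit, type, reason).
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", pheno = "data.frame",
                 snpInfo = "data.frame", qcLog = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@pheno) != nrow(object@dosage))
      msg <- c(msg, "pheno rows != individuals")
    if (nrow(object@snpInfo) != ncol(object@dosage))
      msg <- c(msg, "snpInfo rows != SNPs")
    d <- object@dosage[!is.na(object@dosage)]
    if (length(d) && !all(d %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (length(msg)) msg else TRUE
  }
)
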