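# Universal genetic code bookkeeping for the 61 sense codons, built once at
# load from Biostrings::GENETIC_CODE.

.codonEnv <- new.env(parent = emptyenv())

.ntLevels <- c("A", "C", "G", "T")

#' Sense codons of the universal genetic code
#'
#' @return character vector of the 61 sense codons (stop codons excluded),
#'   in the fixed state order used throughout the package.
#' @export
senseCodons <- function() .codonTable()$codons

# transition pairs (purine-purine or pyrimidine-pyrimidine)
.isTransition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

.codonTable <- function() {
  if (!is.null(.codonEnv$tab)) return(.codonEnv$tab)
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  codons <- all64[gc != "*"]
  aa <- gc[codons]
  k <- length(codons)
  stopifnot(k == 61L)
  cmat <- do.call(rbind, strsplit(codons, ""))
  # enumerate ordered pairs differing at exactly one position
  i <- integer(0); j <- integer(0); pos <- integer(0)
  for (p in 1:3) {
    same <- outer(cmat[, setdiff(1:3, p)[1]], cmat[, setdiff(1:3, p)[1]], "==") &
            outer(cmat[, setdiff(1:3, p)[2]], cmat[, setdiff(1:3, p)[2]], "==")
    diffp <- outer(cmat[, p], cmat[, p], "!=")
    hit <- which(same & diffp, arr.ind = TRUE)
    i <- c(i, hit[, 1]); j <- c(j, hit[, 2]); pos <- c(pos, rep(p, nrow(hit)))
  }
  targetNt <- match(cmat[cbind(j, pos)], .ntLevels)
  sourceNt <- cmat[cbind(i, pos)]
  transition <- .isTransition(sourceNt, .ntLevels[targetNt])
  synonymous <- aa[i] == aa[j]
  .codonEnv$tab <- list(
    codons = codons, aa = unname(aa), cmat = cmat,
    pairs = data.frame(i = i, j = j, pos = pos, targetNt = targetNt,
                       transition = transition, synonymous = synonymous)
  )
  .codonEnv$tab
}

# map codon strings to 1..61 state indices; stop codons and codons with
# non-ACGT characters -> NA
.codonIndex <- function(codonStrings) {
  match(codonStrings, .codonTable()$codons)
}
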