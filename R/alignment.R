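#' Construct a PhyloAlignment from character sequences
#'
#' Ambiguity codes and gaps become missing data (they are marginalized in
#' likelihood computations, never treated as a fifth state).  Under the
#' codon alphabet a codon containing any non-ACGT base is masked whole, and
#' stop codons are masked with a warning (internal stops are treated as
#' alignment artifacts, not states of the model).
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param alphabet `"nucleotide"` or `"codon"`.
#' @return a [PhyloAlignment-class] object.
#' @examples
#' aln <- phyloAlignment(c(H = "ATGAAA", C = "ATGAAG"), alphabet = "codon")
#' nSites(aln)
#' @export
phyloAlignment <- function(seqs, alphabet = c("nucleotide", "codon")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by taxon")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    short <- names(seqs)[which(w != max(w))]
    stop("ragged alignment: record(s) of deviating length: ",
         paste(short, collapse = ", "))
  }
  up <- toupper(seqs)
  up <- gsub("U", "T", up, fixed = TRUE)
  chmat <- do.call(rbind, strsplit(up, ""))
  rownames(chmat) <- names(seqs)
  if (alphabet == "nucleotide") {
    states <- matrix(match(chmat, .ntLevels), nrow = nrow(chmat))
  } else {
    if (w[1] %% 3 != 0)
      stop("codon alphabet requires length divisible by 3 (got ", w[1], ")")
    ncod <- w[1] / 3
    tmp <- vapply(seq_len(nrow(chmat)), function(r) {
      s <- chmat[r, ]
      paste0(s[seq(1, w[1], 3)], s[seq(2, w[1], 3)], s[seq(3, w[1], 3)])
    }, character(ncod))
    codMat <- if (ncod == 1L) matrix(tmp, ncol = 1L) else t(tmp)  # taxa x codons
    states <- matrix(.codonIndex(codMat), nrow = nrow(chmat))
    nStop <- sum(is.na(states) & grepl("^[ACGT]{3}$", codMat))
    if (nStop > 0)
      warning(nStop, " stop codon(s) masked as missing")
  }
  rownames(states) <- names(seqs)
  new("PhyloAlignment", taxa = names(seqs), states = states, alphabet = alphabet)
}

#' Read an alignment from FASTA or PHYLIP
#'
#' @param path file path.
#' @param format `"fasta"` (default) or `"phylip"` (sequential or
#'   interleaved, auto-detected by \pkg{ape}).
#' @param alphabet passed to [phyloAlignment()].
#' @return a [PhyloAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "phylip"),
                          alphabet = c("nucleotide", "codon")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    m <- tryCatch(
      ape::read.dna(path, format = "sequential", as.character = TRUE),
      error = function(e)
        ape::read.dna(path, format = "interleaved", as.character = TRUE))
    seqs <- setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
  }
  phyloAlignment(seqs, alphabet = alphabet)
}

#' @rdname writeAlignmentFasta
#' @details `writeAlignmentPhylip` writes sequential PHYLIP via
#'   \pkg{ape}.
#' @export
writeAlignmentPhylip <- function(x, path) {
  seqs <- alignmentStrings(x)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  ape::write.dna(m, path, format = "sequential", nbcol = -1, colsep = "")
  invisible(path)
}

#' Write a PhyloAlignment to FASTA
#'
#' Missing states are written as `N` (nucleotide) or `NNN` (codon).
#'
#' @param x a [PhyloAlignment-class].
#' @param path output file path.
#' @export
writeAlignmentFasta <- function(x, path) {
  seqs <- alignmentStrings(x)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname writeAlignmentFasta
#' @return `alignmentStrings` returns the named character vector of
#'   sequences.
#' @export
alignmentStrings <- function(x) {
  stopifnot(is(x, "PhyloAlignment"))
  if (x@alphabet == "nucleotide") {
    ch <- matrix(.ntLevels[x@states], nrow = nrow(x@states))
    ch[is.na(x@states)] <- "N"
  } else {
    ch <- matrix(.codonTable()$codons[x@states], nrow = nrow(x@states))
    ch[is.na(x@states)] <- "NNN"
  }
  setNames(apply(ch, 1, paste0, collapse = ""), x@taxa)
}

#' Ortholog-presence filter
#'
#' A locus is analyzed only if all required taxa are present (have at least
#' one non-missing site) and at least a minimum fraction of a designated
#' mammalian panel is present.
#'
#' @param alignment a [PhyloAlignment-class].
#' @param requiredTaxa taxa that must all be present (default the three
#'   primates of the seven-taxon tree).
#' @param mammalTaxa panel whose presence fraction is thresholded (default
#'   the four non-primate mammals).
#' @param minFraction minimum present fraction of `mammalTaxa` (default
#'   0.75).
#' @return logical: keep (`TRUE`) or drop (`FALSE`), with attribute
#'   `"detail"` listing presence per taxon.
#' @export
filterOrthologPresence <- function(alignment,
                                   requiredTaxa = c("Human", "Chimpanzee", "Macaque"),
                                   mammalTaxa = c("Mouse", "Rat", "Dog", "Cow"),
                                   minFraction = 0.75) {
  if (!length(mammalTaxa)) stop("empty mammal taxon set")
  present <- setNames(logical(length(union(requiredTaxa, mammalTaxa))),
                      union(requiredTaxa, mammalTaxa))
  for (tx in names(present)) {
    r <- match(tx, alignment@taxa)
    present[tx] <- !is.na(r) && any(!is.na(alignment@states[r, ]))
  }
  keep <- all(present[requiredTaxa]) &&
    mean(present[mammalTaxa]) >= minFraction
  structure(keep, detail = present)
}

# Collapse identical site patterns; returns states (taxa x npat) + weights.
.compressPatterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  ux <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[ux])))
  list(states = states[, ux, drop = FALSE], weights = w)
}

# Align alignment rows to tree tip order; absent taxa become all-missing
# rows when allowMissingTaxa, else error.
.statesForTree <- function(alignment, tipLabels, allowMissingTaxa = TRUE) {
  k <- ncol(alignment@states)
  out <- matrix(NA_integer_, nrow = length(tipLabels), ncol = k)
  rownames(out) <- tipLabels
  hit <- match(tipLabels, alignment@taxa)
  if (any(is.na(hit)) && !allowMissingTaxa)
    stop("taxa in tree absent from alignment: ",
         paste(tipLabels[is.na(hit)], collapse = ", "))
  out[!is.na(hit), ] <- alignment@states[hit[!is.na(hit)], , drop = FALSE]
  out
}
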