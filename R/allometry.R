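# Allometric log-log regression across species groups and squared-change
# parsimony reconstruction of continuous life-history characters.

#' Allometric (log-log) regression
#'
#' Ordinary least squares on log-transformed trait values, optionally per
#' species group (e.g. all mammals vs higher primates).
#'
#' @param xLog,yLog log-transformed predictor and response.
#' @param group optional factor/character of group labels; one fit per
#'   group plus the pooled fit `"all"`.
#' @return named list of fits, each with `slope`, `intercept`, `residuals`,
#'   `r2`, `n`.
#' @export
allometricFit <- function(xLog, yLog, group = NULL) {
  stopifnot(length(xLog) == length(yLog))
  fit1 <- function(x, y) {
    if (length(x) < 3) stop("need at least 3 points per fitted group")
    if (var(x) == 0) stop("zero variance in predictor")
    fm <- lm(y ~ x)
    list(slope = unname(coef(fm)[2]), intercept = unname(coef(fm)[1]),
         residuals = unname(fm$residuals),
         r2 = suppressWarnings(summary(fm)$r.squared), n = length(x))
  }
  out <- list(all = fit1(xLog, yLog))
  if (!is.null(group)) {
    for (g in unique(as.character(group))) {
      sel <- as.character(group) == g
      out[[g]] <- fit1(xLog[sel], yLog[sel])
    }
  }
  out
}

#' Squared-change parsimony ancestral reconstruction
#'
#' Assigns internal-node values minimizing the total squared change over
#' edges, cost = sum over edges of (parent - child)^2 -- unweighted by
#' default; `weighted = TRUE` divides each edge's squared change by its
#' branch length.  Solved exactly via the linear system from the
#' stationarity conditions.  A degree-2 root is collapsed (unrooted
#' interpretation), so e.g. tips (1,3,5,7) on ((A,B),(C,D)) reconstruct to
#' internal values 3 and 5 with cost 12.
#'
#' @param tree a `phylo` object.
#' @param tipValues named numeric vector covering every tip.
#' @param weighted use 1/branch-length edge weights.
#' @return an object of class `AncestralReconstruction`: list with
#'   `nodeValues` (tips then internal nodes, ape numbering of the possibly
#'   collapsed tree), `tipValues`, `cost`, `tree`.
#' @export
sqChangeParsimony <- function(tree, tipValues, weighted = FALSE) {
  miss <- setdiff(tree$tip.label, names(tipValues))
  if (length(miss)) stop("missing tip value(s): ", paste(miss, collapse = ", "))
  if (length(tree$tip.label) == 1) {
    v <- tipValues[tree$tip.label]
    return(structure(list(nodeValues = v, tipValues = v, cost = 0, tree = tree),
                     class = "AncestralReconstruction"))
  }
  tree <- .unrootIfNeeded(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  w <- if (weighted) {
    if (is.null(tree$edge.length)) stop("weighted fit needs branch lengths")
    1 / pmax(tree$edge.length, 1e-12)
  } else rep(1, nrow(tree$edge))
  L <- matrix(0, nnode, nnode)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, i] <- L[i, i] + w[e]; L[j, j] <- L[j, j] + w[e]
    L[i, j] <- L[i, j] - w[e]; L[j, i] <- L[j, i] - w[e]
  }
  tipIdx <- seq_len(ntip); intIdx <- (ntip + 1):nnode
  xT <- as.numeric(tipValues[tree$tip.label])
  xI <- solve(L[intIdx, intIdx, drop = FALSE],
              -L[intIdx, tipIdx, drop = FALSE] %*% xT)
  nodeValues <- c(xT, as.numeric(xI))
  names(nodeValues) <- c(tree$tip.label, paste0("node", intIdx))
  cost <- sum(w * (nodeValues[tree$edge[, 1]] - nodeValues[tree$edge[, 2]])^2)
  structure(list(nodeValues = nodeValues,
                 tipValues = setNames(xT, tree$tip.label),
                 cost = cost, tree = tree),
            class = "AncestralReconstruction")
}

#' @export
print.AncestralReconstruction <- function(x, ...) {
  ntip <- length(x$tipValues)
  cat("AncestralReconstruction:", ntip, "tips,",
      length(x$nodeValues) - ntip, "internal nodes, cost =",
      format(x$cost, digits = 6), "\n")
  invisible(x)
}

#' Read a species life-history trait table
#'
#' CSV columns: `species`, `group` (human / higher_primate / other_mammal),
#' `adultBrainG`, `adultBodyG`, `neonatalBrainG`, `neonatalBodyG`,
#' `gestationDays`.  Natural-log gestation-to-neonatal-trait ratios are
#' appended.
#'
#' @param path CSV path, or a data.frame with those columns.
#' @return validated data.frame with `lnGestBrain` and `lnGestBody` added.
#' @export
readTraitTable <- function(path) {
  tt <- if (is.data.frame(path)) path else read.table(path, sep = ",",
                                                      header = TRUE,
                                                      stringsAsFactors = FALSE)
  need <- c("species", "group", "adultBrainG", "adultBodyG",
            "neonatalBrainG", "neonatalBodyG", "gestationDays")
  miss <- setdiff(need, names(tt))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- need[-(1:2)]
  if (any(vapply(tt[num], function(v) any(!is.finite(v) | v <= 0), logical(1))))
    stop("weights and gestation must be positive and finite")
  tt$lnGestBrain <- log(tt$gestationDays / tt$neonatalBrainG)
  tt$lnGestBody <- log(tt$gestationDays / tt$neonatalBodyG)
  tt
}

#' Reconstructed gestation-to-neonatal-size ratio profiles
#'
#' Reconstructs the natural-log gestation/neonatal-brain and
#' gestation/neonatal-body ratios over a phylogeny by squared-change
#' parsimony and reports per-species ratios plus ratio-of-ratio fractions
#' for named species pairs (e.g. human vs gorilla).
#'
#' @param traitTable data.frame as from [readTraitTable()].
#' @param tree phylogeny whose tips are a subset of `traitTable$species`.
#' @param pairs optional 2-column matrix/data.frame of species pairs
#'   (numerator, denominator).
#' @return list with `reconstruction` (per ratio), `speciesRatios`, and
#'   `pairFractions` (raw-ratio scale, numerator/denominator).
#' @export
ratioProfiles <- function(traitTable, tree, pairs = NULL) {
  tt <- readTraitTable(traitTable)
  absent <- setdiff(tree$tip.label, tt$species)
  if (length(absent)) stop("species in tree absent from table: ",
                           paste(absent, collapse = ", "))
  rows <- match(tree$tip.label, tt$species)
  recon <- list()
  speciesRatios <- data.frame(species = tree$tip.label,
                              gestBrain = exp(tt$lnGestBrain[rows]),
                              gestBody = exp(tt$lnGestBody[rows]))
  for (ratio in c("lnGestBrain", "lnGestBody")) {
    tv <- setNames(tt[[ratio]][rows], tree$tip.label)
    recon[[ratio]] <- sqChangeParsimony(tree, tv)
  }
  pairFractions <- NULL
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    pairFractions <- data.frame(
      numerator = pairs[, 1], denominator = pairs[, 2],
      gestBrainFraction = exp(tt$lnGestBrain[match(pairs[, 1], tt$species)] -
                              tt$lnGestBrain[match(pairs[, 2], tt$species)]),
      gestBodyFraction = exp(tt$lnGestBody[match(pairs[, 1], tt$species)] -
                             tt$lnGestBody[match(pairs[, 2], tt$species)]))
  }
  list(reconstruction = recon, speciesRatios = speciesRatios,
       pairFractions = pairFractions)
}
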