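#' Read and write species trees in Newick format
#'
#' Thin validating wrappers around \pkg{ape}. Leaf labels must be unique;
#' parse failures report the offending text.
#'
#' @param text a Newick string (a terminating semicolon is added if absent).
#' @return an \pkg{ape} `phylo` object.
#' @examples
#' tr <- readNewick("((H,C),M);")
#' writeNewick(tr)
#' @export
readNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  nOpen <- lengths(regmatches(text, gregexpr("\\(", text)))
  nClose <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (nOpen != nClose)
    stop("malformed Newick: ", nOpen, " '(' vs ", nClose, " ')' in ",
         sQuote(substr(text, 1, 60)))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in ", sQuote(substr(text, 1, 60)))
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  tr
}

#' @rdname readNewick
#' @param tree a `phylo` object.
#' @export
writeNewick <- function(tree) {
  ape::write.tree(tree)
}

#' The fixed seven-taxon mammalian species tree
#'
#' Topology (((Human,Chimpanzee),Macaque),((Mouse,Rat),(Dog,Cow))) used by
#' both screens; branch lengths are always estimated, never the topology.
#'
#' @return a `phylo` object with 7 tips.
#' @export
mammalTree <- function() {
  readNewick("(((Human,Chimpanzee),Macaque),((Mouse,Rat),(Dog,Cow)));")
}

# Stable branch identifiers: each branch is named after its child clade --
# the tip label for terminal branches, otherwise the sorted tip labels of
# the subtended clade joined with "+".  Invariant under edge reordering.
branchIds <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ids <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    ids[e] <- if (ch <= ntip) tree$tip.label[ch]
              else paste(sort(desc[[ch]]), collapse = "+")
  }
  ids
}

# Postorder traversal index used by the likelihood engine.  Fitting always
# operates on the unrooted tree (reversible models make the root placement
# irrelevant); a degree-2 root is collapsed by ape::unroot upstream.
treeIndex <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(edge = tr$edge, ntip = ntip, nnode = ntip + tr$Nnode,
       root = ntip + 1L, tipLabels = tr$tip.label,
       branchIds = branchIds(tr))
}

#' Focal-lineage branch identifiers
#'
#' @param tree a `phylo` object.
#' @param tip label of the focal terminal branch (e.g. `"Human"`).
#' @param includeAncestor if `TRUE`, also include the branch leading to the
#'   focal tip's parent clade (the human--chimpanzee ancestor branch in the
#'   seven-taxon tree); the acceleration parameter is shared across both
#'   branches so the test keeps one degree of freedom.
#' @return character vector of 1 or 2 branch identifiers.
#' @export
focalBranches <- function(tree, tip, includeAncestor = FALSE) {
  ids <- branchIds(tree)
  if (!tip %in% tree$tip.label) stop("focal tip not in tree: ", tip)
  out <- tip
  if (includeAncestor) {
    ntip <- length(tree$tip.label)
    tipIdx <- match(tip, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == tipIdx, 1]
    e <- which(tree$edge[, 2] == parent)
    if (!length(e))
      stop("focal tip's parent is the root; no ancestor branch exists")
    out <- c(out, ids[e])
  }
  out
}

# Unroot if the root is degree 2 (fitting convention).
.unrootIfNeeded <- function(tree) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2) ape::unroot(tree) else tree
}
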