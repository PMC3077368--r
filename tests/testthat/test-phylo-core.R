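test_that("Newick parsing validates and round-trips", {
  tr <- readNewick("((H,C),M);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("H", "C", "M"))

  tr7 <- mammalTree()
  expect_equal(length(tr7$tip.label), 7)
  expect_setequal(tr7$tip.label, c("Human", "Chimpanzee", "Macaque",
                                   "Mouse", "Rat", "Dog", "Cow"))
  # the two deep clades
  ids <- accelscreen:::branchIds(tr7)
  expect_true("Chimpanzee+Human" %in% ids)
  expect_true("Mouse+Rat" %in% ids)

  rt <- readNewick(writeNewick(tr7))
  expect_equal(writeNewick(rt), writeNewick(tr7))

  expect_error(readNewick("((A,B),C;"), "malformed")
  expect_error(readNewick("((A,B),A);"), "duplicate")
})

test_that("alignment construction masks ambiguity and rejects bad input", {
  aln <- phyloAlignment(c(H = "ACGT", C = "ACNT"), "nucleotide")
  expect_equal(nSites(aln), 4)
  expect_true(is.na(stateMatrix(aln)["C", 3]))
  expect_false(anyNA(stateMatrix(aln)["H", ]))

  expect_error(phyloAlignment(c(A = "ACGT", B = "ACG"), "nucleotide"), "ragged")
  expect_error(phyloAlignment(c(A = "ACGT", B = "ACGT"), "codon"),
               "divisible by 3")
  # codon with an ambiguous base is masked whole; stop codons masked
  a2 <- phyloAlignment(c(A = "ATNAAA", B = "ATGAAA"), "codon")
  expect_true(is.na(stateMatrix(a2)["A", 1]))
  expect_warning(phyloAlignment(c(A = "TAAAAA"), "codon"), "stop codon")
})

test_that("FASTA I/O round-trips through the state encoding", {
  aln <- simulateCodonAlignment(theTree(), nCodons = 15, seed = 21)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeAlignmentFasta(aln, f)
  rt <- readAlignment(f, "fasta", "codon")
  expect_identical(stateMatrix(rt)[taxa(aln), ], stateMatrix(aln))
})

test_that("ortholog presence filter applies the 75% mammal rule", {
  aln <- simulateCodonAlignment(theTree(), nCodons = 10, seed = 3)
  s <- alignmentStrings(aln)
  expect_true(filterOrthologPresence(aln))

  blank <- function(x) paste(rep("N", nchar(x)), collapse = "")
  s2 <- s; s2["Cow"] <- blank(s2["Cow"])
  expect_true(filterOrthologPresence(phyloAlignment(s2, "codon")))  # 3/4 = 0.75
  s3 <- s2; s3["Dog"] <- blank(s3["Dog"])
  expect_false(filterOrthologPresence(phyloAlignment(s3, "codon")))  # 2/4
  s4 <- s; s4["Chimpanzee"] <- blank(s4["Chimpanzee"])
  expect_false(filterOrthologPresence(phyloAlignment(s4, "codon")))
  expect_error(filterOrthologPresence(aln, mammalTaxa = character()), "empty")
})

test_that("pruning likelihood matches hand limits", {
  tr <- readNewick("(A:1,B:1);")
  m <- hkyMatrix(2, rep(0.25, 4))
  same <- phyloAlignment(c(A = "A", B = "A"), "nucleotide")
  expect_equal(pruneLoglik(tr, same, m, c(A = 0, B = 0)), log(0.25))
  diff <- phyloAlignment(c(A = "A", B = "G"), "nucleotide")
  expect_equal(pruneLoglik(tr, diff, m, c(A = 60, B = 60)), 2 * log(0.25),
               tolerance = 1e-8)
  expect_error(pruneLoglik(tr, same, m, c(A = -1, B = 0)), "negative")
})

test_that("pruning equals state-enumeration oracle on random small trees", {
  topologies <- c("((A:0.1,B:0.3):0.2,C:0.4);",
                  "((A:0.2,B:0.1):0.15,(C:0.3,D:0.05):0.2);",
                  "(((A:0.1,B:0.2):0.1,C:0.3):0.2,(D:0.25,E:0.15):0.1);")
  for (rep in 1:5) {
    set.seed(100 + rep)
    for (top in topologies) {
      tr <- accelscreen:::.unrootIfNeeded(readNewick(top))
      idx <- accelscreen:::treeIndex(tr)
      fr <- as.numeric(gtools_rdirichlet <- {x <- rexp(4); x / sum(x)})
      m <- hkyMatrix(runif(1, 0.5, 5), fr)
      bl <- setNames(runif(nrow(idx$edge), 0.01, 0.8), idx$branchIds)
      nsite <- sample(2:5, 1)
      st <- matrix(sample(c(1:4, NA), idx$ntip * nsite, TRUE,
                          prob = c(rep(0.23, 4), 0.08)),
                   idx$ntip, nsite, dimnames = list(idx$tipLabels, NULL))
      if (all(is.na(st))) next
      aln <- new("PhyloAlignment", taxa = rownames(st), states = st,
                 alphabet = "nucleotide")
      expect_equal(pruneLoglik(tr, aln, m, bl),
                   bruteLnL(tr, st, m@Q, m@pi, bl), tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to row order and rerooting", {
  tr <- accelscreen:::.unrootIfNeeded(
    readNewick("((A:0.2,B:0.1):0.15,(C:0.3,D:0.05):0.2);"))
  idx <- accelscreen:::treeIndex(tr)
  m <- hkyMatrix(3, c(0.3, 0.2, 0.3, 0.2))
  bl <- setNames(numeric(5), idx$branchIds)
  bl[c("A", "B", "C", "D")] <- c(0.2, 0.1, 0.3, 0.05)
  bl[setdiff(idx$branchIds, c("A", "B", "C", "D"))] <- 0.35
  set.seed(5)
  st <- matrix(sample(1:4, 4 * 6, TRUE), 4, 6,
               dimnames = list(idx$tipLabels, NULL))
  aln <- new("PhyloAlignment", taxa = rownames(st), states = st,
             alphabet = "nucleotide")
  ll <- pruneLoglik(tr, aln, m, bl)
  # permute alignment rows
  perm <- c("C", "A", "D", "B")
  aln2 <- new("PhyloAlignment", taxa = perm,
              states = st[perm, , drop = FALSE], alphabet = "nucleotide")
  expect_equal(pruneLoglik(tr, aln2, m, bl), ll, tolerance = 1e-12)
  # pulley principle: on the rooted tree, sliding the root along its edge
  # (holding the two root-edge lengths' sum fixed) leaves lnL unchanged,
  # and both match the unrooted likelihood with the merged edge
  trR <- readNewick("((A,B),(C,D));")
  blR <- c(bl[c("A", "B", "C", "D")], "A+B" = 0.15, "C+D" = 0.20)
  blR2 <- blR; blR2["A+B"] <- 0.01; blR2["C+D"] <- 0.34
  expect_equal(pruneLoglik(trR, aln, m, blR), ll, tolerance = 1e-10)
  expect_equal(pruneLoglik(trR, aln, m, blR2), ll, tolerance = 1e-10)
})

test_that("transition matrices are stochastic across branch lengths", {
  m <- mg94Matrix(2.5, 0.3)
  for (t in c(0, 1e-5, 0.01, 0.3, 2, 20)) {
    P <- transitionMatrix(m, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
  }
})
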