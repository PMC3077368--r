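# Shared fixtures and independent oracles used across the suite.

theTree <- function() accelscreen:::.unrootIfNeeded(mammalTree())

# flat asymptotic-regime regional parameters used by calibration and
# recovery experiments (enough focal-branch information for chi-squared
# asymptotics; see the methods vignette)
calibContext <- function(dSr = 0.15, a = 0.8, kappa = 2) {
  regionalContext(theTree(), dSr = dSr, a = a, kappa = kappa)
}

calibNtContext <- function(dNC = 0.1, kappa = 2) {
  regionalContext(theTree(), dSr = dNC, kappa = kappa,
                  freqs3x4 = rep(0.25, 4))
}

# Brute-force phylogenetic likelihood by explicit summation over every
# internal-node (and missing-tip) state assignment -- independent of the
# pruning recursion.
bruteLnL <- function(tree, states, Q, pi, branchLengths) {
  idx <- accelscreen:::treeIndex(tree)
  k <- length(pi)
  bl <- branchLengths[idx$branchIds]
  P <- lapply(seq_len(nrow(idx$edge)), function(e)
    accelscreen:::.transMatCpp(Q * bl[e], pi))
  total <- 0
  for (s in seq_len(ncol(states))) {
    col <- states[, s]
    freeNodes <- c(which(is.na(col)), (idx$ntip + 1):idx$nnode)
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(freeNodes))))
    sumL <- 0
    for (g in seq_len(nrow(grid))) {
      assign_ <- numeric(idx$nnode)
      assign_[seq_len(idx$ntip)] <- col
      assign_[freeNodes] <- grid[g, ]
      pr <- pi[assign_[idx$root]]
      for (e in seq_len(nrow(idx$edge)))
        pr <- pr * P[[e]][assign_[idx$edge[e, 1]], assign_[idx$edge[e, 2]]]
      sumL <- sumL + pr
    }
    total <- total + log(sumL)
  }
  total
}

# closed-form OLS via the normal equations
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# numerically minimize the (optionally weighted) squared-change cost over
# internal values -- independent of the linear-system solution
sqChangeOracle <- function(tree, tipValues, weighted = FALSE) {
  tree <- accelscreen:::.unrootIfNeeded(tree)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  w <- if (weighted) 1 / tree$edge.length else rep(1, nrow(tree$edge))
  cost <- function(xI) {
    v <- c(as.numeric(tipValues[tree$tip.label]), xI)
    sum(w * (v[tree$edge[, 1]] - v[tree$edge[, 2]])^2)
  }
  fit <- optim(rep(mean(tipValues), nint), cost, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  list(values = fit$par, cost = fit$value)
}

# allele-count 2x2 helper for simulated genotype matrices
alleleCounts <- function(g) {
  g <- g[!is.na(g)]
  c(sum(g), 2 * length(g) - sum(g))
}
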