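test_that("allometric regression matches exact and closed-form fits", {
  x <- log(seq(2, 40, length.out = 10))
  f <- allometricFit(x, x)
  expect_equal(f$all$slope, 1)
  expect_equal(f$all$intercept, 0, tolerance = 1e-12)
  expect_equal(f$all$r2, 1)
  # y = 2 * x^0.75 on the log scale
  y <- log(2) + 0.75 * x
  f2 <- allometricFit(x, y)
  expect_equal(f2$all$slope, 0.75)
  expect_equal(f2$all$intercept, log(2))
  # noisy power law vs normal-equations oracle
  set.seed(33)
  xn <- log(runif(50, 1, 1000))
  yn <- 0.3 + 0.7 * xn + rnorm(50, 0, 0.2)
  f3 <- allometricFit(xn, yn)
  o <- olsOracle(xn, yn)
  expect_equal(f3$all$slope, o$slope, tolerance = 1e-12)
  expect_equal(f3$all$intercept, o$intercept, tolerance = 1e-12)
  # residual orthogonality
  expect_lt(abs(sum(f3$all$residuals * xn)), 1e-10)
  expect_error(allometricFit(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(allometricFit(1:2, 1:2), "at least 3")
})

test_that("squared-change parsimony solves the worked examples", {
  star <- readNewick("(A,B,C);")
  r <- sqChangeParsimony(star, c(A = 1, B = 2, C = 3))
  expect_equal(unname(r$nodeValues[4]), 2)
  expect_equal(r$cost, 2)

  tr <- readNewick("((A,B),(C,D));")
  r2 <- sqChangeParsimony(tr, c(A = 1, B = 3, C = 5, D = 7))
  internals <- sort(unname(r2$nodeValues[5:6]))
  expect_equal(internals, c(3, 5))
  expect_equal(r2$cost, 12)

  single <- ape::read.tree(text = "(A:1);")
  r3 <- sqChangeParsimony(single, c(A = 4.2))
  expect_equal(unname(r3$nodeValues["A"]), 4.2)
  expect_equal(r3$cost, 0)

  expect_error(sqChangeParsimony(tr, c(A = 1, B = 2, C = 3)), "missing tip")
})

test_that("reconstruction is linear in tip values and locally optimal", {
  tr <- readNewick("(((A,B),C),(D,(E,F)));")
  set.seed(4)
  tv <- setNames(rnorm(6), tr$tip.label)
  r <- sqChangeParsimony(tr, tv)
  r2 <- sqChangeParsimony(tr, 3 * tv + 1)
  expect_equal(unname(r2$nodeValues), unname(3 * r$nodeValues + 1),
               tolerance = 1e-10)
  # random perturbations of internal values never reduce the cost
  tru <- accelscreen:::.unrootIfNeeded(tr)
  ntip <- 6
  for (i in 1:25) {
    pert <- r$nodeValues
    j <- sample((ntip + 1):length(pert), 1)
    pert[j] <- pert[j] + rnorm(1, 0, 0.5)
    cost <- sum((pert[tru$edge[, 1]] - pert[tru$edge[, 2]])^2)
    expect_gte(cost, r$cost - 1e-12)
  }
  # agreement with an independent numerical minimizer
  o <- sqChangeOracle(tr, tv)
  expect_equal(r$cost, o$cost, tolerance = 1e-6)
})

test_that("weighted reconstruction matches Brownian-motion ML on a small tree", {
  tr <- readNewick("(((A:1,B:2):1.5,C:3):1,(D:2,E:1):2);")
  set.seed(9)
  tv <- simulateTraitsBM(tr, sigma2 = 1, rootValue = 0, seed = 12)
  r <- sqChangeParsimony(tr, tv, weighted = TRUE)
  o <- sqChangeOracle(tr, tv, weighted = TRUE)
  expect_equal(r$cost, o$cost, tolerance = 1e-6)
  tru <- accelscreen:::.unrootIfNeeded(tr)
  expect_equal(unname(r$nodeValues[(length(tv) + 1):length(r$nodeValues)]),
               o$values, tolerance = 1e-4)
})

test_that("trait tables validate and ratio profiles report pair fractions", {
  tt <- data.frame(
    species = c("X", "Y", "Z"), group = "higher_primate",
    adultBrainG = c(400, 450, 100), adultBodyG = c(5e4, 6e4, 1e4),
    neonatalBrainG = c(350, 250, 60), neonatalBodyG = c(3000, 2000, 500),
    gestationDays = c(270, 260, 160))
  tt2 <- readTraitTable(tt)
  expect_equal(tt2$lnGestBrain, log(tt2$gestationDays / tt2$neonatalBrainG))
  bad <- tt; bad$gestationDays[1] <- -1
  expect_error(readTraitTable(bad), "positive")
  expect_error(readTraitTable(tt[, -1]), "missing column")

  tr <- readNewick("((X,Y),Z);")
  rp <- ratioProfiles(tt, tr, pairs = rbind(c("X", "Y")))
  frac <- (270 / 350) / (260 / 250)
  expect_equal(rp$pairFractions$gestBrainFraction, frac, tolerance = 1e-12)
  # identical ratios across species reconstruct at zero cost
  ttEq <- tt
  ttEq$neonatalBrainG <- ttEq$gestationDays / 2
  ttEq$neonatalBodyG <- ttEq$gestationDays / 4
  rpEq <- ratioProfiles(ttEq, tr)
  expect_equal(rpEq$reconstruction$lnGestBrain$cost, 0, tolerance = 1e-20)
  expect_true(all(abs(rpEq$reconstruction$lnGestBrain$nodeValues - log(2)) < 1e-12))
  expect_error(ratioProfiles(tt, readNewick("((X,Y),W);")), "absent")
})
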