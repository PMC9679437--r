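field0 <- function(r0 = 2.5, k = 500, kr = k)
  curvatureField(center = c(0, 0, 0), r0 = r0, kAttract = k, kRepel = kr)

test_that("shell potential is harmonic in the distance from the shell", {
  fld <- field0()
  expect_equal(attractEnergy(c(2.5, 0, 0), fld), 0)
  expect_equal(attractEnergy(c(2.6, 0, 0), fld), 2.5)    # 0.5*500*0.1^2
  expect_equal(attractEnergy(c(2.4, 0, 0), fld), 2.5)    # symmetric inside
  # strictly increasing in |r - r0|
  dev <- seq(0, 1, by = 0.1)
  eOut <- attractEnergy(cbind(2.5 + dev, 0, 0), fld)
  eIn <- attractEnergy(cbind(2.5 - dev, 0, 0), fld)
  expect_true(all(diff(eOut) > 0))
  expect_true(all(diff(eIn) > 0))
})

test_that("flat-bottom term vanishes on and outside the sphere, C1 at the wall", {
  fld <- field0()
  expect_identical(flatBottomEnergy(c(3.5, 0, 0), fld), 0)
  expect_identical(flatBottomEnergy(c(2.5, 0, 0), fld), 0)
  expect_equal(flatBottomEnergy(c(2.3, 0, 0), fld), 10)  # 0.5*500*0.2^2
  expect_equal(flatBottomForce(c(3, 0, 0), fld), c(0, 0, 0))
  expect_equal(flatBottomForce(c(2.5, 0, 0), fld), c(0, 0, 0))
  # approaching the wall from inside, both energy and force go to zero
  eps <- 10^seq(-3, -7, by = -1)
  eWall <- flatBottomEnergy(cbind(2.5 - eps, 0, 0), fld)
  expect_true(all(diff(eWall) < 0) && eWall[length(eps)] < 1e-10)
  # inside, the force points radially outward with magnitude k*(r0 - r)
  f <- flatBottomForce(c(0, 2.0, 0), fld)
  expect_equal(f, c(0, 500 * 0.5, 0))
})

test_that("analytic forces match central finite differences", {
  set.seed(31)
  fld <- field0(r0 = 1.2, k = 350, kr = 420)
  pts <- matrix(rnorm(60, sd = 1.5), 20, 3)
  h <- 1e-6
  for (fn in list(c(attractEnergy, attractForce),
                  c(flatBottomEnergy, flatBottomForce))) {
    eFun <- fn[[1]]; fFun <- fn[[2]]
    num <- sapply(1:3, function(d) {
      ep <- em <- pts
      ep[, d] <- ep[, d] + h; em[, d] <- em[, d] - h
      -(eFun(ep, fld) - eFun(em, fld)) / (2 * h)
    })
    ana <- fFun(pts, fld)
    scale <- pmax(abs(ana), 1e-6)
    expect_lt(max(abs(num - ana) / scale), 1e-4)
  }
  # degenerate point: at the center the direction is undefined, force is 0
  expect_equal(attractForce(c(0, 0, 0), fld), c(0, 0, 0))
  expect_equal(flatBottomForce(c(0, 0, 0), fld), c(0, 0, 0))
})

test_that("field evaluation equals the brute-force per-atom sum", {
  set.seed(37)
  pos <- matrix(rnorm(60, sd = 2), 20, 3)
  nano <- c(2L, 5L, 9L)
  pept <- 1:20
  fld <- curvatureField(c(0.3, -0.2, 0.1), r0 = 1.5, kAttract = 500,
                        kRepel = 400, nanoIndices = nano,
                        peptideIndices = pept)
  # independent oracle: plain formulas summed atom by atom
  eOracle <- 0
  fOracle <- matrix(0, 20, 3)
  for (i in nano) {
    d <- pos[i, ] - fld@center; r <- sqrt(sum(d^2))
    eOracle <- eOracle + 0.5 * 500 * (r - 1.5)^2
    fOracle[i, ] <- fOracle[i, ] - 500 * (r - 1.5) * d / r
  }
  for (i in pept) {
    d <- pos[i, ] - fld@center; r <- sqrt(sum(d^2))
    if (r < 1.5) {
      eOracle <- eOracle + 0.5 * 400 * (r - 1.5)^2
      fOracle[i, ] <- fOracle[i, ] - 400 * (r - 1.5) * d / r
    }
  }
  got <- evaluateField(pos, fld)
  expect_equal(got$energy, eOracle, tolerance = 1e-12)
  expect_equal(got$forces, fOracle, tolerance = 1e-12)

  # empty groups: nothing happens
  off <- curvatureField(c(0, 0, 0), r0 = 1)
  expect_equal(evaluateField(pos, off)$energy, 0)
  expect_true(all(evaluateField(pos, off)$forces == 0))
  # out-of-range indices name the offending group
  bad <- curvatureField(c(0, 0, 0), r0 = 1, nanoIndices = 99L)
  expect_error(evaluateField(pos, bad), "NANO")
})

test_that("field energy is invariant under rotation about the center", {
  set.seed(41)
  fld <- curvatureField(c(1, -0.5, 2), r0 = 2, kAttract = 500,
                        nanoIndices = 1:4, peptideIndices = 1:10)
  pos <- matrix(rnorm(30, sd = 2), 10, 3)
  e0 <- evaluateField(pos, fld)$energy
  for (rep in 1:5) {
    R <- randomRotation()
    rot <- sweep(sweep(pos, 2, fld@center) %*% t(R), 2, fld@center,
                 FUN = "+")
    expect_equal(evaluateField(rot, fld)$energy, e0, tolerance = 1e-9)
  }
})

test_that("limiting cases: pure shell restraint and harmonic position restraint", {
  set.seed(43)
  pos <- matrix(rnorm(15, sd = 2), 5, 3)
  # kRepel = 0: only the shell term remains
  fld <- curvatureField(c(0, 0, 0), r0 = 1.5, kAttract = 500, kRepel = 0,
                        nanoIndices = 1:5, peptideIndices = 1:5)
  onlyShell <- curvatureField(c(0, 0, 0), r0 = 1.5, kAttract = 500,
                              nanoIndices = 1:5)
  expect_equal(evaluateField(pos, fld)$energy,
               evaluateField(pos, onlyShell)$energy)
  # r0 = 0: the shell term is an ordinary harmonic restraint to the center
  fld0 <- curvatureField(c(0, 0, 0), r0 = 0, kAttract = 500,
                         nanoIndices = 1:5)
  expect_equal(evaluateField(pos, fld0)$energy,
               sum(0.5 * 500 * rowSums(pos^2)))
})

test_that("surface displacement is signed and equivariant in r0", {
  fld <- field0()
  frame <- rbind(c(2.5, 0, 0), c(0, 0, 0), c(0, 4, 0))
  got <- surfaceDisplacement(frame, fld, group = 1:3)
  expect_equal(got, c(0, -2.5, 1.5))
  # growing r0 by delta lowers every displacement by exactly delta
  set.seed(47)
  pos <- matrix(rnorm(30, sd = 3), 10, 3)
  delta <- 0.7
  d1 <- surfaceDisplacement(pos, field0(r0 = 1.1), group = 1:10)
  d2 <- surfaceDisplacement(pos, field0(r0 = 1.1 + delta), group = 1:10)
  expect_equal(d2, d1 - delta)
  expect_error(surfaceDisplacement(pos, field0()), "NANO")
})
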