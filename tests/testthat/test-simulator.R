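test_that("the synthetic oligomer has fibril-like topology", {
  single <- buildFibrilOligomer(1, 5)
  expect_identical(nrow(single@bonds), 4L)
  expect_identical(nrow(single@contacts), 0L)

  sys <- buildFibrilOligomer(5, 7)
  expect_identical(nrow(sys@bonds), 30L)
  # independent brute-force pair scan at the 0.6 nm cutoff
  pos <- positions(sys)
  ch <- chainIds(sys)
  expected <- 0L
  for (i in 1:34) for (j in (i + 1):35)
    if (ch[i] != ch[j] &&
        sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 0.6)
      expected <- expected + 1L
  expect_identical(nrow(sys@contacts), expected)
  # contacts only between adjacent chains
  expect_true(all(abs(ch[sys@contacts$i] - ch[sys@contacts$j]) == 1L))

  ten <- buildFibrilOligomer(10, 7)
  expect_identical(length(unique(chainIds(ten))), 10L)
  expect_error(buildFibrilOligomer(0, 5), "nChains")
})

test_that("each internal term is at its minimum in the built geometry", {
  sys <- buildFibrilOligomer(4, 6)
  e <- internalForces(sys)$energy
  expect_equal(unname(e["bonded"]), 0, tolerance = 1e-20)
  expect_equal(unname(e["contacts"]), -4 * nrow(sys@contacts))
  # doubling epsilon doubles the contact energy exactly
  sys2 <- buildFibrilOligomer(4, 6, epsContact = 8)
  expect_equal(unname(internalForces(sys2)$energy["contacts"]),
               2 * unname(e["contacts"]))
})

test_that("internal forces are the negative gradient of the energy", {
  set.seed(59)
  sys <- buildFibrilOligomer(3, 4)
  pos <- positions(sys) + matrix(rnorm(36, sd = 0.03), 12, 3)
  ana <- internalForces(sys, pos)$forces
  num <- fdForces(function(p) internalForces(sys, p)$energy[["total"]], pos)
  expect_lt(max(abs(num - ana)) / max(abs(ana)), 1e-4)
  # overlapping beads are rejected
  bad <- pos; bad[2, ] <- bad[1, ]
  expect_error(internalForces(sys, bad), "overlap")
})

test_that("minimisation relaxes a stretched bond and never raises the energy", {
  sys <- buildFibrilOligomer(1, 2)
  positions(sys) <- rbind(c(0, 0, 0), c(0, 0.6, 0))   # b0 = 0.38
  out <- minimizeSystem(sys, tol = 0.5)
  rep <- attr(out, "minimization")
  expect_lt(rep$finalEnergy, rep$initialEnergy)
  expect_equal(sqrt(sum(diff(positions(out))^2)), 0.38, tolerance = 1e-3)

  relaxed <- buildFibrilOligomer(3, 4)
  out2 <- minimizeSystem(relaxed, tol = 50)
  expect_equal(positions(out2), positions(relaxed))   # already minimal
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  sys <- buildFibrilOligomer(2, 3)
  p <- simulationParams(nSteps = 200L, seed = 17L, reportInterval = 20L)
  t1 <- langevinRun(sys, NULL, p)
  t2 <- langevinRun(sys, NULL, p)
  expect_identical(t1@positions, t2@positions)
  expect_identical(t1@energies, t2@energies)
  expect_identical(t1@seed, 17L)
  expect_true(all(diff(frameTimes(t1)) > 0))
})

test_that("zero friction reduces to velocity Verlet with tiny energy drift", {
  sys <- buildFibrilOligomer(3, 4)
  p <- simulationParams(dt = 1e-4, nSteps = 10000L, temperature = 300,
                        friction = 0, seed = 3L, reportInterval = 100L)
  e <- energyDecomposition(langevinRun(sys, NULL, p))
  drift <- max(abs(e$total - e$total[1]))
  expect_lt(drift, 0.001 * e$kinetic[1])
})

test_that("cold overdamped dynamics is gradient flow into a minimum", {
  sys <- buildFibrilOligomer(2, 3)
  set.seed(61)
  positions(sys) <- positions(sys) + matrix(rnorm(18, sd = 0.05), 6, 3)
  e0 <- internalForces(sys)$energy[["total"]]
  p <- simulationParams(dt = 0.002, nSteps = 4000L, temperature = 0,
                        friction = 50, seed = 5L, reportInterval = 400L)
  traj <- langevinRun(sys, NULL, p)
  eEnd <- tail(energyDecomposition(traj)$total, 1)
  expect_lt(eEnd, e0)
  fEnd <- internalForces(sys, framePositions(traj, nFrames(traj)))$forces
  expect_lt(max(abs(fEnd)), 50)
})

test_that("replicates use independent seeds and velocities", {
  sys <- buildFibrilOligomer(2, 3)
  p <- simulationParams(nSteps = 100L, seed = 100L, reportInterval = 10L)
  trio <- runReplicates(sys, NULL, p, nReps = 3L)
  expect_length(trio, 3L)
  expect_identical(vapply(trio, function(t) t@seed, integer(1)),
                   c(101L, 102L, 103L))
  expect_false(identical(trio[[1]]@positions, trio[[2]]@positions))
  # equal seeds reproduce each other
  again <- runReplicates(sys, NULL, p, nReps = 3L)
  expect_identical(trio[[2]]@positions, again[[2]]@positions)
})

test_that("without attraction the anchors drift off the shell", {
  sys <- placeOligomer(buildFibrilOligomer(3, 4))
  box <- soluteBox(positions(sys))
  nano <- seq(1, 12, by = 4)
  fld <- curvatureField(nanoparticleCenter(box, 1.5), r0 = 1.5,
                        kAttract = 0, kRepel = 500,
                        nanoIndices = nano, peptideIndices = 1:12)
  p <- simulationParams(dt = 0.005, nSteps = 4000L, seed = 9L,
                        reportInterval = 100L)
  traj <- langevinRun(sys, fld, p)
  d0 <- mean(abs(surfaceDisplacement(framePositions(traj, 1), fld)))
  dEnd <- mean(vapply(31:40, function(i)
    mean(abs(surfaceDisplacement(framePositions(traj, i), fld))),
    numeric(1)))
  expect_gt(dEnd, d0)
})
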