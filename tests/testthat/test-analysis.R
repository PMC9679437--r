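test_that("native-contact fraction counts surviving contacts", {
  sys <- buildFibrilOligomer(5, 7)
  pos <- positions(sys)
  expect_equal(nativeContactFraction(pos, sys@contacts), 1)
  # pull chains far apart: full dissociation
  apart <- pos
  for (c_ in 1:5) apart[chainIds(sys) == c_, 1] <-
      apart[chainIds(sys) == c_, 1] + (c_ - 1) * 10
  expect_equal(nativeContactFraction(apart, sys@contacts), 0)
  # agree with a direct brute-force recount on a perturbed frame
  ct <- sys@contacts
  set.seed(67)
  frame2 <- pos + matrix(rnorm(length(pos), sd = 0.12), nrow(pos), 3)
  d <- sqrt(rowSums((frame2[ct$i, ] - frame2[ct$j, ])^2))
  expect_equal(nativeContactFraction(frame2, ct),
               mean(d <= 1.2 * ct$sigma))
  # rigid motion leaves Q unchanged
  R <- randomRotation()
  moved <- sweep(frame2 %*% t(R), 2, c(3, -2, 5), FUN = "+")
  expect_equal(nativeContactFraction(moved, ct),
               nativeContactFraction(frame2, ct))
  expect_error(nativeContactFraction(pos, ct[0, ]), "empty")
})

test_that("a frame of exactly half-broken contacts scores Q = 0.5", {
  # two chains of two beads: contacts (1,3) and (2,4); stretch one pair
  pos <- rbind(c(0, 0, 0), c(0, 0.38, 0), c(0.47, 0, 0), c(0.47, 0.38, 0))
  ct <- data.frame(i = c(1L, 2L), j = c(3L, 4L), sigma = c(0.47, 0.47))
  frame <- pos
  frame[4, 1] <- 2   # contact (2,4) now far beyond 1.2 * sigma
  expect_equal(nativeContactFraction(frame, ct), 0.5)
})

test_that("superposition RMSD removes rigid motion and is a metric", {
  set.seed(71)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(A, A), 0)
  moved <- sweep(A %*% t(randomRotation()), 2, c(1, 2, 3), FUN = "+")
  expect_lt(rmsd(moved, A), 1e-9)
  # triangle inequality on random frames
  for (rep in 1:5) {
    B <- A + matrix(rnorm(30, sd = 0.3), 10, 3)
    C <- A + matrix(rnorm(30, sd = 0.3), 10, 3)
    expect_lte(rmsd(A, C), rmsd(A, B) + rmsd(B, C) + 1e-9)
  }
  expect_error(rmsd(A[1:2, ], A[1:2, ]), "3 atoms")
  expect_error(rmsd(A[1:4, ], A), "same number")
})

test_that("RMSD matches a brute-force rotational grid search on a planar toy", {
  # planar 4-atom configuration with an in-plane displacement: the optimal
  # superposition rotation is about z, so a fine 1D angle scan is an
  # independent oracle
  ref <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  frame <- ref
  frame[1, ] <- c(1.3, 0.2, 0)
  oracle <- function(frame, ref) {
    P <- sweep(frame, 2, colMeans(frame))
    Q <- sweep(ref, 2, colMeans(ref))
    best <- Inf
    for (th in seq(-pi, pi, length.out = 720001)) {
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
      best <- min(best, sqrt(mean(rowSums((P %*% t(R) - Q)^2))))
    }
    best
  }
  expect_equal(rmsd(frame, ref), oracle(frame, ref), tolerance = 1e-4)
})

test_that("restraint fluctuations match equipartition on Gaussian samples", {
  set.seed(73)
  k <- 500; temp <- 300
  sigma <- sqrt(0.0083144621 * temp / k)
  samples <- 2.5 + rnorm(2e4, sd = sigma)
  chk <- restraintDistributionCheck(samples, k = k, temperature = temp)
  expect_false(chk$degenerate)
  expect_lt(abs(chk$ratio - 1), 0.05)
  expect_gt(chk$ksP, 0.01)
  # doubling k halves the expected variance
  chk2 <- restraintDistributionCheck(samples, k = 2 * k, temperature = temp)
  expect_equal(chk2$expectedVariance, chk$expectedVariance / 2)
  expect_error(restraintDistributionCheck(rnorm(50), k = k), "100")
  # T = 0 is degenerate and reported as such
  cold <- restraintDistributionCheck(rep(c(0, 0), 60), k = k,
                                     temperature = 0)
  expect_true(cold$degenerate)
})

test_that("replicate summaries average per frame", {
  mk <- function(q) data.frame(time = c(1, 2, 3), Q = q,
                               rmsd = c(0.1, 0.2, 0.3),
                               shellDisp = NA_real_, replicate = 1L)
  same <- summarizeReplicates(list(mk(c(1, 0.9, 0.8)), mk(c(1, 0.9, 0.8))))
  expect_equal(same$Q_sd, c(0, 0, 0))
  two <- summarizeReplicates(list(mk(c(1, 1, 1)), mk(c(0.5, 0.7, 0.9))))
  expect_equal(two$Q_mean, c(0.75, 0.85, 0.95))
  # hand-computed three-replicate example
  three <- summarizeReplicates(list(mk(c(0.9, 0.9, 0.9)),
                                    mk(c(0.6, 0.9, 0.9)),
                                    mk(c(0.3, 0.3, 0.3))))
  expect_equal(three$Q_mean, c(0.6, 0.7, 0.7))
  expect_equal(three$Q_sd, c(0.3, sd(c(0.9, 0.9, 0.3)), sd(c(0.9, 0.9, 0.3))))
  bad <- mk(c(1, 1, 1)); bad$time <- c(1, 2, 4)
  expect_error(summarizeReplicates(list(mk(c(1, 1, 1)), bad)), "grid")
})

test_that("stability reports tie the pipeline together", {
  sys <- buildFibrilOligomer(3, 4)
  box <- soluteBox(positions(sys))
  fld <- curvatureField(nanoparticleCenter(box, 1.5), r0 = 1.5,
                        kAttract = 500, nanoIndices = seq(1, 12, by = 4),
                        peptideIndices = 1:12)
  trio <- runReplicates(sys, fld,
                        simulationParams(nSteps = 200L, seed = 10L,
                                         reportInterval = 20L), nReps = 2L)
  reps <- lapply(seq_along(trio), function(i)
    stabilityReport(trio[[i]], positions(sys), sys@contacts, fld,
                    replicate = i))
  expect_true(all(vapply(reps, function(r)
    all(r$Q >= 0 & r$Q <= 1) && all(r$rmsd >= 0), logical(1))))
  summ <- summarizeReplicates(reps)
  expect_identical(attr(summ, "nReplicates"), 2L)
  expect_true(all(c("Q_mean", "Q_sd", "rmsd_mean") %in% names(summ)))
})

test_that("tighter anchoring to a highly curved shell never stabilises the stack", {
  # curvature-stress property: on a small 5mer, raising the anchor force
  # constant at fixed small r0 must not raise the mean contact fraction
  sys <- placeOligomer(buildFibrilOligomer(5, 4))
  box <- soluteBox(positions(sys))
  nano <- seq(1, 20, by = 4)
  meanQ <- vapply(c(10, 200, 1500), function(k) {
    fld <- curvatureField(nanoparticleCenter(box, 0.5), r0 = 0.5,
                          kAttract = k, kRepel = 500,
                          nanoIndices = nano, peptideIndices = 1:20)
    trio <- runReplicates(minimizeSystem(sys, fld, maxSteps = 200), fld,
                          simulationParams(dt = 0.005, nSteps = 5000L,
                                           seed = 100L,
                                           reportInterval = 50L),
                          nReps = 3L)
    qs <- vapply(trio, function(tr) {
      nf <- nFrames(tr)
      mean(vapply(seq(floor(nf / 2) + 1L, nf), function(i)
        nativeContactFraction(framePositions(tr, i), sys@contacts),
        numeric(1)))
    }, numeric(1))
    mean(qs)
  }, numeric(1))
  # non-strict ordering within sampling error
  expect_lte(meanQ[2], meanQ[1] + 0.1)
  expect_lte(meanQ[3], meanQ[2] + 0.1)
  expect_lte(meanQ[3], meanQ[1] + 0.1)
})
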