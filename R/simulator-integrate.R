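#' Langevin dynamics with the BAOAB splitting
#'
#' Integrates the bead-chain system coupled to the curvature field with the
#' BAOAB scheme (kick / drift / Ornstein-Uhlenbeck / drift / kick), which
#' has excellent configurational sampling accuracy per step for a given
#' time step.  With `friction = 0` the O step becomes the identity and the
#' scheme reduces exactly to velocity Verlet (useful for NVE energy-drift
#' checks); with `temperature = 0` and large friction the dynamics follows
#' gradient flow into a local minimum.
#'
#' The run is deterministic for a fixed `params@seed`.  Initial velocities,
#' when not supplied, are drawn from the Maxwell-Boltzmann distribution at
#' the bath temperature using the same seed.
#'
#' @param system a [BeadChainSystem-class] (minimised or otherwise
#'   physically reasonable).
#' @param field optional [CurvatureField-class]; `NULL` runs the bare
#'   oligomer.
#' @param params a [SimulationParams-class].
#' @param velocities optional n x 3 starting velocities, nm/ps.
#' @return a [Trajectory-class]: positions every
#'   `params@reportInterval` steps with per-frame energy decomposition
#'   (bonded, contacts, repulsion, curvature, kinetic, total; kJ/mol).
#' @examples
#' sys <- buildFibrilOligomer(2, 3)
#' traj <- langevinRun(sys, NULL, simulationParams(nSteps = 50, seed = 1))
#' nFrames(traj)
#' @export
langevinRun <- function(system, field = NULL, params = simulationParams(),
                        velocities = NULL) {
  stopifnot(is(system, "BeadChainSystem"), is(params, "SimulationParams"))
  validObject(params)
  n <- nAtoms(system)
  dt <- params@dt
  kT <- .kB * params@temperature
  m <- system@masses
  set.seed(params@seed)

  x <- system@positions
  v <- if (is.null(velocities)) {
    if (kT > 0) matrix(rnorm(3L * n), n, 3L) * sqrt(kT / m)
    else matrix(0, n, 3L)
  } else .asPosMatrix(velocities)

  c1 <- exp(-params@friction * dt)
  sigmaO <- sqrt(kT * (1 - c1^2) / m)  # per-bead OU noise sd

  nFramesOut <- params@nSteps %/% params@reportInterval
  if (nFramesOut < 1L)
    stop("nSteps must cover at least one reportInterval", call. = FALSE)
  frames <- array(NA_real_, dim = c(n, 3L, nFramesOut))
  times <- numeric(nFramesOut)
  eRows <- vector("list", nFramesOut)

  ef <- .totalForces(system, field, x)
  fOut <- 0L
  for (step in seq_len(params@nSteps)) {
    v <- v + (0.5 * dt) * ef$forces / m
    x <- x + (0.5 * dt) * v
    if (c1 < 1 || kT > 0)
      v <- c1 * v + sigmaO * matrix(rnorm(3L * n), n, 3L)
    x <- x + (0.5 * dt) * v
    ef <- .totalForces(system, field, x)
    v <- v + (0.5 * dt) * ef$forces / m

    if (step %% params@reportInterval == 0L) {
      if (!all(is.finite(x)) || max(abs(x)) > 1e3)
        stop(sprintf("trajectory diverged at step %d", step), call. = FALSE)
      fOut <- fOut + 1L
      frames[, , fOut] <- x
      times[fOut] <- step * dt
      ekin <- 0.5 * sum(m * rowSums(v^2))
      eRows[[fOut]] <- c(ef$energy[c("bonded", "contacts", "repulsion",
                                     "curvature")],
                         kinetic = ekin,
                         total = unname(ef$energy["total"]) + ekin)
    }
  }
  energies <- as.data.frame(do.call(rbind, eRows))
  energies <- cbind(time = times, energies)
  new("Trajectory", times = times, positions = frames,
      energies = energies, params = params, seed = params@seed)
}

#' Run replicate simulations with independent initial velocities
#'
#' Emulates the triplicate design of the oligomer-stability study:
#' replicate `i` runs with seed `baseSeed + i`, so each draws independent
#' Maxwell-Boltzmann starting velocities and an independent thermostat
#' stream.  Per-replicate seeds are recorded in the trajectories.
#'
#' @param system a [BeadChainSystem-class].
#' @param field optional [CurvatureField-class].
#' @param params a [SimulationParams-class] (its seed slot is overridden
#'   per replicate).
#' @param nReps number of replicates (default 3).
#' @param baseSeed base seed; defaults to `params@seed`.
#' @return list of [Trajectory-class] objects, one per replicate.
#' @examples
#' sys <- buildFibrilOligomer(2, 3)
#' trio <- runReplicates(sys, NULL, simulationParams(nSteps = 50), nReps = 2)
#' vapply(trio, function(t) t@seed, integer(1))
#' @export
runReplicates <- function(system, field = NULL, params = simulationParams(),
                          nReps = 3L, baseSeed = params@seed) {
  if (nReps < 1L)
    stop("nReps must be >= 1", call. = FALSE)
  lapply(seq_len(nReps), function(i) {
    p <- params
    p@seed <- as.integer(baseSeed + i)
    langevinRun(system, field, p)
  })
}
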