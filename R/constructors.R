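#' Construct a GroStructure
#'
#' @param positions n x 3 matrix (or length-3 vector) of coordinates, nm.
#' @param box rectangular box edges, nm (length 3).
#' @param atoms optional data.frame with columns `resid`, `resname`,
#'   `atomName`, `atomId`; defaults are generated if omitted.
#' @param velocities optional n x 3 matrix, nm/ps.
#' @param chains optional integer chain assignment per atom; inferred from
#'   residue-number resets when omitted.
#' @param title title line for GRO output.
#' @return a [GroStructure-class] object.
#' @examples
#' s <- groStructure(rbind(c(1, 1, 1), c(1.4, 1, 1)), box = c(4, 4, 4))
#' nAtoms(s)
#' @export
groStructure <- function(positions, box, atoms = NULL, velocities = NULL,
                         chains = NULL, title = "curvnp structure") {
  positions <- .asPosMatrix(positions)
  n <- nrow(positions)
  if (is.null(atoms))
    atoms <- data.frame(resid = seq_len(n), resname = "BEA",
                        atomName = "CA", atomId = seq_len(n),
                        stringsAsFactors = FALSE)
  if (is.null(velocities))
    velocities <- matrix(numeric(0), nrow = 0L, ncol = 3L)
  else
    velocities <- .asPosMatrix(velocities)
  if (is.null(chains))
    chains <- .chainsFromResids(atoms$resid)
  new("GroStructure", atoms = atoms, positions = positions,
      velocities = velocities, box = as.numeric(box),
      chains = as.integer(chains), title = title)
}

# A new chain starts wherever the residue number stops increasing
# (GRO files carry no chain field; oligomer chains restart numbering).
.chainsFromResids <- function(resid) {
  if (!length(resid)) return(integer(0))
  breaks <- c(FALSE, diff(resid) < 0)
  cumsum(c(TRUE, breaks[-1L]))
}

#' Construct named index groups
#'
#' @param ... named integer vectors of 1-based atom indices, or a single
#'   named list of them.
#' @return an [IndexGroups-class] object.
#' @examples
#' indexGroups(NANO = c(1L, 42L), PEPTIDE = 1:42)
#' @export
indexGroups <- function(...) {
  g <- list(...)
  if (length(g) == 1L && is.list(g[[1L]]))
    g <- g[[1L]]
  g <- lapply(g, function(v) sort(unique(as.integer(v))))
  new("IndexGroups", groups = g)
}

#' Construct a curvature field
#'
#' @param center sphere center, nm (length 3).
#' @param r0 effective nanoparticle radius, nm.
#' @param kAttract force constant of the attractive shell term,
#'   kJ nm^-2 mol^-1 (default 500, the value used for the published
#'   oligomer simulations).
#' @param kRepel force constant of the flat-bottom excluded-volume term;
#'   defaults to `kAttract` (one `k` governs both formulas).
#' @param nanoIndices 1-based indices of the anchored atoms (NANO group).
#' @param peptideIndices 1-based indices of the excluded-volume atoms
#'   (PEPTIDE group).
#' @param active logical on-switch.
#' @return a [CurvatureField-class] object.
#' @examples
#' fld <- curvatureField(center = c(5.355, 4.924, 4.4015), r0 = 2.5)
#' radius(fld)
#' @export
curvatureField <- function(center, r0, kAttract = 500, kRepel = kAttract,
                           nanoIndices = integer(0),
                           peptideIndices = integer(0), active = TRUE) {
  new("CurvatureField", center = as.numeric(center), r0 = as.numeric(r0),
      kAttract = as.numeric(kAttract), kRepel = as.numeric(kRepel),
      nanoIndices = as.integer(nanoIndices),
      peptideIndices = as.integer(peptideIndices),
      active = as.logical(active))
}

#' Construct a bead-chain system directly
#'
#' Low-level constructor for coarse-grained systems that
#' [buildFibrilOligomer()] does not cover (e.g. a single free bead under a
#' restraint).  Interaction tables default to empty.
#'
#' @param positions n x 3 matrix (or length-3 vector), nm.
#' @param masses bead masses, amu (recycled).
#' @param chains integer chain per bead; defaults to one chain.
#' @param bonds,angles,contacts interaction data.frames; see
#'   [BeadChainSystem-class].
#' @param repulsionPairs integer m x 2 matrix of soft-repulsion pairs.
#' @param sigmaRep,epsRep soft-repulsion diameter (nm) and strength
#'   (kJ/mol).
#' @return a [BeadChainSystem-class].
#' @examples
#' beadChainSystem(c(0, 0, 0))   # one free bead
#' @export
beadChainSystem <- function(positions, masses = 110, chains = NULL,
                            bonds = NULL, angles = NULL, contacts = NULL,
                            repulsionPairs = NULL, sigmaRep = 0.4,
                            epsRep = 1) {
  positions <- .asPosMatrix(positions)
  n <- nrow(positions)
  if (is.null(chains)) chains <- rep(1L, n)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0),
                        b0 = numeric(0), kb = numeric(0))
  if (is.null(angles))
    angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                         theta0 = numeric(0), ka = numeric(0))
  if (is.null(contacts))
    contacts <- data.frame(i = integer(0), j = integer(0),
                           sigma = numeric(0), eps = numeric(0))
  if (is.null(repulsionPairs))
    repulsionPairs <- matrix(integer(0), 0L, 2L)
  new("BeadChainSystem", positions = positions,
      masses = rep_len(as.numeric(masses), n), chains = as.integer(chains),
      bonds = bonds, angles = angles, contacts = contacts,
      repulsionPairs = repulsionPairs, sigmaRep = sigmaRep, epsRep = epsRep)
}

#' Construct Langevin run parameters
#'
#' @param dt time step, ps.
#' @param nSteps number of integration steps.
#' @param temperature bath temperature, K (default 300, the study
#'   temperature).
#' @param friction Langevin friction gamma, ps^-1; this is the implicit
#'   solvent of the coarse-grained model.
#' @param seed RNG seed; recorded in the resulting trajectory.
#' @param reportInterval steps between stored frames.
#' @return a [SimulationParams-class] object.
#' @examples
#' simulationParams(nSteps = 100, seed = 7)
#' @export
simulationParams <- function(dt = 0.005, nSteps = 1000L, temperature = 300,
                             friction = 1, seed = 1L, reportInterval = 10L) {
  new("SimulationParams", dt = as.numeric(dt), nSteps = as.integer(nSteps),
      temperature = as.numeric(temperature), friction = as.numeric(friction),
      seed = as.integer(seed), reportInterval = as.integer(reportInterval))
}
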