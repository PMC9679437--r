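#' Molecular structure in GROMACS GRO conventions
#'
#' Holds atom records (residue number/name, atom name/number), positions in
#' nm, optional velocities in nm/ps, a rectangular box vector and a per-atom
#' chain assignment.  Created by [readGro()], [groStructure()] or
#' [asGroStructure()].
#'
#' @slot atoms data.frame with columns `resid`, `resname`, `atomName`,
#'   `atomId` (one row per atom).
#' @slot positions numeric n x 3 matrix, nm.
#' @slot velocities numeric n x 3 matrix, nm/ps; zero rows when absent.
#' @slot box numeric length-3 vector of rectangular box edges, nm.
#' @slot chains integer chain index per atom (1-based, consecutive).
#' @slot title character title line.
#'
#' @exportClass GroStructure
setClass("GroStructure",
  representation(
    atoms      = "data.frame",
    positions  = "matrix",
    velocities = "matrix",
    box        = "numeric",
    chains     = "integer",
    title      = "character"
  )
)

setValidity("GroStructure", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L || !all(is.finite(object@positions)))
    msg <- c(msg, "positions must be a finite n x 3 matrix")
  if (nrow(object@atoms) != n)
    msg <- c(msg, "atoms table and positions disagree on atom count")
  need <- c("resid", "resname", "atomName", "atomId")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms table must have columns",
                        paste(need, collapse = ", ")))
  if (nrow(object@velocities) != 0L &&
      (nrow(object@velocities) != n || ncol(object@velocities) != 3L))
    msg <- c(msg, "velocities, when present, must be n x 3")
  if (length(object@box) != 3L || !all(is.finite(object@box)) ||
      any(object@box < 0))
    msg <- c(msg, "box must be three finite non-negative edge lengths (nm)")
  if (length(object@chains) != n)
    msg <- c(msg, "chain assignment must cover every atom")
  if (length(msg)) msg else TRUE
})

#' Named atom index groups (GROMACS NDX semantics)
#'
#' An ordered collection of named groups of 1-based atom indices, mirroring
#' the `[ NAME ]` sections of a GROMACS index file.  For the curvature model
#' the groups `NANO` (atoms attracted to the shell) and `PEPTIDE` (all
#' solute atoms, repelled from the particle interior) are the ones that
#' matter.
#'
#' @slot groups named list of sorted integer vectors (1-based indices).
#'
#' @exportClass IndexGroups
setClass("IndexGroups", representation(groups = "list"))

setValidity("IndexGroups", function(object) {
  g <- object@groups
  msg <- character()
  if (length(g)) {
    if (is.null(names(g)) || any(!nzchar(names(g))))
      msg <- c(msg, "every group must be named")
    if (anyDuplicated(names(g)))
      msg <- c(msg, "group names must be unique")
    bad <- vapply(g, function(v)
      !is.integer(v) || anyNA(v) || any(v < 1L), logical(1))
    if (any(bad))
      msg <- c(msg, paste("groups with invalid (non-integer or < 1) indices:",
                          paste(names(g)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Implicit-nanoparticle curvature field
#'
#' The virtual sphere and its two restraint terms: `kAttract` scales the
#' attractive shell potential \eqn{\frac{1}{2}k(r-r_0)^2} felt by
#' `nanoIndices`, and `kRepel` scales the flat-bottom excluded-volume term
#' felt by `peptideIndices` whenever an atom is inside the sphere.  Field
#' distances are computed in absolute coordinates: the nanoparticle is
#' exempt from periodic boundary conditions and solute coordinates are
#' assumed unwrapped.
#'
#' @slot center numeric length-3, sphere center in nm.
#' @slot r0 numeric, effective nanoparticle radius in nm.
#' @slot kAttract numeric, force constant of the shell term,
#'   kJ nm^-2 mol^-1.
#' @slot kRepel numeric, force constant of the excluded-volume term,
#'   kJ nm^-2 mol^-1.
#' @slot nanoIndices integer, 1-based indices of anchored atoms.
#' @slot peptideIndices integer, 1-based indices of excluded-volume atoms.
#' @slot active logical, off-switch mirroring `userint1`.
#'
#' @exportClass CurvatureField
setClass("CurvatureField",
  representation(
    center         = "numeric",
    r0             = "numeric",
    kAttract       = "numeric",
    kRepel         = "numeric",
    nanoIndices    = "integer",
    peptideIndices = "integer",
    active         = "logical"
  )
)

setValidity("CurvatureField", function(object) {
  msg <- character()
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    msg <- c(msg, "center must be a finite 3-vector (nm)")
  if (length(object@r0) != 1L || !is.finite(object@r0) || object@r0 < 0)
    msg <- c(msg, "r0 must be a single non-negative radius (nm)")
  if (length(object@kAttract) != 1L || object@kAttract < 0)
    msg <- c(msg, "kAttract must be a single non-negative force constant")
  if (length(object@kRepel) != 1L || object@kRepel < 0)
    msg <- c(msg, "kRepel must be a single non-negative force constant")
  if (anyNA(object@nanoIndices) || any(object@nanoIndices < 1L))
    msg <- c(msg, "nanoIndices must be 1-based positive indices")
  if (anyNA(object@peptideIndices) || any(object@peptideIndices < 1L))
    msg <- c(msg, "peptideIndices must be 1-based positive indices")
  if (length(object@active) != 1L || is.na(object@active))
    msg <- c(msg, "active must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Curvature user-parameter block of a GROMACS mdp file
#'
#' The nine user parameters that configure the curvature model in an mdp
#' file: the two index-group names (`user1-grps` = attracted anchors,
#' `user2-grps` = excluded-volume group), four integers (`userint1` is the
#' on-switch; `userint2..4` are reserved and zero) and three reals
#' (`userreal1` = radius in nm, `userreal2` = force constant in
#' kJ nm^-2 mol^-1, `userreal3` reserved).
#'
#' @slot user1Grps character, name of the attracted group.
#' @slot user2Grps character, name of the excluded-volume group.
#' @slot userints integer length-4.
#' @slot userreals numeric length-3.
#'
#' @exportClass CurvatureMdpBlock
setClass("CurvatureMdpBlock",
  representation(
    user1Grps = "character",
    user2Grps = "character",
    userints  = "integer",
    userreals = "numeric"
  )
)

setValidity("CurvatureMdpBlock", function(object) {
  msg <- character()
  if (length(object@userints) != 4L || anyNA(object@userints))
    msg <- c(msg, "userints must be four integers")
  else if (!object@userints[1L] %in% c(0L, 1L))
    msg <- c(msg, "userint1 (on switch) must be 0 or 1")
  if (length(object@userreals) != 3L || anyNA(object@userreals))
    msg <- c(msg, "userreals must be three numbers")
  else {
    if (object@userints[1L] == 1L && object@userreals[1L] < 0)
      msg <- c(msg, "userreal1 (radius, nm) must be >= 0 when active")
    if (object@userreals[2L] < 0)
      msg <- c(msg, "userreal2 (force constant) must be >= 0")
  }
  if (object@userints[1L] == 1L && !nzchar(object@user1Grps))
    msg <- c(msg, "active block requires user1-grps")
  if (length(msg)) msg else TRUE
})

#' Coarse-grained bead-chain oligomer
#'
#' A Go-type representation of a preformed fibril oligomer: one bead per
#' residue, harmonic bonds and angles along each chain, attractive 12-10
#' native contacts between chains, and a soft r^-12 repulsion between all
#' remaining bead pairs.  Built by [buildFibrilOligomer()].
#'
#' @slot positions numeric n x 3 matrix, nm.
#' @slot masses numeric bead masses, amu.
#' @slot chains integer chain index per bead.
#' @slot bonds data.frame `i`, `j`, `b0` (nm), `kb` (kJ nm^-2 mol^-1).
#' @slot angles data.frame `i`, `j`, `k`, `theta0` (rad),
#'   `ka` (kJ rad^-2 mol^-1).
#' @slot contacts data.frame `i`, `j`, `sigma` (nm), `eps` (kJ/mol);
#'   the native contacts.
#' @slot repulsionPairs integer m x 2 matrix of non-bonded, non-native
#'   pairs subject to the soft repulsion.
#' @slot sigmaRep numeric, repulsion diameter, nm.
#' @slot epsRep numeric, repulsion strength, kJ/mol.
#'
#' @exportClass BeadChainSystem
setClass("BeadChainSystem",
  representation(
    positions      = "matrix",
    masses         = "numeric",
    chains         = "integer",
    bonds          = "data.frame",
    angles         = "data.frame",
    contacts       = "data.frame",
    repulsionPairs = "matrix",
    sigmaRep       = "numeric",
    epsRep         = "numeric"
  )
)

setValidity("BeadChainSystem", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L || !all(is.finite(object@positions)))
    msg <- c(msg, "positions must be a finite n x 3 matrix")
  if (length(object@masses) != n || any(object@masses <= 0))
    msg <- c(msg, "each bead needs a positive mass")
  if (length(object@chains) != n)
    msg <- c(msg, "chain assignment must cover every bead")
  b <- object@bonds
  if (nrow(b)) {
    if (any(b$kb < 0) || any(b$b0 < 0))
      msg <- c(msg, "bond parameters must be non-negative")
    if (any(object@chains[b$i] != object@chains[b$j]))
      msg <- c(msg, "bonds must connect beads of the same chain")
  }
  if (nrow(object@angles) && any(object@angles$ka < 0))
    msg <- c(msg, "angle force constants must be non-negative")
  ct <- object@contacts
  if (nrow(ct)) {
    if (any(ct$i == ct$j))
      msg <- c(msg, "native contacts must join distinct beads")
    if (any(ct$eps < 0) || any(ct$sigma <= 0))
      msg <- c(msg, "contact parameters must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Langevin dynamics run parameters
#'
#' @slot dt numeric time step, ps.
#' @slot nSteps integer number of integration steps.
#' @slot temperature numeric bath temperature, K.
#' @slot friction numeric Langevin friction, ps^-1.
#' @slot seed integer RNG seed (recorded in the trajectory).
#' @slot reportInterval integer steps between stored frames.
#'
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    dt             = "numeric",
    nSteps         = "integer",
    temperature    = "numeric",
    friction       = "numeric",
    seed           = "integer",
    reportInterval = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (object@temperature < 0) msg <- c(msg, "temperature must be >= 0 K")
  if (object@friction < 0) msg <- c(msg, "friction must be >= 0 ps^-1")
  if (object@reportInterval < 1L) msg <- c(msg, "reportInterval must be >= 1")
  if (is.na(object@seed)) msg <- c(msg, "seed must be set")
  if (length(msg)) msg else TRUE
})

#' Time-ordered trajectory with energy decomposition
#'
#' Frames stored as an n x 3 x F array of positions (nm) at strictly
#' increasing times (ps), together with a per-frame energy decomposition
#' (bonded, contacts, repulsion, curvature, kinetic; kJ/mol) and the
#' parameters and seed that produced the run.
#'
#' @slot times numeric frame times, ps.
#' @slot positions numeric array, dim c(nAtoms, 3, nFrames).
#' @slot energies data.frame, one row per frame.
#' @slot params the [SimulationParams-class] used.
#' @slot seed integer seed actually used for this replicate.
#'
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    times     = "numeric",
    positions = "array",
    energies  = "data.frame",
    params    = "SimulationParams",
    seed      = "integer"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  f <- length(object@times)
  if (f > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "frame times must be strictly increasing")
  d <- dim(object@positions)
  if (length(d) != 3L || d[2L] != 3L || d[3L] != f)
    msg <- c(msg, "positions must be an nAtoms x 3 x nFrames array")
  if (nrow(object@energies) != f)
    msg <- c(msg, "energies must have one row per frame")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroStructure", function(object) {
  cat(sprintf(
    "GroStructure: %d atoms, %d chain(s), box %s nm%s\n  title: %s\n",
    nrow(object@positions), length(unique(object@chains)),
    paste(.fmtNum(object@box, 3L), collapse = " x "),
    if (nrow(object@velocities)) ", with velocities" else "",
    object@title))
})

setMethod("show", "IndexGroups", function(object) {
  cat(sprintf("IndexGroups: %d group(s)\n", length(object@groups)))
  for (nm in names(object@groups))
    cat(sprintf("  [ %s ]  %d atoms\n", nm, length(object@groups[[nm]])))
})

setMethod("show", "CurvatureField", function(object) {
  cat(sprintf(
    paste0("CurvatureField (%s): r0 = %s nm, center = (%s) nm\n",
           "  kAttract = %s, kRepel = %s kJ nm^-2 mol^-1\n",
           "  NANO: %d atom(s), PEPTIDE: %d atom(s)\n"),
    if (object@active) "active" else "inactive",
    .fmtNum(object@r0), paste(.fmtNum(object@center), collapse = ", "),
    .fmtNum(object@kAttract), .fmtNum(object@kRepel),
    length(object@nanoIndices), length(object@peptideIndices)))
})

setMethod("show", "CurvatureMdpBlock", function(object) {
  cat(paste(emitMdpBlock(object), collapse = "\n"), "\n")
})

setMethod("show", "BeadChainSystem", function(object) {
  cat(sprintf(
    paste0("BeadChainSystem: %d beads in %d chain(s)\n",
           "  %d bonds, %d angles, %d native contacts, %d repulsion pairs\n"),
    nrow(object@positions), length(unique(object@chains)),
    nrow(object@bonds), nrow(object@angles), nrow(object@contacts),
    nrow(object@repulsionPairs)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d frames x %d atoms, t = %s..%s ps (seed %d)\n",
    length(object@times), dim(object@positions)[1L],
    .fmtNum(min(object@times)), .fmtNum(max(object@times)), object@seed))
})
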