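#' Internal (bonded plus non-bonded) energies and forces
#'
#' Evaluates the Go-type force field of a bead-chain oligomer: harmonic
#' bonds \eqn{\frac{1}{2} k_b (b - b_0)^2}, harmonic angles
#' \eqn{\frac{1}{2} k_a (\theta - \theta_0)^2}, 12-10 native contacts
#' \eqn{\epsilon [5 (\sigma/r)^{12} - 6 (\sigma/r)^{10}]} (minimum
#' \eqn{-\epsilon} at \eqn{r = \sigma}) and a soft
#' \eqn{\epsilon_{rep} (\sigma_{rep}/r)^{12}} repulsion between the
#' remaining pairs.  Forces are the analytic negative gradient.
#'
#' @param system a [BeadChainSystem-class].
#' @param positions optional n x 3 matrix overriding the system's stored
#'   coordinates, nm.
#' @return list with `energy` (named: bonded, contacts, repulsion, total;
#'   kJ/mol) and `forces` (n x 3, kJ mol^-1 nm^-1).
#' @examples
#' sys <- buildFibrilOligomer(2, 3)
#' internalForces(sys)$energy
#' @export
internalForces <- function(system, positions = NULL) {
  stopifnot(is(system, "BeadChainSystem"))
  pos <- if (is.null(positions)) system@positions else .asPosMatrix(positions)
  n <- nrow(pos)
  F <- matrix(0, n, 3L)
  eBond <- eAngle <- eContact <- eRep <- 0

  pairTerm <- function(i, j) {
    d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-6))
      stop("overlapping beads (r < 1e-6 nm); bad configuration",
           call. = FALSE)
    list(d = d, r = r)
  }

  b <- system@bonds
  if (nrow(b)) {
    pt <- pairTerm(b$i, b$j)
    dev <- pt$r - b$b0
    eBond <- eBond + sum(0.5 * b$kb * dev^2)
    fi <- (-b$kb * dev / pt$r) * pt$d
    F <- .addForce(F, b$i, fi)
    F <- .addForce(F, b$j, -fi)
  }

  a <- system@angles
  if (nrow(a)) {
    u <- pos[a$i, , drop = FALSE] - pos[a$j, , drop = FALSE]
    v <- pos[a$k, , drop = FALSE] - pos[a$j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    sth <- sqrt(pmax(0, 1 - cth^2))
    eAngle <- eAngle + sum(0.5 * a$ka * (th - a$theta0)^2)
    # dE/dcos(theta); the sth -> 0 guard takes the theta0 = pi limit, the
    # only near-linear geometry the builder produces
    dEdc <- ifelse(sth > 1e-8, -a$ka * (th - a$theta0) / sth, a$ka)
    dcdu <- v / (nu * nv) - cth / nu^2 * u
    dcdv <- u / (nu * nv) - cth / nv^2 * v
    fi <- -dEdc * dcdu
    fk <- -dEdc * dcdv
    F <- .addForce(F, a$i, fi)
    F <- .addForce(F, a$k, fk)
    F <- .addForce(F, a$j, -(fi + fk))
  }

  ct <- system@contacts
  if (nrow(ct)) {
    pt <- pairTerm(ct$i, ct$j)
    sr2 <- (ct$sigma / pt$r)^2
    sr10 <- sr2^5
    sr12 <- sr10 * sr2
    eContact <- eContact + sum(ct$eps * (5 * sr12 - 6 * sr10))
    dEdr <- (60 * ct$eps / pt$r) * (sr10 - sr12)
    fi <- (-dEdr / pt$r) * pt$d
    F <- .addForce(F, ct$i, fi)
    F <- .addForce(F, ct$j, -fi)
  }

  rp <- system@repulsionPairs
  if (nrow(rp)) {
    pt <- pairTerm(rp[, 1L], rp[, 2L])
    sr12 <- (system@sigmaRep / pt$r)^12
    eRep <- eRep + sum(system@epsRep * sr12)
    dEdr <- -12 * system@epsRep * sr12 / pt$r
    fi <- (-dEdr / pt$r) * pt$d
    F <- .addForce(F, rp[, 1L], fi)
    F <- .addForce(F, rp[, 2L], -fi)
  }

  energy <- c(bonded = eBond + eAngle, contacts = eContact,
              repulsion = eRep,
              total = eBond + eAngle + eContact + eRep)
  if (!all(is.finite(energy)))
    stop("non-finite internal energy", call. = FALSE)
  list(energy = energy, forces = F)
}

# Internal + curvature field, the total force used by minimisation and
# dynamics.  Returns energy decomposition incl. the curvature term.
.totalForces <- function(system, field, positions = NULL) {
  intf <- internalForces(system, positions)
  pos <- if (is.null(positions)) system@positions else positions
  if (!is.null(field)) {
    fld <- evaluateField(pos, field)
    list(energy = c(intf$energy["bonded"], intf$energy["contacts"],
                    intf$energy["repulsion"],
                    curvature = unname(fld$energy),
                    total = unname(intf$energy["total"]) + fld$energy),
         forces = intf$forces + fld$forces)
  } else {
    list(energy = c(intf$energy["bonded"], intf$energy["contacts"],
                    intf$energy["repulsion"], curvature = 0,
                    total = unname(intf$energy["total"])),
         forces = intf$forces)
  }
}

#' Steepest-descent energy minimisation
#'
#' Relaxes a bead-chain system (optionally under a curvature field) by
#' steepest descent with a backtracking step: the maximum atomic
#' displacement per step starts at `initialStep` and grows 20% after an
#' accepted move or halves after a rejected one.  Terminates when the
#' largest force component drops below `tol` or after `maxSteps` moves.
#' The energy sequence is non-increasing by construction.
#'
#' @param system a [BeadChainSystem-class].
#' @param field optional [CurvatureField-class].
#' @param maxSteps maximum accepted/rejected moves.
#' @param tol force tolerance, kJ mol^-1 nm^-1.
#' @param initialStep initial maximum displacement, nm.
#' @return the system with relaxed coordinates; attribute `"minimization"`
#'   carries `initialEnergy`, `finalEnergy`, `maxForce` and `steps`.
#' @examples
#' sys <- buildFibrilOligomer(2, 3)
#' positions(sys)[1, 1] <- -0.2   # stretch a bond
#' relaxed <- minimizeSystem(sys, tol = 1)
#' attr(relaxed, "minimization")$finalEnergy
#' @export
minimizeSystem <- function(system, field = NULL, maxSteps = 2000L,
                           tol = 10, initialStep = 0.01) {
  stopifnot(is(system, "BeadChainSystem"))
  pos <- system@positions
  ef <- .totalForces(system, field, pos)
  e0 <- unname(ef$energy["total"])
  if (!is.finite(e0))
    stop("non-finite energy at step 0", call. = FALSE)
  h <- initialStep
  steps <- 0L
  while (steps < maxSteps) {
    fmax <- max(abs(ef$forces))
    if (fmax < tol) break
    trial <- pos + (h / fmax) * ef$forces
    efTrial <- tryCatch(.totalForces(system, field, trial),
                        error = function(e) NULL)
    steps <- steps + 1L
    if (!is.null(efTrial) && is.finite(efTrial$energy["total"]) &&
        efTrial$energy["total"] < ef$energy["total"]) {
      pos <- trial
      ef <- efTrial
      h <- h * 1.2
    } else {
      h <- h / 2
      if (h < 1e-10) break
    }
  }
  system@positions <- pos
  attr(system, "minimization") <- list(
    initialEnergy = e0,
    finalEnergy = unname(ef$energy["total"]),
    maxForce = max(abs(ef$forces)),
    steps = steps)
  system
}
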