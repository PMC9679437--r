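#' Restraint energies and forces of the implicit nanoparticle
#'
#' Two terms make up the curvature field.  `attractEnergy()` is the
#' attractive spherical harmonic (shell) potential
#' \eqn{E = \frac{1}{2} k_a (|d| - r_0)^2} with \eqn{d} the displacement of
#' an atom from the sphere center: it penalises any deviation of the
#' distance-from-center from the shell radius, on either side.
#' `flatBottomEnergy()` is the excluded-volume term: the same harmonic,
#' applied only inside the sphere (\eqn{|d| < r_0}) and exactly zero
#' outside, so the surface feels soft from within and invisible from
#' without.  `attractForce()` / `flatBottomForce()` are the analytic
#' negative gradients; at the sphere center the force direction is
#' undefined and both return the zero vector.
#'
#' All inputs are in nm and kJ; forces come back in kJ mol^-1 nm^-1.  The
#' `pos` argument may be one point (length 3) or an n x 3 matrix, in which
#' case a vector of energies (or a matrix of forces) is returned.
#'
#' @param pos atom position(s), nm.
#' @param field a [CurvatureField-class].
#' @return energy in kJ/mol (`attractEnergy`, `flatBottomEnergy`) or
#'   force vectors (`attractForce`, `flatBottomForce`).
#' @examples
#' fld <- curvatureField(center = c(0, 0, 0), r0 = 2.5, kAttract = 500)
#' attractEnergy(c(2.6, 0, 0), fld)     # 0.5 * 500 * 0.1^2 = 2.5
#' flatBottomEnergy(c(3.5, 0, 0), fld)  # outside: 0
#' @name curvature-potentials
NULL

.shellDisp <- function(pos, field) {
  pos <- .asPosMatrix(pos)
  d <- sweep(pos, 2L, field@center)
  r <- sqrt(rowSums(d^2))
  list(d = d, r = r, s = r - field@r0)
}

#' @rdname curvature-potentials
#' @export
attractEnergy <- function(pos, field) {
  sd <- .shellDisp(pos, field)
  e <- 0.5 * field@kAttract * sd$s^2
  if (length(e) == 1L) e[[1L]] else e
}

#' @rdname curvature-potentials
#' @export
attractForce <- function(pos, field) {
  sd <- .shellDisp(pos, field)
  coef <- ifelse(sd$r > 0, -field@kAttract * sd$s / sd$r, 0)
  f <- coef * sd$d
  if (nrow(f) == 1L) as.numeric(f) else f
}

#' @rdname curvature-potentials
#' @export
flatBottomEnergy <- function(pos, field) {
  sd <- .shellDisp(pos, field)
  e <- ifelse(sd$s < 0, 0.5 * field@kRepel * sd$s^2, 0)
  if (length(e) == 1L) e[[1L]] else e
}

#' @rdname curvature-potentials
#' @export
flatBottomForce <- function(pos, field) {
  sd <- .shellDisp(pos, field)
  coef <- ifelse(sd$s < 0 & sd$r > 0, -field@kRepel * sd$s / sd$r, 0)
  f <- coef * sd$d
  if (nrow(f) == 1L) as.numeric(f) else f
}

#' Evaluate the curvature field over a full configuration
#'
#' Sums the attractive shell term over the NANO group and the flat-bottom
#' excluded-volume term over the PEPTIDE group, accumulating forces per
#' atom.  An atom listed in both groups receives both contributions; atoms
#' in neither group feel nothing.  An inactive field contributes zero
#' energy and forces.
#'
#' @param positions n x 3 matrix of all atom positions, nm.
#' @param field a [CurvatureField-class] whose index sets refer to rows of
#'   `positions`.
#' @return list with `energy` (kJ/mol) and `forces` (n x 3,
#'   kJ mol^-1 nm^-1).
#' @examples
#' fld <- curvatureField(c(0, 0, 0), r0 = 1, nanoIndices = 1L,
#'                       peptideIndices = 1:2)
#' evaluateField(rbind(c(1, 0, 0), c(0.5, 0, 0)), fld)
#' @export
evaluateField <- function(positions, field) {
  positions <- .asPosMatrix(positions)
  n <- nrow(positions)
  F <- matrix(0, n, 3L)
  if (!field@active)
    return(list(energy = 0, forces = F))
  for (grp in list(list(name = "NANO", idx = field@nanoIndices),
                   list(name = "PEPTIDE", idx = field@peptideIndices)))
    if (length(grp$idx) && (min(grp$idx) < 1L || max(grp$idx) > n))
      stop(sprintf("index group %s refers to atoms outside 1..%d",
                   grp$name, n), call. = FALSE)
  energy <- 0
  ni <- field@nanoIndices
  if (length(ni)) {
    energy <- energy + sum(attractEnergy(positions[ni, , drop = FALSE],
                                         field))
    fn <- attractForce(positions[ni, , drop = FALSE], field)
    F <- .addForce(F, ni, .asPosMatrix(fn))
  }
  pj <- field@peptideIndices
  if (length(pj)) {
    energy <- energy + sum(flatBottomEnergy(positions[pj, , drop = FALSE],
                                            field))
    fp <- flatBottomForce(positions[pj, , drop = FALSE], field)
    F <- .addForce(F, pj, .asPosMatrix(fp))
  }
  list(energy = energy, forces = F)
}

#' Signed distance from the nanoparticle surface
#'
#' For each selected atom returns \eqn{|pos - center| - r_0}: zero on the
#' shell, negative inside the sphere, positive outside.
#'
#' @param frame n x 3 matrix of positions, nm.
#' @param field a [CurvatureField-class].
#' @param group 1-based atom indices; defaults to the field's NANO group.
#' @return numeric vector of signed displacements, nm.
#' @examples
#' fld <- curvatureField(c(0, 0, 0), r0 = 2.5)
#' surfaceDisplacement(rbind(c(2.5, 0, 0), c(0, 0, 0)), fld, group = 1:2)
#' @export
surfaceDisplacement <- function(frame, field, group = NULL) {
  frame <- .asPosMatrix(frame)
  if (is.null(group)) group <- field@nanoIndices
  if (!length(group))
    stop("no atoms selected: give 'group' or a field with NANO indices",
         call. = FALSE)
  if (min(group) < 1L || max(group) > nrow(frame))
    stop("group indices outside the frame", call. = FALSE)
  .shellDisp(frame[group, , drop = FALSE], field)$s
}
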