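#' Convert a nominal nanoparticle size to the model radius
#'
#' Nanoparticle systems are customarily labelled by diameter ("5nm",
#' "20nm"), while the restraint potentials are parameterised by the
#' effective radius `r0`: the 5 nm case runs with `r0 = 2.5` nm and the
#' 20 nm case with `r0 = 10` nm.  This helper applies that convention.
#'
#' @param nominalSizeNm nominal (diameter) size in nm; non-negative.
#' @return the model radius `r0` in nm, `nominalSizeNm / 2`.
#' @examples
#' nominalToRadius(5)   # 2.5
#' nominalToRadius(20)  # 10
#' @export
nominalToRadius <- function(nominalSizeNm) {
  if (!is.numeric(nominalSizeNm) || anyNA(nominalSizeNm))
    stop("nominal size must be numeric", call. = FALSE)
  if (any(nominalSizeNm < 0))
    stop("nominal size must be >= 0 nm", call. = FALSE)
  nominalSizeNm / 2
}

#' Nanoparticle center for a given box and radius
#'
#' The sphere surface is placed at the box center: the center sits at
#' `(Lx/2 - r0, Ly/2, Lz/2)`, so that the shell passes through the
#' geometric box center where the oligomer's anchor atom is positioned.
#' Consequently the x-coordinate is linear in `r0`; growing the particle
#' slides its center down the x axis while the adsorption point stays put.
#'
#' @param box rectangular box edge lengths `(Lx, Ly, Lz)` in nm, all > 0.
#' @param r0 nanoparticle radius in nm, >= 0.
#' @return numeric length-3 center in nm.
#' @examples
#' nanoparticleCenter(c(15.71, 9.848, 8.803), 2.5)
#' @export
nanoparticleCenter <- function(box, r0) {
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths (nm)", call. = FALSE)
  .assertScalarNum(r0, "r0", min = 0)
  c(box[1L] / 2 - r0, box[2L] / 2, box[3L] / 2)
}

#' Size a rectangular box around a solute
#'
#' Returns the axis-aligned box whose faces, once the solute is centered in
#' it, are at least `margin` away from every solute atom: each edge is the
#' solute extent along that axis plus twice the margin.  The default 2 nm
#' margin keeps the solute from interacting with its periodic images.
#'
#' @param positions n x 3 matrix (or length-3 vector) of solute
#'   coordinates, nm.
#' @param margin clearance between solute and each box face, nm.
#' @return numeric length-3 box edges, nm.
#' @examples
#' soluteBox(rbind(c(0, 0, 0), c(3, 0, 0)))  # 7 4 4
#' @export
soluteBox <- function(positions, margin = 2) {
  positions <- .asPosMatrix(positions)
  if (nrow(positions) < 1L)
    stop("need at least one solute position", call. = FALSE)
  .assertScalarNum(margin, "margin", min = 0)
  extent <- apply(positions, 2L, function(v) diff(range(v)))
  as.numeric(extent + 2 * margin)
}

# Minimal rotation carrying unit vector a onto unit vector b (Rodrigues).
.rotationOnto <- function(a, b) {
  w <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  s2 <- sum(w^2)
  cth <- sum(a * b)
  if (s2 < 1e-24) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- p - sum(p * a) * a
    u <- u / sqrt(sum(u^2))
    return(2 * tcrossprod(u) - diag(3))
  }
  W <- matrix(c(0, w[3L], -w[2L], -w[3L], 0, w[1L], w[2L], -w[1L], 0),
              nrow = 3L)
  diag(3) + W + W %*% W * ((1 - cth) / s2)
}

# Stacking axis = first principal component of the anchor positions, with a
# deterministic sign (x >= 0, ties broken on y then z) so the alignment is
# idempotent.  Degenerate anchor sets fall back to the current x axis.
.stackingAxis <- function(anchors) {
  if (nrow(anchors) < 2L) return(c(1, 0, 0))
  centered <- sweep(anchors, 2L, colMeans(anchors))
  if (max(abs(centered)) < 1e-12) return(c(1, 0, 0))
  pc <- prcomp(anchors, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) > 1L && pc$sdev[1L] - pc$sdev[2L] < 1e-12)
    return(c(1, 0, 0))
  ax <- pc$rotation[, 1L]
  flip <- sign(ax[1L])
  if (flip == 0) flip <- sign(ax[2L])
  if (flip == 0) flip <- sign(ax[3L])
  if (flip == 0) flip <- 1
  ax * flip
}

# Anchor atom per chain: first bead, or first heavy atom when atom names
# are available (hydrogens start with H).
.chainAnchors <- function(chains, atomNames = NULL, selector = NULL) {
  ids <- unique(chains)
  vapply(ids, function(cid) {
    idx <- which(chains == cid)
    if (!is.null(selector)) {
      hit <- selector(idx)
      if (length(hit) < 1L)
        stop(sprintf("anchor selector matched no atom in chain %s", cid),
             call. = FALSE)
      return(as.integer(hit[1L]))
    }
    if (!is.null(atomNames)) {
      heavy <- idx[!startsWith(atomNames[idx], "H")]
      if (length(heavy)) return(heavy[1L])
    }
    idx[1L]
  }, integer(1))
}

.placeCoordinates <- function(pos, chains, box, centralChain = NULL,
                              atomNames = NULL, anchorSelector = NULL) {
  ids <- unique(chains)
  if (length(ids) < 1L)
    stop("structure has no chains", call. = FALSE)
  if (is.null(centralChain))
    centralChain <- ids[ceiling(length(ids) / 2)]
  if (!centralChain %in% ids)
    stop(sprintf("unknown chain '%s'", centralChain), call. = FALSE)
  anchorIdx <- .chainAnchors(chains, atomNames, anchorSelector)
  anchors <- pos[anchorIdx, , drop = FALSE]
  axis <- .stackingAxis(anchors)
  R <- .rotationOnto(axis, c(1, 0, 0))
  pivot <- colMeans(anchors)
  rotated <- sweep(pos, 2L, pivot) %*% t(R)
  rotated <- sweep(rotated, 2L, pivot, FUN = "+")
  # box sized after rotation so repeated placement is a fixed point
  if (is.null(box)) box <- soluteBox(rotated)
  central <- rotated[anchorIdx[match(centralChain, ids)], ]
  shift <- as.numeric(box) / 2 - central
  list(positions = sweep(rotated, 2L, shift, FUN = "+"),
       box = as.numeric(box))
}

#' @describeIn placeOligomer place a GRO structure inside its own box
#'   (or `box` if given); anchors default to the first heavy atom of each
#'   chain, overridable with `anchorSelector`, a function mapping a chain's
#'   atom indices to the chosen anchor index.
#' @param box box edges, nm; defaults to the structure's box.
#' @param centralChain chain id of the central monomer; defaults to chain
#'   `ceiling(n/2)` of `n` chains.
#' @param anchorSelector optional function(chain atom indices) -> anchor
#'   atom index.
#' @export
setMethod("placeOligomer", "GroStructure",
  function(x, box = NULL, centralChain = NULL, anchorSelector = NULL) {
    if (is.null(box)) box <- x@box
    if (any(box <= 0))
      stop("need a positive box to center in", call. = FALSE)
    placed <- .placeCoordinates(x@positions, x@chains, box, centralChain,
                                x@atoms$atomName, anchorSelector)
    x@positions <- placed$positions
    x@box <- placed$box
    validObject(x)
    x
  })

#' @describeIn placeOligomer place a bead-chain oligomer; `box` defaults to
#'   [soluteBox()] of the aligned coordinates, and anchors are the first
#'   bead of each chain.
#' @export
setMethod("placeOligomer", "BeadChainSystem",
  function(x, box = NULL, centralChain = NULL, anchorSelector = NULL) {
    placed <- .placeCoordinates(x@positions, x@chains, box, centralChain,
                                NULL, anchorSelector)
    x@positions <- placed$positions
    validObject(x)
    x
  })
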