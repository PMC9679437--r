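#' @name curvnp-accessors
#' @title Accessors for curvnp objects
#'
#' @description Small read-only accessors: `nAtoms()` counts atoms/beads,
#' `positions()` returns the n x 3 coordinate matrix in nm (and
#' `positions<-` replaces it), `boxVector()` the rectangular box edges,
#' `chainIds()` the per-atom chain assignment, `radius()` / `forceConstant()`
#' / `isActive()` / `fieldCenter()` the curvature parameters, `nFrames()` /
#' `frameTimes()` / `framePositions()` / `energyDecomposition()` the
#' trajectory contents, and `groupNames()` the index-group names.
#'
#' @param x a curvnp object.
#' @param value replacement value.
#' @param i frame index (for `framePositions`).
#' @return the requested component.
#' @examples
#' sys <- buildFibrilOligomer(2, 3)
#' nAtoms(sys)
#' head(positions(sys))
NULL

#' @rdname curvnp-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname curvnp-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname curvnp-accessors
#' @export
setGeneric("positions<-", function(x, value) standardGeneric("positions<-"))

#' @rdname curvnp-accessors
#' @export
setGeneric("boxVector", function(x) standardGeneric("boxVector"))

#' @rdname curvnp-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname curvnp-accessors
#' @export
setGeneric("radius", function(x) standardGeneric("radius"))

#' @rdname curvnp-accessors
#' @export
setGeneric("forceConstant", function(x) standardGeneric("forceConstant"))

#' @rdname curvnp-accessors
#' @export
setGeneric("isActive", function(x) standardGeneric("isActive"))

#' @rdname curvnp-accessors
#' @export
setGeneric("fieldCenter", function(x) standardGeneric("fieldCenter"))

#' @rdname curvnp-accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname curvnp-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname curvnp-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname curvnp-accessors
#' @export
setGeneric("framePositions", function(x, i) standardGeneric("framePositions"))

#' @rdname curvnp-accessors
#' @export
setGeneric("energyDecomposition",
           function(x) standardGeneric("energyDecomposition"))

#' Center an oligomer in a box and align its stacking axis with x
#'
#' Applies the placement convention for curved-surface simulations: the
#' oligomer's stacking axis (the first principal axis of the per-chain
#' anchor positions) is rotated parallel to the x axis, and the anchor atom
#' of the central monomer is translated to the geometric box center.  The
#' motion is rigid, so all internal geometry is preserved.
#'
#' @param x a [GroStructure-class] or [BeadChainSystem-class].
#' @param ... passed to methods; see [placeOligomer,GroStructure-method].
#' @return an object of the same class with transformed coordinates.
#' @export
setGeneric("placeOligomer", function(x, ...) standardGeneric("placeOligomer"))

#' Check the shell-restraint fluctuations against equipartition
#'
#' At temperature T a harmonic shell restraint of force constant k should
#' show displacement fluctuations of variance kB*T/k at stationarity.  This
#' compares the empirical variance of the anchor shell displacements with
#' that closed form and reports the ratio plus a Kolmogorov-Smirnov
#' goodness-of-fit statistic against the implied Gaussian.
#'
#' @param x a [Trajectory-class], or a numeric vector of displacement
#'   samples (nm).
#' @param ... passed to methods; see
#'   [restraintDistributionCheck,numeric-method].
#' @return a list of class `"restraintCheck"`; see the numeric method.
#' @export
setGeneric("restraintDistributionCheck",
           function(x, ...) standardGeneric("restraintDistributionCheck"))
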