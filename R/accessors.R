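#' @rdname curvnp-accessors
setMethod("nAtoms", "GroStructure", function(x) nrow(x@positions))

#' @rdname curvnp-accessors
setMethod("nAtoms", "BeadChainSystem", function(x) nrow(x@positions))

#' @rdname curvnp-accessors
setMethod("positions", "GroStructure", function(x) x@positions)

#' @rdname curvnp-accessors
setMethod("positions", "BeadChainSystem", function(x) x@positions)

#' @rdname curvnp-accessors
setMethod("positions<-", "GroStructure", function(x, value) {
  x@positions <- .asPosMatrix(value)
  validObject(x)
  x
})

#' @rdname curvnp-accessors
setMethod("positions<-", "BeadChainSystem", function(x, value) {
  x@positions <- .asPosMatrix(value)
  validObject(x)
  x
})

#' @rdname curvnp-accessors
setMethod("boxVector", "GroStructure", function(x) x@box)

#' @rdname curvnp-accessors
setMethod("chainIds", "GroStructure", function(x) x@chains)

#' @rdname curvnp-accessors
setMethod("chainIds", "BeadChainSystem", function(x) x@chains)

#' @rdname curvnp-accessors
setMethod("radius", "CurvatureField", function(x) x@r0)

#' @rdname curvnp-accessors
setMethod("radius", "CurvatureMdpBlock", function(x) x@userreals[1L])

#' @rdname curvnp-accessors
setMethod("forceConstant", "CurvatureField", function(x) x@kAttract)

#' @rdname curvnp-accessors
setMethod("forceConstant", "CurvatureMdpBlock", function(x) x@userreals[2L])

#' @rdname curvnp-accessors
setMethod("isActive", "CurvatureField", function(x) x@active)

#' @rdname curvnp-accessors
setMethod("isActive", "CurvatureMdpBlock", function(x) x@userints[1L] == 1L)

#' @rdname curvnp-accessors
setMethod("fieldCenter", "CurvatureField", function(x) x@center)

#' @rdname curvnp-accessors
setMethod("groupNames", "IndexGroups", function(x) names(x@groups))

#' @rdname curvnp-accessors
setMethod("groupNames", "CurvatureMdpBlock",
          function(x) c(x@user1Grps, x@user2Grps))

#' @rdname curvnp-accessors
setMethod("nFrames", "Trajectory", function(x) length(x@times))

#' @rdname curvnp-accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname curvnp-accessors
setMethod("framePositions", "Trajectory", function(x, i) {
  if (i < 1L || i > length(x@times))
    stop("frame index out of range", call. = FALSE)
  x@positions[, , i, drop = TRUE]
})

#' @rdname curvnp-accessors
setMethod("energyDecomposition", "Trajectory", function(x) x@energies)

#' Extract an index group by name
#'
#' @param x an [IndexGroups-class] object.
#' @param i group name or position.
#' @return integer vector of 1-based atom indices.
#' @export
setMethod("[[", "IndexGroups", function(x, i) {
  if (is.character(i) && !i %in% names(x@groups))
    stop(sprintf("no index group named '%s'", i), call. = FALSE)
  x@groups[[i]]
})

#' @describeIn IndexGroups-class number of groups.
#' @param x an `IndexGroups` object.
#' @export
setMethod("length", "IndexGroups", function(x) length(x@groups))
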