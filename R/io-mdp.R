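#' Emit the curvature user-parameter block as mdp lines
#'
#' Renders the nine user parameters that switch on and configure the
#' curvature model in a GROMACS mdp file: the attracted group
#' (`user1-grps`), the excluded-volume group (`user2-grps`), the on-switch
#' `userint1`, the reserved `userint2..4`, the radius `userreal1` (nm), the
#' force constant `userreal2` (kJ nm^-2 mol^-1) and the reserved
#' `userreal3`.
#'
#' @param x a [CurvatureField-class] or a [CurvatureMdpBlock-class].
#' @param groupNames for a field: the two index-group names, attracted
#'   first.
#' @return character vector of `key = value` lines.
#' @examples
#' fld <- curvatureField(c(0, 0, 0), r0 = 2.5, kAttract = 500)
#' emitMdpBlock(fld)
#' @export
emitMdpBlock <- function(x, groupNames = c("NANO", "PEPTIDE")) {
  if (is(x, "CurvatureField"))
    x <- new("CurvatureMdpBlock",
             user1Grps = groupNames[1L], user2Grps = groupNames[2L],
             userints = c(if (x@active) 1L else 0L, 0L, 0L, 0L),
             userreals = c(x@r0, x@kAttract, 0))
  stopifnot(is(x, "CurvatureMdpBlock"))
  c(sprintf("user1-grps = %s", x@user1Grps),
    sprintf("user2-grps = %s", x@user2Grps),
    sprintf("userint%d = %d", 1:4, x@userints),
    sprintf("userreal%d = %s", 1:3, .fmtNum(x@userreals)))
}

#' Parse the curvature user-parameter block from mdp text
#'
#' Accepts general mdp syntax (`key = value ; comment`); comments are
#' stripped, unrelated keys are ignored, and `-`/`_` in key names are
#' interchangeable (`user1-grps` and `user1_grps` are the same key).
#' Missing user parameters default to zero / empty.
#'
#' @param file path or connection to an mdp file.
#' @param text alternatively, the contents as a string or character vector.
#' @return a [CurvatureMdpBlock-class].  Query it with [radius()],
#'   [forceConstant()], [isActive()] and [groupNames()].
#' @examples
#' blk <- parseMdpBlock(text = c("userint1 = 1 ; on switch",
#'                               "user1-grps = NANO", "user2-grps = PEPTIDE",
#'                               "userreal1 = 2.5", "userreal2 = 500"))
#' radius(blk)
#' @export
parseMdpBlock <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
    else text
  } else readLines(file)
  lines <- sub(";.*$", "", lines)
  ints <- c(userint1 = 0L, userint2 = 0L, userint3 = 0L, userint4 = 0L)
  reals <- c(userreal1 = 0, userreal2 = 0, userreal3 = 0)
  grps <- c(user1_grps = "", user2_grps = "")
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) next
    m <- regmatches(l, regexec("^([A-Za-z0-9_-]+)\\s*=\\s*(.*)$", l))[[1L]]
    if (length(m) != 3L) next
    key <- gsub("-", "_", tolower(m[2L]), fixed = TRUE)
    val <- trimws(m[3L])
    if (key %in% names(ints)) {
      v <- suppressWarnings(as.integer(val))
      if (is.na(v))
        stop(sprintf("cannot parse '%s = %s' as an integer (line %d)",
                     key, val, i), call. = FALSE)
      ints[[key]] <- v
    } else if (key %in% names(reals)) {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v))
        stop(sprintf("cannot parse '%s = %s' as a number (line %d)",
                     key, val, i), call. = FALSE)
      reals[[key]] <- v
    } else if (key %in% names(grps)) {
      grps[[key]] <- strsplit(val, "\\s+")[[1L]][1L]
    }
  }
  if (ints[["userint1"]] == 1L && !nzchar(grps[["user1_grps"]]))
    stop("curvature model is active (userint1 = 1) but user1-grps is missing",
         call. = FALSE)
  new("CurvatureMdpBlock",
      user1Grps = unname(grps[["user1_grps"]]),
      user2Grps = unname(grps[["user2_grps"]]),
      userints = unname(ints), userreals = unname(reals))
}

#' Build a curvature field from a parsed mdp block
#'
#' Combines the parsed user parameters with a box (to place the sphere
#' center via [nanoparticleCenter()]) and the index groups that the block's
#' group names refer to.
#'
#' @param block a [CurvatureMdpBlock-class].
#' @param box rectangular box edges, nm.
#' @param groups an [IndexGroups-class] containing the block's group names.
#' @return a [CurvatureField-class].
#' @examples
#' blk <- parseMdpBlock(text = c("userint1 = 1", "user1-grps = NANO",
#'                               "user2-grps = PEPTIDE", "userreal1 = 2.5",
#'                               "userreal2 = 500"))
#' grp <- indexGroups(NANO = 1L, PEPTIDE = 1:4)
#' curvatureFieldFromMdp(blk, box = c(15.71, 9.848, 8.803), groups = grp)
#' @export
curvatureFieldFromMdp <- function(block, box, groups) {
  stopifnot(is(block, "CurvatureMdpBlock"), is(groups, "IndexGroups"))
  r0 <- block@userreals[1L]
  curvatureField(center = nanoparticleCenter(box, r0), r0 = r0,
                 kAttract = block@userreals[2L],
                 nanoIndices = groups[[block@user1Grps]],
                 peptideIndices = groups[[block@user2Grps]],
                 active = block@userints[1L] == 1L)
}
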