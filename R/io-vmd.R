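#' Render a VMD Tk console sphere command
#'
#' Produces a `draw sphere {X Y Z} radius R resolution N` line for pasting
#' into the VMD TkConsole to visualise the implicit nanoparticle.  Inputs
#' are in nm (the internal unit); VMD works in Angstrom, so coordinates and
#' radius are multiplied by 10 on output.  Numbers are printed in their
#' shortest form, without trailing zeros.
#'
#' @param center sphere center, nm (length 3).
#' @param r0 sphere radius, nm.
#' @param resolution VMD sphere tessellation resolution, >= 1.
#' @return a single command string.
#' @examples
#' vmdSphereCommand(c(5.355, 4.924, 4.4015), 2.5, 50)
#' @export
vmdSphereCommand <- function(center, r0, resolution = 50L) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite 3-vector (nm)", call. = FALSE)
  .assertScalarNum(r0, "r0", min = 0)
  if (resolution < 1L)
    stop("resolution must be >= 1", call. = FALSE)
  sprintf("draw sphere {%s %s %s} radius %s resolution %d",
          .fmtNum(center[1L] * 10), .fmtNum(center[2L] * 10),
          .fmtNum(center[3L] * 10), .fmtNum(r0 * 10),
          as.integer(resolution))
}

#' Parse a VMD sphere command
#'
#' Inverse of [vmdSphereCommand()]: recovers center (nm), radius (nm) and
#' resolution from a `draw sphere` line (values divided by 10, Angstrom to
#' nm).
#'
#' @param line a `draw sphere {X Y Z} radius R resolution N` string.
#' @return list with `center` (nm), `r0` (nm), `resolution`.
#' @examples
#' parseVmdSphere("draw sphere {53.55 49.24 44.015} radius 25 resolution 50")
#' @export
parseVmdSphere <- function(line) {
  pat <- paste0("^\\s*draw\\s+sphere\\s*\\{\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)",
                "\\s*\\}\\s+radius\\s+(\\S+)(?:\\s+resolution\\s+(\\d+))?\\s*$")
  m <- regmatches(line, regexec(pat, line))[[1L]]
  if (length(m) < 5L)
    stop("not a 'draw sphere' command: ", line, call. = FALSE)
  nums <- suppressWarnings(as.numeric(m[2:5]))
  if (anyNA(nums))
    stop("non-numeric coordinates in: ", line, call. = FALSE)
  list(center = nums[1:3] / 10, r0 = nums[4L] / 10,
       resolution = if (is.na(m[6L]) || !nzchar(m[6L])) NA_integer_
                    else as.integer(m[6L]))
}

#' Recompute the companion sphere line for a different particle size
#'
#' The placement convention fixes the adsorption point at the box center
#' and puts the sphere center at `box_center_x - r0`.  Given one drawn
#' sphere line, the box center is therefore recoverable
#' (`box_center_x = x + r0`), and the line for any other radius follows
#' from the same rule.  This reproduces, for each oligomer system, the
#' large-particle (20 nm, radius 100 Angstrom) line from the
#' small-particle (5 nm, radius 25 Angstrom) line.
#'
#' @param line an existing `draw sphere` command.
#' @param newRadiusNm radius of the companion sphere, nm (default 10).
#' @param resolution tessellation resolution of the output line
#'   (default 100, the value used for the 20 nm spheres).
#' @return the recomputed command string.
#' @examples
#' vmdCompanionSphere("draw sphere {53.55 49.24 44.015} radius 25 resolution 50")
#' @export
vmdCompanionSphere <- function(line, newRadiusNm = 10, resolution = 100L) {
  sph <- parseVmdSphere(line)
  boxHalf <- c(sph$center[1L] + sph$r0, sph$center[2L], sph$center[3L])
  center <- nanoparticleCenter(2 * boxHalf, newRadiusNm)
  vmdSphereCommand(center, newRadiusNm, resolution)
}
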