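#' Read a GROMACS GRO structure file
#'
#' Parses the fixed-column GRO dialect: a title line, an atom count, one
#' record per atom (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f`, optionally followed by
#' three `%8.4f` velocity fields), and a final box line whose first three
#' numbers are the rectangular box edges.  Positions are in nm, velocities
#' in nm/ps.  Chains are inferred from residue-number resets (GRO carries
#' no chain field).
#'
#' @param file path to a GRO file, or a connection.
#' @param text alternatively, the file contents as a single string or a
#'   character vector of lines.
#' @return a [GroStructure-class].
#' @examples
#' gro <- c("one atom", "    1",
#'          "    1BEA    CA    1   1.000   2.000   3.000",
#'          "   4.00000   4.00000   4.00000")
#' readGro(text = gro)
#' @export
readGro <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
    else text
  } else readLines(file)
  if (length(lines) < 3L)
    stop("GRO input too short: need title, atom count, atoms and box line",
         call. = FALSE)
  title <- lines[1L]
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 1L)
    stop("malformed atom count at line 2", call. = FALSE)
  if (length(lines) < n + 2L)
    stop(sprintf(
      "unexpected end of file at line %d: atom count says %d atoms",
      length(lines) + 1L, n), call. = FALSE)
  rec <- lines[3:(n + 2L)]
  num <- function(from, to) suppressWarnings(as.numeric(substr(rec, from, to)))
  resid <- suppressWarnings(as.integer(substr(rec, 1L, 5L)))
  resname <- trimws(substr(rec, 6L, 10L))
  atomName <- trimws(substr(rec, 11L, 15L))
  atomId <- suppressWarnings(as.integer(substr(rec, 16L, 20L)))
  x <- num(21L, 28L); y <- num(29L, 36L); z <- num(37L, 44L)
  bad <- which(is.na(resid) | is.na(atomId) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("malformed atom record at line %d", bad[1L] + 2L),
         call. = FALSE)
  hasVel <- all(nchar(rec) >= 68L)
  velocities <- matrix(numeric(0), 0L, 3L)
  if (hasVel) {
    vx <- num(45L, 52L); vy <- num(53L, 60L); vz <- num(61L, 68L)
    if (!anyNA(c(vx, vy, vz)))
      velocities <- cbind(vx, vy, vz, deparse.level = 0)
  }
  boxLine <- n + 3L
  boxNums <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[boxLine]), "\\s+")[[1L]]))
  if (length(boxNums) < 3L || anyNA(boxNums[1:3]))
    stop(sprintf("malformed box line at line %d", boxLine), call. = FALSE)
  groStructure(
    positions = cbind(x, y, z, deparse.level = 0),
    box = boxNums[1:3],
    atoms = data.frame(resid = resid, resname = resname,
                       atomName = atomName, atomId = atomId,
                       stringsAsFactors = FALSE),
    velocities = if (nrow(velocities)) velocities else NULL,
    title = title)
}

#' Write a GROMACS GRO structure file
#'
#' Renders the fixed-column format ([readGro()] describes the layout).
#' Residue and atom numbers wrap at 100000, as in GROMACS (the 100000th
#' atom prints as 0).  Velocities are written only when the structure
#' carries them; they are never fabricated.
#'
#' @param structure a [GroStructure-class] with at least one atom.
#' @param file optional path; when omitted the lines are returned.
#' @return character vector of lines (invisibly when `file` is given).
#' @examples
#' s <- groStructure(c(1, 2, 3), box = c(4, 4, 4))
#' writeGro(s)
#' @export
writeGro <- function(structure, file = NULL) {
  stopifnot(is(structure, "GroStructure"))
  n <- nAtoms(structure)
  if (n < 1L)
    stop("refusing to write an empty structure", call. = FALSE)
  a <- structure@atoms
  p <- structure@positions
  hasVel <- nrow(structure@velocities) == n
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  a$resid %% 100000L, a$resname, a$atomName,
                  a$atomId %% 100000L, p[, 1L], p[, 2L], p[, 3L])
  if (hasVel) {
    v <- structure@velocities
    recs <- paste0(recs, sprintf("%8.4f%8.4f%8.4f",
                                 v[, 1L], v[, 2L], v[, 3L]))
  }
  lines <- c(structure@title, sprintf("%5d", n), recs,
             paste0(sprintf("%10.5f", structure@box), collapse = ""))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Convert a bead-chain system to a GRO structure
#'
#' Bead b of chain c becomes atom `CA` of residue b (numbering restarting
#' per chain, so chains survive a GRO round trip), residue name `BEA`.
#'
#' @param system a [BeadChainSystem-class].
#' @param box box edges, nm; defaults to [soluteBox()] of the coordinates.
#' @param title title line.
#' @return a [GroStructure-class].
#' @examples
#' asGroStructure(buildFibrilOligomer(2, 3))
#' @export
asGroStructure <- function(system, box = NULL,
                           title = "curvnp bead-chain oligomer") {
  stopifnot(is(system, "BeadChainSystem"))
  if (is.null(box)) box <- soluteBox(system@positions)
  n <- nAtoms(system)
  resid <- unlist(lapply(split(seq_len(n), system@chains), seq_along),
                  use.names = FALSE)
  groStructure(system@positions, box = box,
               atoms = data.frame(resid = resid, resname = "BEA",
                                  atomName = "CA", atomId = seq_len(n),
                                  stringsAsFactors = FALSE),
               chains = system@chains, title = title)
}
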