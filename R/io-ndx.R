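#' Read a GROMACS NDX index file
#'
#' Sections are delimited by `[ NAME ]` headers followed by
#' whitespace-separated 1-based atom indices.  For the curvature model two
#' groups matter: `NANO` (anchored atoms) and `PEPTIDE` (all solute atoms).
#'
#' @param file path or connection.
#' @param text alternatively, the contents as a string or character vector.
#' @return an [IndexGroups-class]; group order follows the file.
#' @examples
#' readNdx(text = "[ NANO ]\n1 42\n[ PEPTIDE ]\n1 2 3 42\n")
#' @export
readNdx <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
    else text
  } else readLines(file)
  lines <- sub(";.*$", "", lines)
  groups <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) next
    hdr <- regmatches(l, regexec("^\\[\\s*(.+?)\\s*\\]$", l))[[1L]]
    if (length(hdr) == 2L) {
      nm <- hdr[2L]
      if (nm %in% names(groups))
        stop(sprintf("duplicate index group '%s' at line %d", nm, i),
             call. = FALSE)
      groups[[nm]] <- integer(0)
      current <- nm
    } else {
      if (is.null(current))
        stop(sprintf("indices before any [ group ] header at line %d", i),
             call. = FALSE)
      v <- suppressWarnings(as.integer(strsplit(l, "\\s+")[[1L]]))
      if (anyNA(v))
        stop(sprintf("non-integer index at line %d", i), call. = FALSE)
      if (any(v < 1L))
        stop(sprintf("atom indices are 1-based; found %d at line %d",
                     min(v), i), call. = FALSE)
      groups[[current]] <- c(groups[[current]], v)
    }
  }
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty))
    warning(sprintf("empty index group(s): %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  do.call(indexGroups, groups)
}

#' Write a GROMACS NDX index file
#'
#' @param groups an [IndexGroups-class].
#' @param file optional path; when omitted the lines are returned.
#' @param perLine indices per output line.
#' @return character vector of lines (invisibly when `file` is given).
#' @examples
#' writeNdx(indexGroups(NANO = c(1L, 42L)))
#' @export
writeNdx <- function(groups, file = NULL, perLine = 15L) {
  stopifnot(is(groups, "IndexGroups"))
  lines <- character(0)
  for (nm in names(groups@groups)) {
    lines <- c(lines, sprintf("[ %s ]", nm))
    idx <- groups@groups[[nm]]
    if (length(idx)) {
      chunks <- split(idx, ceiling(seq_along(idx) / perLine))
      lines <- c(lines,
                 vapply(chunks, function(v) paste(v, collapse = " "),
                        character(1), USE.NAMES = FALSE))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
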