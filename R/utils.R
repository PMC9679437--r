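# Boltzmann constant, kJ mol^-1 K^-1 (GROMACS units)
.kB <- 0.0083144621

# Shortest decimal rendering without trailing zeros ("53.55" not "53.550",
# "25" not "25.0000"); matches the VMD/mdp printed style.
.fmtNum <- function(x, digits = 4L) {
  s <- formatC(round(x, digits), format = "f", digits = digits)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s[s == "-0"] <- "0"
  s
}

# Scatter-add per-atom force contributions: indices may repeat.
.addForce <- function(F, idx, contrib) {
  m <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(m))
  F[rows, ] <- F[rows, ] + m
  F
}

.assertScalarNum <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

.asPosMatrix <- function(pos) {
  if (is.null(dim(pos))) {
    if (length(pos) != 3L)
      stop("positions must be a length-3 vector or an n x 3 matrix",
           call. = FALSE)
    pos <- matrix(pos, nrow = 1L)
  }
  if (ncol(pos) != 3L)
    stop("positions must have 3 columns (x, y, z in nm)", call. = FALSE)
  storage.mode(pos) <- "double"
  pos
}
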