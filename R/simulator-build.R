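#' Build a synthetic fibril-like bead-chain oligomer
#'
#' Constructs a coarse-grained stand-in for a preformed amyloid oligomer:
#' `nChains` parallel straight bead strands (one bead per residue) stacked
#' along x at the cross-beta strand spacing, with beads running along y.
#' Consecutive beads are bonded harmonically, consecutive bead triples get
#' a straightening angle term, and every inter-chain bead pair closer than
#' `contactCutoff` in the built geometry becomes an attractive 12-10 native
#' contact whose minimum sits at the built distance.  All remaining pairs
#' (beyond first and second bonded neighbours) share a soft r^-12
#' repulsion.  With the default spacings only same-position beads of
#' adjacent chains fall inside the cutoff, mimicking the inter-strand
#' hydrogen-bond ladder of a fibril.
#'
#' The geometry is a deterministic lattice; `jitter > 0` adds Gaussian
#' positional noise (nm) drawn with `seed`, which is also recorded for
#' provenance.
#'
#' @param nChains number of monomers (e.g. 5 or 10, the published oligomer
#'   sizes).
#' @param beadsPerChain beads (residues) per monomer, >= 2.
#' @param stackSpacing inter-chain stacking distance, nm (default 0.47,
#'   the cross-beta strand spacing).
#' @param beadSpacing intra-chain bead spacing, nm (default 0.38, the
#'   C-alpha virtual bond length).
#' @param contactCutoff native-contact distance cutoff, nm.
#' @param seed RNG seed used when `jitter > 0`.
#' @param jitter sd of optional Gaussian positional noise, nm.
#' @param beadMass bead mass, amu (default 110, one average residue).
#' @param kb bond force constant, kJ nm^-2 mol^-1.
#' @param b0 bond rest length, nm; defaults to `beadSpacing`.
#' @param ka angle force constant, kJ rad^-2 mol^-1.
#' @param theta0 angle rest value, rad (default pi: straight strands).
#' @param epsContact native-contact depth, kJ/mol.
#' @param sigmaRep soft-repulsion diameter, nm.
#' @param epsRep soft-repulsion strength, kJ/mol.
#' @return a [BeadChainSystem-class].
#' @examples
#' sys <- buildFibrilOligomer(5, 7)
#' nrow(sys@bonds)     # 5 * 6 = 30
#' nrow(sys@contacts)  # 4 * 7 = 28, adjacent chains only
#' @export
buildFibrilOligomer <- function(nChains, beadsPerChain,
                                stackSpacing = 0.47, beadSpacing = 0.38,
                                contactCutoff = 0.6, seed = NULL,
                                jitter = 0, beadMass = 110,
                                kb = 8000, b0 = beadSpacing,
                                ka = 40, theta0 = pi,
                                epsContact = 4, sigmaRep = 0.4,
                                epsRep = 1) {
  if (nChains < 1L || beadsPerChain < 2L)
    stop("need nChains >= 1 and beadsPerChain >= 2", call. = FALSE)
  n <- nChains * beadsPerChain
  chain <- rep(seq_len(nChains), each = beadsPerChain)
  beadIn <- rep(seq_len(beadsPerChain), times = nChains)
  pos <- cbind((chain - 1L) * stackSpacing, (beadIn - 1L) * beadSpacing, 0)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    pos <- pos + matrix(rnorm(3L * n, sd = jitter), n, 3L)
  }

  first <- which(beadIn < beadsPerChain)
  bonds <- data.frame(i = first, j = first + 1L, b0 = b0, kb = kb)

  mid <- which(beadIn > 1L & beadIn < beadsPerChain)
  angles <- data.frame(i = mid - 1L, j = mid, k = mid + 1L,
                       theta0 = rep(theta0, length(mid)),
                       ka = rep(ka, length(mid)))

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pi_ <- pairs[, 1L]; pj_ <- pairs[, 2L]
  dist <- sqrt(rowSums((pos[pi_, , drop = FALSE] -
                        pos[pj_, , drop = FALSE])^2))
  isContact <- chain[pi_] != chain[pj_] & dist <= contactCutoff
  contacts <- data.frame(i = pi_[isContact], j = pj_[isContact],
                         sigma = dist[isContact],
                         eps = rep(epsContact, sum(isContact)))

  # exclude bonded (1-2), angle (1-3) and native pairs from the repulsion
  key <- function(i, j) pmin(i, j) * (n + 1L) + pmax(i, j)
  excluded <- c(key(bonds$i, bonds$j),
                if (nrow(angles)) key(angles$i, angles$k),
                key(contacts$i, contacts$j))
  keep <- !(key(pi_, pj_) %in% excluded)
  repPairs <- cbind(pi_[keep], pj_[keep])
  storage.mode(repPairs) <- "integer"

  new("BeadChainSystem", positions = pos, masses = rep(beadMass, n),
      chains = as.integer(chain), bonds = bonds, angles = angles,
      contacts = contacts, repulsionPairs = repPairs,
      sigmaRep = sigmaRep, epsRep = epsRep)
}
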