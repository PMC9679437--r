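# Central finite-difference gradient of a scalar energy function of an
# n x 3 configuration; independent oracle for analytic forces.
fdForces <- function(energyFun, pos, h = 1e-6) {
  g <- matrix(0, nrow(pos), 3L)
  for (a in seq_len(nrow(pos))) {
    for (d in 1:3) {
      pp <- pos; pp[a, d] <- pp[a, d] + h
      pm <- pos; pm[a, d] <- pm[a, d] - h
      g[a, d] <- -(energyFun(pp) - energyFun(pm)) / (2 * h)
    }
  }
  g
}

# A tiny hand-written GRO file: n atoms on a line, 4 nm cubic box.
groFixture <- function(n = 1L, box = c(4, 4, 4), vel = FALSE) {
  recs <- vapply(seq_len(n), function(i) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    i, "ALA", "CA", i, 0.1 * i, 0.2, 0.3)
    if (vel) paste0(base, sprintf("%8.4f%8.4f%8.4f", 0.01, -0.02, 0.03))
    else base
  }, character(1))
  c("fixture", sprintf("%5d", n), recs,
    paste(sprintf("%10.5f", box), collapse = ""))
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

vmdFixturePath <- function() {
  system.file("extdata", "vmd_spheres.tsv", package = "curvnp")
}

mdpFixturePath <- function() {
  system.file("extdata", "curvature_params.mdp", package = "curvnp")
}
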