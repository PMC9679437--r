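#' Native-contact fraction Q of a frame
#'
#' The fraction of reference native contacts still formed: a contact
#' `(i, j)` with native distance `sigma` counts as formed when the current
#' distance is at most `tolerance * sigma`.  Q = 1 means the oligomer's
#' stacked arrangement is intact; Q = 0 means full dissociation.  Being a
#' function of inter-bead distances only, Q is invariant under rigid motion
#' of the frame.
#'
#' @param frame n x 3 matrix of positions, nm.
#' @param referenceContacts data.frame with columns `i`, `j`, `sigma`
#'   (e.g. the `contacts` table of [buildFibrilOligomer()]).
#' @param tolerance multiplicative distance tolerance (default 1.2, the
#'   usual Go-analysis convention).
#' @return Q in `[0, 1]`.
#' @examples
#' sys <- buildFibrilOligomer(5, 7)
#' nativeContactFraction(positions(sys), sys@contacts)  # 1 by construction
#' @export
nativeContactFraction <- function(frame, referenceContacts,
                                  tolerance = 1.2) {
  frame <- .asPosMatrix(frame)
  if (is.null(referenceContacts) || nrow(referenceContacts) == 0L)
    stop("reference contact set is empty", call. = FALSE)
  d <- frame[referenceContacts$i, , drop = FALSE] -
       frame[referenceContacts$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  mean(r <= tolerance * referenceContacts$sigma)
}

#' Optimal-superposition RMSD between two frames
#'
#' Root-mean-square deviation after removing the optimal rigid transform:
#' both frames are centered and the rotation minimising the residual is
#' found from the singular value decomposition of the covariance matrix
#' (with the usual determinant correction so reflections are excluded).
#'
#' @param frame,reference n x 3 coordinate matrices, nm.
#' @param selection optional indices of atoms to superpose (default: all).
#' @return minimum RMSD over rigid motions, nm.
#' @examples
#' sys <- buildFibrilOligomer(2, 4)
#' rmsd(positions(sys), positions(sys))   # 0
#' @export
rmsd <- function(frame, reference, selection = NULL) {
  frame <- .asPosMatrix(frame)
  reference <- .asPosMatrix(reference)
  if (!is.null(selection)) {
    frame <- frame[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(frame) != nrow(reference))
    stop("frame and reference must have the same number of atoms",
         call. = FALSE)
  if (nrow(frame) < 3L)
    stop("need at least 3 atoms for superposition", call. = FALSE)
  P <- sweep(frame, 2L, colMeans(frame))
  Q <- sweep(reference, 2L, colMeans(reference))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

#' @rdname restraintDistributionCheck
#' @param field a [CurvatureField-class] (for the Trajectory method:
#'   supplies the shell geometry and `kAttract`).
#' @param temperature bath temperature, K.
#' @param burnIn fraction of initial frames dropped before computing
#'   stationary statistics (default 0.2).
#' @param thin keep every `thin`-th sample to reduce serial correlation
#'   before the goodness-of-fit test.
#' @param k force constant used for the expected variance; defaults to the
#'   field's `kAttract` (numeric method: required).
#' @export
setMethod("restraintDistributionCheck", "Trajectory",
  function(x, field, temperature = x@params@temperature, burnIn = 0.2,
           thin = 1L, k = field@kAttract) {
    nf <- nFrames(x)
    keep <- seq.int(floor(burnIn * nf) + 1L, nf)
    samples <- unlist(lapply(keep, function(i)
      surfaceDisplacement(framePositions(x, i), field)), use.names = FALSE)
    restraintDistributionCheck(samples, k = k, temperature = temperature,
                               thin = thin)
  })

#' @rdname restraintDistributionCheck
#' @export
setMethod("restraintDistributionCheck", "numeric",
  function(x, k, temperature = 300, thin = 1L, burnIn = 0) {
    if (burnIn > 0)
      x <- x[seq.int(floor(burnIn * length(x)) + 1L, length(x))]
    if (thin > 1L)
      x <- x[seq.int(1L, length(x), by = thin)]
    if (length(x) < 100L)
      stop("need at least 100 displacement samples", call. = FALSE)
    .assertScalarNum(k, "k", min = 0)
    expected <- if (k > 0) .kB * temperature / k else Inf
    observed <- var(x)
    if (temperature <= 0 || observed == 0 || !is.finite(expected)) {
      out <- list(degenerate = TRUE, observedVariance = observed,
                  expectedVariance = expected, ratio = NA_real_,
                  ksStatistic = NA_real_, ksP = NA_real_,
                  nSamples = length(x))
      class(out) <- "restraintCheck"
      return(out)
    }
    ks <- suppressWarnings(
      ks.test((x - mean(x)) / sqrt(expected), "pnorm"))
    out <- list(degenerate = FALSE, observedVariance = observed,
                expectedVariance = expected, ratio = observed / expected,
                ksStatistic = unname(ks$statistic), ksP = ks$p.value,
                nSamples = length(x))
    class(out) <- "restraintCheck"
    out
  })

#' @export
print.restraintCheck <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "Shell-restraint check: degenerate (T = 0 or zero variance), n = %d\n",
      x$nSamples))
  } else {
    cat(sprintf(
      paste0("Shell-restraint check (n = %d):\n",
             "  variance observed %.6g, expected kB*T/k = %.6g ",
             "(ratio %.3f)\n  KS statistic %.4f (p = %.3g)\n"),
      x$nSamples, x$observedVariance, x$expectedVariance, x$ratio,
      x$ksStatistic, x$ksP))
  }
  invisible(x)
}

#' Per-frame stability metrics of one trajectory
#'
#' Computes, for every stored frame: the native-contact fraction Q against
#' the reference contact set, the optimal-superposition RMSD to the
#' reference coordinates, and (when a field is given) the mean NANO
#' shell displacement.
#'
#' @param traj a [Trajectory-class].
#' @param reference n x 3 reference coordinates, nm.
#' @param referenceContacts data.frame `i`, `j`, `sigma` of native
#'   contacts.
#' @param field optional [CurvatureField-class] with NANO indices.
#' @param replicate replicate identifier stored in the output.
#' @param tolerance contact tolerance passed to
#'   [nativeContactFraction()].
#' @return data.frame with columns `time`, `Q`, `rmsd`, `shellDisp` (NA
#'   without a field) and `replicate`.
#' @examples
#' sys <- buildFibrilOligomer(3, 4)
#' traj <- langevinRun(sys, NULL, simulationParams(nSteps = 50, seed = 1))
#' head(stabilityReport(traj, positions(sys), sys@contacts))
#' @export
stabilityReport <- function(traj, reference, referenceContacts,
                            field = NULL, replicate = 1L,
                            tolerance = 1.2) {
  stopifnot(is(traj, "Trajectory"))
  nf <- nFrames(traj)
  Q <- numeric(nf); R <- numeric(nf); S <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    fr <- framePositions(traj, i)
    Q[i] <- nativeContactFraction(fr, referenceContacts, tolerance)
    R[i] <- rmsd(fr, reference)
    if (!is.null(field))
      S[i] <- mean(surfaceDisplacement(fr, field))
  }
  data.frame(time = frameTimes(traj), Q = Q, rmsd = R, shellDisp = S,
             replicate = replicate)
}

#' Aggregate stability reports across replicates
#'
#' Per-frame mean and standard deviation of every metric across replicate
#' reports sharing the same frame grid.
#'
#' @param reports list of data.frames as returned by [stabilityReport()]
#'   (identical `time` columns).
#' @return data.frame with `time` and, per metric, `<metric>_mean` and
#'   `<metric>_sd` columns; attribute `"nReplicates"`.
#' @examples
#' sys <- buildFibrilOligomer(3, 4)
#' trio <- runReplicates(sys, NULL, simulationParams(nSteps = 40), nReps = 2)
#' reps <- lapply(seq_along(trio), function(i)
#'   stabilityReport(trio[[i]], positions(sys), sys@contacts, replicate = i))
#' summarizeReplicates(reps)
#' @export
summarizeReplicates <- function(reports) {
  if (!length(reports))
    stop("need at least one report", call. = FALSE)
  times <- reports[[1L]]$time
  for (r in reports[-1L])
    if (length(r$time) != length(times) ||
        max(abs(r$time - times)) > 1e-9)
      stop("replicate reports have mismatched frame grids", call. = FALSE)
  metrics <- setdiff(names(reports[[1L]]), c("time", "replicate"))
  out <- data.frame(time = times)
  for (mname in metrics) {
    vals <- vapply(reports, function(r) as.numeric(r[[mname]]),
                   numeric(length(times)))
    vals <- matrix(vals, nrow = length(times))
    out[[paste0(mname, "_mean")]] <- rowMeans(vals)
    out[[paste0(mname, "_sd")]] <- apply(vals, 1L, sd)
  }
  attr(out, "nReplicates") <- length(reports)
  out
}
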