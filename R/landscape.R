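# Low-dimensional landscape machinery: PCA on non-adjacent Calpha-Calpha
# distances, projection of query ensembles on reference axes, and binned
# free-energy surfaces G = -RT ln P.

.gasConstantKJ <- 8.314462618e-3  # kJ/(mol K)

.distanceFeatures <- function(ensemble, pairs) {
  ca <- .caIndices(ensemble@topology)
  nf <- nFrames(ensemble)
  F <- matrix(NA_real_, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    X <- getFrame(ensemble, f)[ca, , drop = FALSE]
    d <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
    F[f, ] <- sqrt(rowSums(d * d))
  }
  F
}

#' Fit a distance-PCA landscape on a reference ensemble
#'
#' Features are Calpha-Calpha distances of all non-adjacent residue pairs
#' (|i - j| >= 2), centered and unscaled; the top two principal axes are
#' retained. Conventionally the reference (MD) ensemble defines the axes and
#' other ensembles are projected onto them.
#'
#' @param reference an \linkS4class{Ensemble} with >= 3 frames and >= 4
#'   residues.
#' @return a \linkS4class{LandscapeModel}.
#' @export
fitLandscape <- function(reference) {
  L <- nResidues(reference)
  if (nFrames(reference) < 3) stop("landscape PCA needs >= 3 frames")
  if (L < 4) stop("landscape PCA needs >= 4 residues")
  pairs <- which(upper.tri(matrix(0, L, L)) &
                 abs(outer(seq_len(L), seq_len(L), "-")) >= 2, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  F <- .distanceFeatures(reference, pairs)
  if (all(apply(F, 2, stats::var) == 0))
    stop("all distance features have zero variance; PCA undefined")
  pc <- stats::prcomp(F, center = TRUE, scale. = FALSE)
  new("LandscapeModel", featurePairs = pairs, mean = pc$center,
      axes = pc$rotation[, 1:2, drop = FALSE],
      explainedVariance = pc$sdev[1:2]^2)
}

#' Project an ensemble onto landscape axes
#'
#' @param model a \linkS4class{LandscapeModel} fitted on the reference.
#' @param query an \linkS4class{Ensemble} with the same number of residues.
#' @return nframes x 2 matrix of (pc1, pc2) scores.
#' @export
projectLandscape <- function(model, query) {
  maxRes <- max(model@featurePairs)
  if (nResidues(query) < maxRes)
    stop(sprintf("query has %d residues but the landscape model needs >= %d",
                 nResidues(query), maxRes))
  F <- .distanceFeatures(query, model@featurePairs)
  scores <- sweep(F, 2, model@mean) %*% model@axes
  colnames(scores) <- c("pc1", "pc2")
  scores
}

#' Binned 2D free-energy surface
#'
#' Computes G = -RT ln P on a uniform 2D grid spanning the data range, with
#' P the raw histogram frequency (count/total). Empty bins are masked
#' (infinite free energy); G is shifted so its unmasked minimum is 0.
#'
#' @param points nframes x 2 matrix of projected coordinates.
#' @param temperature temperature in Kelvin.
#' @param bins number of bins per axis (default 50).
#' @param units "kJ/mol" (R = 8.314462618e-3 kJ/(mol K)) or "RT".
#' @return a \linkS4class{FreeEnergyGrid}.
#' @export
freeEnergyGrid <- function(points, temperature, bins = 50, units = c("kJ/mol", "RT")) {
  units <- match.arg(units)
  if (temperature <= 0) stop("temperature must be > 0 K")
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("at least one point is required")
  mkEdges <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)   # degenerate axis: unit span
    seq(r[1], r[2], length.out = bins + 1)
  }
  xe <- mkEdges(points[, 1]); ye <- mkEdges(points[, 2])
  bx <- pmin(pmax(findInterval(points[, 1], xe, rightmost.closed = TRUE), 1), bins)
  by <- pmin(pmax(findInterval(points[, 2], ye, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_len(nrow(points))) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1
  P <- counts / nrow(points)
  mask <- counts == 0
  rt <- if (units == "RT") 1 else .gasConstantKJ * temperature
  G <- matrix(NA_real_, bins, bins)
  G[!mask] <- -rt * log(P[!mask])
  G[!mask] <- G[!mask] - min(G[!mask])
  new("FreeEnergyGrid", xEdges = xe, yEdges = ye, G = G, mask = mask, units = units)
}
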