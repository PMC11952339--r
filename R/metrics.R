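# Positional and fluctuation metrics comparing an ensemble against a
# reference ensemble and the initial (native) structure.

.caIndices <- function(topology) which(topology@atomName == "CA")

#' Per-residue Calpha root-mean-square fluctuation
#'
#' Every frame is superposed onto the initial structure over Calpha atoms;
#' the RMSF of residue i is the root-mean-square displacement of its Calpha
#' from the ensemble-mean Calpha position.
#'
#' @param ensemble an \linkS4class{Ensemble} with at least 2 frames.
#' @param initial natoms x 3 matrix: the structure frames are superposed on.
#' @return numeric vector of length nresidues, Angstrom.
#' @export
rmsfProfile <- function(ensemble, initial) {
  nf <- nFrames(ensemble)
  if (nf < 2) stop("RMSF is undefined for a 1-frame ensemble")
  ca <- .caIndices(ensemble@topology)
  pos <- array(NA_real_, c(length(ca), 3, nf))
  for (f in seq_len(nf)) {
    fit <- superpose(getFrame(ensemble, f), initial, ca)
    pos[, , f] <- fit$coords[ca, ]
  }
  m <- apply(pos, c(1, 2), mean)
  dev2 <- sweep(pos, c(1, 2), m)^2
  sqrt(apply(dev2, 1, function(d) mean(colSums(matrix(d, nrow = 3, byrow = TRUE)))))
}

#' Pearson correlation between two RMSF profiles
#'
#' @param profileA,profileB equal-length numeric profiles (length >= 3).
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
rmsfPcc <- function(profileA, profileB) {
  if (length(profileA) != length(profileB) || length(profileA) < 3)
    stop("profiles must have equal length >= 3")
  if (stats::sd(profileA) == 0 || stats::sd(profileB) == 0)
    stop("correlation undefined for a constant RMSF profile")
  stats::cor(profileA, profileB)
}

#' Per-frame Calpha RMSD to the initial structure
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param initial natoms x 3 matrix of the initial structure.
#' @return numeric vector of per-frame RMSD values (Angstrom) after optimal
#'   Calpha superposition.
#' @export
initRmsd <- function(ensemble, initial) {
  ca <- .caIndices(ensemble@topology)
  vapply(seq_len(nFrames(ensemble)), function(f)
    superpose(getFrame(ensemble, f), initial, ca)$rmsd, numeric(1))
}

#' Per-frame radius of gyration
#'
#' Mass-unweighted Rg over all heavy atoms.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @return numeric vector, one Rg per frame, Angstrom.
#' @export
radiusOfGyration <- function(ensemble) {
  vapply(seq_len(nFrames(ensemble)), function(f) {
    X <- getFrame(ensemble, f)
    Xc <- sweep(X, 2, colMeans(X))
    sqrt(mean(rowSums(Xc^2)))
  }, numeric(1))
}

#' Calpha-Calpha contact frequency map
#'
#' Fraction of frames in which two Calpha atoms of non-adjacent residues
#' (|i - j| >= 2) are within the cutoff (inclusive). Diagonal and adjacent
#' entries are 0.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param cutoff contact distance threshold in Angstrom (default 9.0,
#'   i.e. 0.9 nm).
#' @return symmetric nresidues x nresidues matrix of frequencies in [0, 1].
#' @export
contactMap <- function(ensemble, cutoff = 9.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ca <- .caIndices(ensemble@topology)
  L <- length(ca)
  acc <- matrix(0, L, L)
  for (f in seq_len(nFrames(ensemble))) {
    D <- as.matrix(stats::dist(getFrame(ensemble, f)[ca, , drop = FALSE]))
    acc <- acc + (D <= cutoff)
  }
  acc <- acc / nFrames(ensemble)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  acc[sep < 2] <- 0
  acc
}

#' Side-chain centroids of a conformation
#'
#' Unweighted mean position of each residue's side-chain heavy atoms
#' (everything but N, CA, C, O). Glycine falls back to its Calpha; alanine's
#' centroid is its Cbeta.
#'
#' @param conformation natoms x 3 matrix.
#' @param topology the matching \linkS4class{Topology}.
#' @return nresidues x 3 matrix of centroid coordinates, Angstrom.
#' @export
sideChainCentroid <- function(conformation, topology) {
  L <- nResidues(topology)
  out <- matrix(NA_real_, L, 3)
  backbone <- c("N", "CA", "C", "O")
  for (i in seq_len(L)) {
    own <- which(topology@atomResidue == i)
    sc <- own[!(topology@atomName[own] %in% backbone)]
    if (!length(sc)) sc <- own[topology@atomName[own] == "CA"]
    out[i, ] <- colMeans(conformation[sc, , drop = FALSE])
  }
  out
}
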