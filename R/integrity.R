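# Stereochemical integrity counters: heavy-atom clashes between
# non-adjacent residues and peptide-bond length violations.

.peptideBondMean <- 1.348   # Angstrom, reference mean for C-N lengths
.peptideBondSd <- 0.029     # Angstrom, reference standard deviation

#' Count heavy-atom clashes in a conformation
#'
#' A clash is a pair of heavy atoms from non-adjacent residues
#' (|i - j| >= 2) at a distance strictly below half the sum of their van der
#' Waals radii.
#'
#' @param conformation natoms x 3 matrix.
#' @param topology the matching \linkS4class{Topology}.
#' @param radii named element-to-radius vector, Angstrom
#'   (default \code{\link{defaultVdwTable}}).
#' @param details if TRUE, also return the offending pairs.
#' @return integer clash count, or (with \code{details}) a list with
#'   \code{count} and a data.frame \code{pairs} (atom_i, atom_j, distance).
#' @export
countHeavyClashes <- function(conformation, topology, radii = defaultVdwTable(),
                              details = FALSE) {
  el <- topology@atomElement
  missing <- setdiff(unique(el), names(radii))
  if (length(missing))
    stop(sprintf("element(s) missing from the vdW radii table: %s",
                 paste(missing, collapse = ", ")))
  r <- unname(radii[el])
  D <- as.matrix(stats::dist(conformation))
  thr <- 0.5 * outer(r, r, "+")
  sep <- abs(outer(topology@atomResidue, topology@atomResidue, "-"))
  hit <- D < thr & sep >= 2 & upper.tri(D)
  if (!details) return(sum(hit))
  w <- which(hit, arr.ind = TRUE)
  pairs <- data.frame(atom_i = w[, 1], atom_j = w[, 2],
                      distance = D[w])
  pairs <- pairs[order(pairs$distance), , drop = FALSE]
  list(count = nrow(pairs), pairs = pairs)
}

#' Count peptide-bond length violations in a conformation
#'
#' Counts inter-residue C(i)-N(i+1) bonds whose length deviates from the
#' reference mean 1.348 Angstrom by at least 3 reference standard deviations
#' (0.029 Angstrom); the criterion is two-sided and inclusive,
#' |b - 1.348| / 0.029 >= 3.
#'
#' @param conformation natoms x 3 matrix.
#' @param topology the matching \linkS4class{Topology}.
#' @return integer violation count.
#' @export
countPeptideViolations <- function(conformation, topology) {
  L <- nResidues(topology)
  if (L < 2) return(0L)
  idx <- function(i, nm) which(topology@atomResidue == i & topology@atomName == nm)
  b <- vapply(seq_len(L - 1), function(i)
    sqrt(sum((conformation[idx(i, "C"), ] - conformation[idx(i + 1, "N"), ])^2)),
    numeric(1))
  sum(abs(b - .peptideBondMean) / .peptideBondSd >= 3.0)
}

#' Integrity summary of an ensemble
#'
#' Per-frame clash and peptide-bond violation counts, their means (the
#' per-snapshot scores), and the tightest clashing pairs.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param radii vdW radii table.
#' @param nOffenders how many worst clash pairs to record.
#' @return an \linkS4class{IntegrityReport}.
#' @export
integrityReport <- function(ensemble, radii = defaultVdwTable(), nOffenders = 10) {
  top <- ensemble@topology
  nf <- nFrames(ensemble)
  clashes <- numeric(nf); viol <- numeric(nf)
  offenders <- data.frame(frame = integer(0), atom_i = integer(0),
                          atom_j = integer(0), distance = numeric(0))
  for (f in seq_len(nf)) {
    X <- getFrame(ensemble, f)
    d <- countHeavyClashes(X, top, radii, details = TRUE)
    clashes[f] <- d$count
    viol[f] <- countPeptideViolations(X, top)
    if (d$count)
      offenders <- rbind(offenders, cbind(frame = f, d$pairs))
  }
  if (nrow(offenders)) {
    offenders <- offenders[order(offenders$distance), , drop = FALSE]
    offenders <- utils::head(offenders, nOffenders)
  }
  new("IntegrityReport", clashesPerFrame = clashes, violationsPerFrame = viol,
      worstOffenders = offenders)
}

#' @describeIn integrityReport mean clashes per frame.
#' @param x an IntegrityReport.
#' @export
meanClashes <- function(x) mean(x@clashesPerFrame)

#' @describeIn integrityReport mean peptide-bond violations per frame.
#' @export
meanViolations <- function(x) mean(x@violationsPerFrame)
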