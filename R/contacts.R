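# Soft native-contact foldedness: native contact extraction, the logistic
# Q score and the folded-state fraction of an ensemble.

# per-residue atom index lists, cached order
.residueAtomIndex <- function(topology) {
  split(seq_along(topology@atomResidue), topology@atomResidue)
}

# minimal heavy-atom distance between two residues in one frame
.minResidueDistance <- function(X, atomsI, atomsJ) {
  A <- X[atomsI, , drop = FALSE]; B <- X[atomsJ, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Native contacts of a structure
#'
#' All residue pairs at least 3 residues apart in sequence whose minimal
#' heavy-atom distance in the native conformation is at most 10 Angstrom
#' (inclusive); that distance is stored as the reference d0.
#'
#' @param native natoms x 3 matrix of the native structure.
#' @param topology the matching \linkS4class{Topology}.
#' @return a \linkS4class{NativeContactSet}.
#' @export
nativeContacts <- function(native, topology) {
  ra <- .residueAtomIndex(topology)
  L <- length(ra)
  i <- integer(0); j <- integer(0); d0 <- numeric(0)
  for (a in seq_len(L)) {
    for (b in seq_len(L)) {
      if (b < a + 3) next
      d <- .minResidueDistance(native, ra[[a]], ra[[b]])
      if (d <= 10) { i <- c(i, a); j <- c(j, b); d0 <- c(d0, d) }
    }
  }
  new("NativeContactSet", contacts = data.frame(i = i, j = j, d0 = d0))
}

#' Fraction of native contacts Q of one conformation
#'
#' Soft logistic count over the native contact set:
#' Q = mean over contacts of 1 / (1 + exp(beta (d_ij - lambda d0_ij))), with
#' beta = 5.0 per Angstrom and lambda = 1.2. d_ij is recomputed as the
#' minimal heavy-atom distance of the same residue pair.
#'
#' @param conformation natoms x 3 matrix.
#' @param topology the matching \linkS4class{Topology}.
#' @param contacts a \linkS4class{NativeContactSet}.
#' @param beta logistic steepness, 1/Angstrom.
#' @param lambda tolerance factor on the native distance.
#' @return Q in (0, 1).
#' @export
qFraction <- function(conformation, topology, contacts, beta = 5.0, lambda = 1.2) {
  cc <- contacts@contacts
  if (!nrow(cc)) stop("empty native contact set: Q undefined")
  ra <- .residueAtomIndex(topology)
  d <- vapply(seq_len(nrow(cc)), function(r)
    .minResidueDistance(conformation, ra[[cc$i[r]]], ra[[cc$j[r]]]), numeric(1))
  mean(1 / (1 + exp(beta * (d - lambda * cc$d0))))
}

#' Folded-state fraction of an ensemble
#'
#' Fraction of frames whose Q exceeds (strictly) the threshold; 0.6 is used
#' throughout as a system-independent foldedness threshold.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param contacts a \linkS4class{NativeContactSet} from the native
#'   structure.
#' @param qThresh foldedness threshold on Q (default 0.6).
#' @return FSF in [0, 1]; the per-frame Q series is attached as attribute
#'   \code{q}.
#' @export
foldedStateFraction <- function(ensemble, contacts, qThresh = 0.6) {
  top <- ensemble@topology
  q <- vapply(seq_len(nFrames(ensemble)), function(f)
    qFraction(getFrame(ensemble, f), top, contacts), numeric(1))
  structure(mean(q > qThresh), q = q)
}
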