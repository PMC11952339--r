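#' Backbone and side-chain torsion angles of an ensemble
#'
#' Measures phi, psi, omega and chi1-chi4 for every residue in every frame.
#' phi is undefined at the first residue, psi/omega at the last; chi_k is
#' undefined where the residue type defines fewer than k chi angles (ALA and
#' GLY have none). Side-chain chi angles follow the standard IUPAC
#' quadruples; for residues whose side chain is incomplete in the input the
#' affected chi entries are masked invalid.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @return a \linkS4class{TorsionTable}: \code{values} is an
#'   nframes x nresidues x 8 array (phi, psi, omega, chi1..chi4, reserved) in
#'   degrees on (-180, 180], \code{valid} the matching mask.
#' @examples
#' tt <- computeTorsions(buildIdealChain("AKA", preset = "helix"))
#' tt@values[1, 2, 1:2]   # phi, psi of the central residue
#' @export
computeTorsions <- function(ensemble) {
  top <- ensemble@topology
  L <- nResidues(top)
  nf <- nFrames(ensemble)
  idx <- function(i, name) {
    w <- which(top@atomResidue == i & top@atomName == name)
    if (length(w) != 1) NA_integer_ else w
  }
  need <- function(i, name) {
    w <- idx(i, name)
    if (is.na(w))
      stop(sprintf("residue %d (%s) is missing backbone atom %s",
                   i, top@resNames[i], name))
    w
  }
  quads <- matrix(integer(0), 0, 4)
  slot <- integer(0); res <- integer(0)
  for (i in seq_len(L)) {
    Ni <- need(i, "N"); CAi <- need(i, "CA"); Ci <- need(i, "C")
    if (i > 1) {
      quads <- rbind(quads, c(need(i - 1, "C"), Ni, CAi, Ci))
      slot <- c(slot, 1L); res <- c(res, i)
    }
    if (i < L) {
      Nn <- need(i + 1, "N"); CAn <- need(i + 1, "CA")
      quads <- rbind(quads, c(Ni, CAi, Ci, Nn), c(CAi, Ci, Nn, CAn))
      slot <- c(slot, 2L, 3L); res <- c(res, i, i)
    }
    rn <- top@resNames[i]
    for (k in seq_len(.aaChiCount[[rn]])) {
      q <- .chiQuadruple(rn, k)
      w <- vapply(q, function(a) idx(i, a), integer(1))
      if (anyNA(w)) next   # incomplete side chain: stays masked
      quads <- rbind(quads, w)
      slot <- c(slot, 3L + k); res <- c(res, i)
    }
  }
  values <- array(NA_real_, c(nf, L, 8),
                  dimnames = list(NULL, NULL,
                                  c("phi", "psi", "omega", paste0("chi", 1:4), "reserved")))
  valid <- array(FALSE, c(nf, L, 8))
  for (f in seq_len(nf)) {
    X <- getFrame(ensemble, f)
    ang <- dihedralAngle(X[quads[, 1], , drop = FALSE], X[quads[, 2], , drop = FALSE],
                         X[quads[, 3], , drop = FALSE], X[quads[, 4], , drop = FALSE])
    values[cbind(f, res, slot)] <- ang
    valid[cbind(f, res, slot)] <- TRUE
  }
  new("TorsionTable", values = values, valid = valid)
}

# per-frame torsion lists in builder layout, used by fixtures and the relaxer
.torsionsToSpec <- function(tt, frame = 1) {
  v <- tt@values[frame, , , drop = FALSE]
  dim(v) <- dim(v)[2:3]
  list(phi = v[, 1], psi = v[, 2], omega = v[, 3], chi = v[, 4:7, drop = FALSE])
}
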