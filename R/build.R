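# Construction of idealized heavy-atom polypeptides from internal
# coordinates. Bond lengths/angles and side-chain branch geometry come from
# the CCD-derived templates in templates-data.R; backbone torsions and
# side-chain chi angles are free parameters, which makes the builder the
# exact inverse of computeTorsions() and the ground-truth source for every
# synthetic fixture.

#' Topology for a sequence of standard residues
#'
#' Atom order per residue is N, CA, C, O followed by the side chain in
#' template build order, hydrogens excluded.
#'
#' @param sequence character: either a 1-letter string ("AEK...") or a vector
#'   of 3-letter codes.
#' @param chain chain identifier.
#' @return a \linkS4class{Topology}.
#' @export
topologyFromSequence <- function(sequence, chain = "A") {
  resNames <- .asThreeLetter(sequence)
  atomName <- character(0); atomElement <- character(0); atomResidue <- integer(0)
  for (i in seq_along(resNames)) {
    tpl <- .sidechainTemplates[[resNames[i]]]
    nm <- c("N", "CA", "C", "O", tpl$atom)
    el <- c("N", "C", "C", "O", tpl$element)
    atomName <- c(atomName, nm)
    atomElement <- c(atomElement, el)
    atomResidue <- c(atomResidue, rep(i, length(nm)))
  }
  new("Topology", chain = chain, resNames = resNames, atomName = atomName,
      atomElement = atomElement, atomResidue = as.integer(atomResidue))
}

.asThreeLetter <- function(sequence) {
  if (length(sequence) == 1 && !sequence[1] %in% names(.aaChiCount)) {
    codes <- strsplit(toupper(sequence), "")[[1]]
    bad <- !(codes %in% names(.oneToThree))
    if (any(bad))
      stop(sprintf("invalid residue code(s) '%s'; supported: %s",
                   paste(unique(codes[bad]), collapse = ""),
                   paste(names(.oneToThree), collapse = "")))
    unname(.oneToThree[codes])
  } else {
    bad <- !(sequence %in% names(.aaChiCount))
    if (any(bad))
      stop(sprintf("unknown residue name(s): %s; supported codes: %s",
                   paste(unique(sequence[bad]), collapse = ", "),
                   paste(names(.aaChiCount), collapse = ", ")))
    sequence
  }
}

# core internal builder: coordinates from per-residue torsions.
# phi[1], and entries beyond a residue's chi count, are ignored.
.buildCoords <- function(topology, phi, psi, omega, chi) {
  resNames <- topology@resNames
  L <- length(resNames)
  g <- .backboneGeom
  n <- nAtoms(topology)
  xyz <- matrix(NA_real_, n, 3)
  idx <- function(i, name) which(topology@atomResidue == i & topology@atomName == name)
  if (is.null(dim(chi))) chi <- matrix(chi, L, 4, byrow = TRUE)
  for (i in seq_len(L)) {
    if (i == 1) {
      Npos <- c(0, 0, 0)
      CApos <- c(g$bNCa, 0, 0)
      th <- (180 - g$aNCaC) * pi / 180
      Cpos <- CApos + g$bCaC * c(cos(th), sin(th), 0)
    } else {
      Nprev <- xyz[idx(i - 1, "N"), ]; CAprev <- xyz[idx(i - 1, "CA"), ]
      Cprev <- xyz[idx(i - 1, "C"), ]
      Npos <- placeAtom(Nprev, CAprev, Cprev, g$bCN, g$aCaCN, psi[i - 1])
      CApos <- placeAtom(CAprev, Cprev, Npos, g$bNCa, g$aCNCa, omega[i - 1])
      Cpos <- placeAtom(Cprev, Npos, CApos, g$bCaC, g$aNCaC, phi[i])
    }
    xyz[idx(i, "N"), ] <- Npos
    xyz[idx(i, "CA"), ] <- CApos
    xyz[idx(i, "C"), ] <- Cpos
    oTor <- if (i < L) wrapAngle(psi[i] + 180) else 180
    xyz[idx(i, "O"), ] <- placeAtom(Npos, CApos, Cpos, g$bCO, g$aCaCO, oTor)
    tpl <- .sidechainTemplates[[resNames[i]]]
    if (nrow(tpl)) {
      for (r in seq_len(nrow(tpl))) {
        dih <- if (tpl$dihtype[r] == "chi")
          wrapAngle(chi[i, tpl$chik[r]] + tpl$dihval[r]) else tpl$dihval[r]
        xyz[idx(i, tpl$atom[r]), ] <-
          placeAtom(xyz[idx(i, tpl$dref[r]), ], xyz[idx(i, tpl$aref[r]), ],
                    xyz[idx(i, tpl$parent[r]), ], tpl$length[r], tpl$angle[r], dih)
      }
    }
  }
  xyz
}

#' Build an idealized polypeptide chain
#'
#' Constructs a single-frame ensemble with idealized bond lengths and angles,
#' the requested backbone torsions and side-chain rotamers. Peptide C-N bonds
#' are built at the reference mean length (1.348 Angstrom), so freshly built
#' chains carry zero peptide-bond violations by construction.
#'
#' @param sequence 1-letter string or vector of 3-letter codes.
#' @param preset named backbone preset: "helix" (phi = -57, psi = -47) or
#'   "extended" (phi = psi = 180). Ignored when phi/psi are given.
#' @param phi,psi backbone torsions in degrees; scalars are recycled to the
#'   chain length.
#' @param omega peptide-bond torsions (default 180, trans).
#' @param chi L x 4 matrix of side-chain torsions in degrees; NULL uses
#'   common default rotamers (unneeded entries are ignored).
#' @param label ensemble label.
#' @return a 1-frame \linkS4class{Ensemble}; \code{metadata$torsions} records
#'   the torsion specification actually used.
#' @examples
#' helix <- buildIdealChain("AEKLFDAQSMIR", preset = "helix")
#' helix
#' @export
buildIdealChain <- function(sequence, preset = c("helix", "extended"),
                            phi = NULL, psi = NULL, omega = 180, chi = NULL,
                            label = NULL) {
  top <- topologyFromSequence(sequence)
  L <- nResidues(top)
  if (is.null(phi) || is.null(psi)) {
    preset <- match.arg(preset)
    if (preset == "helix") { phi <- -57; psi <- -47 } else { phi <- 180; psi <- 180 }
    if (is.null(label)) label <- preset
  }
  phi <- rep_len(phi, L); psi <- rep_len(psi, L); omega <- rep_len(omega, L)
  if (is.null(chi)) {
    chi <- matrix(NA_real_, L, 4)
    for (i in seq_len(L)) {
      d <- .defaultChis(top@resNames[i])
      if (length(d)) chi[i, seq_along(d)] <- d
    }
  }
  xyz <- .buildCoords(top, phi, psi, omega, chi)
  newEnsemble(top, xyz, label = if (is.null(label)) "ideal" else label,
              metadata = list(torsions = list(phi = phi, psi = psi,
                                              omega = omega, chi = chi)))
}

#' Covalent bond list of a topology
#'
#' Enumerates all covalent heavy-atom bonds: backbone N-CA, CA-C, C-O, the
#' inter-residue peptide C(i)-N(i+1), side-chain tree bonds from the residue
#' templates and ring-closure bonds, each with its idealized reference
#' length.
#'
#' @param topology a \linkS4class{Topology}.
#' @return data.frame with columns ai, aj (atom indices) and length
#'   (reference bond length, Angstrom).
#' @export
topologyBonds <- function(topology) {
  g <- .backboneGeom
  ai <- integer(0); aj <- integer(0); len <- numeric(0)
  idx <- function(i, name) which(topology@atomResidue == i & topology@atomName == name)
  L <- nResidues(topology)
  for (i in seq_len(L)) {
    rn <- topology@resNames[i]
    add <- function(a, b, l) {
      ai <<- c(ai, idx(i, a)); aj <<- c(aj, idx(i, b)); len <<- c(len, l)
    }
    add("N", "CA", g$bNCa); add("CA", "C", g$bCaC); add("C", "O", g$bCO)
    tpl <- .sidechainTemplates[[rn]]
    if (nrow(tpl)) for (r in seq_len(nrow(tpl)))
      add(tpl$parent[r], tpl$atom[r], tpl$length[r])
    cl <- .ringClosures[[rn]]
    if (!is.null(cl)) for (b in cl) add(b[1], b[2], as.numeric(b[3]))
    if (i < L) {
      ai <- c(ai, idx(i, "C")); aj <- c(aj, idx(i + 1, "N")); len <- c(len, g$bCN)
    }
  }
  data.frame(ai = ai, aj = aj, length = len)
}
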