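# Secondary-structure assignment from backbone hydrogen-bond geometry
# (Kabsch-Sander energy criterion with ideal amide-hydrogen placement, since
# the model is hydrogen-free), simplified to three states:
# {H, G, I} -> H, {E, B} -> E, everything else -> C.

# HB[i, j]: C=O of residue i accepts a hydrogen bond from N-H of residue j
.hbondMatrix <- function(X, topology) {
  L <- nResidues(topology)
  idx <- function(i, nm) which(topology@atomResidue == i & topology@atomName == nm)
  Npos <- t(vapply(seq_len(L), function(i) X[idx(i, "N"), ], numeric(3)))
  Cpos <- t(vapply(seq_len(L), function(i) X[idx(i, "C"), ], numeric(3)))
  Opos <- t(vapply(seq_len(L), function(i) X[idx(i, "O"), ], numeric(3)))
  # ideal amide H: 1 Angstrom from N, antiparallel to the preceding C=O
  Hpos <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    co <- Cpos[i - 1, ] - Opos[i - 1, ]
    Hpos[i, ] <- Npos[i, ] + co / sqrt(sum(co^2))
  }
  hb <- matrix(FALSE, L, L)
  q1q2f <- 0.084 * 332   # kcal/mol when distances are in Angstrom
  for (i in seq_len(L)) {        # acceptor C=O of i
    for (j in seq_len(L)) {      # donor N-H of j
      if (abs(i - j) < 2) next
      if (j == 1 || topology@resNames[j] == "PRO") next  # no amide H
      rON <- sqrt(sum((Opos[i, ] - Npos[j, ])^2))
      if (rON > 5.2) next        # beyond any plausible H bond
      rCH <- sqrt(sum((Cpos[i, ] - Hpos[j, ])^2))
      rOH <- sqrt(sum((Opos[i, ] - Hpos[j, ])^2))
      rCN <- sqrt(sum((Cpos[i, ] - Npos[j, ])^2))
      E <- q1q2f * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (E < -0.5) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Three-state secondary structure of one conformation
#'
#' Hydrogen bonds are detected with the standard electrostatic energy
#' criterion (E < -0.5 kcal/mol) using an ideal amide hydrogen constructed
#' 1 Angstrom from N antiparallel to the preceding carbonyl. Helices come
#' from consecutive 3-/4-/5-turns, strands from parallel or antiparallel
#' bridge patterns; 8-state classes collapse to H (helix), E (strand) and C.
#' Chains shorter than 4 residues are all C.
#'
#' @param conformation natoms x 3 coordinate matrix.
#' @param topology the matching \linkS4class{Topology}.
#' @return character vector of per-residue states in {"H", "E", "C"}.
#' @export
assignSse <- function(conformation, topology) {
  L <- nResidues(topology)
  if (L < 4) return(rep("C", L))
  hb <- .hbondMatrix(conformation, topology)
  turn <- function(n) vapply(seq_len(L), function(i)
    i + n <= L && hb[i, i + n], logical(1))
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  helix <- rep(FALSE, L); g310 <- rep(FALSE, L); ppi <- rep(FALSE, L)
  for (i in 2:L) {
    if (t4[i - 1] && t4[i]) helix[i:min(L, i + 3)] <- TRUE
    if (t3[i - 1] && t3[i]) g310[i:min(L, i + 2)] <- TRUE
    if (t5[i - 1] && t5[i]) ppi[i:min(L, i + 4)] <- TRUE
  }
  bridge <- rep(FALSE, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j < i + 3) next
      iOk <- i > 1 && i < L; jOk <- j > 1 && j < L
      par <- (iOk && hb[i - 1, j] && hb[j, i + 1]) ||
             (jOk && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (iOk && jOk && hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridge[c(i, j)] <- TRUE
    }
  }
  out <- rep("C", L)
  out[g310 | ppi] <- "H"
  out[bridge] <- "E"
  out[helix] <- "H"   # alpha helix takes precedence
  out
}

#' Native secondary structure element preservation (SSEP)
#'
#' For each frame, S(x) is the fraction of natively helical (H) or strand (E)
#' residues whose 3-state assignment in the frame equals their native state;
#' SSEP is the mean of S(x) over the ensemble.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param native natoms x 3 matrix of the native structure.
#' @return SSEP in [0, 1]; the per-frame series is attached as attribute
#'   \code{perFrame} and the native assignment as \code{nativeStates}.
#' @export
ssep <- function(ensemble, native) {
  top <- ensemble@topology
  s0 <- assignSse(native, top)
  hot <- which(s0 %in% c("H", "E"))
  if (!length(hot))
    stop("SSEP undefined: the native structure has no residue in an H or E state")
  per <- vapply(seq_len(nFrames(ensemble)), function(f) {
    s <- assignSse(getFrame(ensemble, f), top)
    mean(s[hot] == s0[hot])
  }, numeric(1))
  structure(mean(per), perFrame = per, nativeStates = s0)
}
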