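# Ensemble I/O: multi-model PDB (and optionally DCD trajectories) in,
# multi-model PDB out. Coordinates are Angstrom throughout.

#' Read a conformational ensemble
#'
#' Reads a (multi-model) PDB file, optionally replacing its frames with a
#' binary DCD trajectory sharing the topology. Hydrogens, waters and hetero
#' records are dropped; only blank/'A' alternate locations are kept; a single
#' chain is used (the first, unless named). Frames are subsampled by
#' \code{frameStride} and then truncated to \code{maxFrames}.
#'
#' @param structurePath path to a PDB file (topology; one frame per MODEL).
#' @param trajectoryPath optional path to a DCD trajectory whose atom count
#'   matches the filtered topology.
#' @param temperature optional ensemble temperature, Kelvin.
#' @param frameStride keep every frameStride-th frame (>= 1).
#' @param maxFrames optional cap on the number of frames after striding.
#' @param chain optional chain identifier.
#' @param label ensemble label (defaults to the file name).
#' @return an \linkS4class{Ensemble}.
#' @export
readEnsemble <- function(structurePath, trajectoryPath = NULL,
                         temperature = NA_real_, frameStride = 1L,
                         maxFrames = NULL, chain = NULL, label = NULL) {
  if (!file.exists(structurePath)) stop("structure file not found: ", structurePath)
  if (frameStride < 1) stop("frameStride must be >= 1")
  pdb <- bio3d::read.pdb(structurePath, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  noEl <- is.na(el) | el == ""
  el[noEl] <- substr(gsub("^[0-9]", "", trimws(at$elety[noEl])), 1, 1)
  keep <- at$type == "ATOM" &
    toupper(el) != "H" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    at$resid %in% names(.aaChiCount)
  if (!any(keep)) stop("no protein heavy atoms after filtering")
  chains <- unique(at$chain[keep])
  useChain <- if (is.null(chain)) chains[1] else chain
  keep <- keep & at$chain %in% useChain
  sel <- which(keep)
  resKey <- paste(at$chain[sel], at$resno[sel], at$insert[sel])
  resIdx <- as.integer(factor(resKey, levels = unique(resKey)))
  resNames <- at$resid[sel][!duplicated(resIdx)]
  top <- new("Topology", chain = as.character(useChain), resNames = resNames,
             atomName = trimws(at$elety[sel]),
             atomElement = toupper(el[sel]), atomResidue = resIdx)
  if (is.null(trajectoryPath)) {
    xyzm <- pdb$xyz
    if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  } else {
    if (!grepl("\\.dcd$", trajectoryPath, ignore.case = TRUE))
      stop("unsupported trajectory format (only DCD is read): ", trajectoryPath)
    xyzm <- bio3d::read.dcd(trajectoryPath, verbose = FALSE)
    if (ncol(xyzm) != 3 * nrow(at))
      stop(sprintf("trajectory holds %d atoms but the PDB %d",
                   ncol(xyzm) / 3, nrow(at)))
  }
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  frames <- seq(1, nrow(xyzm), by = frameStride)
  if (!is.null(maxFrames)) frames <- utils::head(frames, maxFrames)
  if (!length(frames)) stop("zero frames after stride/maxFrames filtering")
  coords <- array(NA_real_, c(length(sel), 3, length(frames)))
  for (k in seq_along(frames))
    coords[, , k] <- matrix(xyzm[frames[k], cols], ncol = 3, byrow = TRUE)
  newEnsemble(top, coords, temperature = temperature,
              label = label %||% basename(structurePath))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits MODEL/ENDMDL records even for single-frame ensembles, standard atom
#' naming and occupancy 1.00. Coordinates are written at PDB precision
#' (1e-3 Angstrom), so a read/write round trip is lossless to that
#' precision.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param path output file path.
#' @export
writeEnsemble <- function(ensemble, path) {
  top <- ensemble@topology
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot open path for writing: ", path))
  on.exit(close(con))
  fmtName <- function(nm, el) {
    # columns 13-16: element right-justified in 13-14 for 1-letter symbols
    if (nchar(el) == 1 && nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
  }
  for (f in seq_len(nFrames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- getFrame(ensemble, f)
    lines <- vapply(seq_len(nAtoms(top)), function(a) {
      sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              a, fmtName(top@atomName[a], top@atomElement[a]),
              top@resNames[top@atomResidue[a]], top@chain,
              top@atomResidue[a], X[a, 1], X[a, 2], X[a, 3], 1.00, 0.00,
              top@atomElement[a])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
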