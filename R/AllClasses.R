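#' @import methods
NULL

#' Topology of a heavy-atom protein chain
#'
#' Describes one protein chain: residue names and the atoms belonging to each
#' residue, hydrogens excluded. Backbone connectivity (N-CA-C-O plus the
#' inter-residue C(i)-N(i+1) peptide bond) is implied by the standard atom
#' names and is materialized on demand by \code{\link{topologyBonds}}.
#'
#' @slot chain single chain identifier.
#' @slot resNames character vector of 3-letter residue codes, one per residue.
#' @slot atomName PDB atom names, one per heavy atom.
#' @slot atomElement element symbols, one per heavy atom.
#' @slot atomResidue 1-based residue index of every atom.
#' @export
setClass("Topology", representation(
  chain = "character",
  resNames = "character",
  atomName = "character",
  atomElement = "character",
  atomResidue = "integer"
))

setValidity("Topology", function(object) {
  L <- length(object@resNames)
  n <- length(object@atomName)
  if (length(object@atomElement) != n || length(object@atomResidue) != n)
    return("atom vectors must have equal length")
  if (L == 0) return("topology must contain at least one residue")
  if (!all(sort(unique(object@atomResidue)) == seq_len(L)))
    return("residue indices must be contiguous from 1 and every residue must own atoms")
  bad <- !(object@resNames %in% names(.aaChiCount))
  if (any(bad))
    return(sprintf("unknown residue name(s): %s; supported codes: %s",
                   paste(unique(object@resNames[bad]), collapse = ", "),
                   paste(names(.aaChiCount), collapse = ", ")))
  for (i in seq_len(L)) {
    nm <- object@atomName[object@atomResidue == i]
    if (anyDuplicated(nm)) return(sprintf("duplicate atom names in residue %d", i))
    if (!all(c("N", "CA", "C") %in% nm))
      return(sprintf("residue %d (%s) lacks a backbone atom (needs N, CA, C)",
                     i, object@resNames[i]))
  }
  TRUE
})

#' Conformational ensemble
#'
#' A stack of heavy-atom conformations sharing one \linkS4class{Topology},
#' optionally tagged with a simulation temperature in Kelvin. Coordinates are
#' stored in Angstrom as an natoms x 3 x nframes array.
#'
#' @slot topology a \linkS4class{Topology}.
#' @slot coords numeric array, natoms x 3 x nframes, Angstrom.
#' @slot temperature temperature label in Kelvin, or NA.
#' @slot label free-text ensemble label.
#' @slot metadata list of generator-specific annotations (e.g. ground truth
#'   of synthetic fixtures).
#' @export
setClass("Ensemble", representation(
  topology = "Topology",
  coords = "array",
  temperature = "numeric",
  label = "character",
  metadata = "list"
))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an natoms x 3 x nframes array")
  if (d[1] != length(object@topology@atomName))
    return(sprintf("coords hold %d atoms but topology %d", d[1],
                   length(object@topology@atomName)))
  if (d[3] < 1) return("ensemble must contain at least one frame")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (!is.na(object@temperature) && object@temperature <= 0)
    return("temperature, when set, must be > 0 K")
  TRUE
})

#' Per-frame, per-residue torsion angles
#'
#' @slot values nframes x nresidues x 8 array of angles in degrees on
#'   (-180, 180]; third dimension named phi, psi, omega, chi1..chi4, reserved.
#' @slot valid logical array of the same shape; FALSE marks torsions that do
#'   not exist (chain termini, residues lacking a given chi).
#' @export
setClass("TorsionTable", representation(values = "array", valid = "array"))

setValidity("TorsionTable", function(object) {
  if (!identical(dim(object@values), dim(object@valid)))
    return("values and valid must share a shape")
  if (dim(object@values)[3] != 8) return("third dimension must have size 8")
  v <- object@values[object@valid]
  if (length(v) && (any(v <= -180) || any(v > 180)))
    return("valid angles must lie in (-180, 180]")
  TRUE
})

#' Native contact set
#'
#' Residue pairs (|i - j| >= 3) whose minimal heavy-atom distance in the
#' native structure is at most 10 Angstrom, with that distance stored as the
#' reference d0 of the soft native-contact score Q.
#'
#' @slot contacts data.frame with columns i, j (1-based residue indices) and
#'   d0 (Angstrom).
#' @export
setClass("NativeContactSet", representation(contacts = "data.frame"))

setValidity("NativeContactSet", function(object) {
  cc <- object@contacts
  if (!all(c("i", "j", "d0") %in% names(cc))) return("contacts needs i, j, d0")
  if (nrow(cc)) {
    if (any(abs(cc$i - cc$j) < 3)) return("contacts must be >= 3 residues apart")
    if (any(cc$d0 <= 0) || any(cc$d0 > 10)) return("d0 must be in (0, 10] Angstrom")
  }
  TRUE
})

#' Distance-PCA landscape model
#'
#' @slot featurePairs integer matrix (n x 2) of residue pairs |i-j| >= 2 whose
#'   Calpha distances are the PCA features.
#' @slot mean feature-mean vector.
#' @slot axes nfeatures x 2 matrix of the top-2 principal axes (orthonormal).
#' @slot explainedVariance variances along the two axes, non-increasing.
#' @export
setClass("LandscapeModel", representation(
  featurePairs = "matrix", mean = "numeric", axes = "matrix",
  explainedVariance = "numeric"
))

setValidity("LandscapeModel", function(object) {
  if (ncol(object@axes) != 2) return("axes must have 2 columns")
  G <- crossprod(object@axes)
  if (max(abs(G - diag(2))) > 1e-6) return("axes must be orthonormal")
  ev <- object@explainedVariance
  if (length(ev) != 2 || any(ev < 0) || ev[1] < ev[2] - 1e-12)
    return("explainedVariance must be 2 non-negative, non-increasing values")
  TRUE
})

#' Binned free-energy surface
#'
#' @slot xEdges,yEdges bin edges (length nbins + 1, monotone).
#' @slot G energy matrix relative to the minimum (unmasked minimum is 0).
#' @slot mask logical matrix; TRUE marks empty bins (infinite free energy).
#' @slot units either "kJ/mol" or "RT".
#' @export
setClass("FreeEnergyGrid", representation(
  xEdges = "numeric", yEdges = "numeric", G = "matrix", mask = "matrix",
  units = "character"
))

#' Observable-versus-temperature series
#'
#' @slot temperatures strictly increasing temperatures, Kelvin.
#' @slot values observable values in [0, 1].
#' @slot observable which foldedness observable, "FSF" or "SSEP".
#' @export
setClass("MeltSeries", representation(
  temperatures = "numeric", values = "numeric", observable = "character"
))

setValidity("MeltSeries", function(object) {
  if (length(object@temperatures) != length(object@values))
    return("temperatures and values must have equal length")
  if (length(object@temperatures) < 4) return("a melt series needs >= 4 points")
  if (any(diff(object@temperatures) <= 0))
    return("temperatures must be strictly increasing and unique")
  if (!object@observable %in% c("FSF", "SSEP")) return("observable must be FSF or SSEP")
  TRUE
})

#' Fitted melting sigmoid
#'
#' Parameters of f(T) = ymin + (ymax - ymin) / (1 + exp(-(T - tm)/k)),
#' with ymin/ymax fixed to the series extremes and (tm, k) fitted by
#' nonlinear least squares. A decreasing observable yields a negative k.
#'
#' @slot tm apparent melting temperature, Kelvin.
#' @slot kSlope slope parameter, Kelvin (sign encodes orientation).
#' @slot yMin,yMax series extremes used as fixed asymptotes.
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical convergence flag.
#' @export
setClass("MeltFit", representation(
  tm = "numeric", kSlope = "numeric", yMin = "numeric", yMax = "numeric",
  rss = "numeric", converged = "logical"
))

#' Stereochemical integrity summary
#'
#' @slot clashesPerFrame,violationsPerFrame per-frame counts.
#' @slot worstOffenders data.frame (frame, atom_i, atom_j, distance) of the
#'   tightest clashing pairs.
#' @export
setClass("IntegrityReport", representation(
  clashesPerFrame = "numeric", violationsPerFrame = "numeric",
  worstOffenders = "data.frame"
))

#' Configuration of the restrained clash-relaxation protocol
#'
#' @slot maxIterations optimizer iteration cap.
#' @slot forceTolerance projected-gradient tolerance (energy/Angstrom).
#' @slot restraintKTorsion harmonic constant tethering phi/psi/chi to their
#'   input values, energy/deg^2.
#' @slot restraintKCa harmonic constant tethering adjacent Calpha-Calpha
#'   distances to their input values, energy/Angstrom^2.
#' @slot repulsionEnabled whether the soft steric repulsion term is active.
#' @slot repulsionScale fraction of the van der Waals contact distance below
#'   which repulsion engages, in (0, 1).
#' @export
setClass("RelaxConfig", representation(
  maxIterations = "numeric", forceTolerance = "numeric",
  restraintKTorsion = "numeric", restraintKCa = "numeric",
  repulsionEnabled = "logical", repulsionScale = "numeric"
))

setValidity("RelaxConfig", function(object) {
  if (object@restraintKTorsion < 0 || object@restraintKCa < 0)
    return("force constants must be >= 0")
  if (object@repulsionScale <= 0 || object@repulsionScale >= 1)
    return("repulsionScale must be in (0, 1)")
  TRUE
})

#' Nested report of every ensemble-comparison metric
#'
#' @slot meta run metadata (schema version, inputs, seed, timestamp).
#' @slot scalar named list of scalar scores.
#' @slot profiles named list of per-residue or per-frame series.
#' @slot histograms named list of matrices/tables (contact maps, chi-pair
#'   histograms, free-energy grids).
#' @slot warnings character vector of warnings raised while scoring.
#' @export
setClass("MetricReport", representation(
  meta = "list", scalar = "list", profiles = "list", histograms = "list",
  warnings = "character"
))

## ---- show methods ----

#' @export
setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: chain %s, %d residues, %d heavy atoms\n",
              object@chain, length(object@resNames), length(object@atomName)))
  cat("  sequence:", paste(.threeToOne[object@resNames], collapse = ""), "\n")
})

#' @export
setMethod("show", "Ensemble", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Ensemble '%s': %d frames, %d residues, %d heavy atoms",
              object@label, d[3], length(object@topology@resNames), d[1]))
  if (!is.na(object@temperature)) cat(sprintf(", %.1f K", object@temperature))
  cat("\n")
})

#' @export
setMethod("show", "MeltFit", function(object) {
  cat(sprintf("MeltFit: Tm = %.2f K, k = %.2f K, y in [%.3f, %.3f], rss = %.3g (%s)\n",
              object@tm, object@kSlope, object@yMin, object@yMax, object@rss,
              if (object@converged) "converged" else "NOT converged"))
})

#' @export
setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n  scalars:\n")
  for (nm in names(object@scalar))
    cat(sprintf("    %-16s %s\n", nm, format(object@scalar[[nm]], digits = 5)))
  cat(sprintf("  profiles: %s\n", paste(names(object@profiles), collapse = ", ")))
  cat(sprintf("  histograms: %s\n", paste(names(object@histograms), collapse = ", ")))
  if (length(object@warnings)) cat("  warnings:", length(object@warnings), "\n")
})

## ---- accessors ----

#' @rdname ensemble-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname ensemble-accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname ensemble-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname ensemble-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname ensemble-accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))
#' @rdname ensemble-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Accessors for Ensemble objects
#'
#' @param x an \linkS4class{Ensemble} (or \linkS4class{Topology}).
#' @param i frame index.
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])
#' @rdname ensemble-accessors
setMethod("nResidues", "Ensemble", function(x) length(x@topology@resNames))
#' @rdname ensemble-accessors
setMethod("nResidues", "Topology", function(x) length(x@resNames))
#' @rdname ensemble-accessors
setMethod("nAtoms", "Ensemble", function(x) dim(x@coords)[1])
#' @rdname ensemble-accessors
setMethod("nAtoms", "Topology", function(x) length(x@atomName))
#' @rdname ensemble-accessors
setMethod("getFrame", "Ensemble", function(x, i) {
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})
#' @rdname ensemble-accessors
setMethod("temperature", "Ensemble", function(x) x@temperature)
#' @rdname ensemble-accessors
setMethod("topology", "Ensemble", function(x) x@topology)

#' Subset frames of an ensemble
#'
#' @param x an Ensemble.
#' @param i frame indices to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "Ensemble", function(x, i, j, ..., drop = FALSE) {
  newEnsemble(x@topology, x@coords[, , i, drop = FALSE],
              temperature = x@temperature, label = x@label,
              metadata = x@metadata)
})

#' Construct an Ensemble
#'
#' @param topology a \linkS4class{Topology}.
#' @param coords natoms x 3 x nframes array, or an natoms x 3 matrix for a
#'   single frame.
#' @param temperature optional temperature, Kelvin.
#' @param label ensemble label.
#' @param metadata optional annotation list.
#' @return an \linkS4class{Ensemble}.
#' @export
newEnsemble <- function(topology, coords, temperature = NA_real_,
                        label = "ensemble", metadata = list()) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  new("Ensemble", topology = topology, coords = coords,
      temperature = as.numeric(temperature), label = label, metadata = metadata)
}

#' Default relaxation configuration
#'
#' @param maxIterations iteration cap of the L-BFGS optimizer.
#' @param forceTolerance projected-gradient stopping tolerance.
#' @param restraintKTorsion torsion restraint constant, energy/deg^2.
#' @param restraintKCa adjacent Calpha distance restraint, energy/Angstrom^2.
#' @param repulsionEnabled enable the soft steric repulsion term.
#' @param repulsionScale repulsion onset as a fraction of the vdW contact
#'   distance.
#' @return a \linkS4class{RelaxConfig}.
#' @export
relaxConfig <- function(maxIterations = 200, forceTolerance = 1e-3,
                        restraintKTorsion = 0.02, restraintKCa = 20,
                        repulsionEnabled = TRUE, repulsionScale = 0.7) {
  new("RelaxConfig", maxIterations = maxIterations,
      forceTolerance = forceTolerance, restraintKTorsion = restraintKTorsion,
      restraintKCa = restraintKCa, repulsionEnabled = repulsionEnabled,
      repulsionScale = repulsionScale)
}
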