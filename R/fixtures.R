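# Seeded generators of synthetic ensembles with known ground truth. These
# emulate the phenomenology the scores are designed to detect -- two-state
# folding with a logistic folded probability in temperature, categorical
# rotamer-bin sampling, torsion jitter, injected steric/bond defects --
# without pretending to be physically realistic unfolded-state models.

.nativeTorsionSpec <- function(native) {
  if (!is.null(native@metadata$torsions)) return(native@metadata$torsions)
  .torsionsToSpec(computeTorsions(native), 1)
}

.jitterSpec <- function(spec, sd, L) {
  phi <- spec$phi + stats::rnorm(L, 0, sd)
  psi <- spec$psi + stats::rnorm(L, 0, sd)
  chi <- spec$chi
  ok <- !is.na(chi)
  chi[ok] <- chi[ok] + stats::rnorm(sum(ok), 0, sd)
  list(phi = wrapAngle(phi), psi = wrapAngle(psi), omega = spec$omega,
       chi = chi)
}

.randomCoilSpec <- function(spec, L) {
  chi <- spec$chi
  ok <- !is.na(chi)
  chi[ok] <- stats::runif(sum(ok), -180, 180)
  list(phi = stats::runif(L, -180, 180), psi = stats::runif(L, -180, 180),
       omega = spec$omega, chi = chi)
}

#' Ensemble of torsion-jittered copies of a native structure
#'
#' Adds independent Gaussian noise (degrees) to every defined phi/psi/chi of
#' the native torsion specification and rebuilds the chain with ideal
#' geometry.
#'
#' @param native 1-frame \linkS4class{Ensemble} (typically from
#'   \code{\link{buildIdealChain}}).
#' @param sigma torsion jitter standard deviation, degrees.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return an \linkS4class{Ensemble}.
#' @export
torsionJitterEnsemble <- function(native, sigma = 5, nFrames = 100, seed = 1) {
  set.seed(seed)
  top <- native@topology
  L <- nResidues(top)
  spec <- .nativeTorsionSpec(native)
  coords <- array(NA_real_, c(nAtoms(top), 3, nFrames))
  for (f in seq_len(nFrames)) {
    s <- .jitterSpec(spec, sigma, L)
    coords[, , f] <- .buildCoords(top, s$phi, s$psi, s$omega, s$chi)
  }
  newEnsemble(top, coords, label = "torsion_jitter")
}

#' Ensemble with isotropic Gaussian coordinate noise
#'
#' Adds i.i.d. N(0, sigma) displacement to every Cartesian coordinate of the
#' native structure, per frame; the expected per-atom RMSF is sigma * sqrt(3).
#'
#' @param native 1-frame \linkS4class{Ensemble}.
#' @param sigma per-coordinate noise standard deviation, Angstrom.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return an \linkS4class{Ensemble}.
#' @export
gaussianNoiseEnsemble <- function(native, sigma = 0.5, nFrames = 2000, seed = 1) {
  set.seed(seed)
  X0 <- getFrame(native, 1)
  n <- nrow(X0)
  coords <- array(stats::rnorm(n * 3 * nFrames, 0, sigma), c(n, 3, nFrames))
  coords <- coords + as.vector(X0)
  newEnsemble(native@topology, coords, label = "gaussian_noise")
}

#' Two-state folded/unfolded ensemble with logistic folded probability
#'
#' Each frame is independently folded with probability
#' p(T) = 1 / (1 + exp((T - trueTm)/trueK)). Folded frames are rebuilt from
#' the native torsions with 5-degree jitter; unfolded frames are randomized
#' phi/psi/chi rebuilds, self-avoiding by rejection (clash count <= 5 within
#' 100 retries, best-effort otherwise). The realized folded count is recorded
#' in \code{metadata$foldedCount} / \code{metadata$foldedMask}.
#'
#' @param native 1-frame \linkS4class{Ensemble}.
#' @param temperature ensemble temperature, Kelvin.
#' @param trueTm ground-truth melting temperature, Kelvin.
#' @param trueK ground-truth transition width, Kelvin (> 0).
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @param jitterSd torsion jitter of folded frames, degrees.
#' @return an \linkS4class{Ensemble} with temperature label and ground-truth
#'   metadata.
#' @export
twoStateEnsemble <- function(native, temperature, trueTm = 400, trueK = 20,
                             nFrames = 200, seed = 1, jitterSd = 5) {
  if (trueK <= 0) stop("trueK must be > 0")
  set.seed(seed)
  top <- native@topology
  L <- nResidues(top)
  spec <- .nativeTorsionSpec(native)
  p <- 1 / (1 + exp((temperature - trueTm) / trueK))
  folded <- stats::runif(nFrames) < p
  coords <- array(NA_real_, c(nAtoms(top), 3, nFrames))
  for (f in seq_len(nFrames)) {
    if (folded[f]) {
      s <- .jitterSpec(spec, jitterSd, L)
      coords[, , f] <- .buildCoords(top, s$phi, s$psi, s$omega, s$chi)
    } else {
      best <- NULL; bestClashes <- Inf
      for (try in seq_len(100)) {
        s <- .randomCoilSpec(spec, L)
        X <- .buildCoords(top, s$phi, s$psi, s$omega, s$chi)
        nc <- countHeavyClashes(X, top)
        if (nc < bestClashes) { best <- X; bestClashes <- nc }
        if (nc <= 5) break
      }
      coords[, , f] <- best
    }
  }
  newEnsemble(top, coords, temperature = temperature, label = "two_state",
              metadata = list(foldedCount = sum(folded), foldedMask = folded,
                              trueTm = trueTm, trueK = trueK,
                              foldedProbability = p))
}

#' Rotamer-bin categorical ensemble
#'
#' Samples side-chain chi angles so that consecutive chi-pair observations
#' follow prescribed 3 x 3 torus-bin probability tables: the (chi1, chi2)
#' cell is drawn from its table, later chis are drawn from the row of their
#' table conditional on the previous chi's bin (exact when the tables are
#' consistent, e.g. point masses or products). Angles are uniform inside the
#' chosen 120-degree bin; the backbone is a fixed extended chain.
#'
#' @param sequence 1-letter string or vector of 3-letter codes.
#' @param binTables list over residue indices; each entry a list of 3 x 3
#'   probability matrices, one per chi pair (1,2), (2,3), (3,4) the residue
#'   type defines. Residues without an entry use default rotamers.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return an \linkS4class{Ensemble}.
#' @export
rotamerEnsemble <- function(sequence, binTables, nFrames = 100, seed = 1) {
  set.seed(seed)
  native <- buildIdealChain(sequence, preset = "extended")
  top <- native@topology
  L <- nResidues(top)
  spec <- .nativeTorsionSpec(native)
  binLo <- c(-120, 0, 120)   # bin index b covers [binLo[b], binLo[b] + 120)
  sampleInBin <- function(b) wrapAngle(stats::runif(1, binLo[b], binLo[b] + 120))
  coords <- array(NA_real_, c(nAtoms(top), 3, nFrames))
  for (f in seq_len(nFrames)) {
    chi <- spec$chi
    for (i in seq_len(L)) {
      tabs <- if (i <= length(binTables)) binTables[[i]] else NULL
      if (is.null(tabs)) next
      nchi <- .aaChiCount[[top@resNames[i]]]
      if (nchi < 2) next
      T12 <- tabs[[1]]
      if (abs(sum(T12) - 1) > 1e-9) stop("bin tables must sum to 1")
      cell <- sample(9, 1, prob = as.vector(T12))
      b1 <- (cell - 1) %% 3 + 1; b2 <- (cell - 1) %/% 3 + 1
      # as.vector(matrix) is column-major: rows = chi_j bin, cols = chi_k bin
      chi[i, 1] <- sampleInBin(b1); chi[i, 2] <- sampleInBin(b2)
      prevBin <- b2
      for (j in seq_len(nchi - 2)) {
        Tj <- tabs[[j + 1]]
        row <- Tj[prevBin, ]
        pr <- if (sum(row) > 0) row / sum(row) else rep(1 / 3, 3)
        b <- sample(3, 1, prob = pr)
        chi[i, j + 2] <- sampleInBin(b)
        prevBin <- b
      }
    }
    coords[, , f] <- .buildCoords(top, spec$phi, spec$psi, spec$omega, chi)
  }
  newEnsemble(top, coords, label = "rotamer_categorical")
}

#' Inject steric clashes and peptide-bond stretches into an ensemble
#'
#' Clash specs move one named side-chain/backbone atom along the line towards
#' a target atom of a distant residue to a prescribed distance; the generator
#' verifies that exactly one new clashing pair results (and errors
#' otherwise, or when the target pair is from adjacent residues, which the
#' clash counter would ignore). Stretch specs set one inter-residue
#' C(i)-N(i+1) bond to a target length by rigidly translating the downstream
#' residues.
#'
#' @param ensemble input \linkS4class{Ensemble} (modified copy returned).
#' @param clashSpecs list of lists with fields \code{frame}, \code{i},
#'   \code{atomI}, \code{j}, \code{atomJ}, \code{distance} (Angstrom; atom J
#'   is moved).
#' @param stretchSpecs list of lists with fields \code{frame}, \code{bond}
#'   (residue index i of the C(i)-N(i+1) bond) and \code{length} (Angstrom).
#' @param radii vdW radii used for the cleanliness verification.
#' @return the modified \linkS4class{Ensemble}; \code{metadata$defectManifest}
#'   holds per-frame expected increments of the two integrity counters.
#' @export
injectDefects <- function(ensemble, clashSpecs = list(), stretchSpecs = list(),
                          radii = defaultVdwTable(), cleanMargin = 0.2) {
  top <- ensemble@topology
  coords <- ensemble@coords
  nf <- dim(coords)[3]
  clashInc <- integer(nf); violInc <- integer(nf)
  idx <- function(i, nm) which(top@atomResidue == i & top@atomName == nm)
  r <- unname(radii[top@atomElement])
  clashPairSet <- function(X) {
    D <- as.matrix(stats::dist(X))
    sep <- abs(outer(top@atomResidue, top@atomResidue, "-"))
    thr <- 0.5 * outer(r, r, "+")
    w <- which(D < thr & sep >= 2 & upper.tri(D), arr.ind = TRUE)
    paste(w[, 1], w[, 2])
  }
  basePairs <- lapply(seq_len(nf), function(f) clashPairSet(coords[, , f]))
  intended <- lapply(seq_len(nf), function(f) character(0))
  touched <- integer(0)   # atoms moved or used as anchors so far
  for (sp in clashSpecs) {
    f <- sp$frame %||% 1L
    if (abs(sp$i - sp$j) < 2)
      stop("clash spec targets adjacent residues; such pairs are not counted")
    ai <- idx(sp$i, sp$atomI); aj <- idx(sp$j, sp$atomJ)
    if (length(ai) != 1 || length(aj) != 1) stop("clash spec names an unknown atom")
    if (any(c(ai, aj) %in% touched))
      stop("clash specs must not reuse an atom already involved in an injection")
    if (sp$distance >= 0.5 * (r[ai] + r[aj]))
      stop("clash spec distance does not fall below the clash threshold")
    X <- coords[, , f]
    # candidate approach directions: the original one plus a fixed grid;
    # deterministically choose the first placement that clashes with the
    # intended partner only and clears every other atom by cleanMargin
    u0 <- X[aj, ] - X[ai, ]
    u0 <- u0 / sqrt(sum(u0^2))
    grid <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1)))
    grid <- grid[rowSums(grid^2) > 0, ]
    dirs <- rbind(u0, grid / sqrt(rowSums(grid^2)))
    sep <- abs(top@atomResidue - top@atomResidue[aj])
    cand <- setdiff(which(sep >= 2), ai)
    placed <- FALSE
    for (di in seq_len(nrow(dirs))) {
      pos <- X[ai, ] + dirs[di, ] * sp$distance
      d <- sqrt(rowSums((X[cand, , drop = FALSE] -
                         matrix(pos, length(cand), 3, byrow = TRUE))^2))
      if (all(d >= 0.5 * (r[cand] + r[aj]) + cleanMargin)) {
        X[aj, ] <- pos; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("injected clash is not clean: no approach direction yields exactly one new clashing pair")
    coords[, , f] <- X
    clashInc[f] <- clashInc[f] + 1L
    intended[[f]] <- c(intended[[f]], paste(min(ai, aj), max(ai, aj)))
    touched <- c(touched, ai, aj)
  }
  for (sp in stretchSpecs) {
    f <- sp$frame %||% 1L
    i <- sp$bond
    if (i < 1 || i >= nResidues(top)) stop("stretch spec bond index out of range")
    ci <- idx(i, "C"); ni <- idx(i + 1, "N")
    X <- coords[, , f]
    u <- X[ni, ] - X[ci, ]
    old <- sqrt(sum(u^2))
    u <- u / old
    shift <- (sp$length - old) * u
    down <- which(top@atomResidue > i)
    X[down, ] <- X[down, ] + matrix(shift, length(down), 3, byrow = TRUE)
    coords[, , f] <- X
    wasViol <- abs(old - .peptideBondMean) / .peptideBondSd >= 3.0
    isViol <- abs(sp$length - .peptideBondMean) / .peptideBondSd >= 3.0
    violInc[f] <- violInc[f] + (isViol - wasViol)
  }
  # final verification: the clash set must be exactly base + intended pairs
  # (a stretch translation could otherwise silently tip a near-threshold
  # pair over the edge)
  for (f in seq_len(nf)) {
    got <- clashPairSet(coords[, , f])
    want <- c(basePairs[[f]], intended[[f]])
    if (!setequal(got, want))
      stop(sprintf("injection produced an inconsistent clash set in frame %d", f))
  }
  newEnsemble(top, coords, temperature = ensemble@temperature,
              label = ensemble@label,
              metadata = c(ensemble@metadata,
                           list(defectManifest = list(clashIncrement = clashInc,
                                                      violationIncrement = violInc))))
}
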