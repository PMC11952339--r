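# Restrained clash relaxation: per-frame minimization of a reduced bonded
# energy (harmonic bonds and angles, planarity/chirality torsion terms) plus
# harmonic restraints tethering phi/psi/chi1-4 (circular difference) and
# adjacent Calpha-Calpha distances to their input values, plus an optional
# soft half-quadratic steric repulsion. The goal is the protocol contract --
# remove heavy clashes while perturbing the restrained features and the
# backbone as little as possible -- not a full force field.

.kBond <- 300      # energy/A^2
.kAngle <- 80      # energy/rad^2
.kPlanar <- 40     # energy/rad^2
.kRepulsion <- 15  # energy/A^2 (soft: restraints must dominate clash-free frames)

# term bundle for one topology + one input frame
.relaxTerms <- function(topology, X0, config, idealAngles, bonds) {
  L <- nResidues(topology)
  idx <- function(i, nm) which(topology@atomResidue == i & topology@atomName == nm)
  torDeg2 <- (180 / pi)^2
  kTor <- config@restraintKTorsion * torDeg2   # energy/rad^2
  tt <- computeTorsions(newEnsemble(topology, X0))
  spec <- .torsionsToSpec(tt, 1)
  quads <- matrix(integer(0), 0, 4); targets <- numeric(0); ks <- numeric(0)
  addDih <- function(q, targetDeg, k) {
    quads <<- rbind(quads, q)
    targets <<- c(targets, targetDeg * pi / 180)
    ks <<- c(ks, k)
  }
  for (i in seq_len(L)) {
    Ni <- idx(i, "N"); CAi <- idx(i, "CA"); Ci <- idx(i, "C"); Oi <- idx(i, "O")
    if (i > 1) addDih(c(idx(i - 1, "C"), Ni, CAi, Ci), spec$phi[i], kTor)
    if (i < L) {
      addDih(c(Ni, CAi, Ci, idx(i + 1, "N")), spec$psi[i], kTor)
      addDih(c(CAi, Ci, idx(i + 1, "N"), idx(i + 1, "CA")), spec$omega[i], kTor)
    }
    # carbonyl planarity: O stays anti to the following N
    oTarget <- if (i < L) wrapAngle(spec$psi[i] + 180) else
      dihedralAngle(X0[Ni, ], X0[CAi, ], X0[Ci, ], X0[Oi, ])
    addDih(c(Ni, CAi, Ci, Oi), oTarget, .kPlanar)
    rn <- topology@resNames[i]
    nchi <- .aaChiCount[[rn]]
    canonical <- character(0)
    for (k in seq_len(nchi)) {
      q <- .chiQuadruple(rn, k)
      canonical <- c(canonical, q[4])
      addDih(vapply(q, function(a) idx(i, a), integer(1)), spec$chi[i, k], kTor)
    }
    tpl <- .sidechainTemplates[[rn]]
    if (nrow(tpl)) for (r in seq_len(nrow(tpl))) {
      if (tpl$dihtype[r] == "chi" && tpl$atom[r] %in% canonical) next
      target <- if (tpl$dihtype[r] == "chi")
        wrapAngle(spec$chi[i, tpl$chik[r]] + tpl$dihval[r]) else tpl$dihval[r]
      addDih(c(idx(i, tpl$dref[r]), idx(i, tpl$aref[r]),
               idx(i, tpl$parent[r]), idx(i, tpl$atom[r])), target, .kPlanar)
    }
  }
  ca <- .caIndices(topology)
  caPairs <- cbind(ca[-length(ca)], ca[-1])
  caTargets <- sqrt(rowSums((X0[caPairs[, 1], , drop = FALSE] -
                             X0[caPairs[, 2], , drop = FALSE])^2))
  radii <- unname(defaultVdwTable()[topology@atomElement])
  sep <- abs(outer(topology@atomResidue, topology@atomResidue, "-"))
  repPairs <- which(sep >= 2 & upper.tri(sep), arr.ind = TRUE)
  repOnset <- config@repulsionScale *
    (radii[repPairs[, 1]] + radii[repPairs[, 2]])
  list(bonds = bonds, angles = idealAngles,
       dih = list(quads = quads, targets = targets, ks = ks),
       caPairs = caPairs, caTargets = caTargets, kCa = config@restraintKCa,
       repPairs = repPairs, repOnset = repOnset,
       repulsion = config@repulsionEnabled)
}

# bonded-angle triple list with ideal values measured on an ideal-geometry
# build of the same sequence (bond angles are torsion-independent)
.idealAngleTerms <- function(topology, bonds) {
  adj <- vector("list", nAtoms(topology))
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$ai[r]]] <- c(adj[[bonds$ai[r]]], bonds$aj[r])
    adj[[bonds$aj[r]]] <- c(adj[[bonds$aj[r]]], bonds$ai[r])
  }
  trip <- matrix(integer(0), 0, 3)
  for (b in seq_along(adj)) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    trip <- rbind(trip, cbind(cmb[1, ], b, cmb[2, ]))
  }
  ideal <- buildIdealChain(topology@resNames)
  Xi <- getFrame(ideal, 1)
  vals <- bondAngle(Xi[trip[, 1], , drop = FALSE], Xi[trip[, 2], , drop = FALSE],
                    Xi[trip[, 3], , drop = FALSE]) * pi / 180
  list(trip = trip, theta0 = vals)
}

.relaxEnergyGrad <- function(x, terms, wantGrad = TRUE) {
  X <- matrix(x, ncol = 3)
  G <- if (wantGrad) matrix(0, nrow(X), 3) else NULL
  E <- 0
  addG <- function(ix, g) G[ix, ] <<- G[ix, ] + g
  # bonds
  b <- terms$bonds
  d <- X[b$ai, , drop = FALSE] - X[b$aj, , drop = FALSE]
  dist <- sqrt(rowSums(d * d))
  dev <- dist - b$length
  E <- E + .kBond * sum(dev^2)
  if (wantGrad) {
    f <- 2 * .kBond * dev / dist
    gv <- d * f
    for (r in seq_len(nrow(b))) {
      G[b$ai[r], ] <- G[b$ai[r], ] + gv[r, ]
      G[b$aj[r], ] <- G[b$aj[r], ] - gv[r, ]
    }
  }
  # angles
  tr <- terms$angles$trip; th0 <- terms$angles$theta0
  u <- X[tr[, 1], , drop = FALSE] - X[tr[, 2], , drop = FALSE]
  v <- X[tr[, 3], , drop = FALSE] - X[tr[, 2], , drop = FALSE]
  nu <- .rownorm(u); nv <- .rownorm(v)
  cth <- pmin(1, pmax(-1, .rowdot(u, v) / (nu * nv)))
  th <- acos(cth)
  dev <- th - th0
  E <- E + .kAngle * sum(dev^2)
  if (wantGrad) {
    sth <- pmax(sqrt(1 - cth^2), 1e-8)
    uh <- u / nu; vh <- v / nv
    dthA <- (uh * cth - vh) / (nu * sth)
    dthC <- (vh * cth - uh) / (nv * sth)
    coefA <- 2 * .kAngle * dev
    for (r in seq_len(nrow(tr))) {
      gA <- coefA[r] * dthA[r, ]; gC <- coefA[r] * dthC[r, ]
      G[tr[r, 1], ] <- G[tr[r, 1], ] + gA
      G[tr[r, 3], ] <- G[tr[r, 3], ] + gC
      G[tr[r, 2], ] <- G[tr[r, 2], ] - gA - gC
    }
  }
  # dihedral restraints (circular difference)
  q <- terms$dih$quads
  if (nrow(q)) {
    A <- X[q[, 1], , drop = FALSE]; B <- X[q[, 2], , drop = FALSE]
    C <- X[q[, 3], , drop = FALSE]; D <- X[q[, 4], , drop = FALSE]
    b1 <- B - A; b2 <- C - B; b3 <- D - C
    n1 <- .rowcross(b1, b2); n2 <- .rowcross(b2, b3)
    nb2 <- .rownorm(b2)
    m1 <- .rowcross(n1, b2 / nb2)
    phi <- atan2(.rowdot(m1, n2), .rowdot(n1, n2))
    dev <- (phi - terms$dih$targets + pi) %% (2 * pi) - pi
    E <- E + sum(terms$dih$ks * dev^2)
    if (wantGrad) {
      n1sq <- pmax(.rowdot(n1, n1), 1e-12); n2sq <- pmax(.rowdot(n2, n2), 1e-12)
      dA <- n1 * (nb2 / n1sq)
      dD <- -n2 * (nb2 / n2sq)
      c1 <- .rowdot(b1, b2) / nb2^2
      c2 <- .rowdot(b3, b2) / nb2^2
      dB <- -dA * (1 + c1) + dD * c2
      dC <- dA * c1 - dD * (1 + c2)
      coef <- 2 * terms$dih$ks * dev
      for (r in seq_len(nrow(q))) {
        G[q[r, 1], ] <- G[q[r, 1], ] + coef[r] * dA[r, ]
        G[q[r, 2], ] <- G[q[r, 2], ] + coef[r] * dB[r, ]
        G[q[r, 3], ] <- G[q[r, 3], ] + coef[r] * dC[r, ]
        G[q[r, 4], ] <- G[q[r, 4], ] + coef[r] * dD[r, ]
      }
    }
  }
  # adjacent Calpha-Calpha restraints
  cp <- terms$caPairs
  d <- X[cp[, 1], , drop = FALSE] - X[cp[, 2], , drop = FALSE]
  dist <- .rownorm(d)
  dev <- dist - terms$caTargets
  E <- E + terms$kCa * sum(dev^2)
  if (wantGrad) {
    f <- 2 * terms$kCa * dev / dist
    gv <- d * f
    for (r in seq_len(nrow(cp))) {
      G[cp[r, 1], ] <- G[cp[r, 1], ] + gv[r, ]
      G[cp[r, 2], ] <- G[cp[r, 2], ] - gv[r, ]
    }
  }
  # soft steric repulsion
  if (terms$repulsion) {
    rp <- terms$repPairs
    d <- X[rp[, 1], , drop = FALSE] - X[rp[, 2], , drop = FALSE]
    dist <- .rownorm(d)
    pen <- terms$repOnset - dist
    act <- which(pen > 0)
    if (length(act)) {
      E <- E + .kRepulsion * sum(pen[act]^2)
      if (wantGrad) {
        f <- -2 * .kRepulsion * pen[act] / dist[act]
        for (kk in seq_along(act)) {
          r <- act[kk]
          gv <- f[kk] * d[r, ]
          G[rp[r, 1], ] <- G[rp[r, 1], ] + gv
          G[rp[r, 2], ] <- G[rp[r, 2], ] - gv
        }
      }
    }
  }
  list(E = E, G = G)
}

#' Restrained relaxation of an ensemble
#'
#' Minimizes, per frame, a reduced bonded energy plus harmonic restraints on
#' phi/psi/chi1-4 and adjacent Calpha-Calpha distances (tethered to their
#' input-frame values) and a soft steric repulsion between heavy atoms of
#' non-adjacent residues, using L-BFGS-B with analytic gradients. Frames
#' whose minimization yields a non-finite energy, a higher energy or more
#' clashes than the input are returned unmodified and flagged.
#'
#' @param ensemble input \linkS4class{Ensemble}.
#' @param config a \linkS4class{RelaxConfig} (see \code{\link{relaxConfig}}).
#' @return list with \code{ensemble} (relaxed) and \code{diagnostics}, a
#'   data.frame with per-frame clashesBefore, clashesAfter, caRmsdShift
#'   (Angstrom), iterations, energy and modified flag.
#' @export
relaxEnsemble <- function(ensemble, config = relaxConfig()) {
  top <- ensemble@topology
  bonds <- topologyBonds(top)
  angles <- .idealAngleTerms(top, bonds)
  nf <- nFrames(ensemble)
  out <- ensemble@coords
  ca <- .caIndices(top)
  diag <- data.frame(clashesBefore = numeric(nf), clashesAfter = numeric(nf),
                     caRmsdShift = numeric(nf), iterations = integer(nf),
                     energy = numeric(nf), modified = logical(nf))
  for (f in seq_len(nf)) {
    X0 <- getFrame(ensemble, f)
    before <- countHeavyClashes(X0, top)
    terms <- .relaxTerms(top, X0, config, angles, bonds)
    fn <- function(x) .relaxEnergyGrad(x, terms, wantGrad = FALSE)$E
    gr <- function(x) as.vector(.relaxEnergyGrad(x, terms, wantGrad = TRUE)$G)
    e0 <- fn(as.vector(X0))
    opt <- tryCatch(
      stats::optim(as.vector(X0), fn, gr, method = "L-BFGS-B",
                   control = list(maxit = config@maxIterations,
                                  factr = 1e3,
                                  pgtol = config@forceTolerance)),
      error = function(e) NULL)
    ok <- !is.null(opt) && is.finite(opt$value) && opt$value <= e0
    X1 <- if (ok) matrix(opt$par, ncol = 3) else X0
    after <- countHeavyClashes(X1, top)
    if (after > before) { X1 <- X0; after <- before; ok <- FALSE }
    out[, , f] <- X1
    diag$clashesBefore[f] <- before
    diag$clashesAfter[f] <- after
    diag$caRmsdShift[f] <- if (ok) superpose(X1, X0, ca)$rmsd else 0
    diag$iterations[f] <- if (is.null(opt)) 0L else opt$counts[1]
    diag$energy[f] <- if (is.null(opt)) e0 else opt$value
    diag$modified[f] <- ok
  }
  list(ensemble = newEnsemble(top, out, temperature = ensemble@temperature,
                              label = paste0(ensemble@label, "_relaxed"),
                              metadata = ensemble@metadata),
       diagnostics = diag)
}
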