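bruteForceContacts <- function(X, top) {
  L <- nResidues(top)
  out <- data.frame(i = integer(0), j = integer(0), d0 = numeric(0))
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (b - a < 3) next
    da <- Inf
    for (p in which(top@atomResidue == a)) for (q in which(top@atomResidue == b))
      da <- min(da, sqrt(sum((X[p, ] - X[q, ])^2)))
    if (da <= 10) out <- rbind(out, data.frame(i = a, j = b, d0 = da))
  }
  out
}

bruteForceQ <- function(X, top, contacts, beta = 5, lambda = 1.2) {
  cc <- contacts@contacts
  total <- 0
  for (r in seq_len(nrow(cc))) {
    da <- Inf
    for (p in which(top@atomResidue == cc$i[r]))
      for (q in which(top@atomResidue == cc$j[r]))
        da <- min(da, sqrt(sum((X[p, ] - X[q, ])^2)))
    total <- total + 1 / (1 + exp(beta * (da - lambda * cc$d0[r])))
  }
  total / nrow(cc)
}

test_that("native contact extraction equals a brute-force double loop", {
  e <- buildIdealChain("AKSLFDAQSM", preset = "extended")
  X <- getFrame(e, 1)
  got <- nativeContacts(X, e@topology)@contacts
  want <- bruteForceContacts(X, e@topology)
  expect_equal(got$i, want$i)
  expect_equal(got$j, want$j)
  expect_equal(got$d0, want$d0, tolerance = 1e-12)
  # helical fixture too (denser contacts)
  h <- helixNative()
  gotH <- nativeContacts(getFrame(h, 1), h@topology)@contacts
  wantH <- bruteForceContacts(getFrame(h, 1), h@topology)
  expect_equal(nrow(gotH), nrow(wantH))
  expect_equal(gotH$d0, wantH$d0, tolerance = 1e-12)
})

test_that("contact rules: inclusive 10 A boundary, >= 3 sequence separation", {
  # residues i, i+2 close in space are never contacts
  h <- helixNative()
  cc <- nativeContacts(getFrame(h, 1), h@topology)@contacts
  expect_true(all(cc$j - cc$i >= 3))
  # exact 10.0 A minimal distance is included: stretch a two-residue pair
  e <- buildIdealChain("AAAA", preset = "extended")
  X <- getFrame(e, 1)
  top <- e@topology
  # move residue 4 so its closest heavy atom to residue 1 sits at 10.000
  r1 <- which(top@atomResidue == 1); r4 <- which(top@atomResidue == 4)
  d <- as.matrix(stats::dist(X))[r1, r4]
  gap <- min(d)
  axis <- X[which(top@atomName == "CA")[4], ] - X[which(top@atomName == "CA")[1], ]
  axis <- axis / sqrt(sum(axis^2))
  # iterate: min distance is not linear in the translation
  for (it in 1:60) {
    gap <- min(as.matrix(stats::dist(X))[r1, r4])
    if (abs(gap - 10) < 1e-9) break
    X[r4, ] <- X[r4, ] + matrix(axis * (10 - gap), length(r4), 3, byrow = TRUE)
  }
  dNew <- min(as.matrix(stats::dist(X))[r1, r4])
  expect_equal(dNew, 10, tolerance = 1e-6)  # geometric construction sanity
  cc2 <- nativeContacts(X, top)@contacts
  expect_true(any(cc2$i == 1 & cc2$j == 4))
})

test_that("Q matches its logistic closed forms", {
  # single contact at d = lambda * d0 contributes exactly 0.5
  e <- buildIdealChain("AAAA", preset = "extended")
  top <- e@topology
  contacts <- new("NativeContactSet",
                  contacts = data.frame(i = 1, j = 4, d0 = 5))
  X <- getFrame(e, 1)
  r1 <- which(top@atomResidue == 1); r4 <- which(top@atomResidue == 4)
  ca <- which(top@atomName == "CA")
  axis <- X[ca[4], ] - X[ca[1], ]; axis <- axis / sqrt(sum(axis^2))
  setMinDist <- function(target) {
    X2 <- X
    for (it in 1:60) {
      gap <- min(as.matrix(stats::dist(X2))[r1, r4])
      if (abs(gap - target) < 1e-9) break
      X2[r4, ] <- X2[r4, ] + matrix(axis * (target - gap), length(r4), 3,
                                    byrow = TRUE)
    }
    X2
  }
  expect_equal(qFraction(setMinDist(1.2 * 5), top, contacts), 0.5, tolerance = 1e-7)
  # logistic inversion: d = lambda d0 -+ ln(3)/beta gives terms 0.75 / 0.25
  expect_equal(qFraction(setMinDist(1.2 * 5 - log(3) / 5), top, contacts), 0.75,
               tolerance = 1e-7)
  expect_equal(qFraction(setMinDist(1.2 * 5 + log(3) / 5), top, contacts), 0.25,
               tolerance = 1e-7)
  expect_error(qFraction(X, top, new("NativeContactSet",
                                     contacts = data.frame(i = integer(0),
                                                           j = integer(0),
                                                           d0 = numeric(0)))),
               "empty")
})

test_that("Q of the native is near 1 when native distances are not tiny", {
  h <- helixNative()
  X <- getFrame(h, 1)
  contacts <- nativeContacts(X, h@topology)
  big <- contacts@contacts[contacts@contacts$d0 >= 5, ]
  cs <- new("NativeContactSet", contacts = big)
  q <- qFraction(X, h@topology, cs)
  expect_gte(q, 0.99)  # each term >= 1/(1 + exp(-5)) = 0.9933
})

test_that("Q equals the brute-force oracle on random fixtures", {
  set.seed(26)
  for (rep in 1:5) {
    ens <- torsionJitterEnsemble(buildIdealChain("AKSLFDAQ", preset = "helix"),
                                 15, 1, seed = 30 + rep)
    X <- getFrame(ens, 1)
    nat <- getFrame(buildIdealChain("AKSLFDAQ", preset = "helix"), 1)
    contacts <- nativeContacts(nat, ens@topology)
    expect_equal(qFraction(X, ens@topology, contacts),
                 bruteForceQ(X, ens@topology, contacts), tolerance = 1e-12)
  }
})

test_that("Q strictly decreases when a contact distance grows", {
  e <- buildIdealChain("AAAAA", preset = "extended")
  top <- e@topology
  contacts <- new("NativeContactSet",
                  contacts = data.frame(i = c(1, 1), j = c(4, 5), d0 = c(5, 6)))
  X <- getFrame(e, 1)
  r5 <- which(top@atomResidue == 5)
  q0 <- qFraction(X, top, contacts)
  X2 <- X
  X2[r5, 1] <- X2[r5, 1] + 0.5   # push residue 5 further out
  expect_lt(qFraction(X2, top, contacts), q0)
})

test_that("FSF counts strict exceedances and is monotone in the threshold", {
  h <- helixNative()
  X <- getFrame(h, 1)
  contacts <- nativeContacts(X, h@topology)
  copies <- newEnsemble(h@topology, array(X, c(dim(X), 4)))
  expect_equal(as.numeric(foldedStateFraction(copies, contacts)), 1.0)
  ext <- newEnsemble(h@topology,
                     array(getFrame(extendedNative(), 1), c(dim(X), 4)))
  expect_equal(as.numeric(foldedStateFraction(ext, contacts)), 0.0)
  # counting: threshold sits among the per-frame Q values
  mix <- twoStateEnsemble(h, 400, trueTm = 400, trueK = 20, nFrames = 10, seed = 27)
  fsf <- foldedStateFraction(mix, contacts)
  q <- attr(fsf, "q")
  expect_equal(as.numeric(fsf), mean(q > 0.6))
  ths <- seq(0.1, 0.9, by = 0.1)
  fs <- vapply(ths, function(t)
    as.numeric(foldedStateFraction(mix, contacts, qThresh = t)), numeric(1))
  expect_true(all(diff(fs) <= 0))
  # strictness at the boundary
  expect_equal(as.numeric(foldedStateFraction(copies, contacts,
                                              qThresh = max(attr(foldedStateFraction(copies, contacts), "q")))),
               0)
})
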