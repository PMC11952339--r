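bruteForceClashes <- function(X, top, radii = defaultVdwTable()) {
  n <- nrow(X)
  count <- 0
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    if (abs(top@atomResidue[p] - top@atomResidue[q]) < 2) next
    d <- sqrt(sum((X[p, ] - X[q, ])^2))
    if (d < 0.5 * (radii[top@atomElement[p]] + radii[top@atomElement[q]]))
      count <- count + 1
  }
  count
}

test_that("ideal-geometry chains carry zero clashes and zero violations", {
  for (e in list(helixNative(), extendedNative(),
                 buildIdealChain("ACDEFGHIKLMNPQRSTVWY", preset = "helix"))) {
    X <- getFrame(e, 1)
    expect_equal(countHeavyClashes(X, e@topology), 0)
    expect_equal(countPeptideViolations(X, e@topology), 0)
  }
})

test_that("clash counting follows the strict half-vdW criterion", {
  # two carbons from residues i and i+3: clash iff d < 1.70
  e <- buildIdealChain("AAAA", preset = "extended")
  top <- e@topology
  X <- getFrame(e, 1)
  cb1 <- which(top@atomResidue == 1 & top@atomName == "CB")
  cb4 <- which(top@atomResidue == 4 & top@atomName == "CB")
  base <- countHeavyClashes(X, top)
  setD <- function(d) {
    X2 <- X
    u <- X[cb4, ] - X[cb1, ]; u <- u / sqrt(sum(u^2))
    X2[cb4, ] <- X[cb1, ] + u * d
    X2
  }
  expect_equal(countHeavyClashes(setD(1.0), top) -
                 bruteForceClashes(setD(1.0), top), 0)
  expect_gte(countHeavyClashes(setD(1.0), top), base + 1)
  # exact boundary d = 1.70 = 0.5 * (1.70 + 1.70): strictly below only
  X170 <- setD(1.70)
  expect_equal(countHeavyClashes(X170, top), bruteForceClashes(X170, top))
  d170 <- countHeavyClashes(X170, top, details = TRUE)
  expect_false(any(abs(d170$pairs$distance - 1.70) < 1e-9))
  m <- buildIdealChain("AMA", preset = "extended")   # methionine carries S
  expect_error(countHeavyClashes(getFrame(m, 1), m@topology,
                                 radii = c(C = 1.7, N = 1.55, O = 1.52)),
               "missing from the vdW radii table: S")
})

test_that("peptide-bond violations use the two-sided inclusive z >= 3 rule", {
  e <- buildIdealChain("AAAA", preset = "extended")
  top <- e@topology
  X <- getFrame(e, 1)
  expect_equal(countPeptideViolations(X, top), 0)  # all bonds at 1.348
  stretch <- function(len) getFrame(
    injectDefects(newEnsemble(top, X),
                  stretchSpecs = list(list(frame = 1, bond = 2, length = len))), 1)
  expect_equal(countPeptideViolations(stretch(1.440), top), 1)  # z = 3.17
  expect_equal(countPeptideViolations(stretch(1.260), top), 1)  # |z| = 3.03
  # the exact z = 3 boundary is not floating-point representable; bracket it
  expect_equal(countPeptideViolations(stretch(1.348 + 3 * 0.029 + 1e-9), top), 1)
  expect_equal(countPeptideViolations(stretch(1.348 + 3 * 0.029 - 1e-9), top), 0)
  expect_equal(countPeptideViolations(stretch(1.348 + 2.9 * 0.029), top), 0)
})

test_that("counters equal the brute-force double loop on random fixtures", {
  set.seed(40)
  for (rep in 1:6) {
    ens <- twoStateEnsemble(buildIdealChain("AKSLFDAQ", preset = "helix"),
                            temperature = 600, trueTm = 400, trueK = 20,
                            nFrames = 1, seed = 40 + rep)
    X <- getFrame(ens, 1)
    expect_equal(countHeavyClashes(X, ens@topology),
                 bruteForceClashes(X, ens@topology))
  }
})

test_that("injection manifests agree exactly with the counters", {
  e <- buildIdealChain("AEKLFDAQSMIRAEKL", preset = "extended")
  top <- e@topology
  base <- countHeavyClashes(getFrame(e, 1), top)
  def <- injectDefects(e,
    clashSpecs = list(
      list(frame = 1, i = 2, atomI = "CB", j = 6, atomJ = "OD2", distance = 1.0),
      list(frame = 1, i = 9, atomI = "CB", j = 13, atomJ = "CB", distance = 1.2),
      list(frame = 1, i = 4, atomI = "CD1", j = 11, atomJ = "CD1", distance = 1.1)),
    stretchSpecs = list(list(frame = 1, bond = 7, length = 1.45)))
  man <- def@metadata$defectManifest
  expect_equal(man$clashIncrement, 3L)
  expect_equal(man$violationIncrement, 1L)
  expect_equal(countHeavyClashes(getFrame(def, 1), top), base + 3)
  expect_equal(countPeptideViolations(getFrame(def, 1), top), 1)
  # empty specs are the identity
  same <- injectDefects(e)
  expect_equal(same@coords, e@coords)
  # adjacent-residue clash specs are refused
  expect_error(injectDefects(e, clashSpecs = list(
    list(frame = 1, i = 3, atomI = "CB", j = 4, atomJ = "CB", distance = 1.0))),
    "adjacent")
})

test_that("integrity counters are invariant to global rigid motion", {
  ens <- twoStateEnsemble(helixNative(), 600, trueTm = 400, trueK = 20,
                          nFrames = 2, seed = 44)
  ir0 <- integrityReport(ens)
  for (s in 1:3) {
    rot <- rotateEnsemble(ens, seed = 400 + s)
    ir <- integrityReport(rot)
    expect_equal(ir@clashesPerFrame, ir0@clashesPerFrame)
    expect_equal(ir@violationsPerFrame, ir0@violationsPerFrame)
  }
  expect_equal(meanClashes(ir0), mean(ir0@clashesPerFrame))
  expect_equal(meanViolations(ir0), mean(ir0@violationsPerFrame))
})
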