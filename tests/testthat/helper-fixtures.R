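# shared fixtures, built once per test run

fixtureSequence <- "AEKLFDAQSMIRAEKL"

helixNative <- function() {
  if (is.null(.fixtureCache$helix))
    .fixtureCache$helix <- buildIdealChain(fixtureSequence, preset = "helix")
  .fixtureCache$helix
}

extendedNative <- function() {
  if (is.null(.fixtureCache$extended))
    .fixtureCache$extended <- buildIdealChain(fixtureSequence, preset = "extended")
  .fixtureCache$extended
}

.fixtureCache <- new.env()

# minimal hand-built topology: n "residues" of a single pseudo-atom each is
# not valid (needs N/CA/C), so toy geometric cases use real small chains or
# direct matrices instead.

expectRigidInvariant <- function(value, recompute, tol = 1e-6) {
  expect_equal(recompute(), value, tolerance = tol)
}

randomRotate <- function(X, seed) {
  set.seed(seed)
  EnsembleMetrics:::.randomRigid(X)
}

rotateEnsemble <- function(ens, seed) {
  set.seed(seed)
  coords <- ens@coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- EnsembleMetrics:::.randomRigid(coords[, , f])
  newEnsemble(ens@topology, coords, temperature = ens@temperature,
              label = ens@label, metadata = ens@metadata)
}
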