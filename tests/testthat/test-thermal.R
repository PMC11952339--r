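sigmoidSeries <- function(tm, k, yMin = 0, yMax = 1,
                          temps = seq(250, 670, length.out = 20)) {
  y <- yMin + (yMax - yMin) / (1 + exp(-(temps - tm) / k))
  new("MeltSeries", temperatures = temps, values = pmin(pmax(y, 0), 1),
      observable = "FSF")
}

test_that("noise-free self-consistency recovers the generating parameters", {
  fit <- fitSigmoid(sigmoidSeries(400, -15))
  expect_true(fit@converged)
  expect_equal(fit@tm, 400, tolerance = 0.5 / 400)
  expect_equal(fit@kSlope, -15, tolerance = 0.01)
})

test_that("noisy series recover Tm within a few Kelvin (20 seeds)", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    base <- sigmoidSeries(400, -15)
    noisy <- new("MeltSeries", temperatures = base@temperatures,
                 values = base@values + rnorm(20, 0, 0.03),
                 observable = "FSF")
    fitSigmoid(noisy)@tm - 400
  }, numeric(1))
  expect_lte(median(abs(errs)), 3)
  expect_lte(max(abs(errs)), 15)
})

test_that("the fit is invariant to shifts and affine rescaling", {
  base <- sigmoidSeries(420, -18, yMin = 0.05, yMax = 0.95)
  f0 <- fitSigmoid(base)
  shifted <- new("MeltSeries", temperatures = base@temperatures,
                 values = base@values * 0.5 + 0.1, observable = "FSF")
  f1 <- fitSigmoid(shifted)
  expect_equal(f1@tm, f0@tm, tolerance = 1e-6)
  expect_equal(f1@kSlope, f0@kSlope, tolerance = 1e-6)
})

test_that("increasing observables fit with positive slope; degenerate input errors", {
  up <- sigmoidSeries(400, +15)
  fit <- fitSigmoid(up)
  expect_true(fit@converged)
  expect_gt(fit@kSlope, 0)
  expect_equal(fit@tm, 400, tolerance = 0.01)
  flat <- new("MeltSeries", temperatures = seq(300, 400, length.out = 5),
              values = rep(0.5, 5), observable = "FSF")
  expect_error(fitSigmoid(flat), "no transition")
  expect_error(new("MeltSeries", temperatures = c(300, 320, 340),
                   values = c(1, 0.5, 0), observable = "FSF"),
               ">= 4 points")
  expect_error(new("MeltSeries", temperatures = c(300, 300, 340, 360),
                   values = c(1, 1, 0.5, 0), observable = "FSF"),
               "strictly increasing")
})

test_that("melt series compose per-ensemble observables sorted by temperature", {
  nat <- helixNative()
  X <- getFrame(nat, 1)
  copies <- function(t) newEnsemble(nat@topology, array(X, c(dim(X), 3)),
                                    temperature = t)
  s <- buildMeltSeries(list(copies(450), copies(300), copies(400), copies(350)),
                       X, "FSF")
  expect_equal(s@temperatures, c(300, 350, 400, 450))
  expect_equal(s@values, rep(1, 4))
  ext <- getFrame(extendedNative(), 1)
  extEns <- function(t) newEnsemble(nat@topology, array(ext, c(dim(ext), 3)),
                                    temperature = t)
  s0 <- buildMeltSeries(lapply(c(300, 350, 400, 450), extEns), X, "FSF")
  expect_equal(s0@values, rep(0, 4))
  expect_error(buildMeltSeries(list(copies(300), copies(300), copies(400),
                                    copies(450)), X, "FSF"), "duplicate")
  noT <- newEnsemble(nat@topology, array(X, c(dim(X), 3)))
  expect_error(buildMeltSeries(list(copies(300), noT, copies(400), copies(450)),
                               X, "FSF"), "temperature")
})

test_that("two-state sweeps track the generator's folded fractions", {
  nat <- helixNative()
  temps <- seq(340, 460, by = 24)
  ens <- lapply(seq_along(temps), function(i)
    twoStateEnsemble(nat, temps[i], trueTm = 400, trueK = 20,
                     nFrames = 60, seed = 300 + i))
  s <- buildMeltSeries(ens, getFrame(nat, 1), "FSF")
  realized <- vapply(ens, function(e) e@metadata$foldedCount / nFrames(e),
                     numeric(1))[order(temps)]
  expect_equal(s@values, realized, tolerance = 0.1)
})

test_that("deltaTm subtracts converged fits and rejects unconverged ones", {
  fa <- fitSigmoid(sigmoidSeries(432.6, -15))
  fb <- fitSigmoid(sigmoidSeries(400.0, -15))
  expect_equal(deltaTm(fa, fa), 0, tolerance = 1e-9)
  expect_equal(deltaTm(fa, fb), 32.6, tolerance = 0.05)
  bad <- new("MeltFit", tm = 1, kSlope = 1, yMin = 0, yMax = 1, rss = 0,
             converged = FALSE)
  expect_error(deltaTm(fa, bad), "converged")
})

test_that("melting temperatures recovered from two fixture sweeps differ as designed", {
  nat <- helixNative()
  temps <- seq(330, 470, by = 20)
  sweepAt <- function(tm, seedBase) lapply(seq_along(temps), function(i)
    twoStateEnsemble(nat, temps[i], trueTm = tm, trueK = 20,
                     nFrames = 100, seed = seedBase + i))
  fitA <- meltingTemperature(sweepAt(380, 400), getFrame(nat, 1), "FSF")$fsf
  fitB <- meltingTemperature(sweepAt(420, 500), getFrame(nat, 1), "FSF")$fsf
  expect_equal(deltaTm(fitA, fitB), -40, tolerance = 10 / 40)
})
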