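test_that("JSD matches term-by-term KL oracle and its bounds", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-15)
  # direct-summation oracle for p = (1, 0), q = (1/2, 1/2)
  klOracle <- function(p, q) {
    m <- (p + q) / 2
    s <- 0
    for (i in seq_along(p)) {
      if (p[i] > 0) s <- s + 0.5 * p[i] * log(p[i] / m[i])
      if (q[i] > 0) s <- s + 0.5 * q[i] * log(q[i] / m[i])
    }
    s
  }
  p <- c(1, 0); q <- c(0.5, 0.5)
  expect_equal(jsd(p, q), klOracle(p, q), tolerance = 1e-15)
  expect_equal(jsd(p, q), 0.2157616, tolerance = 1e-6)
  set.seed(16)
  for (k in 1:10) {
    a <- runif(9); a <- a / sum(a)
    b <- runif(9); b <- b / sum(b)
    expect_equal(jsd(a, b), klOracle(a, b), tolerance = 1e-12)
    expect_equal(jsd(a, b), jsd(b, a), tolerance = 1e-15)
    expect_gte(jsd(a, b), 0)
    expect_lte(jsd(a, b), log(2))
  }
  expect_error(jsd(c(0.5, 0.6), c(0.5, 0.5)), "probability")
  expect_error(jsd(c(-0.1, 1.1), c(0.5, 0.5)), "probability")
})

test_that("the torus discretization yields exactly 9 bins with wrapping", {
  bin <- EnsembleMetrics:::.chiBin
  # exhaustive 1-degree sweep: every angle falls in exactly one of 3 bins
  sweep <- seq(-180, 180, by = 1)
  bins <- bin(sweep)
  expect_true(all(bins %in% 1:3))
  expect_equal(sort(unique(bins)), 1:3)
  # boundary conventions: edges at -120, 0, 120; [-180,-120) wraps to bin 3
  expect_equal(bin(c(-120, -1e-9, 0, 119.999, 120, 239.9 - 360)), c(1, 1, 2, 2, 3, 3))
  expect_equal(bin(-170), bin(170))       # same torus bin
  expect_equal(bin(-170), 3)
  # joint histogram has 9 cells and counts every valid frame exactly once
  tab <- matrix(1 / 9, 3, 3)
  ens <- rotamerEnsemble("AKA", list(NULL, list(tab, tab, tab), NULL),
                         nFrames = 40, seed = 17)
  h <- chiPairHistograms(ens)
  expect_equal(length(h), 3)             # lysine: pairs (1,2), (2,3), (3,4)
  for (hh in h) {
    expect_equal(dim(hh$counts), c(3, 3))
    expect_equal(sum(hh$counts), 40)
  }
})

test_that("chi pair enumeration depends on residue type", {
  ens <- buildIdealChain(c("SER", "LEU", "MET", "ARG"), preset = "extended")
  h <- chiPairHistograms(ens)
  byRes <- table(factor(vapply(h, function(x) x$residue, numeric(1)), levels = 1:4))
  expect_equal(unname(c(byRes)), c(0, 1, 2, 3))  # SER none, LEU (1,2), MET +(2,3), ARG +(3,4)
})

test_that("chiJSD attains 0 on identical and ln 2 on disjoint ensembles", {
  tab <- matrix(1 / 9, 3, 3)
  a <- rotamerEnsemble("AKA", list(NULL, list(tab, tab, tab), NULL), 60, seed = 18)
  expect_equal(as.numeric(chiJsd(a, a)), 0)
  pm1 <- matrix(0, 3, 3); pm1[1, 1] <- 1
  pm2 <- matrix(0, 3, 3); pm2[2, 2] <- 1
  p <- rotamerEnsemble("AKA", list(NULL, list(pm1, pm1, pm1), NULL), 50, seed = 19)
  q <- rotamerEnsemble("AKA", list(NULL, list(pm2, pm2, pm2), NULL), 50, seed = 20)
  expect_equal(as.numeric(chiJsd(p, q)), log(2), tolerance = 1e-12)
  expect_equal(as.numeric(chiJsd(p, q)), as.numeric(chiJsd(q, p)))
  expect_error(chiJsd(buildIdealChain("GGG"), buildIdealChain("GGG")),
               "undefined")
})

test_that("chiJSD composes the per-pair JSD oracle", {
  # one lysine: reference all in cell (1,1); proposed split 50/50 between
  # cells (1,1) and (2,2) on each pair -> three identical JSD terms
  pm <- matrix(0, 3, 3); pm[1, 1] <- 1
  split <- matrix(0, 3, 3); split[1, 1] <- 0.5; split[2, 2] <- 0.5
  ref <- rotamerEnsemble("AKA", list(NULL, list(pm, pm, pm), NULL), 400, seed = 21)
  prop <- rotamerEnsemble("AKA", list(NULL, list(split, split, split), NULL),
                          400, seed = 22)
  pv <- c(1, rep(0, 8))
  target <- jsd(pv, c(0.5, 0, 0, 0, 0.5, 0, 0, 0, 0))   # = 0.2158 nats
  got <- as.numeric(chiJsd(ref, prop))
  # sampling follows the prescribed tables only stochastically at the
  # 50/50 split; binomial noise at n = 400 stays well under 0.02 nats
  expect_equal(got, target, tolerance = 0.05)
  expect_equal(attr(chiJsd(ref, prop), "nPairs"), 3)
})

test_that("chi histograms are invariant to global rigid motion", {
  tab <- matrix(1 / 9, 3, 3)
  ens <- rotamerEnsemble("AKA", list(NULL, list(tab, tab, tab), NULL), 30, seed = 23)
  h0 <- chiPairHistograms(ens)
  rot <- rotateEnsemble(ens, seed = 24)
  h1 <- chiPairHistograms(rot)
  for (k in seq_along(h0)) expect_equal(h1[[k]]$counts, h0[[k]]$counts)
})
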