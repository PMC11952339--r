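# Side-chain torsion divergence: Jensen-Shannon divergence between joint
# 9-bin torus histograms of consecutive chi-angle pairs, averaged over all
# residue/pair combinations of the chain (the chiJSD score).

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Natural-log JSD with M = (p + q)/2 and the convention 0 ln 0 = 0;
#' symmetric, bounded by ln 2.
#'
#' @param p,q non-negative vectors summing to 1 (within 1e-9).
#' @return JSD in [0, ln 2].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0) || abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("p and q must be probability vectors (non-negative, summing to 1)")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# torus bin index in 1..3 for an angle in degrees: half-open bins
# [-120, 0), [0, 120), [120, 240) with values outside wrapped onto the torus
.chiBin <- function(a) {
  w <- (a + 120) %% 360 - 120   # fold into [-120, 240)
  pmin(floor((w + 120) / 120) + 1, 3)
}

#' Joint chi-pair histograms of an ensemble
#'
#' For every residue, every existing consecutive chi pair among (1,2), (2,3),
#' (3,4) is discretized into a 3 x 3 joint histogram per axis over torus bins
#' with edges at -120, 0, 120 degrees (9 equally sized bins in total; angles
#' outside the range wrap around the torus).
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param torsions optional precomputed \linkS4class{TorsionTable}.
#' @return list of entries with fields \code{residue}, \code{pair} (c(j, k)),
#'   \code{counts} (3 x 3 integer matrix; rows = chi_j bin, cols = chi_k bin).
#' @export
chiPairHistograms <- function(ensemble, torsions = computeTorsions(ensemble)) {
  top <- ensemble@topology
  out <- list()
  for (i in seq_len(nResidues(top))) {
    nchi <- .aaChiCount[[top@resNames[i]]]
    if (nchi < 2) next
    for (j in seq_len(nchi - 1)) {
      k <- j + 1
      ok <- torsions@valid[, i, 3 + j] & torsions@valid[, i, 3 + k]
      a <- torsions@values[ok, i, 3 + j]
      b <- torsions@values[ok, i, 3 + k]
      counts <- matrix(0L, 3, 3)
      if (length(a)) {
        tab <- table(factor(.chiBin(a), levels = 1:3),
                     factor(.chiBin(b), levels = 1:3))
        counts <- matrix(as.integer(tab), 3, 3)
      }
      out[[length(out) + 1]] <- list(residue = i, pair = c(j, k), counts = counts)
    }
  }
  out
}

#' Side-chain torsion divergence between two ensembles (chiJSD)
#'
#' Mean Jensen-Shannon divergence between the normalized 9-bin joint
#' histograms of consecutive chi pairs, taken over all residue/pair
#' combinations that have at least one valid observation in both ensembles.
#' 0 means identical side-chain torsion statistics; ln 2 maximal divergence.
#'
#' @param reference,proposed \linkS4class{Ensemble}s sharing a topology.
#' @return chiJSD in [0, ln 2]. The number of evaluated and skipped pairs is
#'   attached as attributes \code{nPairs} and \code{nSkipped}.
#' @export
chiJsd <- function(reference, proposed) {
  if (!identical(reference@topology@resNames, proposed@topology@resNames))
    stop("ensembles must share a topology")
  hr <- chiPairHistograms(reference)
  hp <- chiPairHistograms(proposed)
  vals <- numeric(0); skipped <- 0L
  for (idx in seq_along(hr)) {
    cr <- hr[[idx]]$counts; cp <- hp[[idx]]$counts
    if (sum(cr) == 0 || sum(cp) == 0) { skipped <- skipped + 1L; next }
    vals <- c(vals, jsd(as.vector(cr) / sum(cr), as.vector(cp) / sum(cp)))
  }
  if (!length(vals))
    stop("chiJSD undefined: no residue has an evaluable chi pair (e.g. polyglycine)")
  structure(mean(vals), nPairs = length(vals), nSkipped = skipped)
}
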