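# Melting-curve machinery: observable-versus-temperature series from
# multi-temperature ensembles and apparent melting temperatures from a
# sigmoid fit with asymptotes fixed to the series extremes.

#' Build an observable-versus-temperature series
#'
#' Computes FSF or SSEP for each temperature-labelled ensemble and sorts by
#' temperature.
#'
#' @param ensembles list of \linkS4class{Ensemble}s, each with a temperature
#'   label, all sharing the native's topology.
#' @param native natoms x 3 matrix of the native structure.
#' @param observable "FSF" or "SSEP".
#' @return a \linkS4class{MeltSeries}.
#' @export
buildMeltSeries <- function(ensembles, native, observable = c("FSF", "SSEP")) {
  observable <- match.arg(observable)
  temps <- vapply(ensembles, temperature, numeric(1))
  if (anyNA(temps)) stop("every ensemble needs a temperature label (K)")
  if (anyDuplicated(temps)) stop("duplicate ensemble temperatures")
  ord <- order(temps)
  top <- ensembles[[1]]@topology
  if (observable == "FSF") {
    contacts <- nativeContacts(native, top)
    vals <- vapply(ensembles, function(e)
      as.numeric(foldedStateFraction(e, contacts)), numeric(1))
  } else {
    vals <- vapply(ensembles, function(e) as.numeric(ssep(e, native)), numeric(1))
  }
  new("MeltSeries", temperatures = temps[ord], values = vals[ord],
      observable = observable)
}

#' Fit a melting sigmoid to an observable series
#'
#' Fits f(T) = ymin + (ymax - ymin) / (1 + exp(-(T - Tm)/k)) by nonlinear
#' least squares (Levenberg-Marquardt) over (Tm, k) only, with ymin/ymax
#' fixed to the minimum and maximum of the series. The functional form rises
#' with T for k > 0; a decreasing observable (FSF, SSEP) therefore yields a
#' negative fitted k rather than a reordered series.
#'
#' Initialization: Tm0 is the temperature where the series first crosses the
#' midpoint (ymin + ymax)/2 (linear interpolation); k0 = +-20 K by series
#' orientation. Tm is bounded to [min(T) - 100, max(T) + 100].
#'
#' @param series a \linkS4class{MeltSeries} (or any object with
#'   \code{temperatures}/\code{values} slots), >= 4 points.
#' @return a \linkS4class{MeltFit}.
#' @export
fitSigmoid <- function(series) {
  Tt <- series@temperatures; y <- series@values
  yMin <- min(y); yMax <- max(y)
  if (yMax - yMin <= 0)
    stop("no transition detected: flat observable series")
  # orientation from the ends of the series
  increasing <- mean(y[Tt >= stats::median(Tt)]) >= mean(y[Tt < stats::median(Tt)])
  mid <- (yMin + yMax) / 2
  cross <- which(diff(sign(y - mid)) != 0)
  tm0 <- if (length(cross)) {
    i <- cross[1]
    Tt[i] + (mid - y[i]) * (Tt[i + 1] - Tt[i]) / (y[i + 1] - y[i])
  } else stats::median(Tt)
  k0 <- if (increasing) 20 else -20
  lowerTm <- min(Tt) - 100; upperTm <- max(Tt) + 100
  f <- function(T, tm, k) yMin + (yMax - yMin) / (1 + exp(-(T - tm) / k))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ f(Tt, tm, k),
                      start = list(tm = tm0, k = k0),
                      lower = c(lowerTm, -Inf), upper = c(upperTm, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct RSS minimization; report best iterate, unconverged
    rss <- function(p) sum((y - f(Tt, p[1], p[2]))^2)
    op <- stats::optim(c(tm0, k0), rss, method = "Nelder-Mead")
    return(new("MeltFit", tm = op$par[1], kSlope = op$par[2], yMin = yMin,
               yMax = yMax, rss = op$value, converged = FALSE))
  }
  cf <- stats::coef(fit)
  new("MeltFit", tm = unname(cf["tm"]), kSlope = unname(cf["k"]), yMin = yMin,
      yMax = yMax, rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apparent melting temperature(s) of a multi-temperature ensemble set
#'
#' Convenience composition of \code{\link{buildMeltSeries}} and
#' \code{\link{fitSigmoid}} for one or both foldedness observables. When both
#' are requested the difference of the two Tm estimates is attached as a
#' consistency diagnostic.
#'
#' @param ensembles list of temperature-labelled \linkS4class{Ensemble}s.
#' @param native natoms x 3 matrix of the native structure.
#' @param observable "FSF", "SSEP" or "both".
#' @return a named list of \linkS4class{MeltFit} objects (fields
#'   \code{fsf} and/or \code{ssep}); with both observables the list also
#'   carries \code{tmDifference} (Tm_FSF - Tm_SSEP, K).
#' @export
meltingTemperature <- function(ensembles, native,
                               observable = c("both", "FSF", "SSEP")) {
  observable <- match.arg(observable)
  out <- list()
  if (observable %in% c("both", "FSF"))
    out$fsf <- fitSigmoid(buildMeltSeries(ensembles, native, "FSF"))
  if (observable %in% c("both", "SSEP"))
    out$ssep <- fitSigmoid(buildMeltSeries(ensembles, native, "SSEP"))
  if (!is.null(out$fsf) && !is.null(out$ssep))
    out$tmDifference <- out$fsf@tm - out$ssep@tm
  out
}

#' Difference between two fitted melting temperatures
#'
#' @param fitA,fitB converged \linkS4class{MeltFit} objects.
#' @return Tm_A - Tm_B in Kelvin.
#' @export
deltaTm <- function(fitA, fitB) {
  if (!fitA@converged || !fitB@converged)
    stop("deltaTm requires two converged fits")
  fitA@tm - fitB@tm
}
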