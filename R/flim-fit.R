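# Poisson maximum-likelihood decay fitting.
#
# For a single truncated-exponential component observed in n equal bins over
# window T, the per-bin probabilities form a truncated geometric distribution
# in the bin index with ratio rho = exp(-dt/tau). Profiling out the (Poisson)
# amplitude leaves a multinomial likelihood whose score equation reduces to
# matching the model mean bin index
#     m(rho) = rho/(1-rho) - n rho^n / (1 - rho^n)
# to the observed photon-weighted mean bin index. The mono-exponential MLE is
# therefore the root of a monotone 1-D equation, which we solve by bisection
# to fixed precision -- deterministic and fast enough to run per pixel.

# Model mean bin index (0-based) as a function of tau.
meanBinIndex <- function(tau, nBins, dt) {
  rho <- exp(-dt / tau)
  # guard rho -> 1 (tau >> window): limit is (n-1)/2
  m <- rho / (1 - rho) - nBins * rho^nBins / (1 - rho^nBins)
  m[rho > 1 - 1e-12] <- (nBins - 1) / 2
  m
}

# Vectorized inversion of meanBinIndex by bisection on log(tau).
# Returns tau; entries where mbar is outside the attainable range get the
# bound value and are reported via the "converged" attribute.
invertMeanIndex <- function(mbar, nBins, dt,
                            tauRange = c(dt / 50, 50 * nBins * dt)) {
  lo <- rep(log(tauRange[1]), length(mbar))
  hi <- rep(log(tauRange[2]), length(mbar))
  mLo <- meanBinIndex(tauRange[1], nBins, dt)
  mHi <- meanBinIndex(tauRange[2], nBins, dt)
  conv <- mbar > mLo & mbar < mHi
  for (it in 1:64) {
    mid <- (lo + hi) / 2
    m <- meanBinIndex(exp(mid), nBins, dt)
    below <- m < mbar
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  tau <- exp((lo + hi) / 2)
  tau[!conv & mbar <= mLo] <- tauRange[1]
  tau[!conv & mbar >= mHi] <- tauRange[2]
  attr(tau, "converged") <- conv
  tau
}

monoGoodness <- function(counts, tau, nBins, timeWindow) {
  p <- binProbabilities(tau, nBins, timeWindow)
  e <- sum(counts) * p
  keep <- e > 1e-12
  sum((counts[keep] - e[keep])^2 / e[keep]) / max(1, nBins - 2)
}

#' Fit a mono-exponential decay by Poisson maximum likelihood
#'
#' Maximizes the Poisson likelihood of a single truncated-exponential decay
#' (amplitude + lifetime) over the measurement window. Counts are photon
#' counts, so the Poisson objective is the statistically correct one at the
#' low per-bin counts typical of 256-bin histograms. The fit is deterministic
#' for a given histogram.
#'
#' @param counts non-negative integer vector, the decay histogram.
#' @param binWidth time bin width in ns.
#' @param minPhotons minimum total photons required (default 100).
#' @return a [DecayFit-class].
#' @export
fitMonoexponential <- function(counts, binWidth, minPhotons = 100) {
  stopifnot(binWidth > 0, all(counts >= 0))
  nBins <- length(counts)
  N <- sum(counts)
  if (N < minPhotons)
    stop("insufficient photons (", N, " < ", minPhotons, ")")
  mbar <- sum(counts * (seq_len(nBins) - 1)) / N
  tau <- invertMeanIndex(mbar, nBins, binWidth)
  conv <- attr(tau, "converged")
  tau <- as.numeric(tau)
  new("DecayFit", lifetimes = tau, ampFractions = 1, photonCount = N,
      goodness = monoGoodness(counts, tau, nBins, nBins * binWidth),
      converged = conv,
      flags = if (conv) character() else "bound")
}

# Multinomial negative log-likelihood of a two-component mixture.
biexpNLL <- function(counts, tau1, tau2, f, nBins, timeWindow) {
  p <- f * binProbabilities(tau1, nBins, timeWindow) +
    (1 - f) * binProbabilities(tau2, nBins, timeWindow)
  -sum(counts * log(pmax(p, 1e-300)))
}

#' Fit a bi-exponential decay by Poisson maximum likelihood
#'
#' Two-component Poisson-MLE fit with ordered lifetimes (short component
#' first). The short component can be fixed (e.g. to a known autofluorescence
#' lifetime) or bounded to a band via `shortRange`, which is how the
#' two-component mode of the lifetime filter isolates a contaminant while
#' reporting the long (donor) component.
#'
#' Falls back to the mono-exponential fit when either fitted fraction drops
#' below 0.01. When the two lifetimes approach within 5% of each other the
#' model is ill-conditioned and the fit collapses to mono-exponential with a
#' `"degenerate"` flag (still converged).
#'
#' @param counts non-negative integer vector, the decay histogram.
#' @param binWidth time bin width in ns.
#' @param minPhotons minimum total photons required (default 400).
#' @param fixShort optional numeric: fix the short lifetime at this value.
#' @param shortRange optional numeric(2): bounds for the short lifetime.
#' @return a [DecayFit-class]; two components unless collapsed.
#' @export
fitBiexponential <- function(counts, binWidth, minPhotons = 400,
                             fixShort = NULL, shortRange = NULL) {
  stopifnot(binWidth > 0, all(counts >= 0))
  nBins <- length(counts)
  timeWindow <- nBins * binWidth
  N <- sum(counts)
  if (N < minPhotons)
    stop("insufficient photons (", N, " < ", minPhotons, ")")
  mono <- fitMonoexponential(counts, binWidth, minPhotons = 0)
  tauM <- lifetimes(mono)

  toShort <- function(th1) {
    if (!is.null(fixShort)) return(fixShort)
    if (!is.null(shortRange))
      return(shortRange[1] + (shortRange[2] - shortRange[1]) *
               stats::plogis(th1))
    exp(th1)
  }
  nll <- function(par) {
    tau1 <- toShort(par[1])
    tau2 <- tau1 + exp(par[2])
    f <- stats::plogis(par[3])
    biexpNLL(counts, tau1, tau2, f, nBins, timeWindow)
  }
  s0 <- max(0.5 * tauM, binWidth)
  start1 <- if (!is.null(fixShort)) 0 else if (!is.null(shortRange)) {
    s <- min(max(s0, shortRange[1] * 1.01), shortRange[2] * 0.99)
    stats::qlogis((s - shortRange[1]) / (shortRange[2] - shortRange[1]))
  } else log(s0)
  start <- c(start1, log(max(1.2 * tauM - s0, binWidth)), stats::qlogis(0.25))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  tau1 <- toShort(opt$par[1])
  tau2 <- tau1 + exp(opt$par[2])
  f <- stats::plogis(opt$par[3])

  collapse <- function(flag) {
    new("DecayFit", lifetimes = lifetimes(mono), ampFractions = 1,
        photonCount = N, goodness = mono@goodness,
        converged = mono@converged, flags = flag)
  }
  if (min(f, 1 - f) < 0.01) return(collapse("fallback_mono"))
  if ((tau2 - tau1) / tau2 < 0.05) return(collapse("degenerate"))
  # a second component is only reported when it genuinely improves on the
  # nested mono model; otherwise the decomposition is ill-conditioned
  nllMono <- biexpNLL(counts, lifetimes(mono), lifetimes(mono), 0.5,
                      nBins, timeWindow)
  if (nllMono - opt$value < max(1, 1e-6 * N)) return(collapse("degenerate"))
  p <- f * binProbabilities(tau1, nBins, timeWindow) +
    (1 - f) * binProbabilities(tau2, nBins, timeWindow)
  e <- N * p
  keep <- e > 1e-12
  gof <- sum((counts[keep] - e[keep])^2 / e[keep]) / max(1, nBins - 4)
  new("DecayFit", lifetimes = c(tau1, tau2), ampFractions = c(f, 1 - f),
      photonCount = N, goodness = gof, converged = opt$convergence == 0,
      flags = character())
}
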