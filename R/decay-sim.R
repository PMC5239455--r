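#' Construct a TCSPCCube from a count array
#'
#' @param counts non-negative integer array, rows x cols x time bins.
#' @param timeWindow full measurement window in ns.
#' @param metadata optional list of metadata.
#' @return a [TCSPCCube-class].
#' @export
TCSPCCube <- function(counts, timeWindow = 12.5, metadata = list()) {
  storage.mode(counts) <- "integer"
  new("TCSPCCube", counts = counts, timeWindow = timeWindow,
      metadata = metadata)
}

#' Configuration of the synthetic TCSPC decay generator
#'
#' Defines the forward model used to emulate FLIM acquisitions of
#' donor-stained tissue: a mono-exponential donor decay, a FRET-shortened
#' decay in a configurable fraction of the donor population, a short-lifetime
#' autofluorescence contaminant, Poisson photon noise, and a smooth spatial
#' intensity texture. The instrument response is a delta function by default;
#' an optional Gaussian response of width `irfSigma` can be convolved in.
#'
#' @param tauDonor donor lifetime in ns (Alexa546 band).
#' @param tauFret shortened donor lifetime (ns) of the FRET subpopulation;
#'   must be below `tauDonor`.
#' @param fretFraction fraction of the donor population undergoing FRET,
#'   in \[0, 1\].
#' @param tauAuto autofluorescence lifetime (ns).
#' @param autoFraction fraction of total photons contributed by
#'   autofluorescence, in \[0, 1\] (image-wide expectation; see `sigmaAuto`).
#' @param photonsPerPixel expected photon count per pixel.
#' @param nBins number of time bins (>= 8).
#' @param timeWindow measurement window in ns; all lifetimes must lie below it.
#' @param imageShape integer(2), rows and cols of the simulated image.
#' @param sigmaTexture log-sd of the smooth log-normal photon-budget texture.
#' @param sigmaAuto log-sd of the autofluorescence spatial field. Large values
#'   make the contaminant patchy (autofluorescence concentrates in stroma-like
#'   pockets), which is what lifetime filtering exploits.
#' @param blobCells lattice size of the low-resolution noise grid that is
#'   smoothly interpolated to produce the spatial fields.
#' @param irfSigma Gaussian instrument-response width in ns (0 = delta).
#' @param seed integer seed making every draw reproducible.
#' @return a list of class `DecaySimConfig`.
#' @export
decaySimConfig <- function(tauDonor = 2.8, tauFret = 1.4, fretFraction = 0,
                           tauAuto = 0.6, autoFraction = 0,
                           photonsPerPixel = 300, nBins = 256L,
                           timeWindow = 12.5, imageShape = c(256L, 256L),
                           sigmaTexture = 0.3, sigmaAuto = 1.5,
                           blobCells = 8L, irfSigma = 0, seed = 1L) {
  stopifnot(tauDonor > 0, tauFret > 0, tauAuto > 0)
  if (tauFret >= tauDonor)
    stop("tauFret must be smaller than tauDonor")
  if (fretFraction < 0 || fretFraction > 1)
    stop("fretFraction must be in [0, 1]")
  if (autoFraction < 0 || autoFraction > 1)
    stop("autoFraction must be in [0, 1]")
  if (photonsPerPixel <= 0) stop("photonsPerPixel must be positive")
  if (nBins < 8) stop("need at least 8 time bins")
  if (timeWindow <= 0) stop("timeWindow must be positive")
  if (max(tauDonor, tauFret, tauAuto) >= timeWindow)
    stop("all lifetimes must be below the time window")
  if (length(imageShape) != 2L || any(imageShape < 1))
    stop("imageShape must be two positive integers")
  structure(list(
    tauDonor = tauDonor, tauFret = tauFret, fretFraction = fretFraction,
    tauAuto = tauAuto, autoFraction = autoFraction,
    photonsPerPixel = photonsPerPixel, nBins = as.integer(nBins),
    timeWindow = timeWindow, imageShape = as.integer(imageShape),
    sigmaTexture = sigmaTexture, sigmaAuto = sigmaAuto,
    blobCells = as.integer(blobCells), irfSigma = irfSigma,
    seed = as.integer(seed)
  ), class = "DecaySimConfig")
}

# Probability that a photon from a truncated exponential decay with lifetime
# tau falls into each of nBins equal bins spanning [0, timeWindow]. Optional
# Gaussian instrument response is applied by discrete convolution of the bin
# probabilities followed by renormalization over the window.
binProbabilities <- function(tau, nBins, timeWindow, irfSigma = 0) {
  edges <- seq(0, timeWindow, length.out = nBins + 1L)
  p <- (exp(-edges[-(nBins + 1L)] / tau) - exp(-edges[-1L] / tau)) /
    (1 - exp(-timeWindow / tau))
  if (irfSigma > 0) {
    dt <- timeWindow / nBins
    half <- max(1L, ceiling(4 * irfSigma / dt))
    kern <- stats::dnorm(seq(-half, half) * dt, sd = irfSigma)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), p, numeric(half))
    p <- stats::convolve(padded, rev(kern), type = "filter")
    p <- p / sum(p)
  }
  p
}

#' Simulate a single TCSPC decay histogram
#'
#' Draws a photon arrival-time histogram for a mixture of exponential decay
#' components over the measurement window. With noise enabled, counts are
#' Poisson with per-bin expectation
#' `photons * sum_k w_k * (exp(-t_lo/tau_k) - exp(-t_hi/tau_k)) / (1 - exp(-T/tau_k))`;
#' with noise disabled, the expectation itself is returned.
#'
#' @param config a [decaySimConfig()]; supplies `nBins`, `timeWindow`,
#'   `photonsPerPixel` and `irfSigma`.
#' @param components list of `c(lifetime, weight)` pairs (or a 2-column
#'   matrix); weights must be non-negative and sum to 1.
#' @param noise logical, draw Poisson counts (TRUE) or return expectations.
#' @param photons optional photon budget overriding `config$photonsPerPixel`.
#' @return numeric vector of length `config$nBins`.
#' @export
simulateDecayHistogram <- function(config, components, noise = TRUE,
                                   photons = config$photonsPerPixel) {
  stopifnot(inherits(config, "DecaySimConfig"))
  if (length(components) == 0L) stop("empty component list")
  if (is.list(components)) components <- do.call(rbind, components)
  if (is.null(dim(components))) components <- matrix(components, ncol = 2)
  taus <- components[, 1]; w <- components[, 2]
  if (any(taus <= 0)) stop("non-positive lifetime in components")
  if (any(w < 0)) stop("negative component weight")
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  p <- numeric(config$nBins)
  for (k in seq_along(taus))
    p <- p + w[k] * binProbabilities(taus[k], config$nBins, config$timeWindow,
                                     config$irfSigma)
  mu <- photons * p
  if (noise) stats::rpois(length(mu), mu) else mu
}

# Smooth positive spatial field with mean ~1: white noise on a coarse lattice,
# bilinearly interpolated to the image grid, then exponentiated.
blobField <- function(shape, sigma, cells) {
  if (sigma <= 0) return(matrix(1, shape[1], shape[2]))
  g <- matrix(stats::rnorm((cells + 1L)^2), cells + 1L, cells + 1L)
  rx <- seq(0, cells, length.out = shape[1])
  cx <- seq(0, cells, length.out = shape[2])
  i0 <- pmin(floor(rx), cells - 1L); j0 <- pmin(floor(cx), cells - 1L)
  fr <- rx - i0; fc <- cx - j0
  f00 <- g[cbind(rep(i0 + 1L, length(cx)), rep(j0 + 1L, each = length(rx)))]
  f10 <- g[cbind(rep(i0 + 2L, length(cx)), rep(j0 + 1L, each = length(rx)))]
  f01 <- g[cbind(rep(i0 + 1L, length(cx)), rep(j0 + 2L, each = length(rx)))]
  f11 <- g[cbind(rep(i0 + 2L, length(cx)), rep(j0 + 2L, each = length(rx)))]
  wr <- rep(fr, length(cx)); wc <- rep(fc, each = length(rx))
  z <- matrix((1 - wr) * (1 - wc) * f00 + wr * (1 - wc) * f10 +
              (1 - wr) * wc * f01 + wr * wc * f11, shape[1], shape[2])
  fld <- exp(sigma * z)
  fld / mean(fld)
}

# Simulate one cube given per-pixel expected intensities of the clean donor
# signal and the autofluorescence contaminant.
simulateCube <- function(config, fretFraction) {
  sh <- config$imageShape
  donorField <- blobField(sh, config$sigmaTexture, config$blobCells)
  donorInt <- config$photonsPerPixel * (1 - config$autoFraction) * donorField
  if (config$autoFraction > 0) {
    autoField <- blobField(sh, config$sigmaAuto, config$blobCells)
    autoInt <- config$photonsPerPixel * config$autoFraction * autoField
  } else {
    autoInt <- matrix(0, sh[1], sh[2])
  }
  pD  <- binProbabilities(config$tauDonor, config$nBins, config$timeWindow,
                          config$irfSigma)
  pF  <- binProbabilities(config$tauFret, config$nBins, config$timeWindow,
                          config$irfSigma)
  pA  <- binProbabilities(config$tauAuto, config$nBins, config$timeWindow,
                          config$irfSigma)
  npx <- prod(sh)
  # expectation matrix: npx x nBins
  mu <- outer(as.vector(donorInt) * (1 - fretFraction), pD) +
        outer(as.vector(donorInt) * fretFraction, pF) +
        outer(as.vector(autoInt), pA)
  cnt <- stats::rpois(length(mu), mu)
  arr <- array(as.integer(cnt), dim = c(sh[1], sh[2], config$nBins))
  TCSPCCube(arr, config$timeWindow,
            metadata = list(config = unclass(config),
                            fretFraction = fretFraction))
}

#' Simulate a donor / donor-plus-acceptor core pair
#'
#' Emulates the acquisition design in which a 'donor' image and a 'donor with
#' acceptor' image are taken from serial sections of the same tissue core:
#' the two cubes are independent realizations sharing all tissue-level
#' parameters (no pixel registration). The donor-only cube has the FRET
#' fraction forced to zero; both cubes carry the same expected
#' autofluorescence contamination.
#'
#' @param config a [decaySimConfig()].
#' @return list with elements `donor` and `donorAcceptor`, both
#'   [TCSPCCube-class].
#' @export
simulateCorePair <- function(config) {
  stopifnot(inherits(config, "DecaySimConfig"))
  set.seed(config$seed)
  donor <- simulateCube(config, fretFraction = 0)
  donorAcceptor <- simulateCube(config, fretFraction = config$fretFraction)
  list(donor = donor, donorAcceptor = donorAcceptor)
}
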