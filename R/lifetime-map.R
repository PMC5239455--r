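#' FLIM analysis configuration
#'
#' Parameters controlling per-pixel fitting, intensity thresholding, lifetime
#' filtering and ROI averaging.
#'
#' @param minPhotons minimum photons per pixel for a fit (default 100).
#' @param binFactor integer spatial binning factor; histograms are summed in
#'   `binFactor x binFactor` blocks before fitting (the map then has the
#'   block-grid resolution). 1 = no binning.
#' @param fitMode `"mono"` (default) or `"biexp"`. In biexp mode a bounded
#'   short-lifetime contaminant component is co-fitted and the long component
#'   is reported as the pixel lifetime.
#' @param filterWindow numeric(2), lifetime acceptance window in ns used by
#'   [coreFret()] (default `c(1.2, 4.0)`, bracketing the donor band).
#' @param weighting ROI averaging mode, `"photon"` (default) or `"uniform"`.
#' @param shortRange bounds (ns) of the contaminant component in biexp mode.
#' @return a list of class `FlimConfig`.
#' @export
flimConfig <- function(minPhotons = 100, binFactor = 1L,
                       fitMode = c("mono", "biexp"),
                       filterWindow = c(1.2, 4.0),
                       weighting = c("photon", "uniform"),
                       shortRange = c(0.2, 1.2)) {
  fitMode <- match.arg(fitMode)
  weighting <- match.arg(weighting)
  stopifnot(minPhotons >= 0, binFactor >= 1,
            length(filterWindow) == 2L, filterWindow[1] < filterWindow[2])
  structure(list(minPhotons = minPhotons, binFactor = as.integer(binFactor),
                 fitMode = fitMode, filterWindow = filterWindow,
                 weighting = weighting, shortRange = shortRange),
            class = "FlimConfig")
}

# Sum cube counts in b x b spatial blocks; trailing rows/cols that do not
# fill a block are dropped.
binCube <- function(counts, b) {
  d <- dim(counts)
  nr <- d[1] %/% b; nc <- d[2] %/% b
  cropped <- counts[seq_len(nr * b), seq_len(nc * b), , drop = FALSE]
  out <- array(0, dim = c(nr, nc, d[3]))
  for (i in seq_len(b)) for (j in seq_len(b)) {
    out <- out + cropped[seq(i, by = b, length.out = nr),
                         seq(j, by = b, length.out = nc), , drop = FALSE]
  }
  out
}

#' Build a per-pixel lifetime map from a TCSPC cube
#'
#' Fits the decay model at every pixel (after optional spatial binning) and
#' marks pixels invalid when they fail the intensity threshold or the fit
#' does not converge. The default mono-exponential Poisson MLE is evaluated
#' for all pixels at once through its sufficient statistic (the
#' photon-weighted mean arrival time), so full frames fit in well under a
#' second.
#'
#' @param cube a [TCSPCCube-class].
#' @param config a [flimConfig()].
#' @return a [LifetimeMap-class].
#' @export
buildLifetimeMap <- function(cube, config = flimConfig()) {
  stopifnot(is(cube, "TCSPCCube"), inherits(config, "FlimConfig"))
  cnt <- counts(cube)
  if (config$binFactor > 1L) cnt <- binCube(cnt, config$binFactor)
  d <- dim(cnt)
  nBins <- d[3]
  dt <- timeWindow(cube) / nBins
  flat <- matrix(cnt, nrow = d[1] * d[2], ncol = nBins)
  N <- rowSums(flat)
  enough <- N >= max(config$minPhotons, 1)

  tau <- rep(NA_real_, length(N))
  valid <- logical(length(N))
  if (any(enough)) {
    if (config$fitMode == "mono") {
      mbar <- as.vector(flat[enough, , drop = FALSE] %*%
                          (seq_len(nBins) - 1)) / N[enough]
      t <- invertMeanIndex(mbar, nBins, dt)
      conv <- attr(t, "converged")
      tau[enough] <- ifelse(conv, as.numeric(t), NA_real_)
      valid[enough] <- conv
    } else {
      idx <- which(enough)
      for (i in idx) {
        fit <- tryCatch(
          fitBiexponential(flat[i, ], dt, minPhotons = config$minPhotons,
                           shortRange = config$shortRange),
          error = function(e) NULL)
        if (!is.null(fit) && fit@converged) {
          tau[i] <- lifetimes(fit)[length(lifetimes(fit))]
          valid[i] <- TRUE
        }
      }
    }
  }
  if (!any(valid)) stop("no evaluable pixels")
  new("LifetimeMap",
      tau = matrix(tau, d[1], d[2]),
      photons = matrix(N, d[1], d[2]),
      valid = matrix(valid, d[1], d[2]),
      binWidth = dt,
      metadata = list(config = unclass(config)))
}

#' Filter a lifetime map to a lifetime acceptance window
#'
#' Marks invalid every pixel whose fitted lifetime lies outside
#' `[window[1], window[2]]`. This is the window mode of the autofluorescence
#' suppression strategy: contaminant-dominated pixels fit to short apparent
#' lifetimes and are excluded from ROI averaging. All other fields are left
#' unchanged; the operation is idempotent and never adds valid pixels.
#'
#' @param map a [LifetimeMap-class].
#' @param window numeric(2), acceptance window in ns (`min < max`).
#' @return the filtered [LifetimeMap-class].
#' @export
lifetimeFilter <- function(map, window) {
  stopifnot(is(map, "LifetimeMap"), length(window) == 2L,
            window[1] < window[2])
  keep <- map@valid & !is.na(map@tau) &
    map@tau >= window[1] & map@tau <= window[2]
  tau <- map@tau
  tau[!keep] <- NA_real_
  new("LifetimeMap", tau = tau, photons = map@photons, valid = keep,
      binWidth = map@binWidth,
      metadata = c(map@metadata, list(filterWindow = window)))
}

#' ROI mean lifetime of a lifetime map
#'
#' Average lifetime over all valid pixels. The default weights each pixel by
#' its photon count (photon-weighted mean, the estimator implied by pooling
#' all ROI photons); `"uniform"` averages pixels equally.
#'
#' @param map a [LifetimeMap-class].
#' @param weighting `"photon"` (default) or `"uniform"`.
#' @return mean lifetime in ns.
#' @export
roiMeanLifetime <- function(map, weighting = c("photon", "uniform")) {
  stopifnot(is(map, "LifetimeMap"))
  weighting <- match.arg(weighting)
  v <- map@valid
  if (!any(v)) stop("no valid pixels in lifetime map")
  tau <- map@tau[v]
  if (weighting == "photon") {
    w <- map@photons[v]
    sum(tau * w) / sum(w)
  } else {
    mean(tau)
  }
}

#' FRET efficiency from donor and donor+acceptor lifetimes
#'
#' `E = 1 - tauDA / tauD`. E may be negative when `tauDA > tauD` (serial
#' sections are independent tissue samples, so sampling noise can push the
#' donor+acceptor lifetime above the donor-only one); negative values are
#' returned as-is and marked in the `"negative"` attribute rather than
#' clipped, so downstream ROC analysis sees the full scale.
#'
#' @param tauD donor-only lifetime(s), ns, > 0.
#' @param tauDA donor-plus-acceptor lifetime(s), ns, > 0.
#' @return numeric FRET efficiency (unitless, < 1), with a logical
#'   `"negative"` attribute flagging entries below zero.
#' @export
fretEfficiency <- function(tauD, tauDA) {
  if (any(tauD <= 0) || any(tauDA <= 0))
    stop("lifetimes must be positive")
  e <- 1 - tauDA / tauD
  attr(e, "negative") <- e < 0
  e
}

#' ROI FRET efficiency for a donor / donor+acceptor cube pair
#'
#' Runs the full per-core analysis: builds lifetime maps for both cubes,
#' applies the lifetime filter window, computes the ROI mean lifetimes
#' (tauD from the donor cube, tauDA from the donor+acceptor cube) and their
#' FRET efficiency. A core whose maps retain no valid pixels after filtering
#' is excluded with an explicit error (mirroring cores unsuitable for
#' analysis).
#'
#' @param donorCube,donorAcceptorCube [TCSPCCube-class] objects.
#' @param config a [flimConfig()].
#' @return a [FretResult-class].
#' @export
coreFret <- function(donorCube, donorAcceptorCube, config = flimConfig()) {
  mapOne <- function(cube, label) {
    m <- tryCatch(buildLifetimeMap(cube, config), error = function(e)
      stop("core excluded: ", label, " map unevaluable (", conditionMessage(e),
           ")", call. = FALSE))
    m <- lifetimeFilter(m, config$filterWindow)
    if (!any(validMask(m)))
      stop("core excluded: ", label,
           " map has no valid pixels after lifetime filtering", call. = FALSE)
    m
  }
  mD <- mapOne(donorCube, "donor")
  mDA <- mapOne(donorAcceptorCube, "donor+acceptor")
  tauD <- roiMeanLifetime(mD, config$weighting)
  tauDA <- roiMeanLifetime(mDA, config$weighting)
  e <- as.numeric(fretEfficiency(tauD, tauDA))
  new("FretResult", tauD = tauD, tauDA = tauDA, fretEfficiency = e,
      nPixelsD = sum(validMask(mD)), nPixelsDA = sum(validMask(mDA)),
      flags = if (e < 0) "negativeE" else character())
}
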