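#' @import methods
NULL

#' TCSPCCube: a time-correlated single photon counting acquisition
#'
#' Container for a 3-D photon-count histogram cube (rows x cols x time bins)
#' together with its timing metadata. One cube corresponds to one FLIM
#' acquisition of one tissue core (or cell field): each pixel holds the
#' arrival-time histogram of the photons detected there.
#'
#' @slot counts integer array, rows x cols x nBins, non-negative photon counts.
#' @slot timeWindow numeric(1), full measurement window in ns.
#' @slot metadata list of free-form acquisition metadata (seed, config echo).
#'
#' @exportClass TCSPCCube
setClass("TCSPCCube",
  representation(counts = "array", timeWindow = "numeric", metadata = "list"),
  prototype(timeWindow = 12.5, metadata = list())
)

setValidity("TCSPCCube", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be a 3-D array (rows x cols x time bins)")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@timeWindow) != 1L || object@timeWindow <= 0)
    msg <- c(msg, "timeWindow must be a single positive value (ns)")
  if (length(dim(object@counts)) == 3L && dim(object@counts)[3] < 8L)
    msg <- c(msg, "need at least 8 time bins")
  if (length(msg)) msg else TRUE
})

#' LifetimeMap: per-pixel fitted lifetimes with a validity mask
#'
#' Result of fitting a decay model at every pixel of a [TCSPCCube].
#' `tau` holds the per-pixel mean fluorescence lifetime (photon-weighted over
#' components when the fit has more than one), defined only where `valid` is
#' TRUE; elsewhere it is NA. Pixels become invalid by failing the intensity
#' threshold, failing to converge, or falling outside a lifetime acceptance
#' window (see [lifetimeFilter()]).
#'
#' @slot tau numeric matrix of lifetimes (ns); NA where invalid.
#' @slot photons numeric matrix of per-pixel photon counts used in the fit.
#' @slot valid logical matrix, the validity mask.
#' @slot binWidth numeric(1), time bin width (ns) of the source histograms.
#' @slot metadata list (fit configuration echo, filter window applied, ...).
#'
#' @exportClass LifetimeMap
setClass("LifetimeMap",
  representation(tau = "matrix", photons = "matrix", valid = "matrix",
                 binWidth = "numeric", metadata = "list"),
  prototype(metadata = list())
)

setValidity("LifetimeMap", function(object) {
  msg <- character()
  d <- dim(object@tau)
  if (!identical(d, dim(object@photons)) || !identical(d, dim(object@valid)))
    msg <- c(msg, "tau, photons and valid must have identical dimensions")
  if (!is.logical(object@valid))
    msg <- c(msg, "valid must be a logical matrix")
  if (any(object@valid & !is.finite(object@tau)))
    msg <- c(msg, "tau must be finite wherever valid")
  if (any(!is.na(object@tau) & !object@valid))
    msg <- c(msg, "tau must be NA wherever invalid")
  if (length(msg)) msg else TRUE
})

#' DecayFit: a fitted TCSPC decay model for one histogram
#'
#' @slot lifetimes numeric, 1 or 2 fitted lifetimes (ns); for two components
#'   they are strictly ordered, short first.
#' @slot ampFractions numeric, photon fractions per component, in [0,1] and
#'   summing to 1.
#' @slot photonCount numeric(1), total photons in the fitted histogram.
#' @slot goodness numeric(1), reduced chi-square-like Pearson statistic.
#' @slot converged logical(1).
#' @slot flags character, e.g. "degenerate" when a two-component fit collapsed.
#'
#' @exportClass DecayFit
setClass("DecayFit",
  representation(lifetimes = "numeric", ampFractions = "numeric",
                 photonCount = "numeric", goodness = "numeric",
                 converged = "logical", flags = "character"),
  prototype(flags = character())
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (length(object@lifetimes) < 1L || length(object@lifetimes) > 2L)
    msg <- c(msg, "1 or 2 lifetimes expected")
  if (object@converged && any(object@lifetimes <= 0))
    msg <- c(msg, "lifetimes must be positive for a converged fit")
  if (length(object@lifetimes) != length(object@ampFractions))
    msg <- c(msg, "one amplitude fraction per lifetime")
  if (abs(sum(object@ampFractions) - 1) > 1e-9)
    msg <- c(msg, "amplitude fractions must sum to 1")
  if (length(object@lifetimes) == 2L &&
      object@lifetimes[1] >= object@lifetimes[2])
    msg <- c(msg, "two-component lifetimes must be strictly ordered")
  if (length(msg)) msg else TRUE
})

#' FretResult: ROI-level FRET efficiency for one donor / donor+acceptor pair
#'
#' FRET efficiency is defined as E = 1 - tauDA/tauD, where tauD is the
#' average donor lifetime from the donor-only image and tauDA the average
#' donor lifetime in the acceptor's presence. Negative values (tauDA > tauD,
#' possible with serial-section noise) are reported and flagged, not clipped.
#'
#' @slot tauD,tauDA numeric(1), ROI mean lifetimes (ns).
#' @slot fretEfficiency numeric(1), 1 - tauDA/tauD.
#' @slot nPixelsD,nPixelsDA numeric(1), valid pixel counts entering each mean.
#' @slot flags character, e.g. "negativeE".
#'
#' @exportClass FretResult
setClass("FretResult",
  representation(tauD = "numeric", tauDA = "numeric",
                 fretEfficiency = "numeric", nPixelsD = "numeric",
                 nPixelsDA = "numeric", flags = "character"),
  prototype(flags = character())
)

setValidity("FretResult", function(object) {
  msg <- character()
  if (object@tauD <= 0 || object@tauDA <= 0)
    msg <- c(msg, "lifetimes must be positive")
  if (abs(object@fretEfficiency - (1 - object@tauDA / object@tauD)) > 1e-12)
    msg <- c(msg, "fretEfficiency must equal 1 - tauDA/tauD")
  if (length(msg)) msg else TRUE
})

#' RateConstants: dissociation constants of the HER dimerization network
#'
#' Symmetric matrix of dissociation constants Kd[i,j] (concentration units)
#' for every permitted dimer pair; `Inf` disables a pair. Homodimers follow
#' the statistical-factor convention [E_ii] = free_i^2 / Kd[i,i], with
#' conservation counting 2 [E_ii] monomers.
#'
#' @slot kd numeric symmetric matrix of Kd values (> 0, Inf = disabled).
#'
#' @exportClass RateConstants
setClass("RateConstants", representation(kd = "matrix"))

setValidity("RateConstants", function(object) {
  msg <- character()
  k <- object@kd
  if (nrow(k) != ncol(k)) msg <- c(msg, "kd must be square")
  if (!isTRUE(all.equal(k, t(k)))) msg <- c(msg, "kd must be symmetric")
  if (any(k <= 0, na.rm = TRUE)) msg <- c(msg, "all Kd must be positive")
  if (any(is.na(k))) msg <- c(msg, "kd must not contain NA")
  if (length(msg)) msg else TRUE
})

#' EquilibriumState: steady state of the receptor dimerization network
#'
#' Free monomer and dimer concentrations at mass-action equilibrium. The
#' object satisfies, for every receptor i,
#' free_i + sum_{j != i} dimers[i,j] + 2 dimers[i,i] = totals_i
#' and, for every enabled pair, dimers[i,j] * Kd[i,j] = free_i * free_j,
#' both to 1e-8 relative (asserted by the validity method).
#'
#' @slot free numeric, free monomer concentration per receptor.
#' @slot dimers numeric symmetric matrix; `dimers[i,j]` is the concentration
#'   of the i-j dimer ([E_ii] on the diagonal, statistical-factor convention).
#' @slot totals numeric, total abundances the state was solved for.
#' @slot kd numeric matrix, the Kd matrix the state was solved with.
#'
#' @exportClass EquilibriumState
setClass("EquilibriumState",
  representation(free = "numeric", dimers = "matrix", totals = "numeric",
                 kd = "matrix")
)

setValidity("EquilibriumState", function(object) {
  msg <- character()
  f <- object@free; D <- object@dimers; tot <- object@totals; kd <- object@kd
  r <- length(f)
  if (!identical(dim(D), c(r, r))) msg <- c(msg, "dimers must be r x r")
  if (length(tot) != r) msg <- c(msg, "totals must have one entry per receptor")
  if (any(f < 0) || any(D < 0)) msg <- c(msg, "concentrations must be >= 0")
  scale <- pmax(tot, max(tot, 1e-300))
  bound <- rowSums(D) + diag(D)           # sum_{j!=i} D_ij + 2 D_ii
  resid <- abs(f + bound - tot) / pmax(scale, 1e-300)
  if (any(resid > 1e-8))
    msg <- c(msg, sprintf("conservation violated (max rel resid %.3g)",
                          max(resid)))
  # Equilibrium relation checked at 1e-8 relative for every species of
  # appreciable size; species below a small absolute floor (relative to the
  # largest attainable concentration product) are at solver precision and
  # compared absolutely by the same floor.
  floor <- 1e-5 * max(max(tot)^2, 1e-300)
  for (i in seq_len(r)) for (j in i:r) {
    if (is.finite(kd[i, j])) {
      lhs <- D[i, j] * kd[i, j]; rhs <- f[i] * f[j]
      if (max(lhs, rhs) >= floor &&
          abs(lhs - rhs) / max(lhs, rhs) > 1e-8)
        msg <- c(msg, sprintf("equilibrium violated for pair (%d,%d)", i, j))
    } else if (D[i, j] != 0) {
      msg <- c(msg, sprintf("disabled pair (%d,%d) has nonzero dimer", i, j))
    }
  }
  if (length(msg)) msg else TRUE
})
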