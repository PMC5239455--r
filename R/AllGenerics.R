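# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname TCSPCCube-accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname TCSPCCube-accessors
#' @export
setGeneric("timeWindow", function(object) standardGeneric("timeWindow"))

#' @rdname TCSPCCube-accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname TCSPCCube-accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname LifetimeMap-accessors
#' @export
setGeneric("tauMap", function(object) standardGeneric("tauMap"))

#' @rdname LifetimeMap-accessors
#' @export
setGeneric("photonMap", function(object) standardGeneric("photonMap"))

#' @rdname LifetimeMap-accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname DecayFit-accessors
#' @export
setGeneric("lifetimes", function(object) standardGeneric("lifetimes"))

#' @rdname DecayFit-accessors
#' @export
setGeneric("ampFractions", function(object) standardGeneric("ampFractions"))

#' @rdname EquilibriumState-accessors
#' @export
setGeneric("freeMonomers", function(object) standardGeneric("freeMonomers"))

#' @rdname EquilibriumState-accessors
#' @export
setGeneric("dimerLevels", function(object) standardGeneric("dimerLevels"))

#' @rdname RateConstants-accessors
#' @export
setGeneric("kdMatrix", function(object) standardGeneric("kdMatrix"))

#' Accessors for TCSPCCube
#'
#' @param object a [TCSPCCube-class].
#' @param ... unused.
#' @return `counts()` the 3-D count array; `timeWindow()` the window (ns);
#'   `nBins()` the number of time bins; `binWidth()` the bin width (ns).
#' @name TCSPCCube-accessors
#' @aliases counts,TCSPCCube-method timeWindow,TCSPCCube-method
#'   nBins,TCSPCCube-method binWidth,TCSPCCube-method
NULL

#' @rdname TCSPCCube-accessors
setMethod("counts", "TCSPCCube", function(object, ...) object@counts)

#' @rdname TCSPCCube-accessors
setMethod("timeWindow", "TCSPCCube", function(object) object@timeWindow)

#' @rdname TCSPCCube-accessors
setMethod("nBins", "TCSPCCube", function(object) dim(object@counts)[3])

#' @rdname TCSPCCube-accessors
setMethod("binWidth", "TCSPCCube",
          function(object) object@timeWindow / dim(object@counts)[3])

#' Accessors for LifetimeMap
#'
#' @param object a [LifetimeMap-class].
#' @return `tauMap()` per-pixel lifetime matrix (ns, NA where invalid);
#'   `photonMap()` per-pixel photon counts; `validMask()` the logical mask.
#' @name LifetimeMap-accessors
#' @aliases tauMap,LifetimeMap-method photonMap,LifetimeMap-method
#'   validMask,LifetimeMap-method
NULL

#' @rdname LifetimeMap-accessors
setMethod("tauMap", "LifetimeMap", function(object) object@tau)

#' @rdname LifetimeMap-accessors
setMethod("photonMap", "LifetimeMap", function(object) object@photons)

#' @rdname LifetimeMap-accessors
setMethod("validMask", "LifetimeMap", function(object) object@valid)

#' Accessors for DecayFit
#'
#' @param object a [DecayFit-class].
#' @return `lifetimes()` fitted lifetimes (ns); `ampFractions()` photon
#'   fractions per component.
#' @name DecayFit-accessors
#' @aliases lifetimes,DecayFit-method ampFractions,DecayFit-method
NULL

#' @rdname DecayFit-accessors
setMethod("lifetimes", "DecayFit", function(object) object@lifetimes)

#' @rdname DecayFit-accessors
setMethod("ampFractions", "DecayFit", function(object) object@ampFractions)

#' Accessors for EquilibriumState
#'
#' @param object an [EquilibriumState-class].
#' @return `freeMonomers()` named free monomer concentrations;
#'   `dimerLevels()` the symmetric dimer concentration matrix.
#' @name EquilibriumState-accessors
#' @aliases freeMonomers,EquilibriumState-method
#'   dimerLevels,EquilibriumState-method
NULL

#' @rdname EquilibriumState-accessors
setMethod("freeMonomers", "EquilibriumState", function(object) object@free)

#' @rdname EquilibriumState-accessors
setMethod("dimerLevels", "EquilibriumState", function(object) object@dimers)

#' Accessors for RateConstants
#'
#' @param object a [RateConstants-class].
#' @return `kdMatrix()` the symmetric Kd matrix (Inf = pair disabled).
#' @name RateConstants-accessors
#' @aliases kdMatrix,RateConstants-method
NULL

#' @rdname RateConstants-accessors
setMethod("kdMatrix", "RateConstants", function(object) object@kd)

setMethod("show", "TCSPCCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf("TCSPCCube: %d x %d pixels, %d time bins over %.3g ns (bin %.4g ns)\n",
              d[1], d[2], d[3], object@timeWindow, object@timeWindow / d[3]))
  cat(sprintf("  total photons: %.4g (mean %.4g / pixel)\n",
              sum(object@counts), sum(object@counts) / (d[1] * d[2])))
})

setMethod("show", "LifetimeMap", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("LifetimeMap: %d x %d pixels, %d valid (%.1f%%)\n",
              nrow(object@tau), ncol(object@tau), nv,
              100 * nv / length(object@valid)))
  if (nv > 0)
    cat(sprintf("  tau range (valid): %.3g - %.3g ns\n",
                min(object@tau, na.rm = TRUE), max(object@tau, na.rm = TRUE)))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit (%d component%s, %sconverged)\n",
              length(object@lifetimes),
              if (length(object@lifetimes) > 1) "s" else "",
              if (object@converged) "" else "NOT "))
  cat(sprintf("  tau = %s ns, fractions = %s\n",
              paste(signif(object@lifetimes, 5), collapse = ", "),
              paste(signif(object@ampFractions, 4), collapse = ", ")))
  cat(sprintf("  photons = %.4g, reduced chi^2 = %.4g\n",
              object@photonCount, object@goodness))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "FretResult", function(object) {
  cat(sprintf("FretResult: tauD = %.4g ns (%d px), tauDA = %.4g ns (%d px)\n",
              object@tauD, object@nPixelsD, object@tauDA, object@nPixelsDA))
  cat(sprintf("  FRET efficiency = %.4f (%.2f%%)\n",
              object@fretEfficiency, 100 * object@fretEfficiency))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "RateConstants", function(object) {
  cat(sprintf("RateConstants for %d receptors (Inf = pair disabled)\n",
              nrow(object@kd)))
  print(object@kd)
})

setMethod("show", "EquilibriumState", function(object) {
  cat("EquilibriumState\n  free monomers:\n")
  print(signif(object@free, 6))
  cat("  dimers:\n")
  print(signif(object@dimers, 6))
})
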