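#' Accessors for fit objects
#'
#' `ec50()`, `pec50()`, `emax()`, `bottom()` access the estimated asymptotes
#' and potency of a [LogisticFit-class]; `kOff()`, `kOn()`, `kObs()` and
#' `tHalf()` access a [KineticFit-class] (with `tHalf(x) == log(2)/kOff(x)`
#' exactly, by construction); `ki()` and `ic50()` access an
#' [AffinityEstimate-class]; `spatialCoef()` the median coefficients of a
#' [SpatialCoefficients-class]; `transients()` the event table of a
#' [TransientSet-class].
#'
#' @param object a fit or result object.
#' @return numeric scalar(s) or, for `transients()`, a data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))
#' @rdname accessors
#' @export
setGeneric("pec50", function(object) standardGeneric("pec50"))
#' @rdname accessors
#' @export
setGeneric("emax", function(object) standardGeneric("emax"))
#' @rdname accessors
#' @export
setGeneric("bottom", function(object) standardGeneric("bottom"))
#' @rdname accessors
#' @export
setGeneric("kOff", function(object) standardGeneric("kOff"))
#' @rdname accessors
#' @export
setGeneric("kOn", function(object) standardGeneric("kOn"))
#' @rdname accessors
#' @export
setGeneric("kObs", function(object) standardGeneric("kObs"))
#' @rdname accessors
#' @export
setGeneric("tHalf", function(object) standardGeneric("tHalf"))
#' @rdname accessors
#' @export
setGeneric("ki", function(object) standardGeneric("ki"))
#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setGeneric("spatialCoef", function(object) standardGeneric("spatialCoef"))
#' @rdname accessors
#' @export
setGeneric("transients", function(object) standardGeneric("transients"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
setMethod("ec50", "LogisticFit", function(object) object@ec50)
#' @rdname accessors
setMethod("pec50", "LogisticFit", function(object) -log10(object@ec50))
#' @rdname accessors
setMethod("emax", "LogisticFit", function(object) object@top)
#' @rdname accessors
setMethod("bottom", "LogisticFit", function(object) object@bottom)
#' @rdname accessors
setMethod("isConverged", "LogisticFit", function(object) object@converged)

#' @rdname accessors
setMethod("kOff", "KineticFit", function(object) object@kOff)
#' @rdname accessors
setMethod("kOn", "KineticFit", function(object) object@kOn)
#' @rdname accessors
setMethod("kObs", "KineticFit", function(object) object@kObs)
#' @rdname accessors
setMethod("tHalf", "KineticFit", function(object) log(2) / object@kOff)
#' @rdname accessors
setMethod("isConverged", "KineticFit", function(object) object@converged)

#' @rdname accessors
setMethod("ki", "AffinityEstimate", function(object) object@ki)
#' @rdname accessors
setMethod("ic50", "AffinityEstimate", function(object) object@ic50)

#' @rdname accessors
setMethod("spatialCoef", "SpatialCoefficients",
          function(object) object@coefficients)
#' @rdname accessors
setMethod("transients", "TransientSet", function(object) object@events)

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit (", object@direction, ") for ", object@compound, "\n",
      sep = "")
  cat(sprintf("  bottom %.4g  top %.4g  EC50 %.4g M (pEC50 %.3f)\n",
              object@bottom, object@top, object@ec50, -log10(object@ec50)))
  cat("  converged:", object@converged,
      if (length(object@flags)) paste0(" [", paste(object@flags,
                                                   collapse = ", "), "]"),
      "\n")
})

setMethod("show", "KineticFit", function(object) {
  cat("KineticFit\n")
  if (!is.na(object@kOff))
    cat(sprintf("  k_off %.4g /min  t_1/2 %.4g min\n", object@kOff,
                log(2) / object@kOff))
  if (!is.na(object@kObs))
    cat(sprintf("  k_obs %.4g /min  k_on %.4g /M/min (L = %.3g M)\n",
                object@kObs, object@kOn, object@ligandConc))
  cat("  converged:", object@converged,
      if (length(object@flags)) paste0(" [", paste(object@flags,
                                                   collapse = ", "), "]"),
      "\n")
})

setMethod("show", "AffinityEstimate", function(object) {
  cat(sprintf(
    "AffinityEstimate: IC50 %.4g M, Ki %.4g M (L %.3g M, Kd %.3g M)\n",
    object@ic50, object@ki, object@ligandConc, object@kd))
})

setMethod("show", "PhotometryRecording", function(object) {
  cat(sprintf(
    "PhotometryRecording '%s': %d samples at %g Hz (%.1f s)\n",
    object@animalId, length(object@time), object@fs,
    length(object@time) / object@fs))
  cat(sprintf("  baseline [%g, %g] s, injection at %g s\n",
              object@baselineWindow[1], object@baselineWindow[2],
              object@injectionTime))
})

setMethod("show", "TransientSet", function(object) {
  cat(sprintf(
    "TransientSet: %d events (threshold %.4g, %.3g events/min)\n",
    nrow(object@events), object@threshold, object@frequencyPerMin))
})

setMethod("show", "SpatialCoefficients", function(object) {
  cat(sprintf("SpatialCoefficients (median of %d repeats, %d dummies):\n",
              object@nRepeats, object@nDummy))
  print(round(object@coefficients, 4))
})
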