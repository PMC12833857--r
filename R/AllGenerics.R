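## Accessor generics; slot access from user code is discouraged.

#' Peak table of a record
#' @param object a [SpectrumRecord-class].
#' @return The peak `data.frame`.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname peaks
#' @export
setMethod("peaks", "SpectrumRecord", function(object) object@peaks)

#' Number of peaks in a record
#' @param object a [SpectrumRecord-class].
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname nPeaks
#' @export
setMethod("nPeaks", "SpectrumRecord", function(object) nrow(object@peaks))

#' Species label
#' @param object a [SpectrumRecord-class].
#' @export
setGeneric("species", function(object) standardGeneric("species"))
#' @rdname species
#' @export
setMethod("species", "SpectrumRecord", function(object) object@species)

#' Conformer label
#' @param object a [SpectrumRecord-class].
#' @export
setGeneric("conformer", function(object) standardGeneric("conformer"))
#' @rdname conformer
#' @export
setMethod("conformer", "SpectrumRecord", function(object) object@conformer)

#' Record source ("experimental" or "computed")
#' @param object a [SpectrumRecord-class].
#' @export
setGeneric("spectrumSource", function(object)
  standardGeneric("spectrumSource"))
#' @rdname spectrumSource
#' @export
setMethod("spectrumSource", "SpectrumRecord", function(object) object@source)

#' Theory level of a record or factor set
#' @param object a [SpectrumRecord-class] or [ScalingFactorSet-class].
#' @return A [TheoryLevel-class] or `NULL`.
#' @export
setGeneric("theory", function(object) standardGeneric("theory"))
#' @rdname theory
#' @export
setMethod("theory", "SpectrumRecord", function(object) object@theory)
#' @rdname theory
#' @export
setMethod("theory", "ScalingFactorSet", function(object) object@theory)

#' Scaling scheme of a factor set
#' @param object a [ScalingFactorSet-class].
#' @export
setGeneric("scheme", function(object) standardGeneric("scheme"))
#' @rdname scheme
#' @export
setMethod("scheme", "ScalingFactorSet", function(object) object@scheme)

#' Factor table of a ScalingFactorSet
#' @param object a [ScalingFactorSet-class].
#' @return Data frame with columns `class`, `lambda`, `delta_lambda`, `n`.
#' @export
setGeneric("factorTable", function(object) standardGeneric("factorTable"))
#' @rdname factorTable
#' @export
setMethod("factorTable", "ScalingFactorSet", function(object) object@factors)

#' Look up the scaling factor for one mode class
#' @param object a [ScalingFactorSet-class].
#' @param class a mode class label (e.g. `"OH"`, `"mid"`, `"global"`).
#' @return lambda as a single numeric, or `NA` when the class is absent.
#' @export
setGeneric("lambdaFor", function(object, class) standardGeneric("lambdaFor"))
#' @rdname lambdaFor
#' @export
setMethod("lambdaFor", "ScalingFactorSet", function(object, class) {
  i <- match(class, object@factors$class)
  ifelse(is.na(i), NA_real_, object@factors$lambda[i])
})

#' Cost matrix entries
#' @param object a [CostMatrix-class].
#' @export
setGeneric("costEntries", function(object) standardGeneric("costEntries"))
#' @rdname costEntries
#' @export
setMethod("costEntries", "CostMatrix", function(object) object@entries)

#' Matched pairs of a barcode
#' @param object a [Barcode-class].
#' @export
setGeneric("assignedPairs", function(object)
  standardGeneric("assignedPairs"))
#' @rdname assignedPairs
#' @export
setMethod("assignedPairs", "Barcode", function(object) object@pairs)

#' Total assignment cost of a barcode
#' @param object a [Barcode-class].
#' @export
setGeneric("totalCost", function(object) standardGeneric("totalCost"))
#' @rdname totalCost
#' @export
setMethod("totalCost", "Barcode", function(object) object@total_cost)

#' Grid wavenumbers of a continuous spectrum
#' @param object a [ContinuousSpectrum-class].
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
setGeneric("gridWavenumbers", function(object)
  standardGeneric("gridWavenumbers"))
#' @rdname gridWavenumbers
#' @export
setMethod("gridWavenumbers", "ContinuousSpectrum", function(object)
  object@gridStart + (seq_along(object@values) - 1L) * object@gridStep)

#' Intensity values of a continuous spectrum
#' @param object a [ContinuousSpectrum-class].
#' @export
setGeneric("intensityValues", function(object)
  standardGeneric("intensityValues"))
#' @rdname intensityValues
#' @export
setMethod("intensityValues", "ContinuousSpectrum", function(object)
  object@values)
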