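#' @import methods
#' @importFrom stats cor quantile rnorm runif rpois rlnorm sd setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib vibmatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Controlled vocabularies -----------------------------------------------

.FUNCTIONALS <- c("M06-2X", "M06-2X-D3", "B3LYP", "B3LYP-D3", "wB97X-D")
.BASES <- c("6-311++G(d,p)", "cc-pVTZ")

## The functional/basis combinations for which harmonic frequencies are
## tabulated; not every functional is paired with every basis.
.THEORY_LEVELS <- data.frame(
  functional = c("M06-2X", "M06-2X-D3", "M06-2X-D3", "B3LYP",
                 "B3LYP-D3", "B3LYP-D3", "wB97X-D", "wB97X-D"),
  basis = c("6-311++G(d,p)", "6-311++G(d,p)", "cc-pVTZ", "6-311++G(d,p)",
            "6-311++G(d,p)", "cc-pVTZ", "6-311++G(d,p)", "cc-pVTZ"),
  stringsAsFactors = FALSE
)

.MODE_CLASSES <- c("OH", "NH", "CH_ring", "CH_ethyl", "mid", "low", "high")
.STRETCH_CLASSES <- c("OH", "NH", "CH_ring", "CH_ethyl")
.SCHEMES <- c("global", "mode_dependent", "range_dependent")
.CHANNELS <- c("loss", "gain", "computed")

.schemeClasses <- function(scheme) {
  switch(scheme,
         global = "global",
         mode_dependent = c("OH", "NH", "CH_ring", "CH_ethyl", "mid", "low"),
         range_dependent = c("high", "mid", "low"))
}

## Classes ---------------------------------------------------------------

#' TheoryLevel: a density functional / basis set combination
#'
#' Identifies the level of electronic-structure theory at which a set of
#' harmonic vibrational frequencies was computed. Only the combinations for
#' which the scaling-factor machinery carries reference data are accepted:
#' M06-2X and B3LYP with 6-311++G(d,p); M06-2X-D3, B3LYP-D3 and wB97X-D
#' (the ASCII spelling of the omega-B97X-D functional) with either
#' 6-311++G(d,p) or cc-pVTZ.
#'
#' @slot functional character(1), one of `"M06-2X"`, `"M06-2X-D3"`,
#'   `"B3LYP"`, `"B3LYP-D3"`, `"wB97X-D"`.
#' @slot basis character(1), one of `"6-311++G(d,p)"`, `"cc-pVTZ"`.
#' @export
setClass("TheoryLevel",
         representation(functional = "character", basis = "character"))

setValidity("TheoryLevel", function(object) {
  msg <- character()
  if (length(object@functional) != 1L || length(object@basis) != 1L)
    msg <- c(msg, "functional and basis must each be length 1")
  else {
    ok <- any(.THEORY_LEVELS$functional == object@functional &
                .THEORY_LEVELS$basis == object@basis)
    if (!ok)
      msg <- c(msg, sprintf(
        "unknown theory level '%s/%s'; see theoryLevels()",
        object@functional, object@basis))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TheoryLevel
#'
#' @param functional density functional name (ASCII; `"wB97X-D"` denotes
#'   omega-B97X-D).
#' @param basis basis set name.
#' @return A [TheoryLevel-class] object.
#' @examples
#' theoryLevel("M06-2X-D3", "6-311++G(d,p)")
#' @export
theoryLevel <- function(functional, basis) {
  new("TheoryLevel", functional = as.character(functional),
      basis = as.character(basis))
}

#' All supported theory levels
#'
#' @return A list of [TheoryLevel-class] objects, one per supported
#'   functional/basis combination (8 in total).
#' @export
theoryLevels <- function() {
  lapply(seq_len(nrow(.THEORY_LEVELS)), function(i)
    theoryLevel(.THEORY_LEVELS$functional[i], .THEORY_LEVELS$basis[i]))
}

#' @describeIn theoryLevel Compact `"functional/basis"` key for a level.
#' @param object a `TheoryLevel`.
#' @export
levelKey <- function(object) {
  if (is.null(object)) return(NA_character_)
  paste(object@functional, object@basis, sep = "/")
}

setMethod("show", "TheoryLevel", function(object) {
  cat("TheoryLevel:", levelKey(object), "\n")
})

#' SpectrumRecord: a labeled vibrational peak list
#'
#' The central container of the package: an ordered table of spectral
#' features (band maxima used as estimated fundamental frequencies for
#' experimental data, or harmonic stick frequencies for computed data),
#' together with provenance labels.
#'
#' The `peaks` data frame always carries columns `frequency` (wavenumber,
#' cm^-1, strictly positive and strictly increasing), `intensity`
#' (arbitrary units, non-negative), `fwhm` (cm^-1 or `NA`), `snr`
#' (dimensionless or `NA`) and `channel` (`"loss"`, `"gain"`, `"computed"`
#' or `NA`). Computed records may also carry a `mode_class` column
#' labelling pure stretching modes (`"OH"`, `"NH"`, `"CH_ring"`,
#' `"CH_ethyl"`) so that mode-dependent scaling can be applied.
#'
#' @slot species species identifier.
#' @slot conformer conformer label (e.g. `"C*"`, `"G1h"`).
#' @slot source `"experimental"` or `"computed"`.
#' @slot theory a [TheoryLevel-class] for computed records, else `NULL`.
#' @slot peaks the peak data frame (see Details).
#' @slot metadata free-form list; unknown input columns are preserved here.
#' @export
setClass("SpectrumRecord",
         representation(species = "character", conformer = "character",
                        source = "character", theory = "ANY",
                        peaks = "data.frame", metadata = "list"))

.PEAK_COLS <- c("frequency", "intensity", "fwhm", "snr", "channel")

setValidity("SpectrumRecord", function(object) {
  msg <- character()
  p <- object@peaks
  if (!all(c("frequency", "intensity") %in% names(p)))
    return("peaks must have 'frequency' and 'intensity' columns")
  if (length(object@source) != 1L ||
      !object@source %in% c("experimental", "computed"))
    msg <- c(msg, "source must be 'experimental' or 'computed'")
  if (!is.null(object@theory) && !is(object@theory, "TheoryLevel"))
    msg <- c(msg, "theory must be NULL or a TheoryLevel")
  if (nrow(p)) {
    if (!is.numeric(p$frequency) || anyNA(p$frequency) ||
        any(!is.finite(p$frequency)) || any(p$frequency <= 0))
      msg <- c(msg, "peak frequencies must be finite and > 0")
    else {
      if (is.unsorted(p$frequency, strictly = FALSE))
        msg <- c(msg, "peaks must be sorted by ascending frequency")
      if (anyDuplicated(p$frequency))
        msg <- c(msg, "no two peaks may share an identical frequency")
    }
    if (!is.numeric(p$intensity) || anyNA(p$intensity) ||
        any(p$intensity < 0))
      msg <- c(msg, "peak intensities must be numeric and >= 0")
    if ("fwhm" %in% names(p)) {
      bad <- !is.na(p$fwhm) & p$fwhm <= 0
      if (any(bad)) msg <- c(msg, "fwhm must be > 0 when present")
    }
    if ("channel" %in% names(p)) {
      bad <- !is.na(p$channel) & !p$channel %in% .CHANNELS
      if (any(bad))
        msg <- c(msg, sprintf("channel must be one of %s",
                              paste(.CHANNELS, collapse = ", ")))
    }
    if ("mode_class" %in% names(p)) {
      bad <- !is.na(p$mode_class) & !p$mode_class %in% .MODE_CLASSES
      if (any(bad)) msg <- c(msg, "unknown mode_class label in peaks")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumRecord from peak vectors
#'
#' Peaks are sorted by ascending frequency on construction; all auxiliary
#' columns are reordered along with them.
#'
#' @param frequency numeric vector of wavenumbers (cm^-1), > 0.
#' @param intensity numeric vector of intensities (arbitrary units, >= 0).
#' @param fwhm,snr,channel,mode_class optional per-peak columns.
#' @param species,conformer identifying labels.
#' @param source `"experimental"` or `"computed"`.
#' @param theory a [TheoryLevel-class] or `NULL`.
#' @param metadata a list of record-level metadata.
#' @return A [SpectrumRecord-class].
#' @examples
#' spectrumRecord(c(1600, 400, 3600), c(1, 2, 3), source = "experimental")
#' @export
spectrumRecord <- function(frequency, intensity,
                           fwhm = NA_real_, snr = NA_real_,
                           channel = NA_character_, mode_class = NULL,
                           species = "unknown", conformer = "unknown",
                           source = c("experimental", "computed"),
                           theory = NULL, metadata = list()) {
  source <- match.arg(source)
  n <- length(frequency)
  p <- data.frame(frequency = as.numeric(frequency),
                  intensity = as.numeric(intensity),
                  fwhm = rep_len(as.numeric(fwhm), n),
                  snr = rep_len(as.numeric(snr), n),
                  channel = rep_len(as.character(channel), n),
                  stringsAsFactors = FALSE)
  if (!is.null(mode_class))
    p$mode_class <- rep_len(as.character(mode_class), n)
  ord <- order(p$frequency)
  p <- p[ord, , drop = FALSE]
  rownames(p) <- NULL
  new("SpectrumRecord", species = as.character(species),
      conformer = as.character(conformer), source = source,
      theory = theory, peaks = p, metadata = metadata)
}

setMethod("show", "SpectrumRecord", function(object) {
  cat(sprintf("SpectrumRecord '%s' / '%s' (%s%s): %d peaks",
              object@species, object@conformer, object@source,
              if (!is.null(object@theory))
                paste0(", ", levelKey(object@theory)) else "",
              nrow(object@peaks)))
  if (nrow(object@peaks))
    cat(sprintf(", %.1f-%.1f cm-1", min(object@peaks$frequency),
                max(object@peaks$frequency)))
  cat("\n")
})

#' ScalingFactorSet: fitted frequency scaling factors for one scheme
#'
#' Holds, for one scaling scheme and (optionally) one theory level, the
#' least-squares scaling factor lambda, its uncertainty and the number of
#' frequency pairs per class. Schemes: `"global"` (one factor),
#' `"range_dependent"` (`high` > 2000 cm^-1, `mid` 1000-2000 cm^-1,
#' `low` < 1000 cm^-1) and `"mode_dependent"` (`OH`, `NH`, `CH_ring`,
#' `CH_ethyl` stretch labels plus `mid`/`low` ranges).
#'
#' @slot scheme one of `"global"`, `"mode_dependent"`, `"range_dependent"`.
#' @slot theory a [TheoryLevel-class] or `NULL`.
#' @slot factors data frame with columns `class`, `lambda`, `delta_lambda`,
#'   `n`.
#' @export
setClass("ScalingFactorSet",
         representation(scheme = "character", theory = "ANY",
                        factors = "data.frame"))

setValidity("ScalingFactorSet", function(object) {
  msg <- character()
  if (!object@scheme %in% .SCHEMES)
    msg <- c(msg, "unknown scheme")
  f <- object@factors
  need <- c("class", "lambda", "delta_lambda", "n")
  if (!all(need %in% names(f)))
    return("factors must have columns class, lambda, delta_lambda, n")
  if (!is.null(object@theory) && !is(object@theory, "TheoryLevel"))
    msg <- c(msg, "theory must be NULL or a TheoryLevel")
  allowed <- .schemeClasses(object@scheme)
  if (!is.null(allowed) && !all(f$class %in% allowed))
    msg <- c(msg, sprintf("classes must be a subset of {%s} for scheme %s",
                          paste(allowed, collapse = ", "), object@scheme))
  if (anyDuplicated(f$class))
    msg <- c(msg, "duplicate class entries")
  if (nrow(f)) {
    if (any(f$lambda <= 0) || anyNA(f$lambda))
      msg <- c(msg, "lambda must be positive")
    if (any(f$delta_lambda < 0, na.rm = TRUE))
      msg <- c(msg, "delta_lambda must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScalingFactorSet", function(object) {
  cat(sprintf("ScalingFactorSet (%s%s)\n", object@scheme,
              if (!is.null(object@theory))
                paste0(", ", levelKey(object@theory)) else ""))
  f <- object@factors
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-9s lambda = %.4f +/- %.4f  (n = %d)\n",
                f$class[i], f$lambda[i], f$delta_lambda[i], f$n[i]))
})

#' CostMatrix: pairwise peak distances between two records
#'
#' Rows index measured peaks, columns calculated peaks. Entries are one of
#' three metrics: `euclid_1d` |dnu|; `euclid_2d` sqrt(dnu^2 + w^2 dI^2);
#' `manhattan_2d` |dnu| + w|dI|, where w is the intensity weight in cm^-1
#' per unit normalized intensity.
#'
#' @slot entries numeric matrix of costs (>= 0).
#' @slot metric one of `"euclid_1d"`, `"euclid_2d"`, `"manhattan_2d"`.
#' @slot weight intensity weight w (cm^-1 per unit intensity).
#' @slot measured,calc the peak data frames the entries were computed from.
#' @export
setClass("CostMatrix",
         representation(entries = "matrix", metric = "character",
                        weight = "numeric", measured = "data.frame",
                        calc = "data.frame"))

setValidity("CostMatrix", function(object) {
  msg <- character()
  if (!object@metric %in% c("euclid_1d", "euclid_2d", "manhattan_2d"))
    msg <- c(msg, "unknown metric")
  if (length(object@weight) != 1L || object@weight < 0)
    msg <- c(msg, "weight must be a single value >= 0")
  e <- object@entries
  if (length(e) == 0L) msg <- c(msg, "empty cost matrix")
  else if (any(!is.finite(e)) || any(e < 0))
    msg <- c(msg, "entries must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CostMatrix", function(object) {
  cat(sprintf("CostMatrix %d x %d (%s, w = %g)\n", nrow(object@entries),
              ncol(object@entries), object@metric, object@weight))
})

#' Barcode: a minimal-cost assignment of measured to calculated peaks
#'
#' The result of Kuhn-Munkres (Hungarian) assignment on a [CostMatrix-class]:
#' every measured peak is matched to a distinct calculated peak so that the
#' summed cost is minimal; surplus calculated peaks stay unmatched at zero
#' penalty. The ordered matched pairs form the spectral barcode used for
#' distance-based conformer ranking.
#'
#' @slot pairs data frame with columns `measured`, `calculated` (indices),
#'   `measured_freq`, `measured_int`, `calc_freq`, `calc_int`, `cost`.
#' @slot total_cost sum of pair costs (minimal over all assignments).
#' @slot unmatched_calc indices of calculated peaks left unassigned.
#' @slot metric,weight the cost metric the barcode was built from.
#' @slot transposed `TRUE` when the measured side had more peaks than the
#'   calculated side and the roles were swapped internally.
#' @export
setClass("Barcode",
         representation(pairs = "data.frame", total_cost = "numeric",
                        unmatched_calc = "integer", metric = "character",
                        weight = "numeric", transposed = "logical"))

setValidity("Barcode", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("measured", "calculated", "cost")
  if (!all(need %in% names(p)))
    return("pairs must have columns measured, calculated, cost")
  if (anyDuplicated(p$measured) || anyDuplicated(p$calculated))
    msg <- c(msg, "assignment indices must be distinct")
  if (nrow(p) &&
      abs(object@total_cost - sum(p$cost)) >
        1e-8 * max(1, abs(object@total_cost)))
    msg <- c(msg, "total_cost must equal the sum of pair costs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Barcode", function(object) {
  cat(sprintf("Barcode: %d pairs (%s), total cost %.4f, %d calc peaks unmatched\n",
              nrow(object@pairs), object@metric, object@total_cost,
              length(object@unmatched_calc)))
})

#' ContinuousSpectrum: intensities on a regular wavenumber grid
#'
#' The result of convolving a stick spectrum with Lorentzian line shapes
#' onto a regular grid; the representation used by cross-correlation.
#'
#' @slot gridStart first grid wavenumber (cm^-1).
#' @slot gridStep grid spacing (cm^-1, > 0).
#' @slot values non-negative intensities, one per grid point.
#' @export
setClass("ContinuousSpectrum",
         representation(gridStart = "numeric", gridStep = "numeric",
                        values = "numeric"))

setValidity("ContinuousSpectrum", function(object) {
  msg <- character()
  if (length(object@gridStep) != 1L || object@gridStep <= 0)
    msg <- c(msg, "gridStep must be a single value > 0")
  if (length(object@values) < 1L)
    msg <- c(msg, "values must have length >= 1")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ContinuousSpectrum
#'
#' @param gridStart first wavenumber (cm^-1).
#' @param gridStep grid spacing (cm^-1).
#' @param values intensity values.
#' @return A [ContinuousSpectrum-class].
#' @export
continuousSpectrum <- function(gridStart, gridStep, values) {
  new("ContinuousSpectrum", gridStart = as.numeric(gridStart),
      gridStep = as.numeric(gridStep), values = as.numeric(values))
}

setMethod("show", "ContinuousSpectrum", function(object) {
  n <- length(object@values)
  cat(sprintf("ContinuousSpectrum: %d points, %.1f-%.1f cm-1 (step %g)\n",
              n, object@gridStart,
              object@gridStart + (n - 1) * object@gridStep,
              object@gridStep))
})

## Error helpers ---------------------------------------------------------

.vibError <- function(class, fmt, ...) {
  stop(structure(class = c(class, "vibmatch_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
.formatError <- function(fmt, ...) .vibError("vibmatch_format_error", fmt, ...)
.validationError <- function(fmt, ...)
  .vibError("vibmatch_validation_error", fmt, ...)
.ioError <- function(fmt, ...) .vibError("vibmatch_io_error", fmt, ...)
.usageError <- function(fmt, ...) .vibError("vibmatch_usage_error", fmt, ...)
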