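## Preprocessing: intensity normalization and Lorentzian stick-spectrum
## convolution onto a regular wavenumber grid.

#' Normalize peak intensities to a maximum of 1
#'
#' @param record a [SpectrumRecord-class] with at least one positive
#'   intensity.
#' @return The record with intensities divided by their maximum
#'   (idempotent).
#' @export
normalizeIntensities <- function(record) {
  p <- record@peaks
  if (!nrow(p) || max(p$intensity) <= 0)
    .validationError("cannot normalize: no peak with positive intensity")
  p$intensity <- p$intensity / max(p$intensity)
  initialize(record, peaks = p)
}

#' Convolve a stick spectrum with Lorentzian line shapes
#'
#' Each peak contributes a Lorentzian of unit peak height (so the convolved
#' maximum of an isolated line equals its stick intensity, matching the
#' usual plotting convention where stick and convolved heights coincide):
#' `value(x) = sum_k I_k * gamma^2 / ((x - nu_k)^2 + gamma^2)` with
#' `gamma = fwhm / 2`.
#'
#' The default grid, 300-3800 cm^-1 at 1 cm^-1, covers the usual
#' experimental range (about 400-3755 cm^-1) with margin. A warning is
#' emitted when the grid does not cover every peak with at least
#' `5 * fwhm` margin.
#'
#' @param record a [SpectrumRecord-class].
#' @param fwhm Lorentzian full width at half maximum (cm^-1, default 4).
#' @param grid_start,grid_end grid limits (cm^-1).
#' @param grid_step grid spacing (cm^-1, default 1).
#' @return A [ContinuousSpectrum-class].
#' @examples
#' r <- spectrumRecord(1000, 1, source = "computed")
#' s <- lorentzianConvolve(r, fwhm = 4, grid_start = 900, grid_end = 1100)
#' intensityValues(s)[gridWavenumbers(s) == 1000]  # 1
#' intensityValues(s)[gridWavenumbers(s) == 1002]  # 0.5 (half height)
#' @export
lorentzianConvolve <- function(record, fwhm = 4, grid_start = 300,
                               grid_end = 3800, grid_step = 1) {
  if (grid_step <= 0) .usageError("grid_step must be > 0")
  if (fwhm <= 0) .usageError("fwhm must be > 0")
  grid <- seq(grid_start, grid_end, by = grid_step)
  p <- record@peaks
  if (!nrow(p))
    return(continuousSpectrum(grid_start, grid_step,
                              numeric(length(grid))))
  if (min(p$frequency) - 5 * fwhm < grid_start ||
      max(p$frequency) + 5 * fwhm > grid_end)
    warning("grid does not cover all peaks with a 5*fwhm margin",
            call. = FALSE)
  gamma <- fwhm / 2
  values <- as.numeric(
    outer(grid, p$frequency,
          function(x, nu) gamma^2 / ((x - nu)^2 + gamma^2)) %*% p$intensity)
  continuousSpectrum(grid_start, grid_step, values)
}

#' Write / read a continuous spectrum as 2-column CSV
#'
#' @param spectrum a [ContinuousSpectrum-class].
#' @param path output path.
#' @return `writeContinuousSpectrum`: `invisible(path)`;
#'   `readContinuousSpectrum`: a [ContinuousSpectrum-class].
#' @export
writeContinuousSpectrum <- function(spectrum, path) {
  df <- data.frame(wavenumber = gridWavenumbers(spectrum),
                   intensity = spectrum@values)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContinuousSpectrum
#' @export
readContinuousSpectrum <- function(path) {
  if (!file.exists(path)) .ioError("file not found: '%s'", path)
  df <- read.csv(path)
  if (!all(c("wavenumber", "intensity") %in% names(df)))
    .formatError("'%s': expected columns wavenumber, intensity", path)
  if (nrow(df) < 2L)
    .validationError("'%s': need at least 2 grid points", path)
  steps <- diff(df$wavenumber)
  if (max(abs(steps - steps[1])) > 1e-6)
    .validationError("'%s': grid is not regular", path)
  continuousSpectrum(df$wavenumber[1], steps[1], df$intensity)
}
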