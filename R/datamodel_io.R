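## Peak-table and pair-database readers/writers plus the fundamental-band
## inclusion filter.
##
## On-disk contracts (deliberately minimal):
##  * peak-table CSV: comma-separated, UTF-8, mandatory header, "." decimal;
##    columns frequency,intensity plus optional fwhm,snr,channel,mode_class
##    and the record-level columns species,conformer,source,functional,basis.
##  * peak-table JSON mirrors the field names 1:1.
##  * pair-database CSV: species,conformer,mode_class,nu_exp,intensity_exp
##    and one omega__<functional>__<basis> column per theory level.
## Frequencies are written at 0.1 cm^-1 precision (below experimental
## resolution) so that write/read round-trips are exact.

.RECORD_COLS <- c("species", "conformer", "source", "functional", "basis")

.subsetRecord <- function(record, idx) {
  p <- record@peaks[idx, , drop = FALSE]
  rownames(p) <- NULL
  meta <- record@metadata
  if (!is.null(meta$extra) && nrow(meta$extra) == nrow(record@peaks)) {
    meta$extra <- meta$extra[idx, , drop = FALSE]
    rownames(meta$extra) <- NULL
  }
  initialize(record, peaks = p, metadata = meta)
}

.peaksFromTable <- function(tab, path) {
  for (col in c("frequency", "intensity"))
    if (!col %in% names(tab))
      .formatError("'%s': missing mandatory column '%s'", path, col)
  freq <- suppressWarnings(as.numeric(tab$frequency))
  bad <- which(is.na(freq) | freq <= 0)
  if (length(bad))
    .validationError(
      "'%s': non-numeric or non-positive frequency in row %d", path, bad[1])
  inten <- suppressWarnings(as.numeric(tab$intensity))
  bad <- which(is.na(inten) | inten < 0)
  if (length(bad))
    .validationError("'%s': invalid intensity in row %d", path, bad[1])
  n <- nrow(tab)
  grab <- function(col, default)
    if (col %in% names(tab)) tab[[col]] else rep(default, n)
  p <- data.frame(frequency = freq, intensity = inten,
                  fwhm = suppressWarnings(as.numeric(grab("fwhm", NA_real_))),
                  snr = suppressWarnings(as.numeric(grab("snr", NA_real_))),
                  channel = as.character(grab("channel", NA_character_)),
                  stringsAsFactors = FALSE)
  if ("mode_class" %in% names(tab))
    p$mode_class <- as.character(tab$mode_class)
  p
}

#' Read a peak table into a SpectrumRecord
#'
#' Reads a CSV or JSON peak table (columns/keys `frequency` and `intensity`
#' mandatory; `fwhm`, `snr`, `channel`, `mode_class` and the record-level
#' fields `species`, `conformer`, `source`, `functional`, `basis` optional).
#' Peaks are sorted by ascending frequency; unknown columns are preserved in
#' `metadata$extra` (in sorted peak order).
#'
#' @param path path to the file.
#' @param dialect `"csv"` or `"json"`.
#' @return A validated [SpectrumRecord-class].
#' @seealso [writePeakTable()], [filterFundamentals()]
#' @export
readPeakTable <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .ioError("file not found: '%s'", path)
  if (dialect == "csv") {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    rec_fields <- lapply(setNames(.RECORD_COLS, .RECORD_COLS), function(col)
      if (col %in% names(tab) && nrow(tab)) as.character(tab[[col]][1])
      else NULL)
    known <- c(.PEAK_COLS, "mode_class", .RECORD_COLS)
    extra <- tab[setdiff(names(tab), known)]
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    tab <- as.data.frame(obj$peaks, stringsAsFactors = FALSE)
    if (is.null(obj$peaks) || !nrow(tab))
      tab <- data.frame(frequency = numeric(), intensity = numeric())
    rec_fields <- lapply(setNames(.RECORD_COLS, .RECORD_COLS), function(col)
      if (!is.null(obj[[col]])) as.character(obj[[col]]) else NULL)
    known <- c(.PEAK_COLS, "mode_class")
    extra <- tab[setdiff(names(tab), known)]
  }
  p <- .peaksFromTable(tab, path)
  ord <- order(p$frequency)
  p <- p[ord, , drop = FALSE]
  rownames(p) <- NULL
  metadata <- list()
  if (ncol(extra)) {
    extra <- extra[ord, , drop = FALSE]
    rownames(extra) <- NULL
    metadata$extra <- extra
  }
  theory <- NULL
  if (!is.null(rec_fields$functional) && !is.null(rec_fields$basis) &&
      !is.na(rec_fields$functional) && !is.na(rec_fields$basis))
    theory <- theoryLevel(rec_fields$functional, rec_fields$basis)
  src <- rec_fields$source %||% "experimental"
  new("SpectrumRecord",
      species = rec_fields$species %||% "unknown",
      conformer = rec_fields$conformer %||% "unknown",
      source = src, theory = theory, peaks = p, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

.recordToTable <- function(record) {
  p <- record@peaks
  freq <- round(p$frequency, 1)
  ## rounding to the 0.1 cm^-1 storage precision may merge very close
  ## peaks; keep them distinct (and ascending) by bumping duplicates
  while (anyDuplicated(freq))
    freq[duplicated(freq)] <- round(freq[duplicated(freq)] + 0.1, 1)
  out <- data.frame(frequency = freq,
                    intensity = p$intensity, stringsAsFactors = FALSE)
  for (col in c("fwhm", "snr", "channel", "mode_class"))
    if (col %in% names(p) && !all(is.na(p[[col]]))) out[[col]] <- p[[col]]
  out
}

#' Write a SpectrumRecord to a peak table
#'
#' Inverse of [readPeakTable()]: `readPeakTable(writePeakTable(r))` is the
#' identity on valid records (frequencies at 0.1 cm^-1 precision; peaks
#' closer than that precision are kept distinct by a 0.1 cm^-1 bump).
#' Columns that are entirely absent (`NA`) are omitted from the file and
#' remain absent after a round trip.
#'
#' @param record a [SpectrumRecord-class].
#' @param path output path.
#' @param dialect `"csv"` or `"json"`.
#' @return `invisible(path)`.
#' @export
writePeakTable <- function(record, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  validObject(record)
  out <- .recordToTable(record)
  meta <- record@metadata
  if (!is.null(meta$extra) && nrow(meta$extra) == nrow(out))
    out <- cbind(out, meta$extra)
  ok <- tryCatch({
    if (dialect == "csv") {
      n <- max(nrow(out), 1L)
      out$species <- rep(record@species, nrow(out))
      out$conformer <- rep(record@conformer, nrow(out))
      out$source <- rep(record@source, nrow(out))
      if (!is.null(record@theory)) {
        out$functional <- rep(record@theory@functional, nrow(out))
        out$basis <- rep(record@theory@basis, nrow(out))
      }
      write.csv(out, path, row.names = FALSE, quote = TRUE,
                fileEncoding = "UTF-8")
    } else {
      obj <- list(species = record@species, conformer = record@conformer,
                  source = record@source)
      if (!is.null(record@theory)) {
        obj$functional <- record@theory@functional
        obj$basis <- record@theory@basis
      }
      obj$peaks <- out
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           na = "null", dataframe = "rows")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .ioError("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a paired-frequency database
#'
#' Reads a wide CSV with one row per experimental fundamental (columns
#' `species`, `conformer`, `mode_class`, `nu_exp`, `intensity_exp`) and one
#' harmonic-frequency column `omega__<functional>__<basis>` per theory
#' level, and unpivots it into one frequency pair per (row, theory level).
#' Rows lacking an omega value for a level are excluded from that level with
#' a warning; pairs with nu/omega outside the (0.8, 1.1) sanity window
#' (harmonic frequencies overestimate fundamentals) are flagged with a
#' warning but kept.
#'
#' @param path path to the database CSV.
#' @param levels optional list of [TheoryLevel-class] to restrict to.
#' @return A data frame of frequency pairs with columns `species`,
#'   `conformer`, `functional`, `basis`, `mode_class`, `nu_exp`,
#'   `intensity_exp`, `omega_calc`.
#' @seealso [pairsForLevel()], [fitScalingSet()]
#' @export
readPairDatabase <- function(path, levels = NULL) {
  if (!file.exists(path)) .ioError("file not found: '%s'", path)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("mode_class", "nu_exp", "intensity_exp"))
    if (!col %in% names(tab))
      .formatError("'%s': missing mandatory column '%s'", path, col)
  omega_cols <- grep("^omega__", names(tab), value = TRUE)
  if (!length(omega_cols))
    .formatError("'%s': no omega__<functional>__<basis> columns", path)
  nu <- suppressWarnings(as.numeric(tab$nu_exp))
  bad <- which(is.na(nu) | nu <= 0)
  if (length(bad))
    .validationError("'%s': invalid nu_exp in row %d", path, bad[1])
  wanted <- if (is.null(levels)) NULL else vapply(levels, levelKey, "")
  out <- list()
  for (col in omega_cols) {
    parts <- strsplit(sub("^omega__", "", col), "__", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      .formatError("'%s': malformed omega column name '%s'", path, col)
    tl <- theoryLevel(parts[1], parts[2])
    if (!is.null(wanted) && !levelKey(tl) %in% wanted) next
    omega <- suppressWarnings(as.numeric(tab[[col]]))
    keep <- !is.na(omega) & omega > 0
    if (any(!keep))
      warning(sprintf("%s: %d row(s) lacking omega excluded for %s",
                      basename(path), sum(!keep), levelKey(tl)),
              call. = FALSE)
    df <- data.frame(
      species = if ("species" %in% names(tab)) tab$species[keep] else "unknown",
      conformer = if ("conformer" %in% names(tab)) tab$conformer[keep]
                  else "unknown",
      functional = tl@functional, basis = tl@basis,
      mode_class = as.character(tab$mode_class[keep]),
      nu_exp = nu[keep], intensity_exp = as.numeric(tab$intensity_exp[keep]),
      omega_calc = omega[keep], stringsAsFactors = FALSE)
    out[[col]] <- df
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  ratio <- pairs$nu_exp / pairs$omega_calc
  n_out <- sum(ratio <= 0.8 | ratio >= 1.1)
  if (n_out)
    warning(sprintf(
      "%s: %d pair(s) with nu/omega outside the (0.8, 1.1) sanity window",
      basename(path), n_out), call. = FALSE)
  pairs
}

#' Subset a pair table to one theory level
#'
#' @param pairs a pair data frame from [readPairDatabase()] or
#'   [makePairDatabase()].
#' @param theory a [TheoryLevel-class].
#' @return The rows of `pairs` belonging to `theory`.
#' @export
pairsForLevel <- function(pairs, theory) {
  pairs[pairs$functional == theory@functional &
          pairs$basis == theory@basis, , drop = FALSE]
}

#' Fundamental-band inclusion filter
#'
#' Keeps only distinct peaks with signal-to-noise ratio strictly above
#' `snr_min` and full width at half maximum strictly above `fwhm_min`,
#' excluding noise spikes and spurious features. Peaks lacking `snr` or
#' `fwhm` metadata pass unchanged (curated databases list already-filtered
#' features without these columns); their count is reported in a message
#' along with the number of removed peaks.
#'
#' @param record an experimental [SpectrumRecord-class].
#' @param snr_min signal-to-noise threshold (strict, default 2.5).
#' @param fwhm_min line width threshold in cm^-1 (strict, default 4).
#' @return A new [SpectrumRecord-class]; the input is not modified. An empty
#'   result is legal.
#' @examples
#' r <- spectrumRecord(c(500, 600, 700), c(1, 1, 1),
#'                     snr = c(3, 2, 3), fwhm = c(5, 5, 3))
#' nPeaks(filterFundamentals(r))  # 1
#' @export
filterFundamentals <- function(record, snr_min = 2.5, fwhm_min = 4) {
  p <- record@peaks
  no_meta <- is.na(p$snr) | is.na(p$fwhm)
  keep <- no_meta | (p$snr > snr_min & p$fwhm > fwhm_min)
  message(sprintf(
    "filterFundamentals: removed %d of %d peaks (%d kept without snr/fwhm metadata)",
    sum(!keep), nrow(p), sum(no_meta)))
  .subsetRecord(record, which(keep))
}
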