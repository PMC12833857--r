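## Synthetic-data generator: conformer libraries, pseudo-measured spectra
## and Data S1-shaped paired-frequency databases with the statistical
## structure of a curated fundamental-band collection, so the whole
## pipeline (filtering, scaling, resampling, matching) is testable without
## any external file. Everything produced here is synthetic and labelled
## as such.

## Reference mode-dependent scaling factors (per theory level) used as the
## generator's true per-class lambdas: representative published values for
## these functional/basis combinations. Order: OH, NH, CH_ring, CH_ethyl,
## mid, low.
.MODE_LAMBDAS <- list(
  "M06-2X/6-311++G(d,p)"    = c(0.9402, 0.9454, 0.9533, 0.9493, 0.9735, 0.9727),
  "M06-2X-D3/6-311++G(d,p)" = c(0.9402, 0.9454, 0.9533, 0.9493, 0.9735, 0.9728),
  "M06-2X-D3/cc-pVTZ"       = c(0.9454, 0.9485, 0.9535, 0.9499, 0.9723, 0.9672),
  "B3LYP/6-311++G(d,p)"     = c(0.9583, 0.9564, 0.9640, 0.9631, 0.9833, 0.9837),
  "B3LYP-D3/6-311++G(d,p)"  = c(0.9599, 0.9566, 0.9642, 0.9634, 0.9818, 0.9790),
  "B3LYP-D3/cc-pVTZ"        = c(0.9641, 0.9590, 0.9637, 0.9640, 0.9790, 0.9731),
  "wB97X-D/6-311++G(d,p)"   = c(0.9399, 0.9435, 0.9566, 0.9543, 0.9712, 0.9699),
  "wB97X-D/cc-pVTZ"         = c(0.9435, 0.9453, 0.9556, 0.9537, 0.9688, 0.9655))

.MODE_ORDER <- c("OH", "NH", "CH_ring", "CH_ethyl", "mid", "low")

## Class composition of the emulated database (counts per mode class,
## totalling 824) and the harmonic-frequency windows each class is drawn
## from. Windows are chosen so that, after multiplying by the class
## lambda, mid-range fundamentals stay at or above 1000 cm^-1 and
## low-range ones below it, keeping generated data consistent with the
## range classification cutoffs.
.CLASS_COUNTS_FULL <- c(OH = 34, NH = 54, CH_ring = 114, CH_ethyl = 108,
                        mid = 309, low = 175)
.CLASS_WINDOWS <- list(OH = c(3650, 3900), NH = c(3450, 3600),
                       CH_ring = c(3150, 3250), CH_ethyl = c(3050, 3150),
                       mid = c(1030, 2000), low = c(400, 1020))

#' Reference per-class scaling factors for a theory level
#'
#' The mode-dependent scaling factors the synthetic generator uses as
#' ground truth, per supported theory level.
#'
#' @param theory a [TheoryLevel-class].
#' @return Named numeric vector over `OH`, `NH`, `CH_ring`, `CH_ethyl`,
#'   `mid`, `low`.
#' @export
referenceModeLambdas <- function(theory) {
  key <- levelKey(theory)
  v <- .MODE_LAMBDAS[[key]]
  if (is.null(v)) .usageError("no reference lambdas for level '%s'", key)
  setNames(v, .MODE_ORDER)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the statistical structure of the curated database:
#' class composition proportional to OH 34 : NH 54 : CH_ring 114 :
#' CH_ethyl 108 : mid 309 : low 175 (rescaled to `total_modes` per
#' conformer), true per-class scaling factors from
#' [referenceModeLambdas()], 5 cm^-1 frequency jitter, 20% multiplicative
#' intensity noise, 30% peak dropout and 0.5 interloper (gain-line)
#' contaminants per 1000 cm^-1.
#'
#' @param n_conformers number of library conformers (default 8).
#' @param total_modes total modes per conformer before class rounding
#'   (default 60).
#' @param modes_per_class named integer vector overriding the rescaled
#'   composition.
#' @param theory the [TheoryLevel-class] whose reference lambdas are the
#'   generator's ground truth.
#' @param true_lambda named per-class true scaling factors (defaults to
#'   `referenceModeLambdas(theory)`).
#' @param freq_jitter_sigma Gaussian frequency jitter of the measured
#'   fundamentals (cm^-1, default 5).
#' @param intensity_noise_cv coefficient of variation of the log-normal
#'   multiplicative intensity noise (default 0.2).
#' @param dropout_p probability that a true peak is missing from the
#'   measured spectrum (default 0.3).
#' @param interloper_rate expected interloper peaks per 1000 cm^-1
#'   (default 0.5).
#' @param seed integer seed driving library and measurement generation.
#' @return A validated list of class `"SynthConfig"`.
#' @export
synthConfig <- function(n_conformers = 8, total_modes = 60,
                        modes_per_class = NULL,
                        theory = theoryLevel("M06-2X-D3", "6-311++G(d,p)"),
                        true_lambda = referenceModeLambdas(theory),
                        freq_jitter_sigma = 5, intensity_noise_cv = 0.2,
                        dropout_p = 0.3, interloper_rate = 0.5, seed = 1) {
  if (is.null(modes_per_class)) {
    frac <- .CLASS_COUNTS_FULL / sum(.CLASS_COUNTS_FULL)
    modes_per_class <- pmax(round(frac * total_modes), 1L)
  }
  modes_per_class <- modes_per_class[.MODE_ORDER]
  if (anyNA(modes_per_class) || any(modes_per_class < 0))
    .usageError("modes_per_class must cover all six classes, >= 0")
  if (sum(modes_per_class) == 0) .usageError("zero modes requested")
  if (dropout_p < 0 || dropout_p > 1)
    .usageError("dropout_p must be in [0, 1]")
  if (freq_jitter_sigma < 0 || intensity_noise_cv < 0 ||
      interloper_rate < 0)
    .usageError("noise parameters must be >= 0")
  if (any(true_lambda[.MODE_ORDER] <= 0.9) ||
      any(true_lambda[.MODE_ORDER] >= 1.0))
    .usageError("true_lambda values must lie in (0.9, 1.0)")
  structure(list(n_conformers = as.integer(n_conformers),
                 modes_per_class = modes_per_class,
                 theory = theory,
                 true_lambda = true_lambda[.MODE_ORDER],
                 freq_jitter_sigma = freq_jitter_sigma,
                 intensity_noise_cv = intensity_noise_cv,
                 dropout_p = dropout_p, interloper_rate = interloper_rate,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

.drawBaseModes <- function(config) {
  rows <- lapply(.MODE_ORDER, function(cl) {
    n <- config$modes_per_class[[cl]]
    if (!n) return(NULL)
    win <- .CLASS_WINDOWS[[cl]]
    data.frame(frequency = sort(runif(n, win[1], win[2])),
               intensity = rlnorm(n, meanlog = 0, sdlog = 1),
               mode_class = cl, stringsAsFactors = FALSE)
  })
  base <- do.call(rbind, rows)
  base$intensity <- base$intensity / max(base$intensity)
  base
}

#' Generate a synthetic conformer library
#'
#' Draws one base set of harmonic modes (per-class frequency windows:
#' O-H 3650-3900, N-H 3450-3600, C-H ring 3150-3250, C-H ethyl 3050-3150,
#' mid 1030-2000, low 400-1020 cm^-1) and derives each conformer from it
#' by small correlated frequency offsets (a per-conformer, per-class shift
#' of 2-15 cm^-1 in a random direction plus ~2 cm^-1 per-mode scatter) and
#' log-normal intensity redistribution -- mimicking the close spectral
#' similarity of real conformers. The first conformer is the unshifted
#' base. Reproducible under `config$seed`.
#'
#' @param config a [synthConfig()].
#' @return A list of computed [SpectrumRecord-class] objects (conformers
#'   `"C01"`, `"C02"`, ...), with the generator ground truth attached as
#'   `attr(, "truth")` (the base mode table and the configuration).
#' @export
makeConformerLibrary <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  if (config$n_conformers < 1L) .usageError("n_conformers must be >= 1")
  .withSeed(config$seed, {
    base <- .drawBaseModes(config)
    library <- lapply(seq_len(config$n_conformers), function(k) {
      p <- base
      if (k > 1L) {
        for (cl in unique(p$mode_class)) {
          idx <- p$mode_class == cl
          shift <- sample(c(-1, 1), 1) * runif(1, 2, 15)
          p$frequency[idx] <- p$frequency[idx] + shift +
            rnorm(sum(idx), 0, 2)
        }
        p$intensity <- p$intensity * rlnorm(nrow(p), 0, 0.3)
        p$intensity <- p$intensity / max(p$intensity)
      }
      spectrumRecord(p$frequency, p$intensity, mode_class = p$mode_class,
                     channel = "computed",
                     species = "synthetic", conformer = sprintf("C%02d", k),
                     source = "computed", theory = config$theory)
    })
    attr(library, "truth") <- list(base = base, config = config)
    library
  })
}

#' Simulate a measured spectrum from a computed truth record
#'
#' Applies the generator's true per-class scaling factors to the harmonic
#' frequencies, adds Gaussian frequency jitter, multiplies intensities by
#' log-normal noise with the configured coefficient of variation, drops
#' peaks with probability `dropout_p`, and inserts interloper gain-channel
#' peaks at the configured rate with random frequency and intensity. Every
#' surviving true peak gets `snr` and `fwhm` values that pass the
#' fundamental-band inclusion filter; interlopers draw wider ranges so
#' that some of them fail it. The measured-to-truth correspondence is
#' attached as `attr(, "pairing")`.
#'
#' @param truth a computed [SpectrumRecord-class] from
#'   [makeConformerLibrary()].
#' @param config the same [synthConfig()].
#' @param seed optional seed overriding `config$seed` (so that several
#'   measurements can be drawn from one library).
#' @return An experimental [SpectrumRecord-class]; `attr(, "pairing")` is
#'   a data frame with columns `measured_freq`, `truth_index`,
#'   `interloper`.
#' @export
makeMeasuredFrom <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(config, "SynthConfig"))
  p <- truth@peaks
  .withSeed(seed, {
    lam <- config$true_lambda[p$mode_class]
    nu <- lam * p$frequency + rnorm(nrow(p), 0, config$freq_jitter_sigma)
    cv <- config$intensity_noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    inten <- p$intensity *
      rlnorm(nrow(p), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    keep <- runif(nrow(p)) >= config$dropout_p
    df <- data.frame(frequency = nu[keep], intensity = inten[keep],
                     fwhm = runif(sum(keep), 4.5, 12),
                     snr = runif(sum(keep), 3, 30),
                     channel = "loss", truth_index = which(keep),
                     interloper = FALSE, stringsAsFactors = FALSE)
    span <- diff(range(nu)) + 200
    n_int <- rpois(1, config$interloper_rate * span / 1000)
    if (n_int > 0) {
      fi <- runif(n_int, min(nu) - 100, max(nu) + 100)
      di <- data.frame(frequency = fi,
                       intensity = runif(n_int, 0.05,
                                         0.5 * max(df$intensity)),
                       fwhm = runif(n_int, 2, 8),
                       snr = runif(n_int, 1, 6),
                       channel = "gain", truth_index = NA_integer_,
                       interloper = TRUE, stringsAsFactors = FALSE)
      df <- rbind(df, di)
    }
    df <- df[df$frequency > 0, , drop = FALSE]
    ## ties in frequency are astronomically unlikely but would break the
    ## record invariant; nudge any duplicate by 0.01 cm^-1
    while (anyDuplicated(df$frequency))
      df$frequency[duplicated(df$frequency)] <-
        df$frequency[duplicated(df$frequency)] + 0.01
    ord <- order(df$frequency)
    df <- df[ord, , drop = FALSE]
    rec <- spectrumRecord(df$frequency, df$intensity, fwhm = df$fwhm,
                          snr = df$snr, channel = df$channel,
                          species = truth@species,
                          conformer = truth@conformer,
                          source = "experimental")
    attr(rec, "pairing") <- data.frame(measured_freq = df$frequency,
                                       truth_index = df$truth_index,
                                       interloper = df$interloper)
    rec
  })
}

#' Generate a synthetic Data S1-shaped paired-frequency database
#'
#' Emulates a curated fundamental-band database in wide form: one row per
#' experimental fundamental with its intensity and mode class, plus one
#' harmonic-frequency column per theory level. Generation model: for each
#' mode, a reference harmonic frequency is drawn from its class window, the
#' "experimental" fundamental is the reference-level lambda times that
#' frequency plus Gaussian jitter, and each level's harmonic frequency is
#' `nu / lambda_level_class` plus a small harmonic scatter
#' (`omega_jitter_sigma`). Fitting any level therefore recovers that
#' level's reference lambdas up to jitter.
#'
#' @param counts named per-class row counts (default the full 824-row
#'   composition `c(OH = 34, NH = 54, CH_ring = 114, CH_ethyl = 108,
#'   mid = 309, low = 175)`).
#' @param levels list of [TheoryLevel-class] (default all 8).
#' @param freq_jitter_sigma fundamental jitter (cm^-1, default 5).
#' @param omega_jitter_sigma per-level harmonic scatter (cm^-1, default 2).
#' @param seed integer seed.
#' @return A wide data frame ready for [writePairDatabase()]; unpivot with
#'   [readPairDatabase()] after writing, or with [pairsFromWide()].
#' @export
makePairDatabase <- function(counts = .CLASS_COUNTS_FULL,
                             levels = theoryLevels(),
                             freq_jitter_sigma = 5, omega_jitter_sigma = 2,
                             seed = 1) {
  counts <- counts[.MODE_ORDER]
  if (anyNA(counts) || sum(counts) == 0)
    .usageError("counts must cover the six mode classes")
  ref_key <- "M06-2X-D3/6-311++G(d,p)"
  .withSeed(seed, {
    rows <- lapply(.MODE_ORDER, function(cl) {
      n <- counts[[cl]]
      if (!n) return(NULL)
      win <- .CLASS_WINDOWS[[cl]]
      omega_ref <- runif(n, win[1], win[2])
      nu <- .MODE_LAMBDAS[[ref_key]][match(cl, .MODE_ORDER)] * omega_ref +
        rnorm(n, 0, freq_jitter_sigma)
      data.frame(mode_class = cl, nu_exp = nu,
                 intensity_exp = rlnorm(n, 0, 1), stringsAsFactors = FALSE)
    })
    db <- do.call(rbind, rows)
    db <- cbind(data.frame(species = "synthetic",
                           conformer = sprintf("m%04d", seq_len(nrow(db))),
                           stringsAsFactors = FALSE), db)
    for (tl in levels) {
      lam <- referenceModeLambdas(tl)[db$mode_class]
      col <- sprintf("omega__%s__%s", tl@functional, tl@basis)
      db[[col]] <- db$nu_exp / lam + rnorm(nrow(db), 0, omega_jitter_sigma)
    }
    rownames(db) <- NULL
    db
  })
}

#' Unpivot a wide pair database held in memory
#'
#' Same contract as [readPairDatabase()] but for a data frame produced by
#' [makePairDatabase()] without a round trip through disk.
#'
#' @param db a wide pair-database data frame.
#' @param levels optional list of [TheoryLevel-class] to restrict to.
#' @return A long pair data frame.
#' @export
pairsFromWide <- function(db, levels = NULL) {
  omega_cols <- grep("^omega__", names(db), value = TRUE)
  wanted <- if (is.null(levels)) NULL else vapply(levels, levelKey, "")
  out <- list()
  for (col in omega_cols) {
    parts <- strsplit(sub("^omega__", "", col), "__", fixed = TRUE)[[1]]
    tl <- theoryLevel(parts[1], parts[2])
    if (!is.null(wanted) && !levelKey(tl) %in% wanted) next
    keep <- !is.na(db[[col]])
    out[[col]] <- data.frame(
      species = db$species[keep], conformer = db$conformer[keep],
      functional = tl@functional, basis = tl@basis,
      mode_class = db$mode_class[keep], nu_exp = db$nu_exp[keep],
      intensity_exp = db$intensity_exp[keep],
      omega_calc = db[[col]][keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a wide pair database to CSV
#'
#' @param db a wide pair-database data frame (from [makePairDatabase()]).
#' @param path output path.
#' @return `invisible(path)`.
#' @export
writePairDatabase <- function(db, path) {
  out <- db
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, 4))
  write.csv(out, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a complete matching scenario
#'
#' Builds a conformer library, chooses a generating conformer and
#' simulates its measured spectrum.
#'
#' @param config a [synthConfig()].
#' @param generating index of the generating conformer (default drawn at
#'   random under the scenario seed).
#' @return A list with `library`, `measured`, `truth_id` (conformer label)
#'   and `pairing`.
#' @export
makeScenario <- function(config, generating = NULL) {
  library <- makeConformerLibrary(config)
  if (is.null(generating))
    generating <- .withSeed(config$seed + 1L,
                            sample(length(library), 1))
  measured <- makeMeasuredFrom(library[[generating]], config,
                               seed = config$seed + 2L)
  list(library = library, measured = measured,
       truth_id = conformer(library[[generating]]),
       pairing = attr(measured, "pairing"))
}

#' Write a scenario to a directory
#'
#' Emits the candidate spectra and measured spectrum in the package's CSV
#' peak-table dialect plus a `truth.json` ground-truth file (true
#' per-class lambdas, generating conformer id, pairing table).
#'
#' @param scenario a [makeScenario()] result.
#' @param dir output directory (created if needed).
#' @param config the [synthConfig()] used (stored in the ground truth).
#' @return `invisible(dir)`.
#' @export
writeScenario <- function(scenario, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in scenario$library)
    writePeakTable(rec, file.path(dir,
                                  sprintf("candidate_%s.csv",
                                          conformer(rec))), "csv")
  writePeakTable(scenario$measured, file.path(dir, "measured.csv"), "csv")
  truth <- list(truth_id = scenario$truth_id,
                true_lambda = as.list(config$true_lambda),
                theory = levelKey(config$theory),
                seed = config$seed,
                pairing = scenario$pairing)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(dir)
}
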