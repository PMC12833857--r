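## Spectral similarity metrics and candidate ranking: cross-correlation of
## convolved spectra, Euclidean/Manhattan cost matrices with Kuhn-Munkres
## assignment (spectral barcodes), 1-D optimal transport, and first-order
## uncertainty propagation for the average barcode distances.

#' Matching configuration
#'
#' Bundles the tunable parameters of the matching pipeline.
#'
#' @param weight intensity weight w, in cm^-1 per unit normalized
#'   intensity (default 10: a full-scale intensity mismatch costs as much
#'   as a 10 cm^-1 frequency shift, placing typical intensity errors on
#'   the same cost scale as typical median frequency errors).
#' @param fwhm Lorentzian width for convolution (cm^-1, default 4).
#' @param grid_start,grid_end,grid_step convolution grid (cm^-1).
#' @param max_lag cross-correlation lag window (cm^-1, default 20).
#' @return A list of class `"MatchConfig"`.
#' @export
matchConfig <- function(weight = 10, fwhm = 4, grid_start = 300,
                        grid_end = 3800, grid_step = 1, max_lag = 20) {
  if (weight < 0) .usageError("weight must be >= 0")
  if (max_lag < 0) .usageError("max_lag must be >= 0")
  if (grid_step <= 0) .usageError("grid_step must be > 0")
  structure(list(weight = weight, fwhm = fwhm, grid_start = grid_start,
                 grid_end = grid_end, grid_step = grid_step,
                 max_lag = max_lag), class = "MatchConfig")
}

#' Maximal normalized cross-correlation of two spectra
#'
#' Slides the calculated spectrum against the measured one over integer-step
#' displacements within `[-max_lag, +max_lag]` and returns the maximum of
#' the normalized (zero-mean, unit-norm) correlation of the overlapping
#' segments; the score lies in [-1, 1]. A positive lag means the
#' calculated spectrum is displaced to higher wavenumber.
#'
#' @param measured,calc [ContinuousSpectrum-class] objects on the same grid.
#' @param max_lag lag window (cm^-1, default 20).
#' @return A list with `score` and `lag` (cm^-1, the displacement of the
#'   calculated spectrum at the maximum).
#' @export
crossCorrelate <- function(measured, calc, max_lag = 20) {
  if (abs(measured@gridStep - calc@gridStep) > 1e-9)
    .usageError("spectra must share the grid step")
  if (abs(measured@gridStart - calc@gridStart) > 1e-9 ||
      length(measured@values) != length(calc@values))
    .usageError("spectra must be on the same grid")
  x <- measured@values
  y <- calc@values
  n <- length(x)
  L <- floor(max_lag / measured@gridStep + 1e-9)
  if (L >= n) .usageError("max_lag too large for the grid")
  best <- -Inf
  best_lag <- 0L
  for (k in seq(-L, L)) {
    ## displacing calc by +k grid steps: value at grid index i is y[i - k]
    if (k >= 0) { xi <- (1 + k):n; yi <- 1:(n - k) }
    else { xi <- 1:(n + k); yi <- (1 - k):n }
    xs <- x[xi] - mean(x[xi])
    ys <- y[yi] - mean(y[yi])
    nx <- sqrt(sum(xs^2)); ny <- sqrt(sum(ys^2))
    if (nx == 0 || ny == 0)
      .validationError("cross-correlation undefined: zero-variance segment")
    r <- sum(xs * ys) / (nx * ny)
    if (r > best) { best <- r; best_lag <- k }
  }
  list(score = best, lag = best_lag * measured@gridStep)
}

#' Build a cost matrix between measured and calculated peaks
#'
#' Entry (i, j) compares measured peak i with calculated peak j:
#' `euclid_1d` uses |dnu| only; `euclid_2d` is
#' `sqrt(dnu^2 + w^2 * dI^2)`; `manhattan_2d` is `|dnu| + w * |dI|`.
#' Intensities must be normalized (maximum 1) before 2-D metrics are
#' meaningful; intensities above 1 raise an error.
#'
#' @param measured,calc [SpectrumRecord-class] objects (calculated record
#'   already scaled).
#' @param metric one of `"euclid_2d"` (default), `"euclid_1d"`,
#'   `"manhattan_2d"`.
#' @param weight intensity weight w (cm^-1 per unit intensity, default 10).
#' @return A [CostMatrix-class] with measured peaks as rows.
#' @export
costMatrix <- function(measured, calc,
                       metric = c("euclid_2d", "euclid_1d", "manhattan_2d"),
                       weight = 10) {
  metric <- match.arg(metric)
  pm <- measured@peaks
  pc <- calc@peaks
  if (!nrow(pm) || !nrow(pc)) .validationError("empty peak list")
  if (metric != "euclid_1d" &&
      (max(pm$intensity) > 1 + 1e-8 || max(pc$intensity) > 1 + 1e-8))
    .usageError("intensities must be normalized (max 1) for 2-D metrics; see normalizeIntensities()")
  dnu <- outer(pm$frequency, pc$frequency, "-")
  di <- outer(pm$intensity, pc$intensity, "-")
  entries <- switch(metric,
                    euclid_1d = abs(dnu),
                    euclid_2d = sqrt(dnu^2 + weight^2 * di^2),
                    manhattan_2d = abs(dnu) + weight * abs(di))
  new("CostMatrix", entries = entries, metric = metric,
      weight = as.numeric(weight), measured = pm, calc = pc)
}

#' Kuhn-Munkres minimal-cost assignment (spectral barcode)
#'
#' Assigns every measured peak to a distinct calculated peak so that the
#' total cost is minimal (Hungarian algorithm, shortest-augmenting-path
#' implementation in C++). When the calculated spectrum has more features
#' than the measured one -- the usual case, since measured spectra are
#' subsets due to population and band-overlap effects -- the surplus
#' calculated peaks are left unmatched at zero penalty. If the measured
#' side is larger, the matrix is transposed internally and the result is
#' flagged `transposed`.
#'
#' @param costs a [CostMatrix-class].
#' @return A [Barcode-class].
#' @seealso [averageDistance()], [costMatrix()]
#' @export
kuhnMunkres <- function(costs) {
  e <- costs@entries
  if (!length(e)) .validationError("empty cost matrix")
  transposed <- nrow(e) > ncol(e)
  work <- if (transposed) t(e) else e
  assign_col <- hungarian_assign(work)
  rows <- seq_len(nrow(work))
  if (transposed) {
    mi <- assign_col; ci <- rows
  } else {
    mi <- rows; ci <- assign_col
  }
  pairs <- data.frame(
    measured = mi, calculated = ci,
    measured_freq = costs@measured$frequency[mi],
    measured_int = costs@measured$intensity[mi],
    calc_freq = costs@calc$frequency[ci],
    calc_int = costs@calc$intensity[ci],
    cost = e[cbind(mi, ci)])
  ord <- order(pairs$measured)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  unmatched <- setdiff(seq_len(ncol(e)), pairs$calculated)
  new("Barcode", pairs = pairs, total_cost = sum(pairs$cost),
      unmatched_calc = as.integer(unmatched), metric = costs@metric,
      weight = costs@weight, transposed = transposed)
}

#' Average assigned-pair distance of a barcode
#'
#' Total assignment cost divided by the number of assigned pairs, making
#' scores comparable across species with different feature counts.
#'
#' @param barcode a [Barcode-class].
#' @return A single numeric score.
#' @export
averageDistance <- function(barcode) {
  n <- nrow(barcode@pairs)
  if (!n) .validationError("barcode has no assigned pairs")
  barcode@total_cost / n
}

.peakFrame <- function(x) {
  if (is(x, "SpectrumRecord")) x@peaks
  else as.data.frame(x)
}

#' 1-D optimal-transport (Wasserstein-1) distance between stick spectra
#'
#' Both peak lists are normalized to unit total intensity mass; the
#' distance is the minimal work needed to transport the measured intensity
#' distribution onto the calculated one with |dnu| ground cost, computed
#' as the integral over frequency of the absolute difference of the two
#' cumulative mass functions.
#'
#' @param measured,calc [SpectrumRecord-class] objects (or data frames with
#'   `frequency` and `intensity` columns) with positive total intensity.
#' @return The transport distance in cm^-1 (per unit mass).
#' @examples
#' a <- spectrumRecord(1000, 1, source = "experimental")
#' b <- spectrumRecord(1010, 2, source = "computed")
#' otDistance(a, b)  # 10
#' @export
otDistance <- function(measured, calc) {
  pm <- .peakFrame(measured)
  pc <- .peakFrame(calc)
  if (!nrow(pm) || sum(pm$intensity) <= 0 ||
      !nrow(pc) || sum(pc$intensity) <= 0)
    .validationError("both spectra need positive total intensity")
  support <- sort(unique(c(pm$frequency, pc$frequency)))
  cdf <- function(p) {
    mass <- p$intensity / sum(p$intensity)
    vapply(support, function(x) sum(mass[p$frequency <= x]), 0)
  }
  dF <- abs(cdf(pm) - cdf(pc))
  if (length(support) < 2L) return(0)
  sum(dF[-length(dF)] * diff(support))
}

#' First-order uncertainty of the average barcode distance
#'
#' Propagates independent per-peak frequency and intensity uncertainties
#' through the assigned-pair cost sum to the average distance, holding the
#' assignment fixed. The gradient of each pair cost with respect to the
#' four underlying coordinates is used; for 2-D Euclidean pairs with
#' near-zero cost (where the metric is not differentiable) the conservative
#' bound `sqrt(2 sigma_nu^2 + 2 w^2 sigma_I^2)` is used as that pair's
#' standard deviation.
#'
#' @param barcode a [Barcode-class].
#' @param freq_sigma per-peak frequency standard deviation (cm^-1), applied
#'   to both the measured and the calculated peak of each pair.
#' @param intensity_sigma per-peak intensity standard deviation
#'   (normalized units).
#' @return Standard deviation of the average distance.
#' @examples
#' # a single 1-D pair with sigma on both peaks: uncertainty = sigma*sqrt(2)
#' @export
distanceUncertainty <- function(barcode, freq_sigma, intensity_sigma = 0) {
  if (freq_sigma < 0 || intensity_sigma < 0)
    .usageError("sigmas must be >= 0")
  p <- barcode@pairs
  if (!nrow(p)) .validationError("barcode has no assigned pairs")
  w <- barcode@weight
  var_pair <- switch(barcode@metric,
    euclid_1d = rep(2 * freq_sigma^2, nrow(p)),
    manhattan_2d = rep(2 * freq_sigma^2 + 2 * w^2 * intensity_sigma^2,
                       nrow(p)),
    euclid_2d = {
      dnu <- p$measured_freq - p$calc_freq
      di <- p$measured_int - p$calc_int
      c2 <- dnu^2 + w^2 * di^2
      ifelse(c2 < 1e-12,
             2 * freq_sigma^2 + 2 * w^2 * intensity_sigma^2,
             (dnu^2 * 2 * freq_sigma^2 +
                w^4 * di^2 * 2 * intensity_sigma^2) / c2)
    })
  sqrt(sum(var_pair)) / nrow(p)
}

#' Rank candidate conformers against a measured spectrum
#'
#' For each candidate: applies the scaling-factor set, normalizes
#' intensities, and computes the four similarity scores -- maximal
#' cross-correlation of the Lorentzian-convolved spectra, average
#' Euclidean (2-D) and average Manhattan (2-D) barcode distances from
#' Kuhn-Munkres assignment, and the optimal-transport distance on stick
#' intensities. Per-method ranks are 1 = best (cross-correlation
#' descending, distances ascending); ties are broken by candidate input
#' order with a message. Candidates that fail scaling are marked failed
#' and excluded from the ranking; the others are still ranked.
#'
#' @param measured an experimental [SpectrumRecord-class] (filtered;
#'   intensities are normalized internally).
#' @param candidates a list of computed [SpectrumRecord-class] objects.
#' @param set a [ScalingFactorSet-class].
#' @param config a [matchConfig()] list.
#' @return A data frame (one row per candidate) with columns `id`,
#'   `xcorr`, `avg_euclid`, `avg_manhattan`, `ot_dist`, the four
#'   `rank_*` columns and `failed`.
#' @export
rankCandidates <- function(measured, candidates, set,
                           config = matchConfig()) {
  if (!length(candidates)) .usageError("at least one candidate is required")
  measured <- normalizeIntensities(measured)
  meas_cs <- lorentzianConvolve(measured, config$fwhm, config$grid_start,
                                config$grid_end, config$grid_step)
  ids <- vapply(seq_along(candidates), function(i) {
    cid <- conformer(candidates[[i]])
    if (identical(cid, "unknown") || !nzchar(cid)) as.character(i) else cid
  }, "")
  one <- function(cand) {
    scaled <- normalizeIntensities(applyScaling(cand, set))
    calc_cs <- lorentzianConvolve(scaled, config$fwhm, config$grid_start,
                                  config$grid_end, config$grid_step)
    xc <- crossCorrelate(meas_cs, calc_cs, config$max_lag)$score
    bc_e <- kuhnMunkres(costMatrix(measured, scaled, "euclid_2d",
                                   config$weight))
    bc_m <- kuhnMunkres(costMatrix(measured, scaled, "manhattan_2d",
                                   config$weight))
    c(xcorr = xc, avg_euclid = averageDistance(bc_e),
      avg_manhattan = averageDistance(bc_m),
      ot_dist = otDistance(measured, scaled))
  }
  scores <- lapply(candidates, function(cand)
    tryCatch(one(cand), vibmatch_error = function(e) {
      warning(sprintf("candidate failed: %s", conditionMessage(e)),
              call. = FALSE)
      c(xcorr = NA_real_, avg_euclid = NA_real_, avg_manhattan = NA_real_,
        ot_dist = NA_real_)
    }))
  res <- as.data.frame(do.call(rbind, scores))
  res <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), res)
  res$failed <- is.na(res$xcorr)
  rank_of <- function(x, decreasing = FALSE) {
    key <- if (decreasing) -x else x
    r <- rep(NA_integer_, length(x))
    ok <- !is.na(key)
    if (any(duplicated(key[ok])))
      message("rankCandidates: tie broken by candidate input order")
    r[ok] <- rank(key[ok], ties.method = "first")
    r
  }
  res$rank_xcorr <- rank_of(res$xcorr, decreasing = TRUE)
  res$rank_euclid <- rank_of(res$avg_euclid)
  res$rank_manhattan <- rank_of(res$avg_manhattan)
  res$rank_ot <- rank_of(res$ot_dist)
  rownames(res) <- NULL
  res
}

#' Heat-map of a similarity ranking
#'
#' Draws the per-method scores of a [rankCandidates()] result as a simple
#' color map (one row per method, one column per candidate; within each
#' row the best score is darkest).
#'
#' @param result a data frame from [rankCandidates()].
#' @param main plot title.
#' @return `invisible(NULL)`.
#' @export
plotSimilarityMap <- function(result, main = "spectral similarity") {
  methods <- c("xcorr", "avg_euclid", "avg_manhattan", "ot_dist")
  ## per-method 0..1 where 1 = best match
  norm <- sapply(methods, function(m) {
    x <- result[[m]]
    if (m == "xcorr") (x - min(x, na.rm = TRUE)) /
      max(1e-12, diff(range(x, na.rm = TRUE)))
    else 1 - (x - min(x, na.rm = TRUE)) /
      max(1e-12, diff(range(x, na.rm = TRUE)))
  })
  graphics::image(seq_len(nrow(result)), seq_along(methods), norm,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "candidate", ylab = "", main = main)
  graphics::axis(1, at = seq_len(nrow(result)), labels = result$id,
                 las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_along(methods), labels = methods, las = 1,
                 cex.axis = 0.8)
  graphics::box()
  invisible(NULL)
}
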