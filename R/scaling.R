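## Derivation of empirical frequency scaling factors (global, range- and
## mode-dependent), the error-statistics battery, the randomized
## train/test resampling protocol and the top-intensity stability check.
##
## The scaling factor lambda for a class is the least-squares minimizer of
## sum_i (lambda * omega_i - nu_i)^2, i.e. lambda = sum(nu*omega)/sum(omega^2),
## the standard convention of the scaling-factor literature. Its
## uncertainty is, by default, the sample standard deviation of the
## per-pair ratios nu_i/omega_i; an RMS-based alternative
## sqrt(sum((nu - lambda*omega)^2) / sum(omega^2)) is available for
## sensitivity checks.

#' Classify a vibrational feature into a scaling class
#'
#' Range-dependent scheme: `low` below 1000 cm^-1, `mid` in the closed
#' interval 1000-2000 cm^-1, `high` above 2000 cm^-1 (the quoted cutoffs
#' "<1000" and ">2000" are strict, so both boundaries fall in `mid`).
#' Mode-dependent scheme: an explicit label (`OH`, `NH`, `CH_ring`,
#' `CH_ethyl`, `mid`, `low`) is authoritative when present; unlabelled
#' features fall back to the `mid`/`low` ranges, and classification fails
#' for an unlabelled feature above 2000 cm^-1 (a stretch without its
#' label). Global scheme: the single class `"global"`.
#'
#' @param frequency numeric vector of wavenumbers (cm^-1). For database
#'   pairs this is the experimental fundamental; for computed records the
#'   harmonic frequency.
#' @param scheme one of `"global"`, `"mode_dependent"`, `"range_dependent"`.
#' @param label optional stretch-mode labels (recycled), required under the
#'   mode-dependent scheme for frequencies above 2000 cm^-1.
#' @return Character vector of class labels.
#' @examples
#' classifyMode(800, "range_dependent")            # "low"
#' classifyMode(1000, "range_dependent")           # "mid" (closed boundary)
#' classifyMode(3650, "mode_dependent", "OH")      # "OH"
#' @export
classifyMode <- function(frequency,
                         scheme = c("global", "mode_dependent",
                                    "range_dependent"),
                         label = NA_character_) {
  scheme <- match.arg(scheme)
  if (scheme == "global") return(rep("global", length(frequency)))
  label <- rep_len(as.character(label), length(frequency))
  range_class <- ifelse(frequency < 1000, "low",
                        ifelse(frequency <= 2000, "mid", "high"))
  if (scheme == "range_dependent") return(range_class)
  mode_labels <- c(.STRETCH_CLASSES, "mid", "low")
  out <- ifelse(!is.na(label) & label %in% mode_labels, label, range_class)
  bad <- which(out == "high")
  if (length(bad))
    .validationError(
      "mode-dependent classification needs a stretch label for feature at %.1f cm^-1",
      frequency[bad[1]])
  out
}

.classifyPairs <- function(pairs, scheme) {
  classifyMode(pairs$nu_exp, scheme,
               if ("mode_class" %in% names(pairs)) pairs$mode_class
               else NA_character_)
}

#' Fit a single frequency scaling factor
#'
#' Least-squares fit of experimental fundamentals `nu` against harmonic
#' frequencies `omega` through the origin.
#'
#' @param nu experimental fundamental frequencies (cm^-1).
#' @param omega calculated harmonic frequencies (cm^-1).
#' @param uncertainty `"ratio_sd"` (default; sample SD of the nu/omega
#'   ratios) or `"rms"` (residual-RMS based).
#' @return A list with `lambda`, `delta_lambda` and `n`.
#' @examples
#' fitScalingFactor(c(950, 1900), c(1000, 2000))  # lambda = 0.95
#' @export
fitScalingFactor <- function(nu, omega,
                             uncertainty = c("ratio_sd", "rms")) {
  uncertainty <- match.arg(uncertainty)
  if (length(nu) != length(omega))
    .usageError("nu and omega must have equal length")
  if (length(nu) < 2L)
    .validationError("at least 2 frequency pairs are required (got %d)",
                     length(nu))
  if (any(omega == 0))
    .validationError("harmonic frequencies must be non-zero")
  if (any(nu <= 0) || any(omega < 0))
    .validationError("frequencies must be positive")
  lambda <- sum(nu * omega) / sum(omega^2)
  delta <- if (uncertainty == "ratio_sd") sd(nu / omega)
           else sqrt(sum((nu - lambda * omega)^2) / sum(omega^2))
  list(lambda = lambda, delta_lambda = delta, n = length(nu))
}

#' Fit a full set of scaling factors under one scheme
#'
#' Classifies the pairs under `scheme` and calls [fitScalingFactor()] on
#' each class subset. Classes with fewer than 2 pairs are reported absent
#' with a warning rather than causing an error.
#'
#' @param pairs a pair data frame (columns `nu_exp`, `omega_calc`, and
#'   `mode_class` for the mode-dependent scheme), typically one theory
#'   level of [readPairDatabase()] output (see [pairsForLevel()]).
#' @param scheme scaling scheme.
#' @param theory optional [TheoryLevel-class] recorded in the result.
#' @param uncertainty passed to [fitScalingFactor()].
#' @return A [ScalingFactorSet-class].
#' @export
fitScalingSet <- function(pairs,
                          scheme = c("global", "mode_dependent",
                                     "range_dependent"),
                          theory = NULL,
                          uncertainty = c("ratio_sd", "rms")) {
  scheme <- match.arg(scheme)
  uncertainty <- match.arg(uncertainty)
  cls <- .classifyPairs(pairs, scheme)
  rows <- list()
  for (cl in .schemeClasses(scheme)) {
    idx <- which(cls == cl)
    if (length(idx) < 2L) {
      warning(sprintf("class '%s': %d pair(s), factor not fitted", cl,
                      length(idx)), call. = FALSE)
      next
    }
    f <- fitScalingFactor(pairs$nu_exp[idx], pairs$omega_calc[idx],
                          uncertainty)
    rows[[cl]] <- data.frame(class = cl, lambda = f$lambda,
                             delta_lambda = f$delta_lambda, n = f$n,
                             stringsAsFactors = FALSE)
  }
  factors <- do.call(rbind, rows)
  if (is.null(factors))
    .validationError("no class had enough pairs to fit")
  rownames(factors) <- NULL
  new("ScalingFactorSet", scheme = scheme, theory = theory,
      factors = factors)
}

#' Apply a scaling-factor set to a computed record
#'
#' Replaces each harmonic frequency omega by `lambda_class * omega`, where
#' the class is determined from the harmonic frequency (and, for the
#' mode-dependent scheme, the `mode_class` peak label). Intensities are
#' unchanged; ascending order is re-established.
#'
#' @param record a computed [SpectrumRecord-class].
#' @param set a [ScalingFactorSet-class].
#' @return The scaled [SpectrumRecord-class].
#' @export
applyScaling <- function(record, set) {
  if (record@source != "computed")
    .usageError("applyScaling expects a computed record")
  p <- record@peaks
  if (!nrow(p)) return(record)
  cls <- classifyMode(p$frequency, set@scheme,
                      if ("mode_class" %in% names(p)) p$mode_class
                      else NA_character_)
  lam <- lambdaFor(set, cls)
  bad <- which(is.na(lam))
  if (length(bad))
    .validationError("no scaling factor for peak at %.1f cm^-1 (class '%s')",
                     p$frequency[bad[1]], cls[bad[1]])
  p$frequency <- lam * p$frequency
  ord <- order(p$frequency)
  p <- p[ord, , drop = FALSE]
  rownames(p) <- NULL
  out <- record
  meta <- out@metadata
  if (!is.null(meta$extra) && nrow(meta$extra) == nrow(p)) {
    meta$extra <- meta$extra[ord, , drop = FALSE]
    rownames(meta$extra) <- NULL
  }
  initialize(out, peaks = p, metadata = meta)
}

#' Error statistics of scaled predictions
#'
#' Computes the signed prediction errors `e_i = lambda_class * omega_i -
#' nu_i` and summarizes them: RMS, mean absolute deviation, standard
#' deviation (n-1 denominator), mean absolute percentage error
#' `100 * mean(|e|/nu)`, quartiles Q1/Q2/Q3 of the absolute-error
#' distribution (linear interpolation), signed extremes and the pair count.
#'
#' @param pairs a pair data frame (one theory level).
#' @param set a fitted [ScalingFactorSet-class].
#' @return An object of class `"ErrorStats"`: a list with elements `rms`,
#'   `mad`, `sigma`, `mape`, `q1`, `q2`, `q3`, `err_min`, `err_max`, `n`.
#' @export
errorStats <- function(pairs, set) {
  if (!nrow(pairs))
    .validationError("errorStats needs at least one pair")
  cls <- .classifyPairs(pairs, set@scheme)
  lam <- lambdaFor(set, cls)
  keep <- !is.na(lam)
  if (!all(keep))
    warning(sprintf("%d pair(s) in classes without a fitted factor dropped",
                    sum(!keep)), call. = FALSE)
  if (!any(keep)) .validationError("no pair is covered by the factor set")
  e <- lam[keep] * pairs$omega_calc[keep] - pairs$nu_exp[keep]
  ae <- abs(e)
  q <- unname(quantile(ae, c(0.25, 0.5, 0.75), type = 7))
  structure(list(rms = sqrt(mean(e^2)), mad = mean(ae),
                 sigma = sd(e), mape = 100 * mean(ae / pairs$nu_exp[keep]),
                 q1 = q[1], q2 = q[2], q3 = q[3],
                 err_min = min(e), err_max = max(e), n = sum(keep)),
            class = "ErrorStats")
}

#' @export
print.ErrorStats <- function(x, ...) {
  cat(sprintf(paste0("ErrorStats (n = %d): RMS %.2f, MAD %.2f, sigma %.2f ",
                     "cm^-1; MAPE %.2f%%\n  |e| quartiles %.2f / %.2f / %.2f",
                     " cm^-1; signed range [%.2f, %.2f]\n"),
              x$n, x$rms, x$mad, x$sigma, x$mape, x$q1, x$q2, x$q3,
              x$err_min, x$err_max))
  invisible(x)
}

.ERR_FIELDS <- c("rms", "mad", "sigma", "mape", "q1", "q2", "q3",
                 "err_min", "err_max")

#' Randomized train/test resampling of the scaling fit
#'
#' Runs `n_iter` cycles of random `train_frac`/(1 - `train_frac`) splits,
#' stratified per class so that every class retains at least 2 training
#' and 1 test pairs (iterations violating this are redrawn). Each cycle
#' fits a [ScalingFactorSet-class] on the training pairs and evaluates
#' [errorStats()] on the test pairs; results are averaged across runs and
#' standard deviations calculated accordingly. Fully reproducible given
#' `seed`.
#'
#' @param pairs a pair data frame (one theory level).
#' @param scheme scaling scheme.
#' @param n_iter number of cycles (default 100).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed for the whole resampling run.
#' @param uncertainty passed to [fitScalingFactor()].
#' @return An object of class `"SplitStats"`: a list with `per_class`
#'   (data frame `class`, `mean_lambda`, `sd_lambda`), `test_stats`
#'   (data frame `stat`, `mean`, `sd`), `n_iter`, `train_frac`, `seed`.
#' @export
resampleSplits <- function(pairs,
                           scheme = c("global", "mode_dependent",
                                      "range_dependent"),
                           n_iter = 100, train_frac = 0.7, seed = 1,
                           uncertainty = c("ratio_sd", "rms")) {
  scheme <- match.arg(scheme)
  uncertainty <- match.arg(uncertainty)
  if (train_frac <= 0 || train_frac >= 1)
    .usageError("train_frac must be in (0, 1)")
  cls <- .classifyPairs(pairs, scheme)
  classes <- sort(unique(cls))
  n <- nrow(pairs)
  lam_rec <- list()
  stat_rec <- matrix(NA_real_, n_iter, length(.ERR_FIELDS),
                     dimnames = list(NULL, .ERR_FIELDS))
  .withSeed(seed, {
    for (it in seq_len(n_iter)) {
      train <- NULL
      for (attempt in seq_len(1000)) {
        idx <- unlist(lapply(classes, function(cl) {
          members <- which(cls == cl)
          sample(members, max(2L, round(train_frac * length(members))))
        }))
        test_ok <- all(vapply(classes, function(cl)
          any(!(which(cls == cl) %in% idx)), TRUE))
        train_ok <- all(vapply(classes, function(cl)
          sum(idx %in% which(cls == cl)) >= 2L, TRUE))
        if (test_ok && train_ok) { train <- idx; break }
      }
      if (is.null(train))
        .validationError("could not stratify a %g/%g split after 1000 attempts",
                         train_frac, 1 - train_frac)
      set <- suppressWarnings(
        fitScalingSet(pairs[train, , drop = FALSE], scheme,
                      uncertainty = uncertainty))
      st <- suppressWarnings(
        errorStats(pairs[-train, , drop = FALSE], set))
      lam_rec[[it]] <- setNames(set@factors$lambda, set@factors$class)
      stat_rec[it, ] <- unlist(st[.ERR_FIELDS])
    }
  })
  all_classes <- unique(unlist(lapply(lam_rec, names)))
  per_class <- do.call(rbind, lapply(all_classes, function(cl) {
    v <- vapply(lam_rec, function(x) x[cl], 0)
    data.frame(class = cl, mean_lambda = mean(v, na.rm = TRUE),
               sd_lambda = sd(v[!is.na(v)]), stringsAsFactors = FALSE)
  }))
  test_stats <- data.frame(stat = .ERR_FIELDS,
                           mean = colMeans(stat_rec),
                           sd = apply(stat_rec, 2, sd),
                           stringsAsFactors = FALSE)
  rownames(test_stats) <- NULL
  structure(list(per_class = per_class, test_stats = test_stats,
                 n_iter = n_iter, train_frac = train_frac, seed = seed),
            class = "SplitStats")
}

#' @export
print.SplitStats <- function(x, ...) {
  cat(sprintf("SplitStats: %d iterations of %.0f%%/%.0f%% splits (seed %d)\n",
              x$n_iter, 100 * x$train_frac, 100 * (1 - x$train_frac),
              x$seed))
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("  %-9s lambda = %.4f (sd %.4f)\n", x$per_class$class[i],
                x$per_class$mean_lambda[i], x$per_class$sd_lambda[i]))
  m <- x$test_stats
  cat(sprintf("  test MAPE %.2f%% (sd %.2f), Q2 %.1f (sd %.1f) cm^-1\n",
              m$mean[m$stat == "mape"], m$sd[m$stat == "mape"],
              m$mean[m$stat == "q2"], m$sd[m$stat == "q2"]))
  invisible(x)
}

#' Stability of the scaling factors under an intensity cut
#'
#' Refits the scaling factors using only the top `frac` most intense
#' experimental fundamentals (globally by `intensity_exp`) and reports, per
#' class, the absolute shift |lambda_sub - lambda_full| and whether it lies
#' within the full-fit uncertainty margin. Classes with fewer than 2 pairs
#' in the subset are marked not assessable.
#'
#' @param pairs a pair data frame carrying `intensity_exp`.
#' @param scheme scaling scheme.
#' @param frac intensity fraction to keep (default 0.2).
#' @param uncertainty passed to [fitScalingFactor()].
#' @return A data frame with columns `class`, `n_full`, `n_sub`,
#'   `lambda_full`, `delta_full`, `lambda_sub`, `abs_diff`,
#'   `within_uncertainty`, `assessable`.
#' @export
topFractionStability <- function(pairs,
                                 scheme = c("global", "mode_dependent",
                                            "range_dependent"),
                                 frac = 0.2,
                                 uncertainty = c("ratio_sd", "rms")) {
  scheme <- match.arg(scheme)
  uncertainty <- match.arg(uncertainty)
  if (frac <= 0 || frac > 1) .usageError("frac must be in (0, 1]")
  full <- suppressWarnings(fitScalingSet(pairs, scheme,
                                         uncertainty = uncertainty))
  ord <- order(pairs$intensity_exp, decreasing = TRUE)
  keep <- ord[seq_len(ceiling(frac * nrow(pairs)))]
  sub_pairs <- pairs[keep, , drop = FALSE]
  sub_cls <- .classifyPairs(sub_pairs, scheme)
  f <- full@factors
  out <- lapply(seq_len(nrow(f)), function(i) {
    cl <- f$class[i]
    idx <- which(sub_cls == cl)
    assessable <- length(idx) >= 2L
    lam_sub <- if (assessable)
      fitScalingFactor(sub_pairs$nu_exp[idx], sub_pairs$omega_calc[idx],
                       uncertainty)$lambda else NA_real_
    data.frame(class = cl, n_full = f$n[i], n_sub = length(idx),
               lambda_full = f$lambda[i], delta_full = f$delta_lambda[i],
               lambda_sub = lam_sub,
               abs_diff = abs(lam_sub - f$lambda[i]),
               within_uncertainty = !is.na(lam_sub) &&
                 abs(lam_sub - f$lambda[i]) <= f$delta_lambda[i],
               assessable = assessable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation between scaled harmonic and fundamental frequencies
#'
#' @param pairs a pair data frame (one theory level).
#' @param set a fitted [ScalingFactorSet-class].
#' @return The Pearson correlation coefficient between
#'   `lambda_class * omega` and `nu`.
#' @export
pearsonCheck <- function(pairs, set) {
  if (nrow(pairs) < 3L)
    .validationError("pearsonCheck needs at least 3 pairs")
  cls <- .classifyPairs(pairs, set@scheme)
  lam <- lambdaFor(set, cls)
  keep <- !is.na(lam)
  scaled <- lam[keep] * pairs$omega_calc[keep]
  nu <- pairs$nu_exp[keep]
  if (sd(scaled) == 0 || sd(nu) == 0)
    .validationError("correlation undefined: zero variance")
  cor(scaled, nu)
}

## Reproducible local RNG: evaluates `code` under `seed` and restores the
## caller's RNG state afterwards.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
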