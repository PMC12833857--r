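test_that("mode classification honours range cutoffs and stretch labels", {
  expect_equal(classifyMode(800, "range_dependent"), "low")
  expect_equal(classifyMode(1000, "range_dependent"), "mid")
  expect_equal(classifyMode(2000, "range_dependent"), "mid")
  expect_equal(classifyMode(2000.1, "range_dependent"), "high")
  expect_equal(classifyMode(999.9, "range_dependent"), "low")
  expect_equal(classifyMode(3650, "mode_dependent", "OH"), "OH")
  expect_equal(classifyMode(1500, "mode_dependent"), "mid")
  expect_equal(classifyMode(123, "global"), "global")
  expect_error(classifyMode(3650, "mode_dependent"),
               class = "vibmatch_validation_error")
})

test_that("least-squares lambda matches closed forms and the grid oracle", {
  ## identity data
  f <- fitScalingFactor(c(1000, 2000), c(1000, 2000))
  expect_equal(f$lambda, 1)
  expect_equal(f$delta_lambda, 0)

  ## single-pair ratio via the two-pair degenerate copy
  f2 <- fitScalingFactor(c(950, 950), c(1000, 1000))
  expect_equal(f2$lambda, 0.95)

  ## random pair sets vs the grid-search oracle
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    omega <- runif(n, 400, 3900)
    nu <- 0.95 * omega + rnorm(n, 0, 6)
    f <- fitScalingFactor(nu, omega)
    expect_equal(f$lambda, gridSearchLambda(nu, omega), tolerance = 1e-10)
  }

  ## uncertainty estimators
  omega <- c(1000, 2000, 3000); nu <- c(955, 1895, 2850)
  expect_equal(fitScalingFactor(nu, omega)$delta_lambda, sd(nu / omega))
  lam <- sum(nu * omega) / sum(omega^2)
  expect_equal(fitScalingFactor(nu, omega, "rms")$delta_lambda,
               sqrt(sum((nu - lam * omega)^2) / sum(omega^2)))

  expect_error(fitScalingFactor(950, 1000),
               class = "vibmatch_validation_error")
})

test_that("per-class fits recover known lambdas from synthetic pairs", {
  cfg <- synthConfig(seed = 11)
  ## 50+ pairs per class at 1 cm^-1 jitter, pooled over conformers
  db <- makePairDatabase(counts = c(OH = 60, NH = 60, CH_ring = 60,
                                    CH_ethyl = 60, mid = 60, low = 60),
                         levels = list(cfg$theory),
                         freq_jitter_sigma = 1, omega_jitter_sigma = 0,
                         seed = 12)
  pairs <- pairsFromWide(db)
  set <- fitScalingSet(pairs, "mode_dependent", theory = cfg$theory)
  truth <- referenceModeLambdas(cfg$theory)
  f <- factorTable(set)
  for (cl in names(truth))
    expect_lt(abs(f$lambda[f$class == cl] - truth[[cl]]), 0.002)

  ## classes with < 2 pairs are reported absent, not fatal
  two <- pairs[pairs$mode_class %in% c("OH", "NH"), ][1:3, ]
  two$mode_class <- c("OH", "OH", "NH")
  ws <- capture_warnings(s2 <- fitScalingSet(two, "mode_dependent"))
  expect_match(ws, "factor not fitted", all = TRUE)
  expect_false("NH" %in% factorTable(s2)$class)
})

test_that("applyScaling scales each peak by its class factor", {
  set <- new("ScalingFactorSet", scheme = "global", theory = NULL,
             factors = data.frame(class = "global", lambda = 0.95,
                                  delta_lambda = 0, n = 2L))
  rec <- spectrumRecord(1000, 1, source = "computed")
  expect_equal(peaks(applyScaling(rec, set))$frequency, 950)

  ## identity set leaves the record unchanged
  id_set <- new("ScalingFactorSet", scheme = "global", theory = NULL,
                factors = data.frame(class = "global", lambda = 1,
                                     delta_lambda = 0, n = 2L))
  mixed <- spectrumRecord(c(500, 1500, 3700), c(1, 2, 3),
                          mode_class = c(NA, NA, "OH"), source = "computed")
  expect_equal(peaks(applyScaling(mixed, id_set)), peaks(mixed))

  ## mode scheme: per-peak hand computation
  ms <- new("ScalingFactorSet", scheme = "mode_dependent", theory = NULL,
            factors = data.frame(class = c("OH", "mid", "low"),
                                 lambda = c(0.94, 0.97, 0.96),
                                 delta_lambda = 0, n = 2L))
  out <- applyScaling(mixed, ms)
  expect_equal(peaks(out)$frequency,
               sort(c(500 * 0.96, 1500 * 0.97, 3700 * 0.94)))
  ## intensities ride along with their peaks
  expect_equal(peaks(out)$intensity[peaks(out)$frequency == 3700 * 0.94], 3)
  expect_error(applyScaling(spectrumRecord(1, 1, source = "experimental"),
                            ms), class = "vibmatch_usage_error")
})

test_that("error statistics match a hand computation", {
  set <- new("ScalingFactorSet", scheme = "global", theory = NULL,
             factors = data.frame(class = "global", lambda = 0.95,
                                  delta_lambda = 0, n = 5L))
  pairs <- data.frame(nu_exp = c(960, 1880, 2850, 945, 1930),
                      omega_calc = c(1000, 2000, 3000, 1000, 2000),
                      intensity_exp = 1)
  e <- 0.95 * pairs$omega_calc - pairs$nu_exp   # -10, 20, 0, 5, -30
  st <- errorStats(pairs, set)
  expect_equal(st$rms, sqrt(mean(e^2)))
  expect_equal(st$mad, mean(abs(e)))
  expect_equal(st$sigma, sd(e))
  expect_equal(st$mape, 100 * mean(abs(e) / pairs$nu_exp))
  expect_equal(st$q1, unname(quantile(abs(e), 0.25)))
  expect_equal(st$q2, unname(quantile(abs(e), 0.5)))
  expect_equal(st$q3, unname(quantile(abs(e), 0.75)))
  expect_equal(st$err_min, -30)
  expect_equal(st$err_max, 20)
  expect_equal(st$n, 5L)
  expect_lte(st$mad, st$rms)
  expect_true(st$q1 <= st$q2 && st$q2 <= st$q3)

  ## perfect pairs give all-zero statistics
  perfect <- data.frame(nu_exp = 0.95 * c(1000, 2000),
                        omega_calc = c(1000, 2000), intensity_exp = 1)
  stp <- errorStats(perfect, set)
  expect_equal(unlist(stp[c("rms", "mad", "sigma", "mape", "q1", "q2",
                            "q3")]),
               setNames(rep(0, 7), c("rms", "mad", "sigma", "mape", "q1",
                                     "q2", "q3")))

  ## order and intensity-rescaling invariance
  sh <- pairs[sample(nrow(pairs)), ]
  sh$intensity_exp <- sh$intensity_exp * 42
  st2 <- errorStats(sh, set)
  expect_equal(st2$mape, st$mape)
  expect_equal(st2$q2, st$q2)
})

test_that("resampling protocol is seeded, consistent and convergent", {
  db <- makePairDatabase(counts = c(OH = 20, NH = 20, CH_ring = 20,
                                    CH_ethyl = 20, mid = 40, low = 30),
                         levels = theoryLevels()[2], seed = 5)
  pairs <- pairsFromWide(db)
  a <- resampleSplits(pairs, "global", n_iter = 20, seed = 99)
  b <- resampleSplits(pairs, "global", n_iter = 20, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$per_class$sd_lambda >= 0))

  ## means approach the deterministic full fit as train_frac -> 1
  full <- fitScalingSet(pairs, "global")
  near1 <- resampleSplits(pairs, "global", n_iter = 30, train_frac = 0.97,
                          seed = 7)
  frac07 <- resampleSplits(pairs, "global", n_iter = 30, train_frac = 0.7,
                           seed = 7)
  lam_full <- factorTable(full)$lambda
  expect_lt(abs(near1$per_class$mean_lambda - lam_full),
            abs(frac07$per_class$mean_lambda - lam_full) + 2e-4)
  expect_lt(abs(near1$per_class$mean_lambda - lam_full), 2e-4)

  ## recovery: mean lambda within 2 resampling sds of the truth
  truth <- referenceModeLambdas(theoryLevels()[[2]])
  mode_rs <- resampleSplits(pairs, "mode_dependent", n_iter = 20, seed = 3)
  pc <- mode_rs$per_class
  for (i in seq_len(nrow(pc)))
    expect_lt(abs(pc$mean_lambda[i] - truth[[pc$class[i]]]),
              2 * max(pc$sd_lambda[i], 1e-3))
})

test_that("top-intensity stability check behaves at the frac = 1 limit", {
  db <- makePairDatabase(counts = c(OH = 12, NH = 12, CH_ring = 12,
                                    CH_ethyl = 12, mid = 24, low = 16),
                         levels = theoryLevels()[2], seed = 21)
  pairs <- pairsFromWide(db)
  all_of_it <- topFractionStability(pairs, "global", frac = 1)
  expect_equal(all_of_it$lambda_sub, all_of_it$lambda_full)
  expect_equal(all_of_it$abs_diff, 0)

  rep20 <- topFractionStability(pairs, "mode_dependent", frac = 0.4)
  expect_true(all(rep20$n_sub <= rep20$n_full))
  expect_true(all(rep20$abs_diff[rep20$assessable] >= 0))
})

test_that("pearson check matches the textbook formula and edge cases", {
  set <- new("ScalingFactorSet", scheme = "global", theory = NULL,
             factors = data.frame(class = "global", lambda = 0.95,
                                  delta_lambda = 0, n = 4L))
  ## perfect linear pairs
  perfect <- data.frame(nu_exp = 0.95 * c(500, 1500, 2500),
                        omega_calc = c(500, 1500, 2500),
                        intensity_exp = 1)
  expect_equal(pearsonCheck(perfect, set), 1)

  ## hand computation on 4 points
  pairs <- data.frame(nu_exp = c(480, 1400, 2600, 3500),
                      omega_calc = c(500, 1500, 2500, 3600),
                      intensity_exp = 1)
  scaled <- 0.95 * pairs$omega_calc
  num <- sum((scaled - mean(scaled)) * (pairs$nu_exp - mean(pairs$nu_exp)))
  den <- sqrt(sum((scaled - mean(scaled))^2) *
                sum((pairs$nu_exp - mean(pairs$nu_exp))^2))
  expect_equal(pearsonCheck(pairs, set), num / den)

  expect_error(pearsonCheck(pairs[1:2, ], set),
               class = "vibmatch_validation_error")
})
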