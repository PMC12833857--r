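test_that("cross-correlation scores identity, shifts and disjoint spectra", {
  rec <- spectrumRecord(c(1000, 1200, 1350), c(1, 0.6, 0.3),
                        source = "computed")
  s <- lorentzianConvolve(rec, grid_start = 900, grid_end = 1500)
  self <- crossCorrelate(s, s, max_lag = 20)
  expect_equal(self$score, 1)
  expect_equal(self$lag, 0)

  ## calc = measured shifted +5 cm^-1: recovered at lag -5 with score 1
  shifted <- lorentzianConvolve(
    spectrumRecord(c(1005, 1205, 1355), c(1, 0.6, 0.3),
                   source = "computed"),
    grid_start = 900, grid_end = 1500)
  res <- crossCorrelate(s, shifted, max_lag = 10)
  expect_equal(res$score, 1, tolerance = 1e-6)
  expect_equal(res$lag, -5)

  ## far-apart single peaks decorrelate
  a <- lorentzianConvolve(spectrumRecord(500, 1, source = "computed"),
                          grid_start = 300, grid_end = 3800)
  b <- lorentzianConvolve(spectrumRecord(3000, 1, source = "computed"),
                          grid_start = 300, grid_end = 3800)
  expect_lt(abs(crossCorrelate(a, b, max_lag = 20)$score), 0.05)

  flat <- continuousSpectrum(900, 1, rep(1, length(intensityValues(s))))
  expect_error(crossCorrelate(flat, s, max_lag = 5),
               class = "vibmatch_validation_error")
})

test_that("cost matrices match hand arithmetic and the norm inequality", {
  m <- toyRecord(c(1000, 1500), c(1, 0.2))
  c_same <- toyRecord(c(1000, 1500), c(1, 0.2), source = "computed")
  for (metric in c("euclid_1d", "euclid_2d", "manhattan_2d"))
    expect_equal(diag(costEntries(costMatrix(m, c_same, metric))), c(0, 0))

  m1 <- toyRecord(1000, 1)
  c1 <- toyRecord(1003, 0.5, source = "computed")
  expect_equal(costEntries(costMatrix(m1, c1, "euclid_1d"))[1, 1], 3)
  expect_equal(costEntries(costMatrix(m1, c1, "euclid_2d", 10))[1, 1],
               sqrt(9 + 25))
  expect_equal(costEntries(costMatrix(m1, c1, "manhattan_2d", 10))[1, 1], 8)

  set.seed(3)
  mm <- toyRecord(sort(runif(5, 400, 3700)), runif(5))
  cc <- toyRecord(sort(runif(7, 400, 3700)), runif(7), source = "computed")
  e1 <- costEntries(costMatrix(mm, cc, "euclid_1d"))
  e2 <- costEntries(costMatrix(mm, cc, "euclid_2d"))
  mh <- costEntries(costMatrix(mm, cc, "manhattan_2d"))
  expect_true(all(mh >= e2 - 1e-12))
  expect_true(all(e2 >= e1 - 1e-12))

  unnorm <- toyRecord(1000, 5)
  expect_error(costMatrix(unnorm, c1, "euclid_2d"),
               class = "vibmatch_usage_error")
})

test_that("Kuhn-Munkres equals the exhaustive assignment oracle", {
  ## identity-like 3x3
  m <- toyRecord(c(1000, 1100, 1200))
  cc <- toyRecord(c(1000, 1100, 1200), source = "computed")
  bc <- kuhnMunkres(costMatrix(m, cc, "euclid_1d"))
  expect_equal(assignedPairs(bc)$calculated, 1:3)
  expect_equal(totalCost(bc), 0)

  ## random rectangular matrices vs brute force and the greedy bound
  set.seed(17)
  for (i in 1:60) {
    nr <- sample(2:6, 1); nc <- sample(nr:8, 1)
    mm <- toyRecord(sort(runif(nr, 400, 3700)), runif(nr))
    cr <- toyRecord(sort(runif(nc, 400, 3700)), runif(nc),
                    source = "computed")
    cm <- costMatrix(mm, cr, sample(c("euclid_1d", "euclid_2d",
                                      "manhattan_2d"), 1))
    bc <- kuhnMunkres(cm)
    oracle <- bruteForceAssignment(costEntries(cm))
    expect_equal(totalCost(bc), oracle$total, tolerance = 1e-10)
    expect_lte(totalCost(bc), greedyAssignment(costEntries(cm)) + 1e-10)
    expect_equal(sort(assignedPairs(bc)$measured), seq_len(nr))
    expect_equal(length(bc@unmatched_calc), nc - nr)
  }

  ## more measured than calculated: transposed internally
  mt <- toyRecord(c(1000, 1100, 1200))
  ct <- toyRecord(c(1001, 1199), source = "computed")
  bt <- kuhnMunkres(costMatrix(mt, ct, "euclid_1d"))
  expect_true(bt@transposed)
  expect_equal(nrow(assignedPairs(bt)), 2L)
})

test_that("intensity-aware metrics disambiguate flanking assignments", {
  ## a measured peak flanked by two calculated peaks: the nearer one has a
  ## very different intensity, the farther one matches in intensity
  m <- spectrumRecord(1000, 1.0, source = "experimental")
  calc <- spectrumRecord(c(1003, 1009), c(0.05, 1.0), source = "computed")
  bc1 <- kuhnMunkres(costMatrix(m, calc, "euclid_1d"))
  bc2 <- kuhnMunkres(costMatrix(m, calc, "euclid_2d", weight = 10))
  ## frequency-only: the measured peak goes to the nearest (1003)
  expect_equal(assignedPairs(bc1)$calc_freq, 1003)
  ## 2-D metric prefers the intensity-consistent peak at 1009:
  ## sqrt(9 + 100 * 0.95^2) ~ 9.96 > sqrt(81 + 0) = 9
  expect_equal(assignedPairs(bc2)$calc_freq, 1009)
  ## both confirmed optimal by enumeration
  for (metric in c("euclid_1d", "euclid_2d")) {
    cm <- costMatrix(m, calc, metric, weight = 10)
    expect_equal(totalCost(kuhnMunkres(cm)),
                 bruteForceAssignment(costEntries(cm))$total)
  }
})

test_that("average barcode distance", {
  m <- toyRecord(c(1000, 1100))
  cc <- toyRecord(c(1002, 1104), source = "computed")
  bc <- kuhnMunkres(costMatrix(m, cc, "euclid_1d"))
  expect_equal(averageDistance(bc), 3)  # costs 2 and 4

  self <- kuhnMunkres(costMatrix(m, toyRecord(c(1000, 1100),
                                              source = "computed"),
                                 "euclid_1d"))
  expect_equal(averageDistance(self), 0)

  ## duplicating the pair structure leaves the average unchanged
  m2 <- toyRecord(c(1000, 1100, 2000, 2100))
  c2 <- toyRecord(c(1002, 1104, 2002, 2104), source = "computed")
  bc2 <- kuhnMunkres(costMatrix(m2, c2, "euclid_1d"))
  expect_equal(averageDistance(bc2), averageDistance(bc))
})

test_that("optimal transport matches closed forms and the quantile oracle", {
  a <- toyRecord(1000, 1)
  b <- toyRecord(1010, 2, source = "computed")
  expect_equal(otDistance(a, a), 0)
  expect_equal(otDistance(a, b), 10)

  ## small instances vs the independent quantile-coupling oracle
  set.seed(23)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x1 <- sort(runif(n1, 400, 3700)); w1 <- runif(n1, 0.1, 1)
    x2 <- sort(runif(n2, 400, 3700)); w2 <- runif(n2, 0.1, 1)
    got <- otDistance(data.frame(frequency = x1, intensity = w1),
                      data.frame(frequency = x2, intensity = w2))
    expect_equal(got, quantileW1(x1, w1, x2, w2), tolerance = 1e-9)
  }

  ## symmetry and triangle inequality on random triples
  set.seed(29)
  for (i in 1:20) {
    mk <- function() data.frame(frequency = sort(runif(4, 400, 3700)),
                                intensity = runif(4, 0.1, 1))
    p <- mk(); q <- mk(); r <- mk()
    expect_equal(otDistance(p, q), otDistance(q, p))
    expect_lte(otDistance(p, r),
               otDistance(p, q) + otDistance(q, r) + 1e-9)
  }

  zero <- spectrumRecord(1000, 0, source = "experimental")
  expect_error(otDistance(zero, b), class = "vibmatch_validation_error")
})

test_that("distance uncertainty propagation matches closed form and MC", {
  m <- toyRecord(1000, 1)
  cc <- toyRecord(1010, 1, source = "computed")
  bc <- kuhnMunkres(costMatrix(m, cc, "euclid_1d"))
  expect_equal(distanceUncertainty(bc, freq_sigma = 0), 0)
  expect_equal(distanceUncertainty(bc, freq_sigma = 2), 2 * sqrt(2))
  expect_error(distanceUncertainty(bc, freq_sigma = -1),
               class = "vibmatch_usage_error")

  ## Monte-Carlo cross-check with the assignment held fixed
  set.seed(31)
  mm <- toyRecord(c(1000, 1200, 1400), c(1, 0.5, 0.2))
  cr <- toyRecord(c(1008, 1195, 1411), c(0.9, 0.6, 0.25),
                  source = "computed")
  for (metric in c("euclid_1d", "euclid_2d", "manhattan_2d")) {
    cm <- costMatrix(mm, cr, metric, weight = 10)
    bc <- kuhnMunkres(cm)
    fs <- 0.5; is <- 0.02
    got <- distanceUncertainty(bc, fs, is)
    p <- assignedPairs(bc)
    draws <- replicate(10000, {
      mf <- p$measured_freq + rnorm(3, 0, fs)
      cf <- p$calc_freq + rnorm(3, 0, fs)
      mi <- p$measured_int + rnorm(3, 0, is)
      ci <- p$calc_int + rnorm(3, 0, is)
      cost <- switch(metric,
                     euclid_1d = abs(mf - cf),
                     euclid_2d = sqrt((mf - cf)^2 + 100 * (mi - ci)^2),
                     manhattan_2d = abs(mf - cf) + 10 * abs(mi - ci))
      mean(cost)
    })
    expect_equal(got, sd(draws), tolerance = 0.1)
  }
})

test_that("candidate ranking identifies an exact copy and flags OT failure", {
  set.seed(41)
  freqs <- sort(runif(12, 450, 3600))
  meas <- spectrumRecord(freqs, runif(12, 0.2, 1), source = "experimental")
  gset <- new("ScalingFactorSet", scheme = "global", theory = NULL,
              factors = data.frame(class = "global", lambda = 0.95,
                                   delta_lambda = 0, n = 2L))
  copy <- spectrumRecord(freqs / 0.95, peaks(meas)$intensity,
                         source = "computed", conformer = "copy")
  shifted <- spectrumRecord(freqs / 0.95 + 30, peaks(meas)$intensity,
                            source = "computed", conformer = "shifted")
  res <- rankCandidates(meas, list(shifted, copy), gset)
  row <- res[res$id == "copy", ]
  expect_equal(row$rank_xcorr, 1L)
  expect_equal(row$rank_euclid, 1L)
  expect_equal(row$rank_manhattan, 1L)
  expect_equal(row$rank_ot, 1L)
  expect_equal(row$avg_euclid, 0, tolerance = 1e-9)

  ## ranking is invariant to candidate order (up to tie breaking)
  res2 <- rankCandidates(meas, list(copy, shifted), gset)
  expect_equal(res2$rank_euclid[res2$id == "copy"], 1L)

  ## intensity-redistribution adversary: OT prefers the wrong candidate,
  ## the assignment-based metrics keep the true one first
  madv <- spectrumRecord(c(1000, 1004), c(1.0, 0.5),
                         source = "experimental")
  idset <- new("ScalingFactorSet", scheme = "global", theory = NULL,
               factors = data.frame(class = "global", lambda = 1,
                                    delta_lambda = 0, n = 2L))
  truth <- spectrumRecord(c(1002, 1006), c(1.0, 0.5), source = "computed",
                          conformer = "truth")
  swapped <- spectrumRecord(c(1000, 1004), c(0.5, 1.0),
                            source = "computed", conformer = "swapped")
  adv <- rankCandidates(madv, list(truth, swapped), idset,
                        matchConfig(grid_start = 900, grid_end = 1100))
  expect_equal(adv$rank_ot[adv$id == "swapped"], 1L)
  expect_equal(adv$rank_euclid[adv$id == "truth"], 1L)
  expect_equal(adv$rank_manhattan[adv$id == "truth"], 1L)

  ## a failing candidate is marked and the rest are still ranked
  bad <- spectrumRecord(2500, 1, source = "computed", conformer = "bad")
  mset <- new("ScalingFactorSet", scheme = "mode_dependent", theory = NULL,
              factors = data.frame(class = c("mid", "low"),
                                   lambda = c(0.97, 0.96),
                                   delta_lambda = 0, n = 2L))
  mlow <- spectrumRecord(c(800, 1500), c(1, 0.5), source = "experimental")
  okc <- spectrumRecord(c(820, 1540), c(1, 0.5), source = "computed",
                        conformer = "ok")
  suppressWarnings(
    res3 <- rankCandidates(mlow, list(bad, okc), mset,
                           matchConfig(grid_start = 500, grid_end = 1800)))
  expect_true(res3$failed[res3$id == "bad"])
  expect_equal(res3$rank_euclid[res3$id == "ok"], 1L)
})
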