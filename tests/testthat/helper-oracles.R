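## Independent oracles used by the test suite. These deliberately avoid
## the package's own code paths.

## All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

## Exhaustive minimal-cost injection of rows into columns (m <= c),
## vectorized over all C(c, m) * m! injections.
bruteForceAssignment <- function(cost) {
  m <- nrow(cost); cc <- ncol(cost)
  stopifnot(m <= cc)
  subsets <- utils::combn(cc, m)
  pm <- perms(m)
  inj <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(s) {
    cols <- subsets[, s]
    matrix(cols[pm], nrow(pm))
  }))
  rows <- matrix(rep(seq_len(m), each = nrow(inj)), nrow(inj))
  flat <- as.vector((inj - 1L) * m + rows)
  totals <- rowSums(matrix(cost[flat], nrow(inj)))
  i <- which.min(totals)
  list(total = totals[i], cols = inj[i, ])
}

## Grid-search least-squares scaling factor: coarse grid on [0.8, 1.1]
## refined iteratively, then a parabolic-vertex step (exact for the
## quadratic objective) to reach ~1e-12 resolution without running into
## the flat-valley float noise of direct objective comparisons.
gridSearchLambda <- function(nu, omega) {
  obj <- function(l) sum((l * omega - nu)^2)
  lo <- 0.8; hi <- 1.1
  repeat {
    grid <- seq(lo, hi, length.out = 401)
    vals <- vapply(grid, obj, 0)
    i <- which.min(vals)
    lo2 <- grid[max(1, i - 1)]; hi2 <- grid[min(length(grid), i + 1)]
    if (hi2 - lo2 < 1e-4) { center <- grid[i]; break }
    lo <- lo2; hi <- hi2
  }
  h <- 1e-6
  f0 <- obj(center); fp <- obj(center + h); fm <- obj(center - h)
  center - h * (fp - fm) / (2 * (fp - 2 * f0 + fm))
}

## Quantile-coupling oracle for the 1-D Wasserstein-1 distance between two
## discrete mass distributions (independent of the CDF-over-frequency
## implementation): partitions the unit mass axis at every cumulative
## breakpoint of either distribution and sums |F1^-1(q) - F2^-1(q)| dq.
quantileW1 <- function(x1, m1, x2, m2) {
  m1 <- m1 / sum(m1); m2 <- m2 / sum(m2)
  o1 <- order(x1); o2 <- order(x2)
  x1 <- x1[o1]; m1 <- m1[o1]; x2 <- x2[o2]; m2 <- m2[o2]
  q <- sort(unique(c(0, cumsum(m1), cumsum(m2))))
  q <- pmin(pmax(q, 0), 1)
  inv <- function(x, m, p) {
    cum <- cumsum(m)
    cum[length(cum)] <- 1  # guard against cumulative rounding
    x[pmin(findInterval(p, cum, left.open = TRUE) + 1, length(x))]
  }
  mids <- (q[-1] + q[-length(q)]) / 2
  dq <- diff(q)
  sum(abs(inv(x1, m1, mids) - inv(x2, m2, mids)) * dq)
}

## Linear-program transport oracle (scipy.optimize.linprog through the
## system python): solves min sum_ij |x_i - y_j| T_ij subject to row sums
## a and column sums b, for a batch of instances. Returns the optimal
## objective values.
lpTransportOracle <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, infile, digits = NA)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
with open(sys.argv[1]) as fh:
    instances = json.load(fh)
out = []
for inst in instances:
    x = np.asarray(inst["x"], float); a = np.asarray(inst["a"], float)
    y = np.asarray(inst["y"], float); b = np.asarray(inst["b"], float)
    a = a / a.sum(); b = b / b.sum()
    n, m = len(x), len(y)
    C = np.abs(x[:, None] - y[None, :]).ravel()
    A = []
    for i in range(n):
        row = np.zeros((n, m)); row[i, :] = 1; A.append(row.ravel())
    for j in range(m):
        col = np.zeros((n, m)); col[:, j] = 1; A.append(col.ravel())
    res = linprog(C, A_eq=np.array(A), b_eq=np.concatenate([a, b]),
                  bounds=(0, None), method="highs")
    out.append(res.fun)
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, infile, outfile))
  stopifnot(status == 0)
  unlist(jsonlite::fromJSON(outfile))
}

## Greedy nearest-neighbour assignment (upper bound for the optimal one).
greedyAssignment <- function(cost) {
  m <- nrow(cost)
  used <- integer(0)
  tot <- 0
  for (i in seq_len(m)) {
    avail <- setdiff(seq_len(ncol(cost)), used)
    j <- avail[which.min(cost[i, avail])]
    used <- c(used, j)
    tot <- tot + cost[i, j]
  }
  tot
}

## Convenience: a normalized experimental record from vectors.
toyRecord <- function(freq, inten = rep(1, length(freq)),
                      source = "experimental", ...) {
  spectrumRecord(freq, inten, source = source, ...)
}

## A mode-dependent factor set holding the generator's true lambdas.
truthFactorSet <- function(config) {
  new("ScalingFactorSet", scheme = "mode_dependent", theory = config$theory,
      factors = data.frame(class = names(config$true_lambda),
                           lambda = unname(config$true_lambda),
                           delta_lambda = 0, n = 2L,
                           stringsAsFactors = FALSE))
}
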