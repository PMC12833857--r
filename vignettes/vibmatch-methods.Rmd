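---
title: "Frequency scaling and spectral matching with vibmatch"
author: "vibmatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency scaling and spectral matching with vibmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibmatch)
```

## The problem

Harmonic normal-mode calculations systematically overestimate observed
vibrational fundamentals, mostly because they ignore anharmonicity. The
standard remedy is an empirical multiplicative scaling factor
$\lambda$ mapping calculated harmonic frequencies $\omega_i$ onto
experimental fundamentals $\nu_i$. Once scaled, a calculated spectrum can
be compared quantitatively against a measured one, which is the basis for
identifying which conformer of a flexible molecule is actually present in
an experiment (for example, in jet-cooled ionization-detected stimulated
Raman measurements of neurotransmitter-like molecules, where several
conformers with nearly identical spectra are candidates).

`vibmatch` implements both halves of that workflow:

1. **Scaling**: derivation of global, range-dependent and mode-dependent
   scaling factors from a paired-frequency database, with uncertainties,
   a full error-statistics battery and resampling/stability protocols.
2. **Matching**: quantitative similarity between a measured
   fundamental-band peak list and scaled calculated spectra of candidate
   conformers, via cross-correlation, Euclidean/Manhattan cost matrices
   with Kuhn-Munkres assignment (spectral barcodes), and a 1-D
   optimal-transport distance.

## The scaling model

For a set of pairs $(\nu_i, \omega_i)$ the scaling factor is the
least-squares minimizer of $\sum_i (\lambda\omega_i - \nu_i)^2$,

$$\lambda = \frac{\sum_i \nu_i \omega_i}{\sum_i \omega_i^2},$$

the convention of the frequency-scaling literature. Its uncertainty
$\Delta\lambda$ is, by default, the sample standard deviation of the
per-pair ratios $\nu_i/\omega_i$. This choice reproduces the magnitude of
published uncertainty parentheses for databases of this kind (of order
0.01 for a global factor); an alternative residual-based estimator
$\sqrt{\sum_i(\nu_i - \lambda\omega_i)^2 / \sum_i \omega_i^2}$ is exposed
through `uncertainty = "rms"` for sensitivity checks, since the exact
published convention is not always stated.

Three classification schemes are supported:

* **global** -- one factor for the full spectral range;
* **range-dependent** -- `low` ($\nu < 1000$ cm$^{-1}$), `mid`
  ($1000 \le \nu \le 2000$ cm$^{-1}$) and `high` ($\nu > 2000$
  cm$^{-1}$); the quoted cutoffs "<1000" and ">2000" are strict, so both
  boundary values land in `mid`;
* **mode-dependent** -- the pure stretching classes `OH`, `NH`,
  `CH_ring`, `CH_ethyl` above 2000 cm$^{-1}$ (these require an explicit
  label, since vibration type is not deducible from frequency alone)
  plus the same `mid`/`low` ranges below. When a record carries explicit
  `mid`/`low` labels they are authoritative, so a labelled mid-range mode
  that drifts marginally above 2000 cm$^{-1}$ is still scaled as `mid`
  rather than rejected.

For computed records the class is determined from the *harmonic*
frequency (plus labels). Near the 1000 cm$^{-1}$ boundary this can differ
from classification by the scaled frequency; the convention is
deterministic and documented, and the synthetic generator keeps its
frequency windows clear of the cutoffs so that tests are unambiguous.

Error statistics for a fitted set are computed from the signed errors
$e_i = \lambda_{c(i)}\omega_i - \nu_i$: RMS, mean absolute deviation,
standard deviation ($n-1$ denominator), MAPE
($100\cdot\mathrm{mean}(|e_i|/\nu_i)$), and the quartiles Q1/Q2/Q3 of the
*absolute* error distribution with linear interpolation (published
Q-values for such databases are positive and in cm$^{-1}$, which is why
absolute errors are quantiled). The resampling protocol
(`resampleSplits()`) runs 100 cycles of random 70%/30% training/test
splits, fitting on the training pairs and evaluating on the test pairs,
and reports means and standard deviations across cycles. Splits are
stratified per class -- publication-style protocols do not always state
this, but stratification is the only way to guarantee that every class is
fittable in every cycle -- and one integer seed drives the whole run.
`topFractionStability()` refits using only the top 20% most intense
experimental features (globally by intensity, the most direct reading of
"most intense features") and reports whether each class's factor moves
outside its full-fit uncertainty.

## The matching pipeline

A measured peak list is first passed through the fundamental-band
inclusion filter (`filterFundamentals()`): only distinct peaks with
signal-to-noise ratio strictly above 2.5 and FWHM strictly above 4
cm$^{-1}$ are retained, excluding noise spikes; peaks lacking this
metadata (curated databases publish already-filtered features) pass
through and are tallied. Intensities are normalized to a maximum of 1.
Candidate harmonic spectra are scaled with the chosen factor set and
normalized the same way. Four scores are then computed per candidate:

* **Cross-correlation** (`crossCorrelate()`): both peak lists are
  convolved with unit-peak-height Lorentzians (FWHM 4 cm$^{-1}$ by
  default, so the convolved apex of an isolated line equals its stick
  intensity) onto a common grid -- 300--3800 cm$^{-1}$ at 1 cm$^{-1}$ by
  default, covering the usual experimental range with margin; the grid
  step of the published plots is not stated, and 1 cm$^{-1}$ is adopted
  and configurable. The score is the maximum over integer displacements
  within $\pm$ 20 cm$^{-1}$ of the zero-mean, unit-norm correlation of
  the overlapping segments, a bounded score in $[-1, 1]$ comparable
  across species. Positive lag means the calculated spectrum is displaced
  to higher wavenumber.
* **Average Euclidean / Manhattan barcode distances**: a cost matrix over
  (measured peak, calculated peak) pairs with
  `euclid_2d` $= \sqrt{\Delta\nu^2 + w^2\Delta I^2}$ or `manhattan_2d`
  $= |\Delta\nu| + w|\Delta I|$ (a frequency-only `euclid_1d` variant
  exists mainly to demonstrate why intensities matter). The Kuhn-Munkres
  (Hungarian) algorithm then assigns every measured peak to a distinct
  calculated peak at minimal total cost; surplus calculated features stay
  unmatched at zero penalty, because measured spectra are subsets of the
  predicted ones (beam population, band overlap). The score is the total
  cost divided by the number of assigned pairs.
* **Optimal transport** (`otDistance()`): stick intensities are
  normalized to unit total mass per spectrum and the Wasserstein-1
  distance is computed as $\int |F_\mathrm{meas} - F_\mathrm{calc}|\,
  d\nu$ over the merged support, which equals the minimal transport work
  with $|\Delta\nu|$ ground cost. Transport operates on discrete stick
  features, not convolved spectra.

The intensity weight $w$ converts normalized intensity differences into
cm$^{-1}$-equivalent cost. How intensities are "weighted" is generally
left unstated in published work; the default $w = 10$ cm$^{-1}$ per unit
normalized intensity makes a full-scale intensity mismatch cost as much
as a 10 cm$^{-1}$ shift, i.e. it puts typical intensity errors on the
same scale as typical median frequency errors of a scaled spectrum. It is
a `matchConfig()` parameter, declared rather than inferred.

`rankCandidates()` assembles per-method ranks (cross-correlation
descending, distances ascending; ties broken by candidate input order
with a message; candidates that cannot be scaled are marked failed and
excluded). The Euclidean/Manhattan barcode distances are the primary
identification criteria: optimal transport may legitimately redistribute
intensity between adjacent features and therefore *fails* as an
identification criterion in exactly the situation the test suite
constructs (a candidate with intensities swapped between two close peaks
is transport-closer to the measurement than the true conformer, while the
assignment-based distances still rank the truth first).

Uncertainties of the average distances (`distanceUncertainty()`) are
propagated to first order from per-peak frequency/intensity standard
deviations through the assigned-pair cost sum with the assignment held
fixed. The exact published propagation formulas for this quantity are in
unavailable supplementary material; the implementation is a standard
first-order treatment, documented as such, and is validated against
Monte-Carlo perturbation in the tests. At a non-differentiable point of
the 2-D Euclidean cost (coincident peaks) a conservative bound is used.

## The synthetic generator

Because the curated 824-fundamental database is not redistributable with
the package, the generator (`makePairDatabase()`,
`makeConformerLibrary()`, `makeMeasuredFrom()`) emulates its statistical
structure so that every stage is testable end to end:

* **Class composition**: the published per-class counts O-H 34, N-H 54,
  C-H ring 114, C-H ethyl 108, mid 309, low 175. (These printed counts
  sum to 794, although the same source also quotes a total of 824 with a
  high-range count of 340; the 30-feature gap corresponds to
  high-frequency features carrying no stretch label. The generator uses
  the six printed per-class counts.) Conformer libraries rescale the same
  proportions to about 60 modes per conformer.
* **True scaling factors**: the published mode-dependent factors per
  theory level (`referenceModeLambdas()`), e.g. O-H 0.9402 at
  M06-2X-D3/6-311++G(d,p).
* **Frequency windows** (harmonic, cm$^{-1}$): O-H 3650-3900, N-H
  3450-3600, C-H ring 3150-3250, C-H ethyl 3050-3150, mid 1030-2000, low
  400-1020 -- standard stretch regions, with the mid/low windows chosen
  so that scaled fundamentals stay on their side of the 1000 cm$^{-1}$
  cutoff.
* **Noise model** (defaults chosen once, as plausible experimental
  conditions): Gaussian fundamental jitter of 5 cm$^{-1}$; log-normal
  multiplicative intensity noise with CV 0.2; peak dropout probability
  0.3; interloper "gain-line" contaminants at 0.5 per 1000 cm$^{-1}$ with
  SNR/FWHM drawn so that some fail the inclusion filter while all true
  peaks pass. Conformers differ by per-class correlated shifts of 2-15
  cm$^{-1}$ plus ~2 cm$^{-1}$ per-mode scatter and log-normal intensity
  redistribution, mimicking how real conformers differ.
* **Database generation model**: a reference-level harmonic frequency is
  drawn per mode; the "experimental" fundamental is the reference-level
  class factor times that frequency plus jitter; each level's harmonic
  column is $\nu/\lambda_{L,c}$ plus a 2 cm$^{-1}$ harmonic scatter. A
  consequence worth knowing: within one level the mode-scheme residuals
  are governed by the harmonic scatter, not the 5 cm$^{-1}$ fundamental
  jitter (which cancels by construction), so synthetic mode-dependent
  error statistics are tighter than the real database's, while the
  global-scheme statistics -- dominated by between-class factor
  dispersion -- land close to published magnitudes.

What passing tests on synthetic data do show: the estimators recover
known ground truth, the error-ordering of the three schemes, and the
identification power of the metrics under realistic noise. What they do
not show: agreement with the real database's absolute error statistics,
real anharmonic effects (Fermi resonances), non-Gaussian lineshape
effects, or correlated experimental drifts.

## Numerical choices and degenerate inputs

* Frequencies are stored to 0.1 cm$^{-1}$ on write (below experimental
  resolution), which makes file round-trips exact; peaks closer than the
  storage precision are kept distinct by a 0.1 cm$^{-1}$ bump.
* Quartiles use linear interpolation (R type 7); $\sigma$ and ratio-SD
  uncertainties use the $n-1$ denominator.
* Classes with fewer than 2 pairs are reported absent with a warning,
  not fitted; `errorStats()` drops (and counts) pairs in classes with no
  fitted factor.
* The Hungarian solver is an $O(n^3)$ shortest-augmenting-path
  implementation in C++ (the cost matrices here are small, but the
  benchmark runs thousands of them); rectangular matrices with more
  measured than calculated peaks are transposed internally and flagged.
* `resampleSplits()` redraws an iteration (up to 1000 attempts) if a
  class would end up with fewer than 2 training or 1 test members.
* Zero-variance spectra make cross-correlation undefined and raise a
  classed error; all-zero intensity vectors cannot be normalized or
  transported and do likewise.

## Problem sizes used by the checks

The shipped verification uses: 500 random cost matrices up to 6x8 against
exhaustive enumeration; 100 random pair sets against a grid-search
oracle; 100 random transport instances (up to 6 masses a side) against a
linear-program oracle; parameter recovery at 1 cm$^{-1}$ jitter with
50-60 pairs per class; 100 resampling cycles; and 200 seeded
identification scenarios with 8 candidates each at default noise. These
sizes keep the whole suite comfortably fast while leaving the Monte-Carlo
margins far from their thresholds.

## A small worked example

```{r example}
tl <- theoryLevel("M06-2X-D3", "6-311++G(d,p)")
db <- makePairDatabase(levels = list(tl), seed = 7)
pairs <- pairsFromWide(db)
set <- fitScalingSet(pairs, "mode_dependent", theory = tl)
set
errorStats(pairs, set)

cfg <- synthConfig(seed = 7)
sc <- makeScenario(cfg)
meas <- filterFundamentals(sc$measured)
res <- rankCandidates(meas, sc$library, set)
res[c("id", "avg_euclid", "avg_manhattan", "rank_euclid")]
sc$truth_id
```

## Known limitations

* Intensity scaling is out of scope (frequency factors only); measured
  and calculated intensities are compared only after per-spectrum
  normalization.
* Only Lorentzian lineshapes are provided; no baseline handling, peak
  picking from continuous traces, or deconvolution of overlapping
  measured features.
* Mode-dependent factors are specific to the chemical space of the
  database they were fitted on; portability to unrelated molecules is
  not implied.
* The optimal-transport score is included deliberately as a negative
  control for identification, not as a recommended criterion.
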