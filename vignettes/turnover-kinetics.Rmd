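---
title: "Protein turnover kinetics from heavy-water labeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein turnover kinetics from heavy-water labeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoturn)
```

## The measurement

When an animal drinks a small amount of heavy water, deuterium equilibrates
through its body water and is incorporated into newly synthesized proteins at
metabolically accessible hydrogen positions. In a mass spectrum this shows up
as a progressive depletion of the monoisotopic (0th) peak of each peptide's
isotope envelope: old molecules still carry the natural envelope, new ones
are shifted to heavier isotopomers. Following the fractional abundance of the
0th isotopomer, `A0`, over days of labeling therefore measures the rate at
which the protein pool is replaced.

`isoturn` implements the full analysis path from peptide sequence to
protein-level turnover rates: natural-envelope theory, body-water enrichment
calibration, non-steady-state kinetic curve fitting, stringency filtering,
robust protein roll-up, and two label-free abundance measures. A
synthetic-data generator reproduces the statistical structure the analysis
assumes, so the whole pipeline is testable without any raw data.

## Model constants from the sequence

Two constants of the kinetic model are fixed by the peptide sequence alone.

**`a`, the unlabeled 0th-isotopomer fraction.** The natural isotope envelope
of a peptide is the convolution, by integer nominal-mass offset, of the
per-atom isotope distributions of its elemental composition
(`peptide_composition()`, `isotope_envelope()`). `a = A0` at time zero is
the product over elements of the lightest-isotope abundance raised to the
atom count. The shipped abundances are IUPAC representative values in a
plain-text table the user can replace; modification deltas for the six
common search modifications (carbamidomethyl, oxidation, acetyl, phospho,
GG remnant, deamidation) are likewise shipped and user-overridable.
Isotopologues that share a nominal mass offset are aggregated because the
pipeline only consumes the 0th peak, where no aggregation ambiguity exists.
The default envelope truncation is `n_peaks = 5`, which covers more than
99.9% of the envelope mass for tryptic-size peptides; the untruncated
envelope is available with `n_peaks = NULL` and is verified in tests to sum
to one.

**`N`, the number of labeling sites.** Each residue contributes a fixed
effective number of deuterium-accessible hydrogens, taken from the
Commerford-lineage literature values used throughout rodent heavy-water
labeling work and shipped as a replaceable table (`count_sites()`). `N` is
the per-residue sum; modifications do not change it, since no
modification-specific site counts are established.

## Body-water enrichment

Deuterium enrichment of body water is measured by GC-MS of acetone after
exchange: a standard curve of known molar fractions (0–20%) against the
m/z 59 / m/z 58 ion-intensity ratio is fit by ordinary least squares with
the molar fraction as the response (`fit_standard_curve()`), so the line
applies directly to sample ratios (`enrichment_from_ratio()`). Enrichment
over time follows first-order equilibration

\[ p(t) = p_{ss}\,(1 - e^{-k_p t}), \]

fit by bounded Levenberg–Marquardt least squares
(`fit_enrichment_curve()`). `k_p` is capped at 50 per day: above that the
curve is indistinguishable from instant enrichment on any daily sampling
grid and the likelihood is flat (saturated data drive the estimate to
"large", and the cap avoids a runaway ridge).

Identifiability depends on sampling: at `k_p = 2` per day the transient is
95% complete by day 1.5, so a grid whose first labeled sample is day 1
constrains `k_p` only weakly (in simulations at that grid the median
relative error of `k_p` is about 11%, while `p_ss` is recovered to about
1%). This is benign for the downstream kinetics — after the first day the
model depends on enrichment almost entirely through `p_ss` — but the
parameter-recovery validation of the fitter itself uses a calibration grid
with sub-day samples where `k_p` is identified.

The default generator values `p_ss = 0.045`, `k_p = 2` per day are plausible
for a mouse drinking 8% (v/v) heavy water after a priming bolus, which
equilibrates body water to roughly half the supply level. They are
explicitly synthetic defaults, not measured values.

## The kinetic model and its analytic solution

The 0th-isotopomer fraction of a peptide pool relaxes toward the
0th-isotopomer fraction of newly made peptides at the turnover rate `k`.
Because a new peptide synthesized at body-water enrichment `p` keeps its `N`
sites with probability `(1-p)` each of remaining light, the precursor value
is time-dependent:

\[ A_{0,max}(t) = a\,\bigl(1 - p_{ss}(1 - e^{-k_p t})\bigr)^{N}, \qquad
   \frac{dA_0}{dt} = k\,\bigl(A_{0,max}(t) - A_0\bigr), \quad A_0(0) = a. \]

This correction does not delay the curve; it slows its initial descent,
exactly as a late-arriving label supply should. Expanding the forcing term
binomially and integrating gives the closed form implemented in
`model_a0()`:

\[ A_0(t) = a e^{-kt} + a k \sum_{i=0}^{N} \binom{N}{i} (1-p_{ss})^{N-i}
   p_{ss}^{\,i}\; \frac{e^{-i k_p t} - e^{-kt}}{k - i k_p}, \]

with a term replaced by its limit \(a k b_i\, t e^{-kt}\) whenever
\(|k - i k_p| < 10^{-9} k_p\) (the degenerate-denominator tolerance; the
switch is continuous at that scale). The expansion needs integer `N`;
non-integer site counts are rounded to the nearest integer. A numerical
oracle, `ode_a0()`, integrates the same differential equation with `deSolve`
at tolerances of 1e-12 and handles real `N` exactly; the test suite holds
the two routes together to 1e-8 across a dense random parameter grid. The
divergence introduced by rounding is bounded in tests at under 2% of the
decay range for a rounding error of up to half a site — small relative to
measurement noise, but not negligible for peptides whose fractional site
count lands near .5; users needing exactness at real `N` can compare against
`ode_a0()` directly.

## Fitting, fit statistics, and their defaults

`fit_k()` minimizes the residual sum of squares over `k` with the
Nelder–Mead simplex, restarted from 0.1, 0.01 and 1 per day (the rate
distribution spans roughly 0.01–1 per day, so the restarts bracket it), and
keeps the best restart. Search bounds are `[1e-4, 20]` per day; an estimate
pinned at a bound is flagged not-converged, as is the degenerate flat-series
case. An independent quasi-Newton (bounded BFGS-style) pass over the same
restarts is stored alongside for auditing — on simulated data the two
optimizers agree to better than one part in 1e4, so the choice of optimizer
is immaterial, and the simplex value is reported.

Reported statistics follow the pipeline's output conventions:

* `SS`: residual sum of squares of the fit;
* `R2 = 1 - SS / \sum (A_0 - \bar A_0)^2`; negative values for flat or
  poorly fitted series are preserved as computed, because the filter sweep
  depends on them;
* `se`: standard error of estimate in `A0` units. The default denominator is
  `DP - 1` (one fitted parameter); `sqrt(SS/DP)` and `sqrt(SS/(DP-2))` are
  available, as the convention is not standardized;
* `dk`: a linearized one-parameter standard error,
  `sqrt(se^2 / sum((dA0/dk)^2))`, with the derivative taken numerically at
  the optimum.

`fit_turnover()` applies this to a whole `hl-data.out`-style table, deriving
`a` and `N` per peptide, and returns the 14 documented per-peptide columns
(plus `se`, convergence flags, and the audit estimate).

## Stringency filter, roll-up, diagnostics

A fitted series is accepted when it has at least 4 distinct time points and
either `R2 >= 0.8` or `se <= 0.05`. The two branches are deliberately
OR-combined: slow-turnover peptides produce nearly flat decay curves whose
`R2` is low no matter how precisely they are measured, and the `se` branch
rescues exactly those. Rejected rows are kept with a labeled reason so the
identified → quantified → filtered accounting stays visible.

Protein turnover is the median of accepted member-peptide rates; dispersion
is the unscaled median absolute deviation (`median(|k_i - median|)`, no
1.4826 consistency factor — the statistic is reported as a plain MAD). The
experiment-level diagnostic `intra_protein_variability()` is the median over
multi-peptide proteins of `MAD/median`, as a percentage: peptides of one
protein should report the same rate, so values under roughly 30% indicate
acceptable internal consistency. The threshold is interpreted as relative
dispersion because it is quoted as a percentage. `filter_sweep()` evaluates
the cutoff grid and exposes the quality/quantity trade-off; acceptance
counts are provably monotone along each grid axis, and the tests verify
this.

Peptide identity throughout is (sequence including modifications, charge).

## Label-free quantification

Two independent abundance measures are provided. The XIC route
(`xic_protein_abundance()`) normalizes summed peptide envelope areas in
three stages, in order: by the run's total spectral intensity, then per
protein by its count of possible tryptic peptides 6–30 residues long from
in-silico digestion (fully cleaved products, cleaving after K/R except
before P), then to within-sample relative values. The third stage is
applied per time point, so each column of `intensity.txt` sums to one; this
is an interpretation of "total relative areas within the sample", chosen
because each time point is a separately acquired sample. The NSAF route is
the standard length-normalized spectral count,
\( (SpC_i/L_i) / \sum_j (SpC_j/L_j) \). Both are scale-invariant and sum to
one within a sample; on synthetic data sharing a ground truth their ranks
agree strongly.

## Spectral front end

A deliberately simplified envelope integrator stands in for the raw-data
front end: `extract_xic()` sums centroid intensities within a half-open
±60 ppm window, `smooth_trace()` applies a quadratic Savitzky–Golay filter
over 7 points (which passes constant and linear traces unchanged),
and `integrate_envelope()` takes trapezoidal areas between externally
supplied elution bounds, spacing isotopomers by the neutron mass over
charge. Peak detection, deisotoping and vendor formats are out of scope;
elution bounds come from the identification's retention time.

## The synthetic generator

`generate_experiment()` emulates one sample group of a multi-strain labeling
study: random protein sequences at natural residue frequencies, in-silico
tryptic digestion, peptides 6–30 residues sampled per protein, true rates
drawn per protein, `A0` series generated from the analytic model with
Gaussian noise (sd 0.01 by default, matching a well-behaved orbitrap
integration) clamped to [0, 1], and GC-MS fixtures (an 11-point standard
curve and per-day sample ratios on a fixed synthetic instrument response
with slope 0.5 and baseline 0.05). `study_design()` carries the full-study
bookkeeping — 6 strains, two conditions, 7 sampling days (6 for the
treated condition), 18 runs and 2 animals per group-day — whose manifest
reproduces 78 sample groups, 1,404 runs and 156 animals.

`generate_rates()` draws rate constants to match a stated median
(0.094 per day) and interdecile range (0.037–0.30 per day). A
two-parameter log-normal cannot match a median and two deciles that are not
geometrically symmetric, and these are not (0.037 × 0.30 ≠ 0.094²). The
sampler therefore uses a two-piece normal in log space — location
`log(median)`, separate left and right scales set from each decile — which
matches all three quoted statistics exactly and reduces to the exact
log-normal when the bounds are symmetric. What the generator does *not*
emulate: inter-animal variability, missing time points, heteroscedastic
integration noise, isoform ambiguity, and chromatographic peak-shape
artifacts. Passing recovery tests on this generator therefore demonstrates
correctness of the estimation machinery under the model's own assumptions,
not robustness to every pathology of real data.

All stochastic steps take explicit seeds and are reproducible byte-for-byte
under a fixed seed.

## Numerical choices and edge cases

* Envelope convolution truncates at `n_peaks` during the per-element
  repeated-squaring step; truncation can only remove mass beyond the kept
  offsets, so retained peaks are exact.
* `fit_k` evaluates out-of-bounds rate proposals with a steep finite penalty
  so the simplex re-enters the box instead of receiving non-finite values.
* Flat series (no variance in `A0`) have undefined `R2` (reported `NA`) and
  are flagged; noisy-flat series receive `R2 <= 0` and fail the `R2`
  branch, by design.
* Enrichment values implied by a standard curve outside `[0, 1)` are clamped
  with a warning; molar fractions cannot leave that range.
* The enrichment fitter runs bounded Levenberg–Marquardt from several
  starts and keeps the lowest residual; near-saturated data push `k_p`
  toward regions where its Jacobian column vanishes, which the low-level
  `nls.lm` driver tolerates.
* Sweep cutoffs above 1 for `R2` are allowed (they accept nothing through
  that branch), supporting degenerate sweep corners.

## Problem sizes used in validation

The shipped validation uses problem sizes chosen to exercise every claim
while keeping the suite quick to run routinely: 1,000-point random parameter
grids for the analytic-vs-ODE equivalence, 500 simulated peptide series for
optimizer agreement and recovery bias, 1e5 draws for rate-distribution
quantiles, 200 simulated calibration datasets for enrichment recovery, and
a 25-protein synthetic experiment for the end-to-end roll-up. Larger sizes
change none of the conclusions, only the Monte-Carlo error.

## Known limitations

Single-compartment, single-exponential kinetics only: biphasic responses
and precursor-pool compartmentalization are outside the model, as are
fitting isotopomers other than `A0` (`mi` is carried as metadata only),
match-between-runs, and absolute quantification. Proteins secreted from or
shredded into the sampled tissue violate the closed-pool assumption and
appear as altered effective rates; interpreting them needs care regardless
of software.
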