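# isoturn

Protein turnover kinetics from heavy-water (²H₂O) metabolic labeling and
mass spectrometry.

When an animal is labeled with a low dose of heavy water, deuterium enters
newly synthesized proteins at metabolically accessible hydrogen sites, and
each peptide's monoisotopic (0th) isotopomer fraction `A0` decays over the
labeling course at the protein's turnover rate. `isoturn` turns tables of
peptide `A0` time series into protein half-lives, for proteomics researchers
analyzing in vivo labeling studies (and for method developers who want a
tested, self-contained reference implementation of the analysis).

## The model

Body-water enrichment equilibrates with first-order kinetics,
`p(t) = p_ss (1 − e^(−k_p t))`, calibrated from GC-MS acetone-exchange
measurements. The 0th-isotopomer fraction of a peptide with natural
0th-peak fraction `a` (from its elemental composition) and `N`
deuterium-accessible sites (from per-residue literature values) follows the
non-steady-state first-order model

    dA0/dt = k · ( a (1 − p_ss(1 − e^(−k_p t)))^N − A0 ),   A0(0) = a,

whose analytic solution (by binomial expansion of the forcing term) is fit
to each peptide time series by Nelder–Mead least squares, cross-checked
against a quasi-Newton optimizer and a numerical ODE oracle. Series are
accepted when quantified at ≥ 4 time points with `R² ≥ 0.8` **or** standard
error of estimate `≤ 0.05` (the second branch rescues well-measured
slow-turnover peptides); protein rates are the median of accepted peptide
rates with the unscaled MAD as dispersion, and half-life is `ln 2 / k`.
Relative protein abundance is computed two ways: tryptic-peptide-count
normalized XIC intensity, and NSAF spectral counting.

A first-class synthetic-data generator emulates the study structure — six
mouse strains × two conditions, sampling days {0, 1, 3, 5, 7, 10, 14},
a rate distribution matching reported in vivo cardiac proteome statistics
(median 0.094 d⁻¹, interdecile range 0.037–0.30 d⁻¹), first-order
body-water enrichment, and
Gaussian `A0` noise — so the whole pipeline is testable offline.

## Worked example

```r
library(isoturn)

# a synthetic experiment: 6 proteins, ~5 peptides each, 7 sampling days
sim <- generate_experiment(n_proteins = 6, peptides_per_protein = 5, seed = 17)

# 1. calibrate body-water enrichment from the GC-MS fixtures
sc  <- fit_standard_curve(sim$standard_curve)
p   <- enrichment_from_ratio(sc, sim$bodywater$ratio)
enr <- fit_enrichment_curve(tibble::tibble(t = sim$bodywater$t, p = p))
enr
#> Body-water enrichment curve  p(t) = p_ss * (1 - exp(-k_p t))
#>   p_ss = 0.04389   k_p = 2.232 /d   (n = 7)

# 2. fit peptide turnover rates
fits <- fit_turnover(sim$series, sim$metadata, enr)
glance(fits)
#> # A tibble: 1 × 7
#>   n_series n_fitted n_converged k_median half_life_median r2_median se_median
#> 1       30       30          30    0.110             6.32     0.984   0.00827

# 3. filter and roll up to proteins
roll <- rollup_proteins(apply_stringency_filter(fits))
roll
#> # A tibble: 6 × 5
#>   uniprot k_median    k_mad n_peptides half_life
#> 1 SYN0001   0.0552 0.00148           5     12.6
#> 2 SYN0002   0.118  0.00237           5      5.89
#> 3 SYN0003   0.455  0.0135            5      1.52
#> 4 SYN0004   0.104  0.00553           5      6.67
#> 5 SYN0005   0.0281 0.000866          5     24.7
#> 6 SYN0006   0.307  0.00759           5      2.26

intra_protein_variability(roll)
#> [1] 2.83  # percent
```

The recovered enrichment curve (`p_ss ≈ 0.044`, `k_p ≈ 2.2 d⁻¹`) matches the
generator's truth (0.045, 2); each protein's `k_median` is the consensus of
its peptides (here within a few percent of the simulated rates, e.g.
SYN0005 is a slow protein with a 25-day half-life), and the intra-protein
variability of ~3% shows the member peptides of each protein report
consistent rates — the experiment-level quality diagnostic.

`autoplot(fits, sim$series)` draws observed decay points with fitted curves;
`plot_filter_sweep(filter_sweep(fits, seq(0, 1, 0.1), seq(0.01, 0.2, 0.01)))`
maps the quality/quantity trade-off of the stringency cutoffs.

A thin command-line front end (`exec/isoturn`) chains the same steps from a
shell: `simulate`, `bodywater`, `fit`, `filter`, `aggregate`, `quant`,
`sweep`, reading and writing the documented tab-delimited formats
(`hl.out`, `hl-data.out`, `intensity.txt`).

## Vignette

`vignettes/turnover-kinetics.Rmd` documents the model, its assumptions, the
defaults and why they were chosen, what the synthetic generator does and
does not emulate, numerical edge cases, and known limitations.
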