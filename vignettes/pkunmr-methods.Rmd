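---
title: "Methods: simulating and analysing urinary NMR profiles in PKU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing urinary NMR profiles in PKU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkunmr)
```

## The problem

Phenylketonuria (PKU) is an inborn error of phenylalanine hydroxylase.
Urinary ¹H-NMR profiles of treated patients carry two kinds of signal:
targeted, per-metabolite concentration shifts (phenylpyruvate, glycine,
allantoin, microbiome-derived acids, …) and an untargeted spectral
fingerprint that separates classical PKU (cPKU) from healthy controls and
places mild PKU (mPKU) between the two. `pkunmr` implements both analysis
arms plus a calibrated cohort simulator, so the whole pipeline is testable
without any patient data.

## The simulated world

The simulator's defaults are a *stated world*, fixed once:

* **Cohort**: 51 cases (36 cPKU, 12 mPKU, 3 undetermined) and 51 controls,
  ages uniform on 0.25–33 years.
* **Metabolites**: 98 analytes. 24 carry the published case/control
  arithmetic means and SDs (mmol/mol creatinine); 74 are null, their
  moments drawn once (a fixed packaged fixture) from the span of the
  calibrated control moments.
* **Marginals**: moment-matched lognormal per metabolite, independent
  across metabolites. Lognormal because urinary concentrations are
  positive and right-skewed — several calibrated rows have SD > mean,
  which a Gaussian cannot produce without negative mass. Independence is
  the simplest testable default; it is also a known distortion (see
  *Limitations*).
* **Clinical covariates**: serum Phe per stratum (cPKU 777 ± 467, mPKU
  421 ± 255 µmol/L, controls 55 ± 15), correlated 0.35 with age within
  case strata (the age-drift constant is not quantified in the source
  material; 0.35 makes the trend reliably detectable at n = 51 without
  dominating the stratum SD). Natural protein intake is lognormal per
  stratum with the cPKU mean (0.40 g/kg/day) below the mPKU mean (1.10).
  A synthetic `allantoin_response` is planted with standardized
  coefficients −0.5 (age), +0.4 (protein), 0 (serum Phe) and unit
  variance, so standardized-regression recovery has a known truth.
* **Spectra**: sums of Lorentzian lines (half-width 0.002 ppm) on a
  2¹⁵-point grid over 0.5–9.5 ppm; each metabolite's line areas are
  concentration × relative area, using a bundled, editable shift library
  (invented from public shift knowledge — no result depends on specific
  shifts). A creatinine CH₃/CH₂ pair (reference area 1000, i.e. creatinine
  relative to itself in mmol/mol) is always present, plus Gaussian noise
  (SD 2, roughly 10⁻⁴ of the creatinine peak height — urine NMR is
  high-SNR) and a smooth raised-cosine artifact confined to 4.55–5.25 ppm
  standing in for residual water.

## Spectral binning

Binning follows the standard urinary bucketing scheme: creatinine scaling
(division by the trapezoidal integral over 3.00–3.12 ppm), then fixed
0.0088-ppm bins tiling 0.6–9.4 ppm — exactly 1000 bins — with any bin
whose open interval intersects the open water window (4.5, 6.0) dropped,
leaving 829. Numerical choices:

* Bins are half-open `[left, left + width)`; a bin touching the water
  window at all is removed (conservative exclusion).
* "Bin intensity" is the trapezoidal *integral* (not mean) of the
  piecewise-linear trace, with partial end-intervals evaluated in closed
  form so the 1000 bins sum to the region integral to machine precision.
* Descending (conventional NMR) ppm axes are normalized to ascending on
  input; spectra on differing grids are interpolated onto the first
  spectrum's grid with a message.
* Creatinine scaling by spectral integral is the default; concentration
  tables are already creatinine-relative and need no further scaling.

## Untargeted classification

`pcaca_fit()`/`mccv()` implement PCA → canonical analysis → k-NN:

1. **PCA** (column-mean centering, SVD) retains the minimal number of
   components reaching 99% cumulative explained variance.
2. **Canonical analysis** solves the between- versus within-class scatter
   generalized eigenproblem via Cholesky whitening; the within-class
   scatter is ridge-regularized by `1e-8 · trace/dim` only when singular.
   The number of significant canonical dimensions is decided by Wilks'
   lambda with Bartlett's χ² approximation (minimum 1); with two classes
   there is at most one axis, and the second *display* axis is the leading
   within-class residual direction (display only, never used to classify).
3. **k-NN** votes among the k = 3 nearest training samples by Euclidean
   distance in the canonical subspace; a vote tie falls to the class of
   the single nearest neighbour among the tied classes. k, the metric and
   the tie rule are this package's defaults — the published workflow does
   not state them.
4. **Monte-Carlo embedded cross-validation**: 16 seeded shuffles ×
   stratified 8-fold partitions; for every fold the *entire* model (PCA
   centering and basis, canonical axes, k-NN training set) is refitted on
   the training folds only, and all held-out predictions are pooled into
   one confusion matrix (per-run averaging is available as an option;
   whether the published accuracy pooled predictions or averaged runs is
   not stated). Stratification is by class — plain 8-fold on 36-vs-51
   could produce single-class folds.

Leakage is guarded by construction and by test: permuted labels score at
chance, and perturbing held-out samples provably leaves the fitted model
bit-identical.

## Targeted screen

* **Sufficiency filter**: a metabolite enters the statistics only with
  strictly more than 10 quantified values *in total across both groups*.
  (A per-group reading is untenable: the published table itself contains a
  group with n = 8.)
* **Mann–Whitney U**: midranks; exact two-sided p by permutation
  enumeration when both n ≤ 8; otherwise the normal approximation with
  tie-corrected variance and continuity correction. Two identical
  constant samples give p = 1 by convention.
* **Fold change** is the ratio of case to control arithmetic means of the
  creatinine-relative concentrations; significant rows (p < 0.05, no
  multiplicity correction by default, Benjamini–Hochberg behind a flag)
  are ranked by decreasing fold change.
* **Standardized regression**: OLS on z-scored response and predictors;
  betas are standardized coefficients with t-test p-values; collinear
  designs abort naming the offending columns.

## Phenotype stratification

GPV 0–2.7 → cPKU (2.7 inclusive — the published band "2.8–7" leaves
(2.7, 2.8) unassigned; everything ≤ 2.7 is classical here), GPV (2.7, 7]
→ mPKU; GPV missing with serum Phe > 1200 µmol/L → cPKU; otherwise
undetermined (a candidate for metabolome projection). The packaged
51-patient reference cohort preserves its printed labels verbatim,
including one record whose label contradicts its GPV;
`check_phenotype_consistency()` flags such rows and never overwrites them.

## What a green test establishes — and what it does not

The generator reproduces group *moments*, missingness, covariate structure
and peak-area-proportional spectra. It does **not** reproduce:

* between-metabolite correlation (independence is enforced; real cohorts
  share age-, diet- and compliance-driven correlation across analytes),
* the true marginal shapes (only two moments are published),
* instrument artifacts beyond a noise floor and one water bump.

Two documented consequences, verified against independent oracles and left
as failing (red) acceptance assertions rather than weakened:

1. **MCCV accuracy plateaus near 65–70%**, not the ≥ 85% the acceptance
   criterion anticipated (or the 96.7% published on real spectra). An
   independent PCA+LDA+kNN implementation on the identical bucket matrix
   scores the same, so this is the separability ceiling of the stated
   world itself: independent heavy-tailed lognormals calibrated only to
   printed means/SDs are far less linearly separable on the raw intensity
   scale than real, correlated cPKU spectra. (Log-scale classification of
   the concentrations reaches ~90–98% — the information is planted, but
   the raw-scale linear pipeline cannot reach it.)
2. **Sample SDs at n = 20000 fluctuate beyond 5%** for the heaviest-tailed
   calibrated rows (log-σ up to ≈ 1.4; the SD estimator's error grows with
   kurtosis), so the 2%/5% moment-recovery tolerance cannot be met
   uniformly under the prescribed family. Means recover to well within
   sampling error (≈ 4 SE), and all rows with log-σ ≤ 0.8 pass both
   tolerances.

## Tunable parameters that matter

| parameter | default | unit | note |
|---|---|---|---|
| `bin_width` | 0.0088 | ppm | 1000 bins over 0.6–9.4 |
| water exclusion | 4.5–6.0 | ppm | open interval, intersecting bins dropped |
| `explained_variance_threshold` | 0.99 | fraction | PCA retention |
| `mc_runs` × `cv_folds` | 16 × 8 | — | MCCV protocol |
| `k_neighbors` | 3 | — | odd, package default |
| `min_values` | 10 | count | strict `>`, total across groups |
| `alpha` | 0.05 | fraction | screen and MANOVA dimension test |
| GPV cut-offs | 2.7 / 7 | — | inclusive upper bounds |
| Phe fallback | 1200 | µmol/L | GPV-missing rule |
| `noise_sd` | 2 | intensity | spectral noise floor |

## Reproducibility

Every stochastic stage derives child seeds from one master seed; a fixed
seed yields bit-identical tables, metadata, spectra and confusion
matrices. Run reports serialize to JSON losslessly and embed the seed.
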