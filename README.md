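# pkunmr

Urinary ¹H-NMR metabolomics of phenylketonuria (PKU): a tested, end-to-end
R pipeline for case/control cohorts, aimed at metabolomics analysts and
method developers who need the full chain — cohort simulation, spectral
binning, untargeted classification, targeted statistics and phenotype
stratification — reproducible from a single seed.

## What it computes

* **Targeted screen** — per metabolite (concentrations in mmol/mol
  creatinine): a limit-of-detection sufficiency filter (strictly more than
  10 quantified values across both groups), the two-sided Mann–Whitney
  U test (exact by enumeration when both n ≤ 8; tie-corrected,
  continuity-corrected normal approximation otherwise), the case/control
  fold change FC = x̄_case / x̄_control, and ranking of significant
  metabolites (p < 0.05) by decreasing FC.
* **Untargeted classification** — creatinine-scaled spectra are cut into
  fixed 0.0088-ppm bins over 0.6–9.4 ppm (1000 bins; the 171 touching the
  4.5–6.0 ppm water window are dropped, leaving 829), then PCA (99%
  explained variance) → canonical analysis (between- vs within-class
  scatter, Wilks' Λ/Bartlett χ² dimension test) → k-NN (k = 3), validated
  by Monte-Carlo embedded cross-validation (16 runs × stratified 8-fold,
  models refit on training folds only) into a pooled confusion matrix;
  new samples are projected into the trained PCA–CA subspace and
  classified.
* **Phenotype stratification** — genotype/phenotype value (GPV) 0–2.7 →
  cPKU, (2.7, 7] → mPKU, GPV missing with serum Phe > 1200 µmol/L → cPKU,
  else undetermined; plus per-phenotype summaries over a packaged
  51-patient reference cohort.
* **Calibrated simulator** — 51 + 51 samples; 98 metabolites (24 with the
  published group moments, 74 null) as independent moment-matched
  lognormals with below-LOD missingness; clinical metadata with a
  positive Phe–age trend and a planted regression truth; Lorentzian-peak
  spectra whose areas are proportional to concentration.

## Worked example

```r
library(pkunmr)
sim <- simulate_cohort(cohort_config(seed = 1))
res <- compare_groups(sim$table)
head(res[, c("metabolite", "n_control", "mean_control", "n_case",
             "mean_case", "p_value", "fold_change")], 6)
#>           metabolite n_control mean_control n_case mean_case  p_value fold_change
#> 1    D-Mandelic acid        51         2.13     51      9.18 3.30e-13        4.31
#> 2 Phenylpyruvic acid        51        15.16     51     64.96 1.82e-06        4.28
#> 3            Glycine        51       101.46     51    404.86 1.15e-07        3.99
#> 4    2-Furoylglycine        51        13.57     51     50.56 4.13e-06        3.73
#> 5          Neopterin        51         2.46     51      5.85 7.64e-05        2.38
#> 6  Phenylacetic acid        51         5.83     51     13.32 8.78e-05        2.28
```

Each row compares the quantified values of one metabolite between groups:
at seed 1 the screen returns 23 significant metabolites (17 of the 24
planted signals — the weakest planted fold changes, ≈1.4, are
underpowered at n = 51 under heavy-tailed marginals — plus 6 of the 74
nulls at α = 0.05), with the phenylalanine-pathway analytes at the top of
the fold-change ranking.

```r
group_summary(reference_cohort(), "phe_serum")
#>   phenotype  n mean  sd
#> 1      cPKU 37  777 467
#> 2      mPKU 14  421 255
```

Serum phenylalanine (µmol/L) by phenotype over the packaged reference
cohort — classical PKU patients run substantially higher than mild PKU.

The untargeted arm, end to end:

```r
sim <- simulate_cohort(cohort_config(seed = 1), spectra = TRUE)
bt  <- assemble_bucket_table(sim$spectra, sample_ids = sim$table$sample_id)
keep <- sim$metadata$phenotype %in% c("cPKU", "control")
lab  <- factor(sim$metadata$phenotype[keep])
mccv(bt$matrix[keep, ], lab, classifier_config(seed = 1))
#> <confusion_matrix> accuracy 64.7%
```

~65% is the separability ceiling of the simulated world (independent
lognormals calibrated to printed means/SDs), verified against an
independent PCA+LDA+kNN oracle — not a ceiling of the implementation;
see the methods vignette.

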