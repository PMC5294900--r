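# firthde

Case–control differential-expression testing for RNA-Seq counts, comparing
two modelling directions for a single gene:

- **Model A (counts as outcome)** — negative binomial regression

  log E[Y] = β₀ + β₁ D + Σₖ βₖ₊₁ Xₖ,  Var[Y] = μ + φμ²

- **Model B (status as outcome)** — logistic regression

  logit E[D] = β₀\* + β₁\* Y + Σₖ βₖ₊₁\* Xₖ

where *Y* is the read count, *D* the case/control status, *Xₖ* covariates
and φ the gene's NB dispersion. Model B is fitted three ways: classical
maximum likelihood (**CL**), posterior mode under Gelman's weakly
informative Cauchy(0, 2.5) priors (**BL**), and Firth's penalized
likelihood ℓ(β) + ½ log det I(β) (**FL**), which removes first-order bias
and keeps estimates finite under the complete separation that strong
differential expression produces. The logistic direction needs no
dispersion estimate, which makes it attractive for small studies where a
misestimated φ inflates false positives.

Around the fitters the package provides everything needed to study and use
them honestly: median-of-ratios (DESeq-style) size-factor normalization, a
single-gene simulation engine with disease-associated binary covariates,
empirical Type-I-error / power evaluation with calibration-fair empirical
thresholds, stratified permutation of count matrices, exact permutation
p-values (b+1)/(B+1), a data-adaptive (DA) recalibration of test statistics
against a permutation-estimated null, genomic inflation factors λ_gc, and
Benjamini–Hochberg FDR control.

In simulation, small samples or large dispersion make NB regression liberal
(Type-I error ≈ 0.09 at nominal 0.05 for 10 + 10 samples, φ = 1) while CL
and BL are strongly conservative; FL stays close to nominal, and the DA
recalibration restores the size of all methods. That makes FL, optionally
with DA, the recommended workflow for small case–control count studies.

## Worked example

Simulate one gene under a strong effect (10 cases, 10 controls,
μ_control = 1000, φ = 0.5, log2 fold-change 1.2) and fit all four methods:

```r
library(firthde)

d <- simulate_dataset(scenario(n_cases = 10, dispersion = 0.5,
                               log2fc = 1.2, seed = 42))
fit_gene(d, dispersion = 0.5)
#> # A tibble: 4 × 9
#>   method     coef       se  stat stat_type pvalue converged n_iter dispersion_used
#>   <chr>     <dbl>    <dbl> <dbl> <chr>      <dbl> <lgl>      <int>           <dbl>
#> 1 NB     0.767    0.454     1.69 z         0.0911 TRUE           5             0.5
#> 2 CL     0.000658 0.000522  1.26 z         0.208  TRUE           5            NA
#> 3 BL     0.000368 0.000303  1.21 z         0.225  TRUE          13            NA
#> 4 FL     0.000293 0.000326  1.53 chisq     0.216  TRUE           8            NA
```

The NB coefficient is the log fold-change (truth ln 2^1.2 = 0.83); the
logistic coefficients are per-count log-odds, hence their much smaller
scale. At this sample size no method reaches 0.05 — a realistic outcome for
n = 10 + 10.

Measuring the size of each test under the null (log2fc = 0, φ = 1, 2000
replicates) shows the characteristic pattern — NB liberal, CL/BL
conservative, FL near nominal:

```r
ev <- run_scenario(scenario(n_cases = 10, dispersion = 1, n_reps = 2000,
                            seed = 1))
scenario_type1(ev, 0.05)
#> # A tibble: 4 × 9
#>   method dispersion_mode metric      alpha   rate ci_low ci_high n_converged n_total
#> 1 BL     <NA>            type1_error  0.05 0.015  0.0105  0.0213        2000    2000
#> 2 CL     <NA>            type1_error  0.05 0.015  0.0105  0.0213        2000    2000
#> 3 FL     <NA>            type1_error  0.05 0.0395 0.0318  0.0490        2000    2000
#> 4 NB     TRUE            type1_error  0.05 0.0795 0.0684  0.0922        2000    2000
```

For a real count matrix, `analyze()` joins a gene × sample counts table to a
phenotype table by sample id, normalizes, fits the requested methods per
gene, optionally recalibrates p-values against stratified permutations, and
applies BH-FDR; `report()` writes the results, a JSON run summary with
λ_gc, and QQ-plot data. A thin command-line front-end with `simulate`,
`analyze`, `evaluate` and `calibrate` subcommands ships in
`inst/cli/firthde`.

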