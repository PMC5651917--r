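# cvherit

Cross-validated heritability and predictability for genomic selection.

## The problem

Marker-based heritability is usually estimated by fitting a GBLUP mixed model
to the full data set and reporting the share of phenotypic variance captured by
the polygenic term. With dense marker panels, most markers are irrelevant to
any given trait, yet the whole-data fit absorbs noise through them and the
heritability estimate is inflated — the model is partly memorising the
phenotypes it was trained on. `cvherit` estimates heritability from k-fold
cross-validated predictions instead: genetic values for each line are predicted
by a model that never saw that line's phenotype, so the resulting estimate
(**Hcv**) measures signal the markers can actually generalise. Its companion,
the **predictability Pcv** (squared correlation between observed phenotypes and
cross-validated genetic values), tracks Hcv closely; the gap between the
whole-data estimate **H** and Hcv quantifies the overfitting.

## Model

For n inbred lines, `y = Xβ + ξ + ε` with `ξ ~ N(0, K·σ²_A)` and
`ε ~ N(0, I·σ²)`, where `K = n·K′/tr(K′)` and `K′ = ZZᵀ/m` from genotype codes
`Z ∈ {−1, +1}` at m loci. Variance components come from REML via an
eigendecomposition profile likelihood; BLUE/BLUP solve Henderson's equations;
held-out lines are predicted by the conditional expectation
`K₂₁σ²_A (K₁₁σ²_A + Iσ²)⁻¹` applied to training residuals. Then

- `H = σ²_A / (σ²_A + σ²)` (whole data),
- `Hcv = Var(ξ̂_cv) / (Var(ξ̂_cv) + Var(y_c − ξ̂_cv))`,
- `Pcv = cor(y_c, ξ̂_cv)²`,

with `ξ̂_cv` the out-of-sample predictions and `y_c` the phenotype after
removing the fold-specific fixed-effect fit. A classical replicated-trial
ANOVA baseline (`anova_heritability()`) and a recombinant-inbred-line (RIL)
panel simulator are included. See `vignette("cv-heritability-methods")` for
derivations, numerical choices, and limitations.

## Worked example

Simulate a replicated RIL trial (210 lines, 1619 loci on 12 chromosomes,
per-locus effect sd 1/20, unit error sd, 4 replicates), average the
replicates, and compare the whole-data heritability with its cross-validated
counterpart:

```r
library(cvherit)

map  <- genetic_map()                      # 1619 loci, 12 chromosomes
geno <- simulate_ril_genotypes(map, n = 210, seed = 11)
K    <- kinship(geno)
sim  <- simulate_phenotypes(geno, sigma_g = 1/20, sigma_e = 1,
                            replicates = 4, seed = 11)
pheno <- average_replicates(sim)$phenotypes

fit <- gblup(pheno, K = K)
fit
#> <gblup_fit> n = 210 individuals
#> <gblup_varcomp> REML fit, n = 210
#>   sigma_A2 = 3.68957  sigma2 = 0.237336  lambda = 15.5458
#>   h2 = 0.9396  loglik = -165.801  converged = TRUE

cv <- cv_gblup(pheno, K = K, k = 5, repeats = 5, seed = 11)
cv
#> <gblup_cv> 5-fold, 5 repeat(s), varcomp mode 'per_fold'
#> # A tibble: 3 × 3
#>   measure  mean     sd
#>   <chr>   <dbl>  <dbl>
#> 1 Hcv     0.644 0.0179
#> 2 Hcv_alt 0.641 0.0270
#> 3 Pcv     0.646 0.0176
```

The whole-data fit reports `h2 = 0.94`, while the cross-validated estimate is
`Hcv = 0.64` — the difference is the overfitting that cross-validation removes
— and `Pcv = 0.65` confirms that Hcv tracks out-of-sample predictability.
Per-repeat values come from `tidy(cv)`, one-row summaries from `glance()`, and
`autoplot(cv)` draws the spread. The single-plot ANOVA baseline on the
unaveraged replicates sits in between, as it neither averages errors away nor
overfits:

```r
anova_heritability(sim$phenotypes)
#> # A tibble: 1 × 8
#>   ms_line ms_replicate ms_error var_line var_error  Haov n_lines n_replicates
#>     <dbl>        <dbl>    <dbl>    <dbl>     <dbl> <dbl>   <int>        <int>
#> 1    14.1         1.08    0.956     3.28     0.956 0.774     210            4
```

`scan_loci()` re-runs the contrast on growing top-correlated marker subsets
(H keeps climbing as neutral markers are added; Hcv plateaus), and
`experiment_signal_grid()` / `experiment_replicate_grid()` drive the full
simulation experiments. A command-line interface over the same functions is
installed at `system.file("cli", "cvherit.R", package = "cvherit")`.

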