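# permlmm

Linear-mixed-model GWAS with **population-aware Westfall–Young permutation
thresholds**, efficient batch-wise evaluation, a structured-genotype and
phenotype simulator, and a phenotype-wise FDR evaluation protocol.

## Why

Genome-wide association studies test hundreds of thousands of markers, and the
conventional Bonferroni correction ignores both the dependence between markers
and the distribution of the phenotype — it is exact only in an independent,
Gaussian world and conservative (or simply miscalibrated) everywhere else.
The Westfall–Young *maxT* procedure instead estimates the family-wise null
distribution empirically: for each of `q` permutations, re-run the scan and
record the minimal p-value over all markers; the significance threshold is the
`α·100`-th percentile of those minima. This adapts automatically to marker
dependence and to skewed phenotypes.

Permuting the phenotype naively, however, destroys the relatedness structure
that the linear mixed model's kinship matrix encodes. `permlmm`'s default
strategy is **population-aware**: it permutes the rows of the fixed-effects
matrix with the inverse permutation, which is algebraically equivalent to
permuting the phenotype *together with* the rows and columns of the covariance
matrix — the phenotype–kinship relationship stays intact while the
marker–phenotype link is broken.

Permutations multiply the work by `q`, so the implementation leans on two
structural facts:

- after rotating by the kinship eigenvectors the covariance is diagonal, and
  the variance ratio `δ = σe²/σg²` is estimated by a grid-plus-Brent search on
  the profiled likelihood (estimated once on the null model and reused across
  markers);
- the normal equations of `[Z, sᵢ]` decompose into marker-independent blocks
  (computed once per permutation) and three cheap marker-dependent products,
  evaluated batch-wise; a dedicated multi-phenotype scan additionally shares
  each permutation's rotated marker matrix across hundreds of phenotypes.

## What's in the box

| area | functions |
| --- | --- |
| genotype/phenotype IO | `read_genotypes()` (delimited, VCF, PLINK .bed), `read_phenotypes()`, `read_covariates()`, `align_samples()`, `maf_filter()`, `impute_genotypes()`, `write_results()` |
| kinship | `compute_grm()` (centered VanRaden, mean diagonal 1), `spectral_decompose()`, `load_kinship()` / `write_kinship()` |
| mixed-model core | `estimate_variance_components()`, `gls_effects()`, `f_test()`, `lmm_scan()` |
| permutations | `permutation_plan()` (`"x"` population-aware / `"y"` conventional), `permuted_association_stats()`, `battery_scan()` |
| significance | `permutation_threshold()`, `adjusted_pvalues()`, `required_permutations()`, `bonferroni_threshold()`, `benjamini_hochberg()` |
| simulation | `simulate_genotypes()` (Balding–Nichols), `simulate_phenotype()` (HER/EV split, Gaussian or Gamma noise), `simulation_battery()` |
| evaluation | `classify_phenotype()`, `pfdr()`, `evaluate_battery()` |
| pipeline | `run_gwas()`, `gwas_design()`, `tidy()`, `glance()`, `autoplot()`, `plot_qq()`, CLI script `inst/cli/permlmm.R` |

## Worked example

Simulate a structured panel (two subpopulations, Fst 0.3), plant one causal
marker explaining 20% of the phenotypic variance on a 30%-heritability
background, and scan with 100 population-aware permutations:

```r
library(permlmm)

g   <- simulate_genotypes(100, 500, n_subpops = 2, fst = 0.3, seed = 1)
kin <- compute_grm(g)
causal <- which(minor_allele_frequency(g) > 0.2)[1]
ph  <- simulate_phenotype(g, kin, heritability = 0.3, explained_variance = 0.2,
                          causal_index = causal, seed = 2)
fit <- run_gwas(g, ph, q = 100, seed = 3)
fit
```

```
420 of 500 markers pass MAF > 0.05
<permlmm_gwas> trait 'simulated': 100 samples, 420 markers
<variance_components> delta = 0.5828, sigma_g2 = 0.7722, sigma_e2 = 0.45 (pseudo-h2 = 0.632)
  Bonferroni threshold: 0.000119
  x-permutation threshold (q = 100, alpha = 0.05): 0.00017
  markers below permutation threshold: 1
```

```r
glance(fit)
```

```
# A tibble: 1 × 12
      n     m delta sigma_g2 sigma_e2 pseudo_h2     q alpha method
  <int> <int> <dbl>    <dbl>    <dbl>     <dbl> <dbl> <dbl> <chr>
1   100   420 0.583    0.772    0.450     0.632   100  0.05 x
# ℹ 3 more variables: perm_threshold <dbl>, bonferroni <dbl>,
#   bh_threshold <dbl>
```

The top hit is the planted marker:

```r
head(dplyr::arrange(tidy(fit), p_value), 3)[, c("marker_id", "beta", "p_value", "adjusted_p", "significant")]
g$marker_ids[causal]
```

```
# A tibble: 3 × 5
  marker_id       beta     p_value adjusted_p significant
  <chr>          <dbl>       <dbl>      <dbl> <lgl>
1 chr1:225995    0.770 0.000000407       0    TRUE
2 chr1:23716979 -0.444 0.00357           0.71 FALSE
3 chr5:20048822  0.432 0.00909           0.93 FALSE
[1] "chr1:225995"
```

`autoplot(fit)` draws the Manhattan plot with both thresholds; `plot_qq(fit)`
the p-value QQ plot.

### Command line

The same pipeline is scriptable via `inst/cli/permlmm.R`:

```sh
permlmm=$(Rscript -e 'cat(system.file("cli", "permlmm.R", package = "permlmm"))')
Rscript $permlmm simulate --samples 200 --markers 5000 --phenotypes 2 \
        --heritability 0.3 --ev 0.2 --seed 5 --out sim/
Rscript $permlmm gwas --genotype sim/genotypes.csv --phenotype sim/phenotypes.csv \
        --trait gaussian_h0.3_r001 --perm 500 --out res/
Rscript $permlmm evaluate --manifest sim/manifest.csv --results res/ --out eval/
```

Flags can also live in a `key=value` config file (`--config`); explicit flags
win. Defaults: 500 permutations, 5% MAF filter, α = 0.05, x-permutations.

## How many permutations?

`required_permutations(alpha, gamma, theta)` converts a target precision
`theta` for adjusted p-values near `alpha` (at confidence `gamma`) into a
permutation count: pinning p ≈ 0.05 down to ±0.01 at 95% confidence needs
**1825** permutations; ±0.005 needs **7299**.

## Method notes

See the methods vignette (`vignettes/methods.Rmd`) for the model, the
profiled-likelihood search, the handling of the centered-GRM zero eigenvalue,
the permutation conventions (with a worked 3-row example), the block
decomposition, the simulator design and the package's limitations (no linkage
disequilibrium in simulated panels, single causal locus, full-ML variance
components with null-model reuse).
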