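---
title: "Methods: population-aware permutation thresholds for mixed-model GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-aware permutation thresholds for mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permlmm)
options(permlmm.quiet = TRUE)
```

## The model

`permlmm` tests each genetic marker with the linear mixed model

$$ y = X\beta + u + \varepsilon, \qquad
   u \sim N(0, \sigma_g^2 K), \quad \varepsilon \sim N(0, \sigma_e^2 I), $$

where $K$ is a kinship (genomic relationship) matrix, $X = [Z, s_i]$ stacks
an intercept, optional covariates and the candidate marker, and the marker is
assessed with a one-degree-of-freedom F-test of the null model ($Z$ only)
against the alternative.

Writing $\delta = \sigma_e^2/\sigma_g^2$ and eigendecomposing $K = U D U'$,
the rotation $\tilde y = U'y$, $\tilde X = U'X$ turns the covariance into the
diagonal matrix $\sigma_g^2(D + \delta I)$. Every generalized least squares
quantity then costs $O(n)$ per evaluation:

- GLS effects: $\hat\beta = (\tilde X' E^{-1} \tilde X)^{-1}\tilde X' E^{-1}\tilde y$
  with $E = D + \delta I$;
- residual sum of squares: $\sum_i (\tilde y_i - \tilde x_i'\hat\beta)^2 / e_i$;
- profiled negative log-likelihood (full maximum likelihood, with
  $\hat\sigma_g^2 = \mathrm{RSS}/n$):
  $\tfrac12\left(n\log(2\pi\hat\sigma_g^2) + \sum_i \log e_i + n\right)$.

### Estimating the variance ratio

`estimate_variance_components()` evaluates the profiled likelihood on 100
log-equidistant $\delta$ values in $[10^{-5}, 10^{5}]$, then runs Brent
minimization in $\log\delta$ (tolerance $10^{-8}$) inside every bracket
around an interior local minimum; the grid endpoints compete as candidates,
and an optimum at the global boundary is reported with a warning since it
means the heritability is effectively 0 or 1. Following the usual
EMMAX-style approximation, the association scan estimates $\delta$ once on
the null model and reuses it for every marker; `lmm_scan(refit_delta = TRUE)`
provides the exact (but much slower) per-marker refit, and the two rank
markers nearly identically.

### Degenerate coordinates of a centered kinship matrix

A column-centered genomic relationship matrix annihilates the constant
vector, so it has an exact zero eigenvalue whose eigenvector is
$\mathbf{1}/\sqrt n$. With an intercept among the fixed effects, that rotated
coordinate is fitted *exactly* for every $\delta$, while its log-determinant
term contributes $\log\delta$ — the full ML objective therefore diverges to
$-\infty$ as $\delta \to 0$ regardless of the data. `permlmm` uses the
conditional likelihood on the informative coordinates: zero-eigenvalue
coordinates that are exactly absorbable by the fixed effects (the rank of
their rotated fixed-effect rows equals their count) are removed before
optimization, together with fixed-effect columns whose norm on the remaining
coordinates is negligible relative to their full norm (the rotated intercept
concentrates entirely in the removed coordinate). Coordinates that are *not*
absorbable stay, because their residuals penalize small $\delta$ and keep the
likelihood well behaved. The F-tests are unaffected: they compare two fits
under the same $E$.

## Westfall–Young maxT permutation thresholds

For each of $q$ permutations the scan records the maximal F statistic over
all markers (equivalently the minimal p-value). The significance threshold is
the $\alpha\cdot100$-th percentile of the $q$ minimal p-values (linear
interpolation between order statistics at $h = (q-1)\alpha$, the convention
of `stats::quantile(type = 7)`), and the adjusted p-value of marker $i$ is
the fraction of permutation maxima at or above its observed statistic.
`required_permutations()` converts a desired estimation precision
$\theta$ at confidence $\gamma$ into a permutation count
$q = \lceil z^2 \alpha(1-\alpha)/\theta^2 \rceil$; pinning an adjusted
p-value near $\alpha = 0.05$ down to $\pm 0.01$ at 95% confidence takes
1825 permutations.

### Population-aware permutations

Naively shuffling the phenotype destroys the relatedness structure the
kinship matrix encodes: under strong structure the permuted null is too wide
and the thresholds become conservative at best, miscalibrated at worst.
`permlmm`'s default (`method = "x"`) instead permutes the **rows of the
fixed-effects matrix** with the *inverse* permutation, which is algebraically
equivalent to permuting the phenotype together with the rows and columns of
the covariance matrix — the phenotype–kinship relationship stays intact while
the marker–phenotype link is broken.

The row-permutation convention is: `permute_rows(X, tau)` returns the matrix
whose row $i$ is input row `tau[i]`. With three rows and
$\tau = (3, 1, 2)$:

```{r permute-example}
X <- matrix(c("x1", "x2", "x3"), 3, 1)
tau <- c(3, 1, 2)
cbind(forward = permute_rows(X, tau), inverse = permute_rows(X, tau, invert = TRUE))
```

A useful special case: under x-permutations with an intercept-only null
model, permuting a constant column is the identity, so the per-permutation
variance-ratio refit provably equals the unpermuted null fit and is reused.
With covariates (or under y-permutations) $\delta$ is refit per permutation.

## Batched evaluation and the block decomposition

For fixed effects $X_i = [Z, s_i]$ the normal matrix
$\tilde X_i' E^{-1} \tilde X_i$ has a block structure in which
$\tilde Z'E^{-1}\tilde Z$, $\tilde Z'E^{-1}\tilde y$ and
$\tilde y'E^{-1}\tilde y$ do not depend on the marker. They are computed once
per (permutation, $\delta$); per marker batch only
$\tilde Z'E^{-1}\tilde s_i$, $\tilde s_i'E^{-1}\tilde s_i$ and
$\tilde s_i'E^{-1}\tilde y$ are formed and each small system solved. Results
are independent of the batch size (within floating-point reproducibility of
the underlying BLAS: different batch shapes dispatch to different kernels,
so equality holds to $10^{-12}$ rather than bitwise). In the intercept-only
case the $2\times2$ solves are carried out in closed form, vectorized over
the batch.

`battery_scan()` adds one more sharing level for simulation studies that
test hundreds of phenotypes against the same markers and kinship: because a
single permutation plan is reused, each permutation's rotated, row-permuted
marker matrix $U'P_k^{-1}S$ — the dominant cost — is computed once and reused
for every phenotype.

## The phenotype simulator

`simulate_genotypes()` draws structured diploid dosages under the
Balding–Nichols model: per marker an ancestral frequency
$p_0 \sim U(0.05, 0.95)$, per subpopulation a frequency
$\mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$ with divergence $F$ (Fst), and
dosages $\mathrm{Binomial}(2, p_{\text{subpop}})$. Markers get uniform
positions within chromosomes. The model produces drift-style structure but
no linkage disequilibrium — neighbouring markers are independent given the
subpopulation, which is a deliberate simplification.

`simulate_phenotype()` builds $y = \beta_s s + u + \varepsilon$ on the unit
variance scale: the causal marker explains `explained_variance` (EV) of the
total, the polygenic background $u$ (Gaussian with covariance $\propto K$,
drawn via $U\sqrt{D}z$) contributes `heritability` (HER), and the noise —
Gaussian or mean-centered Gamma with shape $k$ (skewness $2/\sqrt k$) — the
remainder. Heritability here is the *background* share, separate from the
causal marker's EV. Components are centered, sequentially orthogonalized and
rescaled so their realized sample variances equal the targets exactly; the
decomposition sums to 1 per replicate rather than only in expectation.

`simulation_battery()` crosses noise families
$\{N, \Gamma_4, \Gamma_3, \Gamma_2, \Gamma_1, \Gamma_{0.5}\}$ with
heritabilities $\{0.1, 0.3, 0.5\}$ at EV $= 0.2$ by default, drawing causal
markers uniformly among markers with MAF $> 0.05$ and recording a
per-phenotype seed in a manifest so any phenotype can be regenerated alone.

## Evaluation protocol

A scanned phenotype is a **true positive** if any significant marker lies
within a window (two-sided, boundary-inclusive; default 10 kbp) of the
causal SNP on its chromosome, and a **false positive** if any significant
marker lies outside that window; a phenotype can be both. The phenotype-wise
false discovery rate is $\mathrm{pFDR} = FP/(TP+FP)$ over phenotypes,
reported as missing when there are no positives at all.
`evaluate_battery()` tabulates TP, FP and pFDR per (setting, method) along
with the spread of the per-phenotype permutation thresholds — the quantity
that distinguishes adaptive thresholds from the fixed Bonferroni $\alpha/m$.

## A small worked example

```{r worked-example}
g <- simulate_genotypes(100, 500, n_subpops = 2, fst = 0.3, seed = 1)
kin <- compute_grm(g)
causal <- which(minor_allele_frequency(g) > 0.2)[1]
ph <- simulate_phenotype(g, kin, heritability = 0.3, explained_variance = 0.2,
                         causal_index = causal, seed = 2)
fit <- run_gwas(g, ph, q = 100, seed = 3)
fit
glance(fit)
head(dplyr::arrange(tidy(fit), p_value), 3)
g$marker_ids[causal]
```

## Choices, defaults and limitations

- Defaults follow the method's standard operating point: 500 permutations,
  5% MAF filter, $\alpha = 0.05$, x-permutations.
- The problem sizes used in the package's own validation suite (e.g.
  $n = 200$, $m = 5000$, 200 null phenotypes) are chosen to make the
  statistical properties testable on a single CPU in minutes; they are much
  smaller than real GWAS panels.
- Full ML (not REML) is used for the profiled likelihood, matching the
  EMMAX-style null-reuse approximation.
- The simulator generates no linkage disequilibrium, one causal locus at
  most, and no epistasis.
- Missing dosages are mean-imputed per marker; markers with more than 10%
  missingness are dropped.
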