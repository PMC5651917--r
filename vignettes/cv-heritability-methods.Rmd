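---
title: "Methods: cross-validated heritability for genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated heritability for genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Marker-based ("genomic") heritability is usually estimated by fitting a mixed
model to the full data set and reporting the ratio of the polygenic variance
component to total variance. When the marker panel contains many loci that are
irrelevant to the trait, that whole-data estimate absorbs noise into the
polygenic term and is inflated: the model partly "memorises" the phenotypes it
was trained on. This package estimates heritability from cross-validated
predictions instead, so that the genetic variance is measured only on lines the
model has never seen.

## Model

For $n$ inbred lines with phenotype vector $y$, fixed-effect design $X$
(default: an intercept), and polygenic values $\xi$:

$$y = X\beta + \xi + \varepsilon, \qquad
  \xi \sim N(0, K\sigma_A^2), \qquad
  \varepsilon \sim N(0, I\sigma^2).$$

$K$ is the marker-inferred kinship matrix. With genotype codes
$Z \in \{-1, +1\}^{n \times m}$ (fully homozygous lines),

$$K' = \tfrac{1}{m} Z Z^\top, \qquad K = \frac{n}{\mathrm{tr}(K')} K',$$

i.e. the cross-product kinship rescaled to trace $n$ so that variance
components are on the per-observation scale. Columns are not centred or
column-scaled: for balanced $\pm 1$ codes the diagonal of $K'$ is exactly 1,
so the rescale is the identity up to sampling of the codes, and the polygenic
variance equals $m\sigma_g^2$ when per-locus effects are drawn with standard
deviation $\sigma_g$.

Heritability on the whole data is $h^2 = \sigma_A^2 / (\sigma_A^2 + \sigma^2)$
(`heritability()`, `naive_heritability()`, `gblup()`).

### REML

`reml_fit()` maximises the restricted log-likelihood

$$L = -\tfrac12 \log |V| - \tfrac12 \log |X^\top V^{-1} X|
      - \tfrac12 (y - X\hat\beta)^\top V^{-1} (y - X\hat\beta),
  \qquad V = K\sigma_A^2 + I\sigma^2,$$

with $\hat\beta$ the GLS estimate (`method = "ML"` drops the middle term).
Numerically, $K = U D U^\top$ is eigendecomposed once, the model is rotated by
$U^\top$ so $V$ becomes diagonal in $\lambda = \sigma_A^2/\sigma^2$, $\sigma^2$
is profiled out analytically ($S/(n-q)$ for REML, $S/n$ for ML), and the
resulting one-dimensional profile is maximised by `stats::optimize()` over
$\log \lambda \in [\log 10^{-6}, \log 10^{6}]$ with tolerance $10^{-9}$. Both
components are floored at $10^{-5}$ to keep downstream solves well posed; a
boundary estimate is reported as-is (a pure-noise trait legitimately pins
$\sigma_A^2$ at the floor). If the profile is flat to $10^{-7}$ across a decade
around the optimum — which happens when $K \approx I$ and the two components
are unidentifiable — the fit carries a `flat_loglik` flag and a warning.

### BLUP and holdout prediction

`henderson_solve()` solves the mixed-model equations

$$\begin{pmatrix} X^\top X & X^\top \\ X & I + K^{-1}/\lambda \end{pmatrix}
  \begin{pmatrix} \beta \\ \xi \end{pmatrix}
  = \begin{pmatrix} X^\top y \\ y \end{pmatrix}$$

and, as an independent route (`route = "vinverse"`), the equivalent
conditional-expectation form
$\hat\xi = \sigma_A^2 K V^{-1}(y - X\hat\beta)$. The two agree to floating
point; the test suite asserts $10^{-8}$ relative agreement. When $K$ is
singular, the Henderson route adds a ridge of $10^{-8}\,\mathrm{tr}(K)/n$
before inverting and warns if the system is still ill-conditioned.

For a holdout set (block 2) with training set (block 1), `predict_holdout()`
uses

$$\hat y_2 = X_2\hat\beta +
  K_{21}\hat\sigma_A^2 (K_{11}\hat\sigma_A^2 + I\hat\sigma^2)^{-1}
  (y_1 - X_1\hat\beta),$$

with $\hat\beta$ estimated by GLS on the training block. Rows with
$K_{21} = 0$ predict exactly $X_2\hat\beta$.

### Cross-validated heritability

`cv_gblup()` splits the $n$ lines into $k$ folds (default $k = 5$; contiguous
blocks of a seeded permutation, sizes differing by at most one), predicts each
fold from the remaining folds, and assembles the out-of-sample polygenic
predictions $\hat\xi_{cv}$. Then

$$H_{cv} = \frac{\mathrm{Var}(\hat\xi_{cv})}
                {\mathrm{Var}(\hat\xi_{cv}) +
                 \mathrm{Var}(y_c - \hat\xi_{cv})}, \qquad
  P_{cv} = \mathrm{cor}(y_c, \hat\xi_{cv})^2,$$

where $y_c$ is the phenotype minus the fold-specific fixed-effect fit.
$H_{cv} \approx P_{cv}$ is the method's central property; both are reported,
along with the alternative normalisation
$\mathrm{Var}(\hat\xi_{cv})/\mathrm{Var}(y)$.

**Per-fold vs global variance components.** By default
(`varcomp_mode = "per_fold"`), REML is re-estimated on each training set, so no
information from the holdout fold leaks into its own prediction; the test
suite verifies bitwise invariance of a line's prediction to perturbations of
its own phenotype. `varcomp_mode = "global"` estimates components once on all
data, which is cheaper and common in practice but mildly optimistic. The
kinship matrix is computed once from genotypes alone and sliced per fold; this
involves no phenotype information and is not leakage.

## The simulator

`genetic_map()` lays out $m$ loci (default 1619) evenly along 12 chromosomes of
150 cM. `simulate_ril_genotypes()` draws recombinant inbred lines (RILs) at
fixation as a Markov chain along each chromosome: the first locus is $\pm 1$
with probability $\tfrac12$, and each subsequent locus flips with the RIL
discordance probability $R = 2r/(1+2r)$, where $r$ is the Haldane
recombination fraction $r = \tfrac12(1 - e^{-2d/100})$ for map distance $d$ cM.

What this emulates: fully homozygous biparental RIL panels with the correct
*adjacent-pair* discordance (verified against a generation-explicit selfing
simulation in the test suite) and LD that decays with map distance.

What it does not: the Markov construction makes non-adjacent discordance the
chain composition of adjacent ones, whereas exact RIL theory gives
$R_{13} = 2r_{13}/(1+2r_{13})$ for the composed recombination fraction; the
difference is about 0.01 at 10 + 10 cM. It also has no segregation distortion,
residual heterozygosity, marker ascertainment, or the empirical LD structure
of any real panel. Consequently parameter settings quoted for real data do not
transfer one-for-one: with near-unit-variance synthetic marker columns the
expected polygenic variance is $m\sigma_g^2$, so a per-locus effect sd of
$\sigma_g = \sqrt{h/((1-h)\,m)}$ targets single-plot signal fraction $h$.

`simulate_phenotypes()` draws per-locus effects
$\gamma \sim N(0, \sigma_g^2)$ (optionally restricted to a causal subset),
sets $\xi = Z\gamma$, and adds iid $N(0, \sigma_e^2)$ errors per replicate.
Defaults ($n = 210$, $m = 1619$, $\sigma_g = 1/20$, $\sigma_e = 1$,
12 chromosomes) describe a replicated rice RIL trial of the size this method
was designed around; they are a scale reference, not a fitted calibration.

## ANOVA baseline

For balanced replicated trials, `anova_heritability()` computes the classical
line-mean decomposition via `stats::aov` on
`value ~ factor(id) + factor(replicate)`:
$\hat\sigma_{line}^2 = (MS_{line} - MS_{err})/r$ (truncated at zero with a
warning) and $H_{aov} = \hat\sigma_{line}^2 / (\hat\sigma_{line}^2 + MS_{err})$.
This estimates the *single-plot* signal fraction, so it stays flat as the
replicate count grows, while $H_{cv}$ on replicate-averaged phenotypes rises —
the contrast the `experiment_replicate_grid()` driver reproduces.

## Numerical and design choices

- One eigendecomposition per REML fit; all likelihood evaluations reuse it.
- `stats::optimize` on the 1-D profile rather than a 2-D optimiser: the
  profile is unimodal in practice and the analytic $\sigma^2$ profile removes
  one dimension exactly. Tests compare against a dense 200×200 grid evaluation
  of the unprofiled objective built with dense Cholesky factorisations,
  independent of the eigen route.
- Kinship files are written with 17 significant digits and read back with the
  base-R `strtod` parser so round-trips are bit-exact.
- Fold assignment, simulation, and CV repeats are all reproducible from a
  single seed; seeded functions restore the caller's RNG state.

## Limitations

- Additive model only: no dominance, epistasis, or genotype-by-environment
  terms, and a single random effect.
- REML uses a dense eigendecomposition, $O(n^3)$; intended for panels of
  hundreds to a few thousand lines, not biobank scale.
- $H_{cv}$ is a property of the panel *and* the prediction machinery: with few
  training lines it is bounded by prediction accuracy and will sit below the
  generating signal fraction even for a perfectly specified model.
- The simulator's Markov approximation (above) and even-spacing map are
  conveniences; conclusions about real panels should use real genotypes via
  `read_genotypes()`.
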