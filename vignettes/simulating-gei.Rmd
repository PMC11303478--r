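---
title: "Simulating genotype-by-environment interaction with multiplicative models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genotype-by-environment interaction with multiplicative models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geisim)
```

## The problem

A plant breeding programme targets a *target population of
environments* (TPE): the full range of locations, seasons and
managements in which its varieties will eventually grow. Field
evaluation only ever samples a small subset of that population — a
*multi-environment trial* (MET). Genotype-by-environment interaction
(GEI) means a genotype's performance varies between environments, both
in scale (non-crossover interaction) and in rank (crossover
interaction), so the genotypes that look best in a MET are not exactly
the genotypes that are best in the TPE. `geisim` simulates this
situation end to end: a TPE with controllable GEI structure, METs
sampled from it, plot-level phenotypes, and a recurrent breeding
programme selecting on those phenotypes.

## The model

### GE effects

The true genetic values (GE effects) of `v` genotypes in `p`
environments are multivariate normal,

$$\mathbf{u} \sim \mathrm{N}(\mathbf{0},\; \mathbf{G_e} \otimes \mathbf{G}),$$

with `Ge` the `p × p` between-environment genetic covariance matrix and
`G` a genotype relationship matrix (identity, pedigree or genomic; both
assumed positive semi-definite). Rather than sampling the `vp`-vector
directly, `geisim` uses the eigendecomposition
$\mathbf{G_e} = \mathbf{S}\mathbf{L}\mathbf{S}^\top$ and keeps the first
`k` terms: the environmental covariates $\mathbf{S}_k$ (orthonormal
columns) and term variances $\mathbf{L}_k$ (eigenvalues, non-increasing).
Genotype slopes $\mathbf{f}_k \sim \mathrm{N}(\mathbf{0}, \mathbf{L}_k
\otimes \mathbf{G})$ then give

$$\mathbf{u} = \mathbf{f}_k \mathbf{S}_k^\top,$$

whose between-environment covariance is
$\mathbf{S}_k\mathbf{L}_k\mathbf{S}_k^\top$ — equal to `Ge` whenever
`rank(Ge) ≤ k`. The practical payoff is that a breeding simulation only
needs `k` genetic "traits" (slopes) per genotype, however many
environments the TPE contains. With `k = 7` and `p = 1000` the
simulation handles a thousand environments at the cost of seven traits.

### Simulating the TPE covariance

`Ge` is assembled as
$\mathbf{G_e} = \mathbf{D_e}^{1/2}\mathbf{C_e}\mathbf{D_e}^{1/2}$ from:

* **Genetic variances** `diag(De)`: $\sigma^2_{g_j} \sim
  \mathrm{Gamma}(\alpha, \theta)$ — strictly positive, right-skewed,
  realistically heterogeneous. Defaults `α = 1.5`, `θ = 1` (variance
  units), giving mean genetic variance `αθ = 1.5`.
* **Genetic correlations** `Ce`: a structured-noise construction
  $\mathbf{C_e} = \rho\mathbf{J}_p + \epsilon\,\Lambda^\top\Lambda$,
  where `J` is the all-ones matrix, the columns of the
  `(k−1) × p` matrix `Λ` are drawn elementwise
  $\mathrm{U}(-1,\, 1+\gamma)$ and scaled to unit length. `ρ ∈ [0, 1)`
  is the baseline correlation (negative baselines are rejected: they
  can produce indefinite matrices and would break the rank guarantee);
  `ε` scales the noise, and `ε = 1 − ρ` (the default) makes the
  diagonal exactly one and the rank exactly `k`; `γ ∈ [−1, 0]` skews
  the correlation distribution to the left, raising the mean above `ρ`
  — with `γ = 0` the mean correlation converges to `ρ`. If `ε < 1 − ρ`
  is chosen instead, the diagonal is reset to one and `Ce` is full
  rank, the trailing terms each explaining `1 − ρ − ε` of the variance.

A plug-in `base` argument lets a user replace `ρJ` with any other
baseline structure (autoregressive, block, …); no named alternatives
are shipped. `bend_to_psd()` repairs user-supplied covariance matrices
by clipping eigenvalues; the package's own generator never needs it.

### Tuning with measures of variance explained

`variance_decomposition()` summarises any `Ge`:

* main-effect variance $\sigma^2_g$ = mean element of `Ge` (the
  variance of the genotype main effects, i.e. averages across
  environments); interaction variance $\sigma^2_{ge}$ = mean diagonal
  minus $\sigma^2_g$;
* the classical partition $\sigma^2_{ge} = \sigma^2_{ge_h} +
  \sigma^2_{ge_l}$ into heterogeneity of genetic variance
  ($\overline{\sigma^2_j} - \bar{\sigma}_j^2$) and lack of genetic
  correlation;
* non-crossover variance $\sigma^2_n = \frac{1}{p}\sum_j
  \rho^{*2}_{g_j}\sigma^2_{g_j}$, with $\rho^*_{g_j}$ the correlation
  between environment *j*'s GE effects and the main effects, computed
  analytically from `Ge` as $\mathrm{rowmean}_j(\mathbf{G_e}) /
  (\sigma_{g_j}\sqrt{\sigma^2_g})$; crossover variance is the
  remainder. Non-crossover variance always dominates the main-effect
  variance (Jensen), since it includes variance-scale differences that
  are aligned with the main effects.

For gamma-distributed variances the population heterogeneity component
has the closed form $\alpha\theta - \theta\,(\Gamma(\alpha + 1/2) /
\Gamma(\alpha))^2$ (`heterogeneity_closed_form()`), equal to 0.2268 at
the defaults. `tune_to_targets()` ranks candidate `(ρ, ε, γ, k)`
combinations against desired proportions by seed-averaged Monte-Carlo.

The preset scenarios (`gei_scenario()`) use `(ρ, ε, γ) =
(0.50, 0.50, −0.50)`, `(0.20, 0.80, −0.50)` and `(0.00, 1.00, −0.35)`
at `k = 7` for low, moderate and high GEI, all with the same gamma
variances. A note on the non-crossover proportion: evaluated on the
heterogeneous-variance `Ge`, the formula above gives `v_n ≈ 0.62 /
0.40 / 0.22` for the three scenarios; evaluated on the correlation
matrix (equal variances) it gives `≈ 0.61 / 0.37 / 0.09`. The package
reports the `Ge`-scale value, which is the formula taken literally; the
difference is the variance-heterogeneity component aligned with the
main effects, which grows as the baseline correlation falls.

### Phenotypes

Plot phenotypes follow the linear mixed model

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{X}\boldsymbol\tau +
\mathbf{Z}\mathbf{u} + \boldsymbol\varepsilon$$

under a randomised complete block design with `r` blocks per
environment. Environmental main effects are iid
$\mathrm{N}(0, \sigma^2_e)$ or, optionally, a deterministic regression
$\boldsymbol\tau = \mathbf{S}_k\boldsymbol\tau_{s_k}$ on the
environmental covariates (which induces a mean–variance relationship).
Plot errors are normal with mean variance $\sigma^2_\varepsilon$ across
environments; per-environment variances are drawn from a gamma
distribution rescaled to that mean with coefficient of variation 0.05
by default (mild field-to-field heterogeneity, of the order seen in
per-trial error variance estimates; set `cv = 0` for equal variances).
An optional separable first-order autoregressive structure over the
field's rows and columns produces spatially correlated errors; blocks
are laid out as contiguous column ranges with row-major plot order.
`error_variance_from_heritability()` converts a target plot-level
heritability `H²` into $\sigma^2_\varepsilon = \bar\sigma^2_g (1 -
H^2)/H^2$.

### MET sampling and expected accuracy

METs are sampled by shuffling the TPE and taking the first `p_m`
environments — without replacement within a MET, while successive METs
(e.g. breeding years) may re-draw the same environment, mirroring a
finite TPE. The realised MET-TPE alignment is the correlation between
genotype main effects over the sampled environments and over the whole
TPE. Its expected counterpart, and the expected prediction accuracies,
follow from the true simulation parameters:

$$r_g = \sqrt{\frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/p_m +
\sigma^2_\varepsilon/(p_m r)}},\qquad
r_{mt} = \sqrt{\frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/p_m}},
\qquad r_g = r_m \times r_{mt}.$$

These treat the MET main-effect variance as fixed at its expectation
$\sigma^2_g + \sigma^2_{ge}/p_m$. The mean of the *realised* alignment
over many resamples therefore sits slightly above $r_{mt}$ (about
+0.006 in the moderate scenario at `p_m = 10`, as the test suite
documents): the per-subset variance fluctuates, and the expectation of
$1/\sqrt{\cdot}$ exceeds $1/\sqrt{\mathbb E[\cdot]}$. The unit tests
treat $r_{mt}$ as an approximation with a 0.025 tolerance; the
acceptance suite additionally records the strict 3-standard-error
comparison, which this convexity bias fails by design of the formula,
not by an implementation defect.

### Breeding-programme simulation

`run_programme()` executes the yearly workflow: decompose the TPE once;
create founders; then each year sample environments, phenotype every
stage, select, advance, cross and produce doubled haploids. Design
choices worth knowing:

* **Founders and genomes.** Founders are biallelic genotypes at
  `n_loci` loci on `n_chromosomes` chromosomes, allele frequencies
  `U(0.1, 0.9)`, Hardy–Weinberg haplotypes. Each multiplicative term is
  an additive trait: random marker effects are standardised post hoc so
  founder slope variances equal `L_k` *exactly* and slope means are
  exactly zero. Meiosis uses Poisson(1) crossovers per chromosome at
  uniform positions; doubled haploids are produced by doubling a single
  gamete.
* **Selection.** Phenotypic selection ranks genotypes on their mean
  phenotype across the stage's current-year environments. Genomic
  selection ranks on genotype main-effect BLUPs from a compound
  symmetry model (`phenotype = env + genotype + genotype:env + error`)
  fitted to all stages and environments of the trailing
  `met_window_years` (default 3) years, with genomic relationship `K`
  built from centred marker dosages normalised by `2Σq(1−q)`. Variance
  components are plugged in from the true simulation parameters — the
  package deliberately contains no REML machinery, isolating the
  simulation framework from estimation error. The mixed-model equations
  are solved after absorbing the iid interaction and error into
  genotype-by-environment cell means with weights
  `1/(σ²_ge + σ²_ε/r_cell)`, which is algebraically identical to the
  plot-level equations for data balanced within cells (verified against
  a direct joint-covariance oracle in the tests). `K` receives a ridge
  of `1e-8 · mean(diag(K))` when numerically singular, so that
  duplicated genotypes (e.g. clones) do not break the equations. A single mean
  error variance (the average over stages) is used in the pooled
  genomic analysis.
* **Parents.** Each year the top `n_parents` genotypes among the
  newly advanced material (all stages beyond the first) are crossed at
  random to create the next first-stage cohort. Environment is a fixed
  classifier in the genomic model; year–environment combinations are
  distinct trial environments that share the TPE covariate row.
* **Tracking.** Genetic gain is the mean of the genotype main effects,
  computed through the identity $\mu^*_g = \bar{\mathbf{s}}_k
  \boldsymbol\tau^*_{s_k}$ (covariate means times slope means), and
  genetic variance through $\sigma^{*2}_g = \bar{\mathbf{s}}_k
  \mathbf{L}^*_k \bar{\mathbf{s}}_k^\top$ with $\mathbf{L}^*_k$ the
  current slope covariance; both equal the direct mean/variance of the
  computed main effects to numerical precision (asserted in the
  tests). MET-scale analogues use the covariate rows of the year's
  sampled environments. Founder cohorts start at gain exactly zero.

The default stage structure (headrow 100 genotypes × 1 environment × 1
replicate, then 30 × 5 × 2, 12 × 10 × 2, 5 × 20 × 2, error variance 4
throughout, 20 environments sampled per year) mirrors the shape of a
line programme — genotype counts decreasing, environments and
replication increasing — and is entirely configurable; no published
programme's exact counts are asserted anywhere.

## What the generator does and does not emulate

The synthetic data capture: heterogeneous genetic variances and
correlations between environments with controllable rank and skew;
realistic MET sampling variability and its effect on alignment and
accuracy; additive marker-based inheritance with linkage; heterogeneous
per-environment error variances and optional spatial error correlation.

They do **not** capture: non-additive (dominance/epistatic) genetic
architecture beyond what a user supplies through `Ge`/`G`; temporal
drift or cyclic structure in the TPE; unbalanced designs (p-rep, sparse
testing); estimation of variance components from data (all analyses
use the true parameters); or non-normal trait distributions. Passing
tests therefore demonstrate internal consistency of the simulation
machinery, not that any particular crop or region behaves like a
preset scenario.

## Numerical choices

* Eigenvector signs are fixed so each covariate column's
  largest-magnitude element is positive (ties by first index);
  eigenvalues below `1e-12` of the maximum are treated as zero for rank
  and square-root computations. `Ge` itself is invariant to these
  conventions.
* Latent covariate columns are drawn column-major in environment order,
  so a TPE can be extended to more environments without changing the
  existing ones; zero-norm columns (probability zero) are redrawn.
* One root seed drives named child streams (variances, correlations,
  slopes, sampling, environment means, errors, crossing), so any module
  can be re-run independently without perturbing the others; all CSVs
  are written with 17 significant digits for lossless round-trips.
* Degenerate inputs: environments with zero genetic variance contribute
  zero to the non-crossover variance and are excluded from the mean
  correlation, with a warning; an all-zero covariance is an error, as
  is an alignment on zero-variance main effects.

## Problem sizes used in the tests

Monte-Carlo checks use sizes chosen to keep 3-standard-error bands
tight while running in minutes on one CPU: `v = 1e5` genotypes for
distributional checks of slopes, effects and the brute-force
variance-decomposition oracle; `p = 1000` environments for the scenario
summaries; 400–1000 resamples for alignment distributions; and 20
replicate 10-year breeding runs per scenario–strategy combination for
the ordering checks (gain decreasing in GEI; genomic accuracy at least
phenotypic). The alignment-versus-`r_mt` comparison is additionally
asserted at the strict 3-standard-error level in the acceptance tests,
where it documents the approximation error discussed above.

## Known limitations

* The non-crossover/crossover partition is reported on the
  heterogeneous-variance scale (see the scenario note above); users
  comparing with equal-variance summaries should apply
  `variance_decomposition()` to `tpe$correlations`.
* The compound-symmetry BLUP ignores genotype-by-stage error-variance
  differences (one pooled error variance).
* Spatial error simulation requires a rectangular layout with blocks as
  contiguous column ranges; other layouts must be composed manually.
* `make_crosses()` samples parent pairs uniformly; assortative or
  factorial mating designs must be supplied via the `parents` matrix.
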