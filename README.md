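# geisim

Simulation of genotype-by-environment interaction (GEI) for plant
breeding research, using reduced-rank multiplicative models.

Plant breeders evaluate candidate genotypes in multi-environment trials
(METs) that sample a much larger target population of environments
(TPE). Because genotypes respond differently to different environments —
changes of scale (non-crossover GEI) and changes of rank (crossover
GEI) — selection decisions made from a MET only partially transfer to
the TPE. Many breeding simulations either ignore GEI or reduce it to a
single variance component, which makes projections of genetic gain
optimistic. `geisim` generates GEI with controllable, realistic
structure, at TPE scale, for two kinds of users:

* quantitative geneticists comparing statistical models for MET
  analysis on data with known truth, and
* breeding-programme modellers comparing selection strategies
  (phenotypic vs genomic) under different levels of GEI.

## The model

GE effects for `v` genotypes in `p` environments are drawn from

    u ~ N(0, Ge ⊗ G)

where `Ge` is the `p × p` between-environment genetic covariance matrix
and `G` a genotype relationship matrix. `Ge` is simulated with
heterogeneous variances and correlations,

    Ge = De^{1/2} Ce De^{1/2},   σ²_gj ~ Gamma(α, θ),
    Ce = ρ J_p + ε ΛᵀΛ,

with `Λ` a `(k−1) × p` matrix of unit-length latent covariate columns
drawn `U(−1, 1+γ)`; `ρ` sets the baseline genetic correlation, `ε` the
noise magnitude (with `ε = 1 − ρ` enforcing rank `k`), and `γ ∈ [−1, 0]`
the negative skew of the correlation distribution. The eigendecomposition
`Ge = S L Sᵀ` yields environmental covariates `S_k` and term variances
`L_k`, so effects are built multiplicatively as `u = f_k S_kᵀ` with
genotype slopes `f_k ~ N(0, L_k ⊗ G)` — only `k` "traits" are needed no
matter how large `p` is.

Summary measures quantify the simulated structure: the proportions of
main-effect vs interaction variance (`v_g`, `v_ge`), the partition of
interaction into heterogeneity of variance and lack of correlation
(`σ²_ge_h`, `σ²_ge_l`), the proportions of non-crossover vs crossover
variance (`v_n`, `v_c`), and the expected accuracies

    r_g = √(σ²_g / (σ²_g + σ²_ge/p_m + σ²_ε/(p_m r)))      (TPE)
    r_m = √((σ²_g + σ²_ge/p_m) / (…))                      (MET)
    r_mt = √(σ²_g / (σ²_g + σ²_ge/p_m))                    (MET-TPE alignment)

with the identity `r_g = r_m × r_mt`. Phenotypes are generated from
the linear mixed model `y = 1μ + Xτ + Zu + ε` under a randomised
complete block design, and a recurrent breeding-programme simulator
runs multi-stage selection over years with phenotypic or genomic
(compound-symmetry BLUP) selection.

## Worked example

```r
library(geisim)

# a low-GEI TPE of 1000 environments (gamma variances: shape 1.5, scale 1;
# correlations: baseline 0.5, skew -0.5, rank 7)
tpe <- gei_scenario("low", p = 1000, seed = 101)
variance_decomposition(tpe)
#> Variance-explained measures
#>      v_g     v_ge      v_n      v_c mean_var mean_cor     ge_h     ge_l
#>     0.52     0.48     0.62     0.38     1.52     0.61     0.23     0.50
```

About half the genetic variance is main-effect (`v_g = 0.52`), the
interaction splits into heterogeneity 0.23 and lack of correlation
0.50, and 38% of the variance is crossover — rank changes that
selection on main effects cannot capture.

```r
# sample a 10-environment MET of 400 genotypes at plot heritability 0.3
met <- simulate_met_dataset(tpe, n_genotypes = 400, n_envs = 10,
                            n_blocks = 2, mu = 4, h2 = 0.3, seed = 7)
nrow(met$dataset)        # 8000 plot records
met$sample$alignment     # realised MET-TPE alignment, here 0.98
met$sample$expected$r_mt # expected alignment from the true parameters

# compare selection strategies over 10 years of breeding
prog <- run_programme(programme_config(years = 10, selection = "genomic"),
                      tpe, seed = 1)
subset(prog, stage == "HDRW", c(year, gain_tpe, var_tpe, accuracy_tpe))
```

The progress table reports, per year and stage, genetic gain and
variance of the genotype main effects in the TPE and the current MET,
the prediction accuracies and the realised MET-TPE alignment.

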