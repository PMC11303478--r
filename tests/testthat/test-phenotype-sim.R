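test_that("trial designs count plots and validate layouts", {
  d <- trial_design(400, 10, 2, mu = 4)
  expect_equal(d$n_plots, 8000)
  expect_error(trial_design(10, 2, 2, n_rows = 4, n_cols = 4), "plots")
  expect_error(trial_design(10, 2, 2, n_rows = 4), "both")
  expect_error(trial_design(12, 2, 2, n_rows = 8, n_cols = 3),
               "divisible")
})

test_that("environment means are iid normal or a covariate regression", {
  expect_equal(simulate_environment_means(5, sigma2_e = 0, seed = 1),
               rep(0, 5))
  tau <- simulate_environment_means(1e5, sigma2_e = 1, seed = 2)
  expect_lt(abs(var(tau) - 1), 3 * sqrt(2 / 1e5))
  expect_lt(abs(mean(tau)), 3 / sqrt(1e5))

  S <- matrix(rnorm(10), 5, 2)
  expect_equal(simulate_environment_means(5, covariates = S,
                                          tau_s = c(0, 0)), rep(0, 5))
  expect_equal(simulate_environment_means(5, covariates = S,
                                          tau_s = c(1, -1)),
               drop(S %*% c(1, -1)))
  expect_error(simulate_environment_means(5, tau_s = c(1, 1)),
               "covariates")
})

test_that("plot errors have the requested variance and spatial correlation", {
  d <- trial_design(100, 4, 1)
  expect_true(all(simulate_plot_errors(d, plot_error_spec(0), seed = 3) == 0))

  d2 <- trial_design(5e4, 4, 1)
  e <- simulate_plot_errors(d2, plot_error_spec(4, cv = 0), seed = 4)
  expect_lt(abs(var(as.numeric(e)) - 4), 3 * 4 * sqrt(2 / 2e5))
  expect_equal(attr(e, "per_env_variances"), rep(4, 4))

  # heterogeneous variances centre on the requested mean
  e2 <- simulate_plot_errors(trial_design(10, 200, 1), plot_error_spec(4),
                             seed = 5)
  s2 <- attr(e2, "per_env_variances")
  expect_lt(abs(mean(s2) - 4), 3 * sd(s2) / sqrt(200))

  # AR(1) row correlation: same-column neighbours (lag n_cols in row-major
  # plot order) correlate at the row parameter
  ds <- trial_design(2500, 1, 2, n_rows = 100, n_cols = 50)
  es <- simulate_plot_errors(ds, plot_error_spec(1, cv = 0, ar_row = 0.5,
                                                 ar_col = 0), seed = 6)
  X <- matrix(as.numeric(es), nrow = 100, ncol = 50, byrow = TRUE)
  lag1 <- cor(as.vector(X[-100, ]), as.vector(X[-1, ]))
  expect_lt(abs(lag1 - 0.5), 3 / sqrt(4900) + 0.02)
  expect_error(simulate_plot_errors(trial_design(10, 2, 1),
                                    plot_error_spec(1, ar_row = 0.5)),
               "n_rows")
})

test_that("error variance from heritability inverts the plot-level ratio", {
  expect_equal(error_variance_from_heritability(1, 0.5), 1)
  expect_equal(error_variance_from_heritability(1.73, 0.3), 4.0367,
               tolerance = 1e-4)
  expect_lt(error_variance_from_heritability(1, 1 - 1e-9), 1e-8)
  expect_error(error_variance_from_heritability(1, 1.2), "between 0 and 1")
})

test_that("MET datasets follow the linear mixed model exactly", {
  # single plot: phenotype is the trait mean when all effects are zero
  d1 <- trial_design(1, 1, 1, mu = 4)
  met1 <- build_met_dataset(matrix(0, 1, 1), 0, 0, d1)
  expect_equal(met1$phenotype, 4)

  tpe <- simulate_tpe(p = 40, rho = 0.5, gamma_skew = -0.5, k = 5, seed = 7)
  terms <- decompose_covariance(tpe)
  v <- 200
  u <- construct_ge_effects(terms, simulate_slopes(terms, v, seed = 8))
  smp <- sample_tpe(u, 6, seed = 9)
  design <- trial_design(v, 6, 2, mu = 4)
  tau <- simulate_environment_means(6, seed = 10)
  err <- simulate_plot_errors(design, plot_error_spec(2), seed = 11)
  met <- build_met_dataset(smp$u_sampled, tau, err, design)

  expect_equal(nrow(met), v * 6 * 2)
  # RCBD completeness: every (env, block) holds each genotype exactly once
  counts <- table(met$env, met$block)
  expect_true(all(counts == v))
  per_cell <- tapply(met$genotype, interaction(met$env, met$block),
                     function(g) anyDuplicated(g) == 0)
  expect_true(all(per_cell))
  # exact decomposition: subtracting stored truth recovers the errors to
  # machine precision
  recovered <- met$phenotype - 4 - attr(met, "tau")[as.character(met$env)] -
    met$true_ge
  expect_equal(unname(recovered), as.numeric(err), tolerance = 1e-12)

  # large v*r: environment means approach mu + tau_j
  big <- build_met_dataset(
    matrix(rnorm(2000 * 2), 2000, 2), c(1, -1),
    simulate_plot_errors(trial_design(2000, 2, 2), plot_error_spec(1, cv = 0),
                         seed = 12),
    trial_design(2000, 2, 2, mu = 4))
  means <- tapply(big$phenotype, big$env, mean)
  expect_lt(abs(means[[1]] - 5), 3 * sqrt(2 / 4000) + 0.05)
  expect_lt(abs(means[[2]] - 3), 3 * sqrt(2 / 4000) + 0.05)
})

test_that("MET summaries report per-environment heritabilities and an overall row", {
  tpe <- simulate_tpe(p = 50, rho = 0.5, gamma_skew = -0.5, k = 5, seed = 13)
  met <- simulate_met_dataset(tpe, n_genotypes = 100, n_envs = 8,
                              n_blocks = 2, mu = 4, h2 = 0.3, seed = 14)
  tab <- met$summary
  expect_equal(nrow(tab), 9)
  expect_equal(tab$n_plots[9], 100 * 8 * 2)
  per_env <- tab[1:8, ]
  expect_equal(per_env$h2,
               per_env$sigma2_g / (per_env$sigma2_g + per_env$sigma2_eps))
  expect_equal(tab$h2[9], mean(per_env$h2))
  expect_equal(tab$sigma2_g[9], mean(per_env$sigma2_g))

  # zero error variance: heritability of one
  d <- trial_design(20, 2, 1)
  u <- matrix(rnorm(40), 20, 2)
  err <- simulate_plot_errors(d, plot_error_spec(0), seed = 15)
  met0 <- build_met_dataset(u, c(0, 0), err, d)
  expect_equal(summarise_met(met0)$h2[1:2], c(1, 1))

  expect_error(summarise_met(data.frame(x = 1)), "met_dataset")
})
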