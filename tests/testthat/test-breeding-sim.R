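test_that("founders carry exact term variances and zero-mean slopes", {
  terms <- terms_from_matrix(diag(c(2, 1, 0.5)))
  pop <- create_founders(100, n_loci = 200, n_chromosomes = 10, terms,
                         seed = 1)
  f <- population_slopes(pop)
  expect_equal(unname(apply(f, 2, var)), terms$L, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(f))), 1e-10)

  # a zero-variance term gives an all-zero slope column
  terms0 <- terms
  terms0$L <- c(2, 0, 0.5)
  pop0 <- create_founders(50, 100, 5, terms0, seed = 2)
  expect_true(all(population_slopes(pop0)[, 2] == 0))

  # founder progress identities: gain 0, variance s_bar L s_bar'
  pr <- track_progress(f, terms, met_envs = 1:2)
  s_bar <- colMeans(terms$S)
  expect_lt(abs(pr$gain_tpe), 1e-10)
  expect_equal(pr$var_tpe, drop(t(s_bar) %*% cov(f) %*% s_bar),
               tolerance = 1e-12)
  # identity with directly computed main effects
  mains <- rowMeans(construct_ge_effects(terms, f))
  expect_equal(pr$gain_tpe, mean(mains), tolerance = 1e-10)
  expect_equal(pr$var_tpe, var(mains), tolerance = 1e-10)

  expect_error(create_founders(10, n_loci = 2, n_chromosomes = 1, terms),
               "loci")
})

test_that("meiosis respects additive inheritance and degenerate cases", {
  terms <- terms_from_matrix(diag(c(1, 0.5)))
  pop <- create_founders(20, 100, 5, terms, seed = 3)

  # selfing a fully homozygous parent reproduces it exactly
  dh <- make_dh(pop_subset_for_test(pop, 1:4), seed = 4)
  selfed <- make_crosses(dh, 4, seed = 5, parents = cbind(1:4, 1:4))
  expect_equal(unname(dosages(selfed)), unname(dosages(dh)))

  # without crossovers each gamete is one intact parental chromosome
  off <- make_crosses(pop, 30, seed = 6, crossover_rate = 0)
  map <- pop$map
  for (c in seq_along(map$chrom_index)) {
    ix <- map$chrom_index[[c]]
    h <- off$h1[1, ix]
    parents_h <- rbind(pop$h1[, ix], pop$h2[, ix])
    expect_true(any(apply(parents_h, 1, identical, y = h)))
  }

  # progeny mean slope approaches the mid-parent mean
  big <- make_crosses(pop_subset_for_test(pop, 1:2), 4000, seed = 7,
                      parents = cbind(rep(1, 4000), rep(2, 4000)))
  mid <- colMeans(population_slopes(pop)[1:2, ])
  prog_mean <- colMeans(population_slopes(big))
  se <- 3 * apply(population_slopes(big), 2, sd) / sqrt(4000)
  expect_true(all(abs(prog_mean - mid) < se + 1e-8))

  expect_error(make_crosses(pop_subset_for_test(pop, 1), 5), "2 parents")
})

test_that("doubled haploids are homozygous and the genomic matrix is sane", {
  terms <- terms_from_matrix(diag(2))
  pop <- create_founders(30, 120, 6, terms, seed = 8)
  dh <- make_dh(pop, seed = 9)
  expect_identical(dh$h1, dh$h2)
  expect_true(all(dosages(dh) %in% c(0L, 2L)))

  K <- genomic_relationship(pop)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1, tolerance = 0.25)
  # few polymorphic markers: identity fallback
  Wmono <- matrix(2L, 10, 20)
  expect_equal(genomic_relationship(Wmono), diag(10), ignore_attr = TRUE)
})

test_that("compound-symmetry BLUP equals the joint-covariance oracle", {
  # tiny instance: v = 5 genotypes, 2 environments, 1 replicate
  set.seed(10)
  d <- data.frame(env = rep(c("E1", "E2"), each = 5),
                  genotype = rep(paste0("G", 1:5), 2),
                  phenotype = rnorm(10, mean = rep(c(1, 3), each = 5)))
  K <- rand_psd(5, seed = 11)
  rownames(K) <- colnames(K) <- paste0("G", 1:5)
  for (pars in list(c(1, 0.5, 2), c(0.3, 1.5, 0.7))) {
    mine <- predict_main_effects_cs(d, pars[1], pars[2], pars[3], K = K)
    oracle <- blup_oracle(d, pars[1], pars[2], pars[3], K = unname(K))
    expect_lt(max(abs(mine[names(oracle)] - oracle)), 1e-8)
    mine_id <- predict_main_effects_cs(d, pars[1], pars[2], pars[3])
    oracle_id <- blup_oracle(d, pars[1], pars[2], pars[3])
    expect_lt(max(abs(mine_id[names(oracle_id)] - oracle_id)), 1e-8)
  }

  # replicated plots: the cell-mean absorption still matches plot-level algebra
  d2 <- data.frame(env = rep(c("E1", "E2"), each = 8),
                   genotype = rep(rep(paste0("G", 1:4), each = 2), 2),
                   phenotype = rnorm(16))
  expect_lt(max(abs(predict_main_effects_cs(d2, 1, 1, 2)[paste0("G", 1:4)] -
                      blup_oracle(d2, 1, 1, 2))), 1e-8)

  # no genetic signal: all predictions equal
  flat <- predict_main_effects_cs(d, 0, 1, 1)
  expect_true(all(flat == flat[1]))

  # vanishing error with many environments: predictions recover true mains
  terms <- terms_from_matrix(rand_psd(30, seed = 12))
  u <- construct_ge_effects(terms, simulate_slopes(terms, 40, seed = 13))
  met <- build_met_dataset(u, rep(0, 30), rep(0, 40 * 30),
                           trial_design(40, 30, 1))
  vd <- variance_decomposition(rand_psd(30, seed = 12))
  pr <- predict_main_effects_cs(met, vd$sigma2_g, vd$sigma2_ge, 1e-8)
  expect_gt(cor(pr[rownames(u)], rowMeans(u)), 0.99)
})

test_that("programme configuration enforces its constraints", {
  cfg <- programme_config()
  expect_s3_class(cfg, "programme_config")
  expect_error(programme_config(stages = list(
    list(name = "A", n_genotypes = 10, n_envs = 1, n_reps = 1,
         sigma2_eps = 1),
    list(name = "B", n_genotypes = 20, n_envs = 1, n_reps = 1,
         sigma2_eps = 1))), "non-increasing")
  expect_error(programme_config(envs_per_year = 2, stages = list(
    list(name = "A", n_genotypes = 10, n_envs = 5, n_reps = 1,
         sigma2_eps = 1))), "sampled")
  expect_error(programme_config(n_parents = 500), "n_parents")
})

test_that("selection shifts the mean and erodes variance; no signal, no gain", {
  terms <- terms_from_matrix(rand_psd(40, seed = 14))
  pop <- create_founders(200, 200, 10, terms, seed = 15)
  f <- population_slopes(pop)
  mains <- rowMeans(construct_ge_effects(terms, f))

  # truncating the top half on true mains raises the mean and lowers the
  # variance of the main effects (order-statistics direction)
  top <- order(mains, decreasing = TRUE)[1:100]
  pr_all <- track_progress(f, terms, met_envs = 1:5)
  pr_top <- track_progress(f[top, ], terms, met_envs = 1:5)
  expect_gt(pr_top$gain_tpe, pr_all$gain_tpe)
  expect_lt(pr_top$var_tpe, pr_all$var_tpe)

  # one cycle of truncation on true mains under no GEI matches the
  # breeder's equation R = i * sigma_g (selection-intensity oracle)
  ns <- terms_from_matrix(matrix(1.5, 30, 30) + 0, k = 1)
  pop_ns <- create_founders(400, 200, 10, ns, seed = 16)
  mains_ns <- rowMeans(construct_ge_effects(ns, population_slopes(pop_ns)))
  resp <- mean(sort(mains_ns, decreasing = TRUE)[1:80]) # top 20 %
  reps <- withr::with_seed(17, {
    replicate(400, {
      x <- rnorm(400, sd = sd(mains_ns))
      mean(sort(x, decreasing = TRUE)[1:80])
    })
  })
  expect_lt(abs(resp - mean(reps)), 3 * sd(reps))

  # enormous error variance: selection is blind, expected gain is zero
  cfg <- programme_config(
    years = 4, envs_per_year = 4,
    stages = list(list(name = "S1", n_genotypes = 40, n_envs = 1,
                       n_reps = 1, sigma2_eps = 1e6),
                  list(name = "S2", n_genotypes = 10, n_envs = 2,
                       n_reps = 1, sigma2_eps = 1e6)),
    n_parents = 5, n_loci = 100, n_chromosomes = 5)
  tpe <- simulate_tpe(p = 50, rho = 0.5, gamma_skew = -0.5, k = 5, seed = 18)
  gains <- vapply(1:6, function(r) {
    prg <- run_programme(cfg, tpe, seed = 100 + r)
    hd <- prg[prg$stage == "S1", ]
    hd$gain_tpe[nrow(hd)]
  }, numeric(1))
  expect_lt(abs(mean(gains)), 3 * sd(gains) / sqrt(6) + 0.05)
})

test_that("the programme loop tracks progress and samples environments yearly", {
  tpe <- simulate_tpe(p = 80, rho = 0.5, gamma_skew = -0.5, k = 5, seed = 19)
  cfg <- programme_config(
    years = 6, envs_per_year = 5,
    stages = list(list(name = "S1", n_genotypes = 30, n_envs = 1,
                       n_reps = 1, sigma2_eps = 2),
                  list(name = "S2", n_genotypes = 10, n_envs = 3,
                       n_reps = 2, sigma2_eps = 2),
                  list(name = "S3", n_genotypes = 4, n_envs = 5,
                       n_reps = 2, sigma2_eps = 2)),
    n_parents = 6, n_loci = 120, n_chromosomes = 6)
  for (sel in c("phenotypic", "genomic")) {
    cfg$selection <- sel
    prg <- run_programme(cfg, tpe, seed = 20)
    hd <- prg[prg$stage == "S1", ]
    expect_equal(nrow(hd), 6)
    # founders start at zero gain
    expect_lt(abs(hd$gain_tpe[1]), 1e-10)
    # selection produces positive gain by the final year
    expect_gt(hd$gain_tpe[6], 0)
    expect_true(all(is.finite(hd$accuracy_tpe)))
    expect_true(all(hd$alignment > -1 & hd$alignment < 1 + 1e-12))
    env_mat <- attr(prg, "sampled_environments")
    expect_equal(dim(env_mat), c(6, 5))
    expect_true(all(apply(env_mat, 1, anyDuplicated) == 0))
    # deterministic under the same seed
    prg2 <- run_programme(cfg, tpe, seed = 20)
    expect_equal(prg$gain_tpe, prg2$gain_tpe)
  }
})
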