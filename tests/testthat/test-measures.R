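test_that("variance decomposition is exact on analytic cases", {
  # perfect correlation, equal variances: pure main effect, no crossover
  vd1 <- variance_decomposition(matrix(2, 4, 4) + 0) # c * J
  expect_equal(vd1$v_g, 1)
  expect_equal(vd1$v_n, 1)
  expect_equal(vd1$sigma2_ge_h, 0)
  expect_equal(vd1$sigma2_ge_l, 0)

  # identity: half main effect, all interaction from lack of correlation
  vd2 <- variance_decomposition(diag(2))
  expect_equal(vd2$sigma2_g, 0.5)
  expect_equal(vd2$sigma2_ge, 0.5)
  expect_equal(vd2$v_g, 0.5)
  expect_equal(vd2$sigma2_ge_h, 0)
  expect_equal(vd2$sigma2_ge_l, 0.5)
  expect_equal(vd2$v_n, 0.5)
  expect_equal(vd2$v_c, 0.5)

  expect_error(variance_decomposition(matrix(0, 3, 3)), "zero total")
})

test_that("decomposition invariants hold on random PSD matrices", {
  for (seed in 1:12) {
    Ge <- rand_psd(sample(3:12, 1), seed = seed)
    vd <- variance_decomposition(Ge)
    expect_equal(vd$v_g + vd$v_ge, 1, tolerance = 1e-10)
    expect_equal(vd$v_n + vd$v_c, 1, tolerance = 1e-10)
    expect_equal(vd$sigma2_ge_h + vd$sigma2_ge_l, vd$sigma2_ge,
                 tolerance = 1e-10)
    expect_gte(vd$sigma2_n, vd$sigma2_g - 1e-12) # Jensen
    expect_true(all(c(vd$v_g, vd$v_ge, vd$v_n, vd$v_c) >= -1e-12))
    expect_true(all(c(vd$v_g, vd$v_ge, vd$v_n, vd$v_c) <= 1 + 1e-12))
  }
})

test_that("analytic decomposition agrees with a brute-force effect simulation", {
  Ge <- rand_psd(8, seed = 21)
  vd <- variance_decomposition(Ge)
  emp <- empirical_decomposition(Ge, v = 1e5, seed = 22)
  rel_se <- 3 * sqrt(2 / 1e5) # 3 MC SEs on a variance scale, relative
  expect_lt(abs(emp$sigma2_g - vd$sigma2_g), rel_se * vd$sigma2_g + 0.002)
  expect_lt(abs(emp$sigma2_ge - vd$sigma2_ge),
            rel_se * vd$mean_variance + 0.002)
  expect_lt(abs(emp$sigma2_ge_h - vd$sigma2_ge_h),
            rel_se * vd$mean_variance + 0.002)
  expect_lt(abs(emp$sigma2_n - vd$sigma2_n), rel_se * vd$mean_variance + 0.002)
})

test_that("gamma heterogeneity closed form matches Monte-Carlo half-moments", {
  expect_equal(heterogeneity_closed_form(variance_spec(1, 1.5, 1)), 0.2268,
               tolerance = 1e-3)
  v <- withr::with_seed(23, rgamma(1e6, shape = 1.5, scale = 1))
  mc <- mean(v) - mean(sqrt(v))^2
  expect_lt(abs(heterogeneity_closed_form(1.5, 1) - mc), 0.003)
  # no scale, no heterogeneity
  expect_lt(heterogeneity_closed_form(1.5, 1e-12), 1e-10)
  expect_error(heterogeneity_closed_form(-1, 1), "shape")
})

test_that("expected accuracies follow the line-mean heritability formulas", {
  # no interaction, no error: all accuracies are one
  a0 <- expected_accuracies(1, 0, 0, 10, 2)
  expect_equal(c(a0$r_g, a0$r_m, a0$r_mt, a0$r_ge), rep(1, 4))

  # no main effect variance: no accuracy in the TPE
  a1 <- expected_accuracies(0, 1, 1, 10, 2)
  expect_equal(a1$r_g, 0)
  expect_equal(a1$r_mt, 0)

  # worked example and the decomposition identity
  a <- expected_accuracies(1, 1, 2, 10, 2)
  expect_equal(a$r_mt, sqrt(1 / 1.1), tolerance = 1e-12)
  expect_equal(a$r_m, sqrt(1.1 / 1.2), tolerance = 1e-12)
  expect_equal(a$r_g, 0.9129, tolerance = 1e-4)
  expect_equal(a$r_g, a$r_m * a$r_mt, tolerance = 1e-12)

  expect_error(expected_accuracies(0, 0, 0, 10, 2), "undefined")
})

test_that("r_g = r_m * r_mt across a parameter grid, with monotonicity", {
  grid <- expand.grid(s2g = c(0.2, 1, 3), s2ge = c(0.1, 1, 2),
                      s2e = c(0.5, 4), p_m = c(2, 10, 50), r = c(1, 3))
  prev <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- expected_accuracies(g$s2g, g$s2ge, g$s2e, g$p_m, g$r)
    expect_lt(abs(a$r_g - a$r_m * a$r_mt), 1e-12)
    expect_gte(a$r_m, a$r_g)
  }
  # r_g and r_mt non-decreasing in the number of environments, r_g in reps
  rg <- vapply(c(2, 5, 10, 20, 50),
               function(pm) expected_accuracies(1, 1, 2, pm, 2)$r_g,
               numeric(1))
  rmt <- vapply(c(2, 5, 10, 20, 50),
                function(pm) expected_accuracies(1, 1, 2, pm, 2)$r_mt,
                numeric(1))
  rr <- vapply(1:5, function(r) expected_accuracies(1, 1, 2, 10, r)$r_g,
               numeric(1))
  expect_true(all(diff(rg) > 0))
  expect_true(all(diff(rmt) > 0))
  expect_true(all(diff(rr) > 0))
})

test_that("tuning ranks candidate parameter triples by target distance", {
  # the canonical scenario triples: the low-GEI triple should win for the
  # low-GEI non-crossover target
  grid <- data.frame(rho = c(0.5, 0.2, 0.0), gamma_skew = c(-0.5, -0.5, -0.35),
                     k = 7)
  ranked <- tune_to_targets(c(v_n = 0.61), grid, p = 300, n_seeds = 2,
                            seed = 24)
  expect_equal(ranked$rho[1], 0.5)

  # a target of pure non-crossover variance favours the highest baseline
  grid2 <- data.frame(rho = c(0.05, 0.9), gamma_skew = 0, k = 3)
  ranked2 <- tune_to_targets(c(v_n = 1), grid2, p = 200, n_seeds = 2,
                             seed = 25)
  expect_equal(ranked2$rho[1], 0.9)

  # deterministic ordering under a fixed seed
  ranked3 <- tune_to_targets(c(v_g = 0.5), grid2, p = 200, n_seeds = 2,
                             seed = 26)
  ranked4 <- tune_to_targets(c(v_g = 0.5), grid2, p = 200, n_seeds = 2,
                             seed = 26)
  expect_identical(ranked3, ranked4)

  expect_error(tune_to_targets(c(v_n = 0.5), data.frame()), "non-empty")
  expect_error(tune_to_targets(c(bogus = 0.5), grid), "target names")
})
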