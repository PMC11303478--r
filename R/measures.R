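#' Partition a between-environment covariance into variance-explained measures
#'
#' Quantifies the structure simulated in a between-environment genetic
#' variance matrix `Ge`:
#'
#' * main effect variance `sigma2_g` — the mean element of `Ge`, i.e. the
#'   variance of the genotype main effects (averages across
#'   environments);
#' * interaction variance `sigma2_ge` — mean diagonal element minus
#'   `sigma2_g`;
#' * the classical partition of `sigma2_ge` into heterogeneity of genetic
#'   variance `sigma2_ge_h = mean(s2_j) - mean(s_j)^2` and lack of
#'   genetic correlation `sigma2_ge_l = sigma2_ge - sigma2_ge_h`;
#' * non-crossover variance `sigma2_n = mean(rho*_j^2 * s2_j)`, the
#'   genetic variance in each environment attributed to perfect positive
#'   correlation with the genotype main effects, where
#'   `rho*_j = rowmean_j(Ge) / (s_j * sqrt(sigma2_g))`; and crossover
#'   variance `sigma2_c` as the remainder.
#'
#' Proportions `v_g`, `v_ge`, `v_n`, `v_c` divide by the total (mean
#' diagonal) variance. The mean genetic variance and mean off-diagonal
#' correlation are reported alongside, mirroring the summary columns used
#' to classify low/moderate/high GEI scenarios.
#'
#' @param Ge An `env_covariance` object or symmetric PSD `p x p` matrix
#'   with `p >= 2`.
#'
#' @return An object of class `variance_decomposition`: a list with
#'   `sigma2_g`, `sigma2_ge`, `sigma2_ge_h`, `sigma2_ge_l`, `sigma2_n`,
#'   `sigma2_c`, proportions `v_g`, `v_ge`, `v_n`, `v_c`,
#'   `mean_variance`, `mean_correlation` and the per-environment
#'   main-effect correlations `env_main_correlations`.
#' @export
#' @examples
#' variance_decomposition(diag(2))
variance_decomposition <- function(Ge) {
  m <- if (inherits(Ge, "env_covariance")) Ge$matrix else Ge
  if (!is_symmetric_matrix(m, tol = 1e-8)) {
    stop("`Ge` must be a symmetric matrix", call. = FALSE)
  }
  p <- nrow(m)
  if (p < 2) stop("`Ge` must cover at least 2 environments", call. = FALSE)
  s2 <- diag(m)
  total <- mean(s2)
  if (total <= 0) {
    stop("`Ge` has zero total genetic variance", call. = FALSE)
  }
  sigma2_g <- mean(m)
  sigma2_ge <- total - sigma2_g
  sigma2_ge_h <- mean(s2) - mean(sqrt(s2))^2
  sigma2_ge_l <- sigma2_ge - sigma2_ge_h

  row_means <- rowMeans(m)
  zero_var <- s2 <= 0
  if (any(zero_var)) {
    warning(sprintf("%d environment(s) have zero genetic variance; their ",
                    sum(zero_var)),
            "main-effect correlations are set to 0 and they are excluded ",
            "from the mean correlation", call. = FALSE)
  }
  rho_star <- ifelse(zero_var, 0, row_means / (sqrt(s2) * sqrt(sigma2_g)))
  sigma2_n <- mean(rho_star^2 * s2)
  sigma2_c <- total - sigma2_n

  # mean off-diagonal genetic correlation
  if (inherits(Ge, "env_covariance")) {
    Cm <- Ge$correlations
  } else {
    d <- sqrt(ifelse(zero_var, 1, s2))
    Cm <- m / tcrossprod(d)
  }
  keep <- !zero_var
  off <- Cm[keep, keep, drop = FALSE]
  mean_correlation <- mean(off[upper.tri(off)])

  structure(list(
    sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
    sigma2_ge_h = sigma2_ge_h, sigma2_ge_l = sigma2_ge_l,
    sigma2_n = sigma2_n, sigma2_c = sigma2_c,
    v_g = sigma2_g / total, v_ge = sigma2_ge / total,
    v_n = sigma2_n / total, v_c = sigma2_c / total,
    mean_variance = total, mean_correlation = mean_correlation,
    env_main_correlations = setNames(rho_star, rownames(m))
  ), class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, digits = 2, ...) {
  cat("Variance-explained measures\n")
  row <- c(v_g = x$v_g, v_ge = x$v_ge, v_n = x$v_n, v_c = x$v_c,
           mean_var = x$mean_variance, mean_cor = x$mean_correlation,
           ge_h = x$sigma2_ge_h, ge_l = x$sigma2_ge_l)
  print(round(row, digits))
  invisible(x)
}

#' Population heterogeneity-of-variance for gamma-distributed variances
#'
#' Closed-form expectation of the heterogeneity-of-genetic-variance
#' component when the environment variances are `Gamma(shape, scale)`:
#' `E(s2) - E(s)^2 = shape*scale - scale * (Gamma(shape + 1/2) / Gamma(shape))^2`,
#' using the gamma half-moment `E(s) = sqrt(scale) * Gamma(shape + 1/2) / Gamma(shape)`.
#' This is the analytic companion to the sample statistic computed by
#' [variance_decomposition()].
#'
#' @param spec A [variance_spec()], or a gamma shape if `scale` given.
#' @param scale Gamma scale (ignored when `spec` is a `variance_spec`).
#'
#' @return The population value of `sigma2_ge_h` (a single number).
#' @export
#' @examples
#' heterogeneity_closed_form(variance_spec(1, 1.5, 1)) # 0.2268
heterogeneity_closed_form <- function(spec, scale = NULL) {
  if (inherits(spec, "variance_spec")) {
    shape <- spec$shape
    scale <- spec$scale
  } else {
    shape <- spec
    stopifnot_scalar_number(shape, "shape", lower = 0, strict_lower = TRUE)
    stopifnot_scalar_number(scale, "scale", lower = 0, strict_lower = TRUE)
  }
  half_moment <- exp(lgamma(shape + 0.5) - lgamma(shape))
  shape * scale - scale * half_moment^2
}

#' Expected accuracies and MET-TPE alignment
#'
#' Computes the expected (positive) correlations implied by the true
#' simulation parameters for a MET of `n_envs` environments with
#' `n_reps` replicates per environment:
#'
#' * `r_g` — expected genotype main-effect accuracy in the TPE, the
#'   square root of the line-mean heritability across environments;
#' * `r_m` — expected main-effect accuracy in the MET, whose genotype
#'   main-effect variance is inflated by the sampling error
#'   `sigma2_ge / n_envs`;
#' * `r_mt` — expected MET-TPE alignment (`r_g` with the error variance
#'   set to zero), satisfying the identity `r_g = r_m * r_mt`;
#' * `r_ge` — expected accuracy of the GE effects within environments,
#'   the square root of the line-mean heritability within environments.
#'
#' @param sigma2_g Genotype main-effect variance (>= 0).
#' @param sigma2_ge Interaction variance (>= 0).
#' @param sigma2_eps Mean plot error variance (>= 0).
#' @param n_envs Number of environments sampled in the MET (>= 1).
#' @param n_reps Number of replicates per environment (>= 1).
#'
#' @return An object of class `accuracy_set`: list with `r_g`, `r_m`,
#'   `r_mt`, `r_ge` and the echoed inputs.
#' @export
#' @examples
#' expected_accuracies(1, 1, 2, n_envs = 10, n_reps = 2)
expected_accuracies <- function(sigma2_g, sigma2_ge, sigma2_eps,
                                n_envs, n_reps) {
  stopifnot_scalar_number(sigma2_g, "sigma2_g", lower = 0)
  stopifnot_scalar_number(sigma2_ge, "sigma2_ge", lower = 0)
  stopifnot_scalar_number(sigma2_eps, "sigma2_eps", lower = 0)
  n_envs <- stopifnot_count(n_envs, "n_envs")
  n_reps <- stopifnot_count(n_reps, "n_reps")
  if (sigma2_g + sigma2_ge + sigma2_eps <= 0) {
    stop("all variance components are zero: accuracies are undefined",
         call. = FALSE)
  }
  met_var <- sigma2_g + sigma2_ge / n_envs
  denom <- met_var + sigma2_eps / (n_envs * n_reps)
  r_g <- sqrt(sigma2_g / denom)
  r_m <- sqrt(met_var / denom)
  r_mt <- if (met_var > 0) sqrt(sigma2_g / met_var) else 0
  r_ge <- sqrt((sigma2_g + sigma2_ge) /
                 (sigma2_g + sigma2_ge + sigma2_eps / n_reps))
  structure(list(r_g = r_g, r_m = r_m, r_mt = r_mt, r_ge = r_ge,
                 sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
                 sigma2_eps = sigma2_eps, n_envs = n_envs, n_reps = n_reps),
            class = "accuracy_set")
}

#' @export
print.accuracy_set <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Expected accuracies (n_envs = %d, n_reps = %d)\n", x$n_envs, x$n_reps))
  print(round(c(r_g = x$r_g, r_m = x$r_m, r_mt = x$r_mt, r_ge = x$r_ge),
              digits))
  invisible(x)
}

#' Rank candidate TPE parameters against target measures
#'
#' Evaluates a grid of correlation-structure parameters by Monte-Carlo,
#' averaging the variance-explained measures over several seeds, and
#' ranks the grid points by Euclidean distance of the estimated measures
#' to the requested targets. Used to tune `rho`, `epsilon` and
#' `gamma_skew` towards desired proportions of main-effect or
#' non-crossover variance.
#'
#' @param targets Named numeric vector of desired measures, e.g.
#'   `c(v_n = 0.61)`; admissible names are `v_g`, `v_ge`, `v_n`, `v_c`,
#'   `mean_correlation`.
#' @param grid Data frame of candidate parameters with columns `rho`,
#'   `epsilon` (optional, default `1 - rho`), `gamma_skew` and `k`.
#' @param p Number of environments used for evaluation.
#' @param shape,scale Gamma parameters for the genetic variances.
#' @param n_seeds Number of Monte-Carlo replicates per grid point.
#' @param seed Optional integer root seed.
#'
#' @return The grid, ordered best-first, with the seed-averaged measure
#'   estimates and the `distance` to the targets appended.
#' @export
tune_to_targets <- function(targets, grid, p = 500, shape = 1.5, scale = 1,
                            n_seeds = 5, seed = NULL) {
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("`targets` must be a named numeric vector", call. = FALSE)
  }
  ok <- c("v_g", "v_ge", "v_n", "v_c", "mean_correlation")
  if (!all(names(targets) %in% ok)) {
    stop("target names must be among: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("`grid` must be a non-empty data frame", call. = FALSE)
  }
  if (is.null(grid$epsilon)) grid$epsilon <- 1 - grid$rho
  est <- matrix(NA_real_, nrow(grid), length(targets),
                dimnames = list(NULL, names(targets)))
  for (i in seq_len(nrow(grid))) {
    acc <- matrix(0, n_seeds, length(targets))
    for (s in seq_len(n_seeds)) {
      tpe <- simulate_tpe(
        p = p, shape = shape, scale = scale, rho = grid$rho[i],
        epsilon = grid$epsilon[i], gamma_skew = grid$gamma_skew[i],
        k = grid$k[i], enforce_rank = abs(grid$epsilon[i] - (1 - grid$rho[i])) < 1e-12,
        seed = spawn_seed(seed, sprintf("tune-%d-%d", i, s)) %||% NULL)
      vd <- variance_decomposition(tpe)
      acc[s, ] <- unlist(vd[names(targets)])
    }
    est[i, ] <- colMeans(acc)
  }
  out <- cbind(grid, as.data.frame(est))
  out$distance <- sqrt(rowSums(sweep(est, 2, targets)^2))
  out[order(out$distance), , drop = FALSE]
}
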