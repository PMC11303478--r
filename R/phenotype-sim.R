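#' Define a multi-environment trial design
#'
#' A randomised complete block design (RCBD) with `n_genotypes` genotypes
#' in each of `n_blocks` blocks within each of `n_envs` environments, so
#' the total plot count is `n_genotypes * n_envs * n_blocks`. Optional
#' row/column dimensions per environment enable spatially correlated plot
#' errors; they must satisfy `n_rows * n_cols = n_genotypes * n_blocks`,
#' with blocks laid out as contiguous column ranges and plots ordered
#' row-major.
#'
#' @param n_genotypes Number of genotypes `v`.
#' @param n_envs Number of environments `p_m`.
#' @param n_blocks Number of replicate blocks `r`.
#' @param mu Overall trait mean (trait units).
#' @param n_rows,n_cols Optional field layout per environment.
#'
#' @return An object of class `trial_design`.
#' @export
#' @examples
#' trial_design(n_genotypes = 400, n_envs = 10, n_blocks = 2, mu = 4)
trial_design <- function(n_genotypes, n_envs, n_blocks, mu = 0,
                         n_rows = NULL, n_cols = NULL) {
  v <- stopifnot_count(n_genotypes, "n_genotypes")
  p_m <- stopifnot_count(n_envs, "n_envs")
  r <- stopifnot_count(n_blocks, "n_blocks")
  stopifnot_scalar_number(mu, "mu")
  if (xor(is.null(n_rows), is.null(n_cols))) {
    stop("supply both `n_rows` and `n_cols`, or neither", call. = FALSE)
  }
  if (!is.null(n_rows)) {
    n_rows <- stopifnot_count(n_rows, "n_rows")
    n_cols <- stopifnot_count(n_cols, "n_cols")
    if (n_rows * n_cols != v * r) {
      stop(sprintf("field layout %d x %d does not hold %d plots",
                   n_rows, n_cols, v * r), call. = FALSE)
    }
    if (n_cols %% r != 0) {
      stop("`n_cols` must be divisible by `n_blocks` (blocks are contiguous ",
           "column ranges)", call. = FALSE)
    }
  }
  structure(list(n_genotypes = v, n_envs = p_m, n_blocks = r, mu = mu,
                 n_rows = n_rows, n_cols = n_cols,
                 n_plots = v * p_m * r, design = "RCBD"),
            class = "trial_design")
}

#' Simulate environmental main effects
#'
#' In `iid` mode the environment means are drawn `N(0, sigma2_e)`. In
#' regression mode they are the deterministic projection
#' `tau = S_k rows %*% tau_s` of the sampled environments' covariates on
#' the mean genotype responses `tau_s`, which induces a mean-variance
#' relationship and lets genetic gain be tracked through the environment
#' means in a breeding programme.
#'
#' @param n_envs Number of environments.
#' @param sigma2_e Environmental main-effect variance (iid mode).
#' @param covariates Optional `n_envs x k` matrix of environmental
#'   covariates (rows of `S_k` for the sampled environments).
#' @param tau_s Optional `k`-vector of mean genotype responses to each
#'   covariate; requires `covariates`.
#' @param seed Optional integer seed (iid mode only).
#'
#' @return Numeric vector of `n_envs` environment main effects.
#' @export
simulate_environment_means <- function(n_envs, sigma2_e = 1,
                                       covariates = NULL, tau_s = NULL,
                                       seed = NULL) {
  n_envs <- stopifnot_count(n_envs, "n_envs")
  if (!is.null(tau_s)) {
    if (is.null(covariates)) {
      stop("regression mode requires `covariates` for the sampled ",
           "environments", call. = FALSE)
    }
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_envs || ncol(covariates) != length(tau_s)) {
      stop("`covariates` must be n_envs x length(tau_s)", call. = FALSE)
    }
    return(drop(covariates %*% tau_s))
  }
  stopifnot_scalar_number(sigma2_e, "sigma2_e", lower = 0)
  with_seed_(seed, rnorm(n_envs, mean = 0, sd = sqrt(sigma2_e)))
}

#' Specify the plot-error model
#'
#' Plot errors are normal with mean error variance `sigma2_eps` across
#' environments. By default the per-environment error variances are
#' heterogeneous, drawn from a gamma distribution rescaled to mean
#' `sigma2_eps` with coefficient of variation `cv` (fixed variances are
#' obtained with `cv = 0` or by supplying `per_env_variances`). Errors
#' are independent between plots unless autoregressive row/column
#' parameters are given, in which case the within-environment correlation
#' is the separable product of two first-order autoregressive processes
#' over the field layout.
#'
#' @param sigma2_eps Mean plot error variance across environments (>= 0).
#' @param per_env_variances Optional vector of per-environment error
#'   variances (overrides the gamma draw).
#' @param cv Coefficient of variation of the per-environment variances
#'   around `sigma2_eps` (default 0.05, matching mild field-to-field
#'   heterogeneity; 0 gives equal variances).
#' @param ar_row,ar_col Optional AR(1) correlation parameters in (-1, 1)
#'   for rows and columns of the field layout.
#'
#' @return An object of class `plot_error_spec`.
#' @export
plot_error_spec <- function(sigma2_eps, per_env_variances = NULL, cv = 0.05,
                            ar_row = NULL, ar_col = NULL) {
  stopifnot_scalar_number(sigma2_eps, "sigma2_eps", lower = 0)
  stopifnot_scalar_number(cv, "cv", lower = 0)
  if (!is.null(per_env_variances) &&
      (any(!is.finite(per_env_variances)) || any(per_env_variances < 0))) {
    stop("`per_env_variances` must be non-negative", call. = FALSE)
  }
  spatial <- !is.null(ar_row) || !is.null(ar_col)
  if (spatial) {
    if (is.null(ar_row)) ar_row <- 0
    if (is.null(ar_col)) ar_col <- 0
    stopifnot_scalar_number(ar_row, "ar_row", lower = -1, upper = 1,
                            strict_lower = TRUE, strict_upper = TRUE)
    stopifnot_scalar_number(ar_col, "ar_col", lower = -1, upper = 1,
                            strict_lower = TRUE, strict_upper = TRUE)
  }
  structure(list(sigma2_eps = sigma2_eps,
                 per_env_variances = per_env_variances, cv = cv,
                 spatial = spatial, ar_row = ar_row, ar_col = ar_col),
            class = "plot_error_spec")
}

ar1_chol <- function(n, rho) {
  # upper Cholesky factor of an AR(1) correlation matrix
  R <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  chol(R)
}

#' Simulate plot errors for a trial design
#'
#' Draws the plot errors for every environment of the design. In
#' independent mode the errors are iid normal within each environment
#' with that environment's error variance; in spatial mode the
#' within-environment correlation is the separable AR(1) x AR(1)
#' structure over the field layout (plots ordered row-major within an
#' environment). Per-environment variances follow the heterogeneity rule
#' in [plot_error_spec()] and are attached as the
#' `"per_env_variances"` attribute.
#'
#' @param design A [trial_design()].
#' @param spec A [plot_error_spec()].
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of `n_plots` errors ordered environment-major
#'   (within environment: block-major, or row-major in spatial mode —
#'   both index plots identically, see [build_met_dataset()]).
#' @export
simulate_plot_errors <- function(design, spec, seed = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(spec, "plot_error_spec"))
  p_m <- design$n_envs
  plots_per_env <- design$n_genotypes * design$n_blocks
  if (spec$spatial && is.null(design$n_rows)) {
    stop("spatial errors require `n_rows`/`n_cols` in the trial design",
         call. = FALSE)
  }
  with_seed_(seed, {
    s2 <- spec$per_env_variances
    if (is.null(s2)) {
      if (spec$cv > 0 && spec$sigma2_eps > 0) {
        shape <- 1 / spec$cv^2
        s2 <- rgamma(p_m, shape = shape, scale = spec$sigma2_eps / shape)
      } else {
        s2 <- rep(spec$sigma2_eps, p_m)
      }
    } else if (length(s2) != p_m) {
      stop(sprintf("`per_env_variances` has length %d but %d environments",
                   length(s2), p_m), call. = FALSE)
    }
    eps <- vector("list", p_m)
    if (spec$spatial) {
      Lr <- ar1_chol(design$n_rows, spec$ar_row)
      Lc <- ar1_chol(design$n_cols, spec$ar_col)
      for (j in seq_len(p_m)) {
        Z <- matrix(rnorm(design$n_rows * design$n_cols),
                    design$n_rows, design$n_cols)
        X <- t(Lr) %*% Z %*% Lc # matrix-normal: AR1(rows) x AR1(cols)
        eps[[j]] <- sqrt(s2[j]) * as.vector(t(X)) # row-major plot order
      }
    } else {
      for (j in seq_len(p_m)) {
        eps[[j]] <- rnorm(plots_per_env, sd = sqrt(s2[j]))
      }
    }
    structure(unlist(eps), per_env_variances = s2)
  })
}

#' Error variance for a target plot-level heritability
#'
#' Solves `H2 = s2_g / (s2_g + s2_eps)` for the mean error variance:
#' `s2_eps = s2_g * (1 - H2) / H2`.
#'
#' @param mean_genetic_variance Mean genetic variance across environments.
#' @param h2 Target plot-level heritability in (0, 1).
#'
#' @return The implied mean plot error variance.
#' @export
#' @examples
#' error_variance_from_heritability(1.73, 0.3) # about 4.03
error_variance_from_heritability <- function(mean_genetic_variance, h2) {
  stopifnot_scalar_number(mean_genetic_variance, "mean_genetic_variance",
                          lower = 0)
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
    stop("`h2` must lie strictly between 0 and 1", call. = FALSE)
  }
  mean_genetic_variance * (1 - h2) / h2
}

#' Assemble a plot-level MET dataset
#'
#' Combines the sampled GE effects, environment main effects and plot
#' errors in the linear mixed model
#' `phenotype = mu + tau_j + u_ij + eps_plot` under an RCBD: each
#' genotype appears exactly once in each block of each environment. Rows
#' are ordered environment, block, genotype, matching the plot order of
#' [simulate_plot_errors()].
#'
#' @param u_sampled `v x p_m` matrix of GE effects for the sampled
#'   environments (columns named by environment).
#' @param tau Vector of `p_m` environment main effects.
#' @param errors Vector of `n_plots` plot errors (see
#'   [simulate_plot_errors()]).
#' @param design A [trial_design()].
#'
#' @return A data frame of class `met_dataset` with columns `env`,
#'   `block`, `genotype`, `true_ge` and `phenotype`, and attributes
#'   `mu`, `tau` and `per_env_error_variances` (when available).
#' @export
build_met_dataset <- function(u_sampled, tau, errors, design) {
  stopifnot(inherits(design, "trial_design"))
  v <- design$n_genotypes
  p_m <- design$n_envs
  r <- design$n_blocks
  if (!is.matrix(u_sampled) || nrow(u_sampled) != v || ncol(u_sampled) != p_m) {
    stop(sprintf("`u_sampled` must be %d x %d", v, p_m), call. = FALSE)
  }
  if (length(tau) != p_m) {
    stop(sprintf("`tau` must have length %d", p_m), call. = FALSE)
  }
  if (length(errors) != design$n_plots) {
    stop(sprintf("`errors` must have length %d", design$n_plots),
         call. = FALSE)
  }
  env_names <- colnames(u_sampled) %||% env_labels(p_m)
  geno_names <- rownames(u_sampled) %||% geno_labels(v)
  env <- rep(env_names, each = v * r)
  block <- rep(rep(seq_len(r), each = v), times = p_m)
  genotype <- rep(geno_names, times = p_m * r)
  true_ge <- unlist(lapply(seq_len(p_m),
                           function(j) rep(u_sampled[, j], times = r)),
                    use.names = FALSE)
  tau_plot <- rep(tau, each = v * r)
  phenotype <- design$mu + tau_plot + true_ge + as.numeric(errors)
  out <- data.frame(env = factor(env, levels = env_names),
                    block = block, genotype = genotype,
                    true_ge = true_ge, phenotype = phenotype,
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- design$mu
  attr(out, "tau") <- setNames(tau, env_names)
  pev <- attr(errors, "per_env_variances")
  if (!is.null(pev)) {
    attr(out, "per_env_error_variances") <- setNames(pev, env_names)
  }
  class(out) <- c("met_dataset", "data.frame")
  out
}

#' Summarise a MET dataset environment by environment
#'
#' Produces a per-environment table of the number of genotypes, blocks
#' and plots, the mean phenotype, the realised genetic variance (variance
#' of the true GE effects among genotypes), the error variance (the
#' simulated per-environment variance when stored, otherwise the
#' empirical residual variance) and the plot-level heritability
#' `H2_j = s2_gj / (s2_gj + s2_epsj)`. The overall row reports the total
#' plot count and the means of the per-environment columns (so the
#' overall heritability is the mean of the per-environment
#' heritabilities, not a pooled ratio).
#'
#' @param dataset A `met_dataset` from [build_met_dataset()].
#'
#' @return Data frame with one row per environment plus an `Overall` row.
#' @export
summarise_met <- function(dataset) {
  if (!inherits(dataset, "met_dataset")) {
    stop("`dataset` must be a met_dataset (truth columns and attributes ",
         "are required)", call. = FALSE)
  }
  mu <- attr(dataset, "mu")
  tau <- attr(dataset, "tau")
  pev <- attr(dataset, "per_env_error_variances")
  envs <- levels(dataset$env)
  rows <- lapply(envs, function(e) {
    d <- dataset[dataset$env == e, ]
    u_e <- d$true_ge[!duplicated(d$genotype)]
    s2g <- var(u_e)
    s2e <- if (!is.null(pev)) {
      pev[[e]]
    } else {
      var(d$phenotype - mu - tau[[e]] - d$true_ge)
    }
    data.frame(env = e,
               n_genotypes = length(unique(d$genotype)),
               n_blocks = length(unique(d$block)),
               n_plots = nrow(d),
               mean = mean(d$phenotype),
               sigma2_g = s2g,
               sigma2_eps = s2e,
               h2 = s2g / (s2g + s2e))
  })
  tab <- do.call(rbind, rows)
  overall <- data.frame(env = "Overall",
                        n_genotypes = mean(tab$n_genotypes),
                        n_blocks = mean(tab$n_blocks),
                        n_plots = sum(tab$n_plots),
                        mean = mean(tab$mean),
                        sigma2_g = mean(tab$sigma2_g),
                        sigma2_eps = mean(tab$sigma2_eps),
                        h2 = mean(tab$h2))
  rbind(tab, overall)
}

#' Simulate a MET dataset from a TPE in one call
#'
#' Orchestrates the full pipeline: decompose the TPE covariance, simulate
#' genotype slopes, construct GE effects, sample `n_envs` environments,
#' draw environment means and plot errors, and assemble the plot-level
#' dataset. The error variance is set from a target plot-level
#' heritability via [error_variance_from_heritability()] unless
#' `sigma2_eps` is given directly.
#'
#' @param tpe An `env_covariance` object (see [simulate_tpe()]).
#' @param n_genotypes,n_envs,n_blocks Trial dimensions.
#' @param mu Overall trait mean.
#' @param h2 Target plot-level heritability (ignored when `sigma2_eps`
#'   given).
#' @param sigma2_eps Optional mean plot error variance.
#' @param sigma2_e Environmental main-effect variance.
#' @param k Number of multiplicative terms (default: TPE rank hint).
#' @param error_cv Coefficient of variation of per-environment error
#'   variances (see [plot_error_spec()]).
#' @param seed Optional integer root seed; child streams are derived for
#'   slopes, sampling, environment means and errors.
#'
#' @return A list with `dataset` (the `met_dataset`), `sample` (the
#'   `tpe_sample`), `u` (full `v x p` GE effects), `terms` and `summary`
#'   (from [summarise_met()]).
#' @export
#' @examples
#' tpe <- simulate_tpe(p = 100, rho = 0.5, gamma_skew = -0.5, k = 7, seed = 1)
#' met <- simulate_met_dataset(tpe, n_genotypes = 50, n_envs = 5,
#'                             n_blocks = 2, mu = 4, h2 = 0.3, seed = 2)
#' head(met$dataset)
simulate_met_dataset <- function(tpe, n_genotypes, n_envs, n_blocks,
                                 mu = 0, h2 = 0.3, sigma2_eps = NULL,
                                 sigma2_e = 1, k = NULL, error_cv = 0.05,
                                 seed = NULL) {
  stopifnot(inherits(tpe, "env_covariance"))
  terms <- decompose_covariance(tpe, k = k)
  slopes <- simulate_slopes(terms, v = n_genotypes,
                            seed = spawn_seed(seed, "slopes"))
  u <- construct_ge_effects(terms, slopes)
  smp <- sample_tpe(u, n_envs, seed = spawn_seed(seed, "sampling"),
                    Ge = tpe, sigma2_eps = sigma2_eps, n_reps = n_blocks)
  design <- trial_design(n_genotypes, n_envs, n_blocks, mu = mu)
  tau <- simulate_environment_means(n_envs, sigma2_e = sigma2_e,
                                    seed = spawn_seed(seed, "tau"))
  if (is.null(sigma2_eps)) {
    sigma2_eps <- error_variance_from_heritability(
      mean(diag(tpe$matrix)[smp$environments]), h2)
  }
  errors <- simulate_plot_errors(design,
                                 plot_error_spec(sigma2_eps, cv = error_cv),
                                 seed = spawn_seed(seed, "errors"))
  dataset <- build_met_dataset(smp$u_sampled, tau, errors, design)
  list(dataset = dataset, sample = smp, u = u, terms = terms,
       summary = summarise_met(dataset))
}
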