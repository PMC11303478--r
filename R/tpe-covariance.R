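#' Specification of between-environment genetic variances
#'
#' Describes the gamma distribution from which the environment-specific
#' genetic variances of a hypothetical target population of environments
#' (TPE) are drawn. The gamma distribution produces strictly positive
#' variances with realistic right skew; its mean `shape * scale`
#' approaches the mean genetic variance across environments as the number
#' of environments grows.
#'
#' @param p Number of environments in the TPE (integer >= 1).
#' @param shape Gamma shape parameter (> 0).
#' @param scale Gamma scale parameter, in variance units (> 0).
#'
#' @return An object of class `variance_spec`.
#' @seealso [simulate_genetic_variances()], [correlation_spec()]
#' @export
#' @examples
#' variance_spec(p = 1000, shape = 1.5, scale = 1)
variance_spec <- function(p, shape = 1.5, scale = 1) {
  p <- stopifnot_count(p, "p")
  stopifnot_scalar_number(shape, "shape", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(scale, "scale", lower = 0, strict_lower = TRUE)
  structure(list(p = p, shape = shape, scale = scale),
            class = "variance_spec")
}

#' Specification of the between-environment genetic correlation structure
#'
#' Describes the reduced-rank correlation matrix
#' `Ce = rho * J + epsilon * t(Lambda) %*% Lambda`, where `J` is the
#' all-ones matrix and `Lambda` is a `(k-1) x p` matrix of unit-length
#' latent covariate columns. `rho` is the baseline genetic correlation,
#' `epsilon` the magnitude of structured noise around it and `gamma_skew`
#' controls the negative skew of the resulting correlation distribution.
#' When `enforce_rank = TRUE`, `epsilon` is fixed at `1 - rho`, the
#' diagonal equals one exactly and `Ce` has rank `k`; otherwise
#' `epsilon < 1 - rho` is allowed and the diagonal is reset to one, giving
#' a full-rank matrix whose trailing terms each carry a small proportion
#' `1 - rho - epsilon` of variance.
#'
#' @param p Number of environments (integer >= 1).
#' @param rho Baseline genetic correlation, `0 <= rho < 1`. Negative
#'   baselines are rejected because they can yield indefinite matrices
#'   that would need bending, which breaks the rank guarantee.
#' @param epsilon Magnitude of structured noise; defaults to `1 - rho`.
#' @param gamma_skew Skew parameter in `[-1, 0]`; more negative values
#'   shift correlations upwards and skew their distribution left.
#' @param k Target rank of `Ce` (integer >= 2).
#' @param enforce_rank If `TRUE` (default) force `epsilon = 1 - rho` so
#'   that `Ce` has rank exactly `k`.
#'
#' @return An object of class `correlation_spec`.
#' @seealso [simulate_correlation_matrix()]
#' @export
#' @examples
#' correlation_spec(p = 1000, rho = 0.5, gamma_skew = -0.5, k = 7)
correlation_spec <- function(p, rho, epsilon = NULL, gamma_skew = 0, k = 7,
                             enforce_rank = is.null(epsilon)) {
  p <- stopifnot_count(p, "p")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must satisfy 0 <= rho < 1: negative baselines can produce ",
         "indefinite correlation matrices (positive semi-definiteness is ",
         "only guaranteed on [0, 1))", call. = FALSE)
  }
  stopifnot_scalar_number(gamma_skew, "gamma_skew", lower = -1, upper = 0)
  k <- stopifnot_count(k, "k", lower = 2L)
  if (enforce_rank) {
    epsilon <- 1 - rho
  } else {
    if (is.null(epsilon)) epsilon <- 1 - rho
    stopifnot_scalar_number(epsilon, "epsilon", lower = 0)
    if (epsilon > 1 - rho + 1e-12) {
      stop(sprintf("`epsilon` = %g exceeds 1 - rho = %g", epsilon, 1 - rho),
           call. = FALSE)
    }
  }
  structure(list(p = p, rho = rho, epsilon = epsilon,
                 gamma_skew = gamma_skew, k = k,
                 enforce_rank = enforce_rank),
            class = "correlation_spec")
}

#' Simulate environment-specific genetic variances
#'
#' Draws `p` independent genetic variances from the gamma distribution in
#' `spec`, one per environment of the TPE.
#'
#' @param spec A [variance_spec()].
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Numeric vector of `p` strictly positive variances, named
#'   `E1..Ep`.
#' @export
#' @examples
#' v <- simulate_genetic_variances(variance_spec(1000, 1.5, 1), seed = 1)
#' mean(v) # close to shape * scale = 1.5
simulate_genetic_variances <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "variance_spec"))
  v <- with_seed_(seed, rgamma(spec$p, shape = spec$shape, scale = spec$scale))
  names(v) <- env_labels(spec$p)
  v
}

#' Simulate latent covariates for the correlation generator
#'
#' Draws the `(k-1) x p` latent covariate matrix used to build the
#' structured-noise part of the correlation matrix. Each column is drawn
#' elementwise from `U(-1, 1 + gamma_skew)` and scaled to unit Euclidean
#' length; negative `gamma_skew` makes the columns point coherently, which
#' raises and left-skews the pairwise correlations. Columns are drawn in
#' environment order so a TPE can be extended reproducibly.
#'
#' @param p Number of environments.
#' @param k Target rank (integer >= 2); the matrix has `k - 1` rows.
#' @param gamma_skew Skew parameter in `[-1, 0]`.
#' @param seed Optional integer seed.
#'
#' @return A `(k-1) x p` matrix with unit-length columns.
#' @export
simulate_latent_covariates <- function(p, k, gamma_skew = 0, seed = NULL) {
  p <- stopifnot_count(p, "p")
  k <- stopifnot_count(k, "k", lower = 2L)
  stopifnot_scalar_number(gamma_skew, "gamma_skew", lower = -1, upper = 0)
  with_seed_(seed, {
    lam <- matrix(runif((k - 1) * p, min = -1, max = 1 + gamma_skew),
                  nrow = k - 1, ncol = p)
    nrm <- sqrt(colSums(lam^2))
    while (any(nrm == 0)) { # probability-zero guard
      bad <- which(nrm == 0)
      lam[, bad] <- runif((k - 1) * length(bad), -1, 1 + gamma_skew)
      nrm <- sqrt(colSums(lam^2))
    }
    sweep(lam, 2, nrm, "/")
  })
}

#' Simulate a reduced-rank between-environment genetic correlation matrix
#'
#' Builds `Ce = rho * J + epsilon * t(Lambda) %*% Lambda` from a
#' [correlation_spec()]. With the rank constraint `epsilon = 1 - rho` the
#' diagonal is one exactly and `rank(Ce) = k`; otherwise the diagonal is
#' reset to one and `Ce` is full rank. A user-supplied base matrix may
#' replace `rho * J` to impose other baseline structures.
#'
#' @param spec A [correlation_spec()].
#' @param seed Optional integer seed.
#' @param Lambda Optional pre-built `(k-1) x p` latent covariate matrix
#'   with unit-length columns (overrides simulation).
#' @param base Optional `p x p` baseline correlation matrix replacing
#'   `rho * J`; it is the caller's responsibility that the result is a
#'   valid correlation matrix (see [bend_to_psd()]).
#'
#' @return A `p x p` correlation matrix with `E1..Ep` dimnames.
#' @export
#' @examples
#' Ce <- simulate_correlation_matrix(
#'   correlation_spec(p = 500, rho = 0.5, gamma_skew = 0, k = 7), seed = 1)
#' mean(Ce[upper.tri(Ce)]) # approaches rho when gamma_skew = 0
simulate_correlation_matrix <- function(spec, seed = NULL, Lambda = NULL,
                                        base = NULL) {
  stopifnot(inherits(spec, "correlation_spec"))
  p <- spec$p
  if (is.null(Lambda)) {
    Lambda <- simulate_latent_covariates(p, spec$k, spec$gamma_skew,
                                         seed = seed)
  } else {
    if (!is.matrix(Lambda) || nrow(Lambda) != spec$k - 1L ||
        ncol(Lambda) != p) {
      stop("`Lambda` must be a (k-1) x p matrix", call. = FALSE)
    }
  }
  if (is.null(base)) {
    base <- matrix(spec$rho, p, p)
  } else if (!is_symmetric_matrix(base) || nrow(base) != p) {
    stop("`base` must be a symmetric p x p matrix", call. = FALSE)
  }
  Ce <- base + spec$epsilon * crossprod(Lambda)
  Ce <- (Ce + t(Ce)) / 2
  diag(Ce) <- 1
  dimnames(Ce) <- list(env_labels(p), env_labels(p))
  Ce
}

#' Assemble a between-environment genetic variance matrix
#'
#' Combines heterogeneous genetic variances with a correlation matrix as
#' `Ge = D^{1/2} Ce D^{1/2}`, where `D = diag(variances)`.
#'
#' @param variances Vector of `p` positive genetic variances.
#' @param Ce A `p x p` correlation matrix.
#' @param rank_hint Known rank of `Ce` (e.g. `k` when built with the rank
#'   constraint); defaults to `p`.
#'
#' @return An object of class `env_covariance` with elements `matrix`
#'   (the `p x p` covariance), `variances`, `correlations` and
#'   `rank_hint`.
#' @export
#' @examples
#' Ge <- assemble_covariance(c(4, 1), matrix(c(1, .5, .5, 1), 2))
#' Ge$matrix
assemble_covariance <- function(variances, Ce, rank_hint = NULL) {
  if (!is.numeric(variances) || any(!is.finite(variances)) ||
      any(variances <= 0)) {
    stop("`variances` must be strictly positive and finite", call. = FALSE)
  }
  if (!is_symmetric_matrix(Ce, tol = 1e-8)) {
    stop("`Ce` must be a symmetric matrix", call. = FALSE)
  }
  p <- length(variances)
  if (nrow(Ce) != p) {
    stop(sprintf("dimension mismatch: %d variances but %d x %d correlation",
                 p, nrow(Ce), ncol(Ce)), call. = FALSE)
  }
  if (max(abs(diag(Ce) - 1)) > 1e-8) {
    stop("`Ce` must have unit diagonal", call. = FALSE)
  }
  sv <- sqrt(as.numeric(variances))
  Ge <- Ce * tcrossprod(sv)
  diag(Ge) <- as.numeric(variances)
  dimnames(Ge) <- list(env_labels(p), env_labels(p))
  structure(list(matrix = Ge,
                 variances = setNames(as.numeric(variances), env_labels(p)),
                 correlations = Ce,
                 rank_hint = if (is.null(rank_hint)) p else as.integer(rank_hint)),
            class = "env_covariance")
}

#' Simulate a complete TPE covariance matrix
#'
#' Convenience wrapper running the whole TPE construction under one seed:
#' gamma genetic variances, latent covariates, reduced-rank correlation
#' matrix, and the assembled covariance `Ge = D^{1/2} Ce D^{1/2}`.
#'
#' @param p Number of environments.
#' @param shape,scale Gamma parameters for the genetic variances.
#' @param rho,epsilon,gamma_skew,k,enforce_rank Correlation structure
#'   parameters, see [correlation_spec()].
#' @param seed Optional integer root seed; child seeds are derived for the
#'   variance and correlation streams so either can be re-run alone.
#'
#' @return An `env_covariance` object (see [assemble_covariance()]).
#' @export
#' @examples
#' tpe <- simulate_tpe(p = 200, rho = 0.5, gamma_skew = -0.5, k = 7, seed = 1)
#' variance_decomposition(tpe)
simulate_tpe <- function(p, shape = 1.5, scale = 1, rho = 0.5,
                         epsilon = NULL, gamma_skew = 0, k = 7,
                         enforce_rank = is.null(epsilon), seed = NULL) {
  vspec <- variance_spec(p, shape, scale)
  cspec <- correlation_spec(p, rho, epsilon, gamma_skew, k, enforce_rank)
  variances <- simulate_genetic_variances(vspec, seed = spawn_seed(seed, "tpe-variances"))
  Ce <- simulate_correlation_matrix(cspec, seed = spawn_seed(seed, "tpe-correlations"))
  out <- assemble_covariance(variances, Ce,
                             rank_hint = if (cspec$enforce_rank) cspec$k else p)
  out$variance_spec <- vspec
  out$correlation_spec <- cspec
  out$seed <- seed
  out
}

#' Bend a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Clips eigenvalues below `tolerance` up to `tolerance` and reconstructs
#' the matrix. If the input looks like a correlation matrix (unit
#' diagonal) the result is re-scaled to unit diagonal. Already-PSD input
#' is returned unchanged. Intended for user-supplied covariance matrices;
#' the package's own generator never produces indefinite matrices because
#' negative baseline correlations are rejected.
#'
#' @param m Symmetric numeric matrix.
#' @param tolerance Smallest admissible eigenvalue (default 0).
#'
#' @return A positive semi-definite matrix of the same dimension.
#' @export
bend_to_psd <- function(m, tolerance = 0) {
  if (!is_symmetric_matrix(m, tol = 1e-8)) {
    stop("`m` must be symmetric", call. = FALSE)
  }
  eg <- eigen(m, symmetric = TRUE)
  if (min(eg$values) >= tolerance) {
    return(m)
  }
  is_corr <- max(abs(diag(m) - 1)) <= 1e-8
  vals <- pmax(eg$values, tolerance)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  out <- (out + t(out)) / 2
  if (is_corr) {
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
    diag(out) <- 1
  }
  dimnames(out) <- dimnames(m)
  out
}

#' @export
print.env_covariance <- function(x, ...) {
  p <- length(x$variances)
  cat(sprintf("Between-environment genetic variance matrix (%d environments)\n", p))
  cat(sprintf("  mean genetic variance   : %.3f\n", mean(x$variances)))
  off <- x$correlations[upper.tri(x$correlations)]
  cat(sprintf("  mean genetic correlation: %.3f\n", mean(off)))
  cat(sprintf("  rank hint               : %d\n", x$rank_hint))
  invisible(x)
}
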