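#' Decompose a between-environment covariance into multiplicative terms
#'
#' Eigendecomposes `Ge = U L U'` and retains the first `k` terms, giving
#' the `p x k` matrix of environmental covariates `S_k = U_k` and the
#' `k` term variances `L_k` (eigenvalues in non-increasing order). The
#' proportion of genetic variance explained by term `r` is
#' `l_r / trace(Ge)`. Eigenvector signs are fixed so the
#' largest-magnitude element of each column is positive (ties broken by
#' first index), making the covariates reproducible across platforms.
#'
#' @param Ge An `env_covariance` object or a symmetric PSD matrix.
#' @param k Number of multiplicative terms to retain (default: the
#'   covariance's rank hint, else `p`).
#'
#' @return An object of class `multiplicative_terms` with elements `S`
#'   (`p x k` covariates, orthonormal columns), `L` (`k` term variances),
#'   `variance_explained`, `p` and `k`.
#' @export
#' @examples
#' terms <- decompose_covariance(matrix(c(2, 1, 1, 2), 2), k = 2)
#' terms$L                  # c(3, 1)
#' terms$variance_explained # c(0.75, 0.25)
decompose_covariance <- function(Ge, k = NULL) {
  m <- if (inherits(Ge, "env_covariance")) Ge$matrix else Ge
  if (!is_symmetric_matrix(m, tol = 1e-8)) {
    stop("`Ge` must be a symmetric matrix", call. = FALSE)
  }
  p <- nrow(m)
  if (is.null(k)) {
    k <- if (inherits(Ge, "env_covariance")) Ge$rank_hint else p
  }
  k <- stopifnot_count(k, "k")
  if (k > p) {
    stop(sprintf("`k` = %d exceeds the number of environments p = %d", k, p),
         call. = FALSE)
  }
  eg <- eigen(m, symmetric = TRUE)
  vals <- eg$values
  if (min(vals) < -1e-8 * max(abs(vals), 1)) {
    stop("`Ge` is not positive semi-definite; consider bend_to_psd()",
         call. = FALSE)
  }
  vals <- pmax(vals, 0)
  vals[vals < 1e-12 * max(vals, 1)] <- 0 # numerical rank cut-off
  vecs <- eg$vectors
  flip <- apply(vecs, 2, function(col) col[which.max(abs(col))] < 0)
  vecs[, flip] <- -vecs[, flip]
  S <- vecs[, seq_len(k), drop = FALSE]
  rownames(S) <- rownames(m) %||% env_labels(p)
  colnames(S) <- paste0("term", seq_len(k))
  L <- vals[seq_len(k)]
  structure(list(S = S, L = L,
                 variance_explained = L / sum(vals),
                 p = p, k = k),
            class = "multiplicative_terms")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.multiplicative_terms <- function(x, ...) {
  cat(sprintf("Multiplicative terms: k = %d of p = %d environments\n",
              x$k, x$p))
  cat("  term variances    :", paste(sprintf("%.3f", head(x$L, 8)),
                                     collapse = " "), "\n")
  cat(sprintf("  variance explained: %.1f%% cumulative\n",
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' Simulate genotype slopes for the multiplicative terms
#'
#' Draws the `v x k` matrix of genotype slopes `f_k` with independent
#' columns, column `r` distributed `N(0, l_r * G)` where `G` is the
#' genotype relationship matrix (identity by default). The slopes are the
#' genotype "scores" multiplying the environmental covariates.
#'
#' @param terms A `multiplicative_terms` object (see
#'   [decompose_covariance()]).
#' @param v Number of genotypes.
#' @param G Optional `v x v` PSD relationship matrix (pedigree or
#'   genomic); `NULL` means identity.
#' @param seed Optional integer seed.
#'
#' @return A `v x k` numeric matrix of slopes with `G1..Gv` rownames.
#' @export
simulate_slopes <- function(terms, v, G = NULL, seed = NULL) {
  stopifnot(inherits(terms, "multiplicative_terms"))
  v <- stopifnot_count(v, "v")
  k <- terms$k
  root <- NULL
  if (!is.null(G)) {
    if (!is_symmetric_matrix(G, tol = 1e-8) || nrow(G) != v) {
      stop("`G` must be a symmetric v x v matrix", call. = FALSE)
    }
    root <- psd_sqrt(G)
  }
  f <- with_seed_(seed, {
    z <- matrix(rnorm(v * k), v, k)
    if (!is.null(root)) z <- root %*% z
    sweep(z, 2, sqrt(terms$L), "*")
  })
  dimnames(f) <- list(geno_labels(v), colnames(terms$S))
  f
}

#' Construct genotype-by-environment effects
#'
#' Forms the `v x p` matrix of true GE effects `u = f_k S_k'` from the
#' genotype slopes and environmental covariates. Across genotypes the
#' implied between-environment covariance of `u` is `S_k L_k S_k'`, which
#' equals `Ge` whenever `rank(Ge) <= k`.
#'
#' @param terms A `multiplicative_terms` object.
#' @param slopes A `v x k` slope matrix (see [simulate_slopes()]).
#'
#' @return A `v x p` matrix of GE effects with genotype rownames and
#'   environment colnames.
#' @export
construct_ge_effects <- function(terms, slopes) {
  stopifnot(inherits(terms, "multiplicative_terms"))
  if (!is.matrix(slopes) || ncol(slopes) != terms$k) {
    stop(sprintf("`slopes` must have k = %d columns", terms$k), call. = FALSE)
  }
  u <- slopes %*% t(terms$S)
  rownames(u) <- rownames(slopes) %||% geno_labels(nrow(slopes))
  colnames(u) <- rownames(terms$S)
  u
}

#' Genotype main effects
#'
#' Computes each genotype's main effect as the average of its GE effects
#' across environments (optionally a subset, e.g. the environments
#' sampled in a MET).
#'
#' @param u A `v x p` matrix of GE effects.
#' @param environments Optional vector of environment indices or names;
#'   default all.
#'
#' @return Numeric vector of `v` main effects.
#' @export
genotype_main_effects <- function(u, environments = NULL) {
  if (!is.matrix(u)) stop("`u` must be a matrix", call. = FALSE)
  if (is.null(environments)) {
    environments <- seq_len(ncol(u))
  }
  if (length(environments) == 0) {
    stop("`environments` must select at least one environment", call. = FALSE)
  }
  rowMeans(u[, environments, drop = FALSE])
}

#' Import genotype slopes from an external simulator
#'
#' Reads a `v x k` slope matrix from CSV (genotypes in rows, one column
#' per multiplicative term), validating dimensions against `terms`. This
#' supports workflows where each term is simulated as a separate trait in
#' a dedicated breeding simulation package.
#'
#' @param path CSV file path.
#' @param terms A `multiplicative_terms` object used for validation.
#'
#' @return A `v x k` numeric matrix.
#' @export
import_slopes <- function(path, terms) {
  stopifnot(inherits(terms, "multiplicative_terms"))
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  if (ncol(m) != terms$k) {
    stop(sprintf("imported slopes have %d columns but k = %d terms",
                 ncol(m), terms$k), call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}
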