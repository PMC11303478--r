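# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# A NULL seed uses (and advances) the current RNG stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a reproducible child seed for a named stream, so that the modules
# driven by one root seed can be re-run independently. Kept below 2^31.
spawn_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  chars <- utf8ToInt(stream)
  h <- sum(chars * seq_along(chars)) %% 2147483647
  as.integer((as.double(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

stopifnot_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower) {
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}

is_symmetric_matrix <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# Symmetric PSD square root via eigendecomposition; small negative
# eigenvalues (numerical noise) are clipped at zero. Errors on genuinely
# indefinite input.
psd_sqrt <- function(m, tol = 1e-8) {
  eg <- eigen(m, symmetric = TRUE)
  mx <- max(eg$values, 0)
  if (min(eg$values) < -tol * max(mx, 1)) {
    stop("matrix is not positive semi-definite; consider bend_to_psd()",
         call. = FALSE)
  }
  vals <- pmax(eg$values, 0)
  vals[vals < 1e-12 * max(vals, 1)] <- 0 # numerical-rank cut-off
  eg$vectors %*% (sqrt(vals) * t(eg$vectors))
}

env_labels <- function(p) paste0("E", seq_len(p))
geno_labels <- function(v) paste0("G", seq_len(v))
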