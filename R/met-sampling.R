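#' Sample environments from a TPE
#'
#' Draws `p_m` distinct environment indices uniformly at random from the
#' `p` environments of the TPE by shuffling the full set and taking the
#' leading `p_m`, mimicking the natural sampling of environments that
#' occurs during field evaluation. Sampling is without replacement
#' within a MET; across METs (e.g. successive years) environments may
#' recur, mirroring a finite TPE.
#'
#' @param p Number of environments in the TPE.
#' @param p_m Number of environments to sample, `1 <= p_m <= p`.
#' @param seed Optional integer seed.
#'
#' @return Integer vector of `p_m` distinct indices in `1..p`.
#' @export
sample_environments <- function(p, p_m, seed = NULL) {
  p <- stopifnot_count(p, "p")
  p_m <- stopifnot_count(p_m, "p_m")
  if (p_m > p) {
    stop(sprintf("cannot sample p_m = %d environments from a TPE of p = %d",
                 p_m, p), call. = FALSE)
  }
  with_seed_(seed, sample.int(p)[seq_len(p_m)])
}

#' Empirical MET-TPE alignment
#'
#' The Pearson correlation between the genotype main effects computed
#' over the sampled environments (the MET) and over all environments
#' (the TPE). An alignment of 1 means selection on MET means would rank
#' genotypes exactly as in the TPE.
#'
#' @param u `v x p` matrix of GE effects for the full TPE.
#' @param environments Indices (or names) of the sampled environments.
#'
#' @return Correlation in `[-1, 1]`.
#' @export
empirical_alignment <- function(u, environments) {
  if (!is.matrix(u) || nrow(u) < 3) {
    stop("`u` must be a matrix with at least 3 genotypes", call. = FALSE)
  }
  met_means <- genotype_main_effects(u, environments)
  tpe_means <- genotype_main_effects(u)
  if (sd(met_means) == 0 || sd(tpe_means) == 0) {
    stop("main effects have zero variance: alignment is undefined",
         call. = FALSE)
  }
  cor(met_means, tpe_means)
}

#' Sample a MET from a TPE of GE effects
#'
#' Samples `p_m` environments (see [sample_environments()]) and slices
#' the GE effects, recording the realised MET-TPE alignment. When the
#' TPE covariance is supplied the expected accuracies implied by the
#' true simulation parameters are attached: the expected alignment
#' `r_mt` always, and additionally `r_g`/`r_m` when an error variance
#' and replicate count are given.
#'
#' @param u `v x p` matrix of GE effects for the full TPE.
#' @param p_m Number of environments to sample.
#' @param seed Optional integer seed.
#' @param Ge Optional `env_covariance` (or matrix) of the TPE used for
#'   the expected measures.
#' @param sigma2_eps,n_reps Optional error variance and replicate count
#'   for the full expected-accuracy set.
#'
#' @return An object of class `tpe_sample`: list with `environments`,
#'   `u_sampled`, `seed`, `alignment` and (if computable) `expected`
#'   (an `accuracy_set` or the expected alignment alone).
#' @export
sample_tpe <- function(u, p_m, seed = NULL, Ge = NULL, sigma2_eps = NULL,
                       n_reps = NULL) {
  if (!is.matrix(u)) stop("`u` must be a matrix", call. = FALSE)
  idx <- sample_environments(ncol(u), p_m, seed = seed)
  out <- list(environments = idx,
              u_sampled = u[, idx, drop = FALSE],
              seed = seed,
              alignment = if (nrow(u) >= 3) empirical_alignment(u, idx) else NA_real_)
  if (!is.null(Ge)) {
    vd <- variance_decomposition(Ge)
    out$expected <- expected_accuracies(
      vd$sigma2_g, vd$sigma2_ge,
      sigma2_eps = if (is.null(sigma2_eps)) 0 else sigma2_eps,
      n_envs = p_m,
      n_reps = if (is.null(n_reps)) 1L else n_reps)
  }
  class(out) <- "tpe_sample"
  out
}

#' @export
print.tpe_sample <- function(x, ...) {
  cat(sprintf("MET sample: %d environments\n", length(x$environments)))
  cat("  indices  :", paste(head(x$environments, 10), collapse = " "),
      if (length(x$environments) > 10) "..." else "", "\n")
  cat(sprintf("  alignment: %.3f\n", x$alignment))
  if (!is.null(x$expected)) {
    cat(sprintf("  expected : r_mt = %.3f, r_m = %.3f, r_g = %.3f\n",
                x$expected$r_mt, x$expected$r_m, x$expected$r_g))
  }
  invisible(x)
}

#' Write a MET sample manifest
#'
#' Serialises the sampled environment indices, seed, realised alignment
#' and expected accuracies to JSON for provenance.
#'
#' @param sample A `tpe_sample`.
#' @param path Output JSON path.
#'
#' @return `path`, invisibly.
#' @export
write_sample_manifest <- function(sample, path) {
  stopifnot(inherits(sample, "tpe_sample"))
  rec <- list(environments = sample$environments,
              seed = sample$seed,
              alignment = sample$alignment)
  if (!is.null(sample$expected)) {
    rec$expected <- sample$expected[c("r_g", "r_m", "r_mt", "r_ge")]
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
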