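#' Preset low/moderate/high GEI scenarios
#'
#' Simulates a TPE covariance matrix using the parameter triples that
#' define the canonical low, moderate and high GEI scenarios: gamma
#' genetic variances with shape 1.5 and scale 1 throughout, rank-7
#' correlation structure with baseline correlation / noise magnitude /
#' skew of (0.50, 0.50, -0.50) for low, (0.20, 0.80, -0.50) for moderate
#' and (0.00, 1.00, -0.35) for high GEI. The `"none"` level is a
#' GEI-free benchmark with compound-symmetric unit correlation and
#' equal variances matching the mean genetic variance 1.5.
#'
#' @param level `"none"`, `"low"`, `"moderate"` or `"high"`.
#' @param p Number of environments (default 1000).
#' @param seed Optional integer seed.
#'
#' @return An `env_covariance` object.
#' @export
#' @examples
#' vd <- variance_decomposition(gei_scenario("low", p = 1000, seed = 1))
#' round(c(vd$v_g, vd$v_n), 2) # about 0.51 and 0.61
gei_scenario <- function(level = c("low", "moderate", "high", "none"),
                         p = 1000, seed = NULL) {
  level <- match.arg(level)
  if (level == "none") {
    Ce <- matrix(1, p, p)
    dimnames(Ce) <- list(env_labels(p), env_labels(p))
    out <- assemble_covariance(rep(1.5, p), Ce, rank_hint = 1L)
    out$scenario <- level
    return(out)
  }
  par <- switch(level,
                low = list(rho = 0.50, gamma_skew = -0.50),
                moderate = list(rho = 0.20, gamma_skew = -0.50),
                high = list(rho = 0.00, gamma_skew = -0.35))
  out <- simulate_tpe(p = p, shape = 1.5, scale = 1, rho = par$rho,
                      gamma_skew = par$gamma_skew, k = 7, seed = seed)
  out$scenario <- level
  out
}
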