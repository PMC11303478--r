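# Recurrent breeding-programme simulation: founder creation, meiosis,
# genomic relationships, compound-symmetry BLUP and the yearly loop.

new_population <- function(h1, h2, map, effects, intercepts, ids,
                           generation = "founder") {
  rownames(h1) <- rownames(h2) <- ids
  structure(list(h1 = h1, h2 = h2, map = map, effects = effects,
                 intercepts = intercepts, ids = ids,
                 generation = generation),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population: %d individuals, %d loci on %d chromosomes (%s)\n",
              nrow(x$h1), ncol(x$h1), length(x$map$chrom_index),
              x$generation))
  invisible(x)
}

#' Marker dosages of a population
#'
#' @param pop A `population`.
#' @return Integer matrix individuals x loci with dosages in `{0, 1, 2}`.
#' @export
dosages <- function(pop) {
  stopifnot(inherits(pop, "population"))
  pop$h1 + pop$h2
}

#' Genotype slopes of a population
#'
#' Computes each individual's genetic value for every multiplicative
#' term from its marker dosages and the additive marker effects:
#' `slopes = W %*% effects + intercepts`.
#'
#' @param pop A `population`.
#' @return Numeric matrix individuals x k.
#' @export
population_slopes <- function(pop) {
  W <- dosages(pop)
  sweep(W %*% pop$effects, 2, pop$intercepts, "+")
}

pop_subset <- function(pop, idx) {
  new_population(pop$h1[idx, , drop = FALSE], pop$h2[idx, , drop = FALSE],
                 pop$map, pop$effects, pop$intercepts,
                 pop$ids[idx], pop$generation)
}

pop_combine <- function(pops) {
  pops <- Filter(Negate(is.null), pops)
  base <- pops[[1]]
  new_population(do.call(rbind, lapply(pops, `[[`, "h1")),
                 do.call(rbind, lapply(pops, `[[`, "h2")),
                 base$map, base$effects, base$intercepts,
                 unlist(lapply(pops, `[[`, "ids")), "combined")
}

#' Create a founder population
#'
#' Simulates `n` founder individuals at `n_loci` biallelic loci spread
#' evenly over `n_chromosomes`, with per-locus allele frequencies drawn
#' from `U(0.1, 0.9)` and haplotypes in Hardy-Weinberg proportions. Each
#' multiplicative term is treated as a separate additive trait: random
#' marker effects are drawn and then standardised post hoc so the founder
#' slope sample variances equal the term variances `L_k` exactly and the
#' founder slope means are exactly zero. The genotype relationship
#' structure is thereby generated implicitly through the markers.
#'
#' @param n Number of founders (>= 2).
#' @param n_loci Total number of loci (>= number of terms).
#' @param n_chromosomes Number of chromosomes.
#' @param terms A `multiplicative_terms` object supplying `L_k`.
#' @param seed Optional integer seed.
#'
#' @return A `population` object.
#' @export
create_founders <- function(n, n_loci, n_chromosomes, terms, seed = NULL) {
  n <- stopifnot_count(n, "n", lower = 2L)
  n_loci <- stopifnot_count(n_loci, "n_loci")
  n_chromosomes <- stopifnot_count(n_chromosomes, "n_chromosomes")
  stopifnot(inherits(terms, "multiplicative_terms"))
  k <- terms$k
  if (k > n_loci) {
    stop(sprintf("need at least as many loci (%d) as terms (%d)",
                 n_loci, k), call. = FALSE)
  }
  chrom <- rep(seq_len(n_chromosomes), length.out = n_loci)
  chrom <- sort(chrom)
  chrom_index <- split(seq_len(n_loci), chrom)
  chrom_pos <- lapply(chrom_index, function(ix) {
    nl <- length(ix)
    (seq_len(nl) - 0.5) / nl
  })
  map <- list(chrom_index = chrom_index, chrom_pos = chrom_pos)
  with_seed_(seed, {
    q <- runif(n_loci, 0.1, 0.9)
    h1 <- matrix(rbinom(n * n_loci, 1, rep(q, each = n)), n, n_loci)
    h2 <- matrix(rbinom(n * n_loci, 1, rep(q, each = n)), n, n_loci)
    W <- h1 + h2
    effects <- matrix(rnorm(n_loci * k), n_loci, k)
    raw <- W %*% effects
    intercepts <- numeric(k)
    for (r in seq_len(k)) {
      s <- sd(raw[, r])
      if (terms$L[r] <= 0 || s == 0) {
        effects[, r] <- 0
        intercepts[r] <- 0
      } else {
        scale_r <- sqrt(terms$L[r]) / s
        effects[, r] <- effects[, r] * scale_r
        intercepts[r] <- -mean(W %*% effects[, r])
      }
    }
    new_population(h1, h2, map, effects, intercepts,
                   ids = paste0("F", seq_len(n)), generation = "founder")
  })
}

# One gamete from an individual: per chromosome, Poisson(rate) crossovers
# at uniform positions, starting from a random parental haplotype.
gamete_one <- function(h1i, h2i, map, crossover_rate = 1) {
  out <- integer(length(h1i))
  for (c in seq_along(map$chrom_index)) {
    ix <- map$chrom_index[[c]]
    pos <- map$chrom_pos[[c]]
    nxo <- rpois(1, crossover_rate)
    if (nxo > 0) {
      xo <- sort(runif(nxo))
      phase <- (sample.int(2, 1) - 1 + findInterval(pos, xo)) %% 2
    } else {
      phase <- rep(sample.int(2, 1) - 1, length(ix))
    }
    out[ix] <- ifelse(phase == 0, h1i[ix], h2i[ix])
  }
  out
}

#' Cross individuals to produce progeny
#'
#' Produces `n_progeny` progeny from random pairs of distinct parents
#' (or from the supplied `parents` index matrix, which may repeat an
#' index to represent selfing). Gametes are formed per chromosome with a
#' Poisson(1) number of crossovers at uniform positions. Progeny genetic
#' values (slopes) follow from the marker effects, so inheritance is
#' fully additive.
#'
#' @param pop A `population` with at least 2 individuals (or 1 when
#'   `parents` requests selfing).
#' @param n_progeny Number of progeny.
#' @param seed Optional integer seed.
#' @param parents Optional `n_progeny x 2` matrix of parent indices.
#' @param crossover_rate Mean crossovers per chromosome (default 1).
#'
#' @return A `population` of progeny.
#' @export
make_crosses <- function(pop, n_progeny, seed = NULL, parents = NULL,
                         crossover_rate = 1) {
  stopifnot(inherits(pop, "population"))
  n_progeny <- stopifnot_count(n_progeny, "n_progeny")
  n <- nrow(pop$h1)
  if (is.null(parents) && n < 2) {
    stop("need at least 2 parents to make crosses", call. = FALSE)
  }
  with_seed_(seed, {
    if (is.null(parents)) {
      parents <- t(replicate(n_progeny, sample.int(n, 2)))
    } else {
      parents <- as.matrix(parents)
      if (nrow(parents) != n_progeny || ncol(parents) != 2) {
        stop("`parents` must be an n_progeny x 2 index matrix", call. = FALSE)
      }
    }
    L <- ncol(pop$h1)
    h1 <- matrix(0L, n_progeny, L)
    h2 <- matrix(0L, n_progeny, L)
    for (i in seq_len(n_progeny)) {
      h1[i, ] <- gamete_one(pop$h1[parents[i, 1], ], pop$h2[parents[i, 1], ],
                            pop$map, crossover_rate)
      h2[i, ] <- gamete_one(pop$h1[parents[i, 2], ], pop$h2[parents[i, 2], ],
                            pop$map, crossover_rate)
    }
    new_population(h1, h2, pop$map, pop$effects, pop$intercepts,
                   ids = paste0("X", seq_len(n_progeny)), generation = "cross")
  })
}

#' Produce doubled haploids
#'
#' Approximates double-haploid production by one generation of gamete
#' doubling: each individual contributes `n_per` gametes, each doubled
#' into a fully homozygous line.
#'
#' @param pop A `population`.
#' @param n_per Doubled haploids per individual (default 1).
#' @param seed Optional integer seed.
#' @param crossover_rate Mean crossovers per chromosome.
#'
#' @return A `population` of fully homozygous individuals.
#' @export
make_dh <- function(pop, n_per = 1, seed = NULL, crossover_rate = 1) {
  stopifnot(inherits(pop, "population"))
  n_per <- stopifnot_count(n_per, "n_per")
  n <- nrow(pop$h1)
  with_seed_(seed, {
    L <- ncol(pop$h1)
    h <- matrix(0L, n * n_per, L)
    row <- 1L
    for (i in seq_len(n)) {
      for (d in seq_len(n_per)) {
        h[row, ] <- gamete_one(pop$h1[i, ], pop$h2[i, ], pop$map,
                               crossover_rate)
        row <- row + 1L
      }
    }
    new_population(h, h, pop$map, pop$effects, pop$intercepts,
                   ids = paste0("DH", seq_len(n * n_per)), generation = "DH")
  })
}

#' Genomic relationship matrix from marker dosages
#'
#' First-method construction: dosages are centred by twice the observed
#' allele frequencies and the cross-product is normalised by
#' `2 * sum(q * (1 - q))`. Monomorphic loci contribute nothing. Falls
#' back to the identity when fewer than 10 polymorphic loci are
#' available.
#'
#' @param W Dosage matrix (individuals x loci) or a `population`.
#'
#' @return A symmetric relationship matrix with row/col names from `W`.
#' @export
genomic_relationship <- function(W) {
  if (inherits(W, "population")) W <- dosages(W)
  q <- colMeans(W) / 2
  poly <- q > 0 & q < 1
  if (sum(poly) < 10) {
    K <- diag(nrow(W))
    dimnames(K) <- list(rownames(W), rownames(W))
    return(K)
  }
  Wc <- sweep(W[, poly, drop = FALSE], 2, 2 * q[poly])
  K <- tcrossprod(Wc) / (2 * sum(q[poly] * (1 - q[poly])))
  dimnames(K) <- list(rownames(W), rownames(W))
  K
}

#' Compound-symmetry BLUP of genotype main effects
#'
#' Predicts genotype main effects from plot-level MET data under the
#' model `phenotype = env + genotype + genotype:env + error`, with
#' genotype variance `sigma2_g * K` (`K` genomic relationship, identity
#' when `NULL`), iid interaction variance `sigma2_ge` and iid error
#' variance `sigma2_eps`, solved by the mixed-model equations. The iid
#' interaction and error are absorbed exactly into genotype-by-
#' environment cell means with weights `1 / (sigma2_ge + sigma2_eps /
#' r_cell)`, which is algebraically identical to the plot-level
#' equations. Variance components are supplied (typically the true
#' simulation values); no estimation is performed.
#'
#' @param dataset Data frame with columns `env`, `genotype`,
#'   `phenotype` (e.g. a `met_dataset`).
#' @param sigma2_g,sigma2_ge,sigma2_eps Variance components.
#' @param K Optional relationship matrix covering all genotypes in
#'   `dataset` (matched by name); identity when `NULL`. A ridge of
#'   `1e-8 * mean(diag(K))` is added before inversion when `K` is
#'   numerically singular (e.g. duplicated genotypes).
#'
#' @return Named numeric vector of predicted genotype main effects.
#' @export
predict_main_effects_cs <- function(dataset, sigma2_g, sigma2_ge,
                                    sigma2_eps, K = NULL) {
  stopifnot_scalar_number(sigma2_g, "sigma2_g", lower = 0)
  stopifnot_scalar_number(sigma2_ge, "sigma2_ge", lower = 0)
  stopifnot_scalar_number(sigma2_eps, "sigma2_eps", lower = 0)
  need <- c("env", "genotype", "phenotype")
  if (!all(need %in% names(dataset))) {
    stop("`dataset` must have columns env, genotype, phenotype",
         call. = FALSE)
  }
  gl <- unique(as.character(dataset$genotype))
  if (sigma2_g == 0) {
    return(setNames(rep(0, length(gl)), gl))
  }
  env <- factor(as.character(dataset$env))
  geno <- factor(as.character(dataset$genotype), levels = gl)
  v <- length(gl)
  key <- (as.integer(env) - 1L) * v + as.integer(geno)
  ybar <- tapply(dataset$phenotype, key, mean)
  rcell <- tapply(dataset$phenotype, key, length)
  kn <- as.integer(names(ybar))
  cg <- factor(gl[(kn - 1L) %% v + 1L], levels = gl)
  ce <- factor(levels(env)[(kn - 1L) %/% v + 1L], levels = levels(env))
  w <- as.numeric(1 / pmax(sigma2_ge + sigma2_eps / rcell, 1e-12))
  ybar <- as.numeric(ybar)
  X <- if (nlevels(ce) < 2) {
    matrix(1, length(ybar), 1)
  } else {
    model.matrix(~ ce)
  }
  Z <- matrix(0, length(ybar), v)
  Z[cbind(seq_along(ybar), as.integer(cg))] <- 1
  if (is.null(K)) {
    Kinv <- diag(1 / sigma2_g, v)
  } else {
    if (is.null(rownames(K))) {
      if (nrow(K) != v) stop("`K` dimension mismatch", call. = FALSE)
      Ks <- K
    } else {
      missing_g <- setdiff(gl, rownames(K))
      if (length(missing_g)) {
        stop("`K` is missing genotypes: ",
             paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
      }
      Ks <- K[gl, gl]
    }
    if (rcond(Ks) < 1e-10) { # duplicated genotypes make K singular
      Ks <- Ks + diag(1e-8 * mean(diag(Ks)) + 1e-12, v)
    }
    Kinv <- solve(Ks) / sigma2_g
  }
  Xw <- X * w
  Zw <- Z * w
  C <- rbind(cbind(crossprod(Xw, X), crossprod(Xw, Z)),
             cbind(crossprod(Zw, X), crossprod(Zw, Z) + Kinv))
  rhs <- c(crossprod(Xw, ybar), crossprod(Zw, ybar))
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("mixed-model equations are singular (", conditionMessage(e),
         "); check that every environment has data and K is well ",
         "conditioned", call. = FALSE)
  })
  setNames(sol[(ncol(X) + 1):length(sol)], gl)
}

#' Configure a breeding programme
#'
#' Declares the recurrent selection programme: number of years,
#' environments sampled from the TPE per year, the ordered field-
#' evaluation stages (each with its genotype count, number of
#' environments, replicates and error variance), the selection strategy
#' and the founder genome. Stage genotype counts must be non-increasing
#' and stage environment counts cannot exceed `envs_per_year`. The
#' default stage structure mirrors a line programme with decreasing
#' genotype counts and increasing replication (headrow through elite
#' yield trial); all counts are configurable.
#'
#' @param years Number of breeding years.
#' @param envs_per_year Environments sampled from the TPE each year.
#' @param stages List of stages, each a list with `name`, `n_genotypes`,
#'   `n_envs`, `n_reps`, `sigma2_eps`.
#' @param selection `"phenotypic"` (ranking on phenotype means across
#'   the stage's current-year environments) or `"genomic"` (ranking on
#'   compound-symmetry BLUPs pooling all stages from the trailing
#'   `met_window_years` years).
#' @param met_window_years Years of MET data pooled for genomic
#'   selection.
#' @param n_parents Parents crossed each year (top-ranked genotypes
#'   among this year's advanced stages).
#' @param n_loci,n_chromosomes Founder genome dimensions.
#' @param sigma2_e Environmental main-effect variance.
#'
#' @return An object of class `programme_config`.
#' @export
programme_config <- function(years = 20, envs_per_year = 20,
                             stages = list(
                               list(name = "HDRW", n_genotypes = 100,
                                    n_envs = 1, n_reps = 1, sigma2_eps = 4),
                               list(name = "PYT", n_genotypes = 30,
                                    n_envs = 5, n_reps = 2, sigma2_eps = 4),
                               list(name = "AYT", n_genotypes = 12,
                                    n_envs = 10, n_reps = 2, sigma2_eps = 4),
                               list(name = "EYT", n_genotypes = 5,
                                    n_envs = 20, n_reps = 2, sigma2_eps = 4)),
                             selection = c("phenotypic", "genomic"),
                             met_window_years = 3, n_parents = 10,
                             n_loci = 200, n_chromosomes = 10,
                             sigma2_e = 1) {
  selection <- match.arg(selection)
  years <- stopifnot_count(years, "years")
  envs_per_year <- stopifnot_count(envs_per_year, "envs_per_year")
  met_window_years <- stopifnot_count(met_window_years, "met_window_years")
  n_parents <- stopifnot_count(n_parents, "n_parents", lower = 2L)
  n_loci <- stopifnot_count(n_loci, "n_loci")
  n_chromosomes <- stopifnot_count(n_chromosomes, "n_chromosomes")
  stopifnot_scalar_number(sigma2_e, "sigma2_e", lower = 0)
  if (!length(stages)) stop("at least one stage is required", call. = FALSE)
  sizes <- vapply(stages, function(s) s$n_genotypes, numeric(1))
  if (any(diff(sizes) > 0)) {
    stop("stage genotype counts must be non-increasing", call. = FALSE)
  }
  for (s in stages) {
    for (f in c("name", "n_genotypes", "n_envs", "n_reps", "sigma2_eps")) {
      if (is.null(s[[f]])) {
        stop(sprintf("stage is missing field `%s`", f), call. = FALSE)
      }
    }
    if (s$n_envs > envs_per_year) {
      stop(sprintf("stage %s uses %d environments but only %d are sampled ",
                   s$name, s$n_envs, envs_per_year), "per year",
           call. = FALSE)
    }
  }
  if (n_parents > sizes[1]) {
    stop("`n_parents` cannot exceed the first stage's genotype count",
         call. = FALSE)
  }
  structure(list(years = years, envs_per_year = envs_per_year,
                 stages = stages, selection = selection,
                 met_window_years = met_window_years,
                 n_parents = n_parents, n_loci = n_loci,
                 n_chromosomes = n_chromosomes, sigma2_e = sigma2_e),
            class = "programme_config")
}

#' Track genetic progress of a cohort
#'
#' Computes the genetic gain and variance of a cohort in the TPE and in
#' the current MET sample, using the multiplicative-term identity: the
#' mean of the genotype main effects is `mean(S_k) %*% colMeans(f_k)`
#' and their variance is `mean(S_k) %*% cov(f_k) %*% t(mean(S_k))`,
#' where `mean(S_k)` is the row vector of environmental covariate means
#' (over all TPE environments, or over the sampled environments for the
#' MET measures). If predicted values are supplied, the main-effect
#' accuracies in the TPE and MET are added as Pearson correlations with
#' the true main effects, together with the realised MET-TPE alignment.
#'
#' @param slopes Cohort slope matrix (individuals x k), e.g. from
#'   [population_slopes()].
#' @param terms The TPE's `multiplicative_terms`.
#' @param met_envs Indices of the environments sampled in the current
#'   MET.
#' @param predictions Optional vector of predicted genotype main effects
#'   for the cohort (same order as `slopes` rows).
#'
#' @return A one-row data frame with `gain_tpe`, `var_tpe`, `gain_met`,
#'   `var_met`, `alignment`, `accuracy_tpe`, `accuracy_met`.
#' @export
track_progress <- function(slopes, terms, met_envs, predictions = NULL) {
  stopifnot(inherits(terms, "multiplicative_terms"))
  s_tpe <- colMeans(terms$S)
  s_met <- colMeans(terms$S[met_envs, , drop = FALSE])
  mu_slopes <- colMeans(slopes)
  L_star <- cov(slopes)
  mains_tpe <- drop(slopes %*% s_tpe)
  mains_met <- drop(slopes %*% s_met)
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  data.frame(
    gain_tpe = sum(s_tpe * mu_slopes),
    var_tpe = drop(t(s_tpe) %*% L_star %*% s_tpe),
    gain_met = sum(s_met * mu_slopes),
    var_met = drop(t(s_met) %*% L_star %*% s_met),
    alignment = safe_cor(mains_met, mains_tpe),
    accuracy_tpe = if (is.null(predictions)) NA_real_ else
      safe_cor(predictions, mains_tpe),
    accuracy_met = if (is.null(predictions)) NA_real_ else
      safe_cor(predictions, mains_met))
}

# Phenotype one stage in the sampled environments of the current year.
# Rows are ordered environment, block, genotype (RCBD per environment).
phenotype_stage <- function(pop, terms, env_idx, tau, sigma2_eps, n_reps,
                            year, stage_name, seed = NULL) {
  slopes <- population_slopes(pop)
  u <- slopes %*% t(terms$S[env_idx, , drop = FALSE]) # v x n_envs
  v <- nrow(u)
  ne <- length(env_idx)
  true_ge <- unlist(lapply(seq_len(ne),
                           function(j) rep(u[, j], times = n_reps)),
                    use.names = FALSE)
  eps <- with_seed_(seed, rnorm(v * ne * n_reps, sd = sqrt(sigma2_eps)))
  data.frame(
    year = year, stage = stage_name,
    env = rep(paste0("Y", year, "E", env_idx), each = v * n_reps),
    env_idx = rep(env_idx, each = v * n_reps),
    block = rep(rep(seq_len(n_reps), each = v), times = ne),
    genotype = rep(pop$ids, times = ne * n_reps),
    true_ge = true_ge,
    phenotype = true_ge + rep(tau, each = v * n_reps) + eps,
    stringsAsFactors = FALSE)
}

#' Run a recurrent breeding-programme simulation
#'
#' Executes the six-step yearly workflow: (1) the TPE covariance is
#' decomposed once into environmental covariates and term variances;
#' (2) genotype slopes are simulated in a founder population by treating
#' each term as a separate marker-based trait; then each year (3) a
#' subset of environments is sampled from the TPE, (4) GE effects and
#' phenotypes are constructed for every stage's genotypes in its
#' environments, (5) superior genotypes are selected and advanced
#' (phenotypic selection on current-year phenotype means, genomic
#' selection on compound-symmetry BLUPs pooling the trailing MET
#' window), new crosses are made among the top-ranked parents and taken
#' to doubled haploids to form the next first-stage cohort, and (6)
#' genetic progress is tracked for every stage.
#'
#' @param config A [programme_config()].
#' @param tpe An `env_covariance` (see [simulate_tpe()]) or a
#'   `multiplicative_terms` object.
#' @param seed Optional integer root seed.
#'
#' @return A data frame of class `genetic_progress` with one row per
#'   year and stage (columns from [track_progress()] plus `year`,
#'   `stage`, `n_genotypes`), with the matrix of sampled environment
#'   indices attached as attribute `sampled_environments`.
#' @export
run_programme <- function(config, tpe, seed = NULL) {
  stopifnot(inherits(config, "programme_config"))
  terms <- if (inherits(tpe, "multiplicative_terms")) {
    tpe
  } else {
    decompose_covariance(tpe)
  }
  vd_total <- sum(terms$L) / terms$p # mean genetic variance, for BLUP inputs
  s_tpe <- colMeans(terms$S)
  sigma2_g <- drop(t(s_tpe) %*% diag(terms$L, terms$k) %*% s_tpe)
  sigma2_ge <- max(vd_total - sigma2_g, 0)

  n_stages <- length(config$stages)
  stage_pops <- vector("list", n_stages)
  founders <- create_founders(config$stages[[1]]$n_genotypes,
                              config$n_loci, config$n_chromosomes, terms,
                              seed = spawn_seed(seed, "founders"))
  parents <- pop_subset(founders, seq_len(min(config$n_parents,
                                              nrow(founders$h1))))
  marker_bank <- list(founders)
  records <- list()
  progress <- list()
  sampled <- matrix(NA_integer_, config$years, config$envs_per_year)

  for (year in seq_len(config$years)) {
    env_idx <- sample_environments(terms$p, config$envs_per_year,
                                   seed = spawn_seed(seed, paste0("envs-", year)))
    sampled[year, ] <- env_idx
    tau <- simulate_environment_means(
      config$envs_per_year, sigma2_e = config$sigma2_e,
      seed = spawn_seed(seed, paste0("tau-", year)))

    # new first-stage cohort
    if (year == 1) {
      cohort <- founders
    } else {
      f1 <- make_crosses(parents, config$stages[[1]]$n_genotypes,
                         seed = spawn_seed(seed, paste0("cross-", year)))
      cohort <- make_dh(f1, seed = spawn_seed(seed, paste0("dh-", year)))
      cohort$ids <- paste0("Y", year, "N", seq_along(cohort$ids))
      rownames(cohort$h1) <- rownames(cohort$h2) <- cohort$ids
      marker_bank[[length(marker_bank) + 1]] <- cohort
    }
    stage_pops[[1]] <- cohort

    # phenotype every occupied stage in its environments
    year_records <- list()
    for (s in seq_len(n_stages)) {
      pop <- stage_pops[[s]]
      if (is.null(pop)) next
      st <- config$stages[[s]]
      ne <- st$n_envs
      year_records[[s]] <- phenotype_stage(
        pop, terms, env_idx[seq_len(ne)], tau[seq_len(ne)],
        st$sigma2_eps, st$n_reps, year, st$name,
        seed = spawn_seed(seed, paste0("eps-", year, "-", s)))
    }
    records[[year]] <- do.call(rbind, year_records)

    # selection criterion per genotype
    if (config$selection == "genomic") {
      window <- records[seq.int(max(1, year - config$met_window_years + 1),
                                year)]
      pool <- do.call(rbind, window)
      ids <- unique(pool$genotype)
      bank <- do.call(rbind, lapply(marker_bank, dosages))
      K <- genomic_relationship(bank[ids, , drop = FALSE])
      crit <- predict_main_effects_cs(pool, sigma2_g, sigma2_ge,
                                      mean(vapply(config$stages,
                                                  `[[`, numeric(1),
                                                  "sigma2_eps")),
                                      K = K)
    } else {
      # each genotype occupies exactly one stage per year, so its mean
      # phenotype is taken across that stage's current-year environments
      cur <- records[[year]]
      crit <- tapply(cur$phenotype, cur$genotype, mean)
    }

    # track progress and advance
    for (s in seq_len(n_stages)) {
      pop <- stage_pops[[s]]
      if (is.null(pop)) next
      preds <- crit[pop$ids]
      progress[[length(progress) + 1]] <- cbind(
        data.frame(year = year, stage = config$stages[[s]]$name,
                   n_genotypes = nrow(pop$h1)),
        track_progress(population_slopes(pop), terms, env_idx,
                       predictions = unname(preds)))
    }
    new_stage_pops <- vector("list", n_stages)
    for (s in seq_len(n_stages - 1)) {
      pop <- stage_pops[[s]]
      if (is.null(pop)) next
      n_next <- config$stages[[s + 1]]$n_genotypes
      ranks <- order(crit[pop$ids], decreasing = TRUE)
      new_stage_pops[[s + 1]] <- pop_subset(pop, ranks[seq_len(min(n_next,
                                                                   length(ranks)))])
    }
    # parents: top-ranked among this year's advanced material (stages >= 2
    # next year, i.e. everything just selected), falling back to stage 1
    cand <- Filter(Negate(is.null), new_stage_pops)
    cand_pop <- if (length(cand)) pop_combine(cand) else stage_pops[[1]]
    cand_crit <- crit[cand_pop$ids]
    top <- order(cand_crit, decreasing = TRUE)[
      seq_len(min(config$n_parents, nrow(cand_pop$h1)))]
    if (length(top) >= 2) parents <- pop_subset(cand_pop, top)
    stage_pops[seq.int(2L, length.out = n_stages - 1L)] <-
      new_stage_pops[seq.int(2L, length.out = n_stages - 1L)]
  }

  out <- do.call(rbind, progress)
  attr(out, "sampled_environments") <- sampled
  attr(out, "config") <- config
  class(out) <- c("genetic_progress", "data.frame")
  out
}
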