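# CSV/JSON/YAML readers and writers, run manifests and config loading.

#' Write a labelled numeric matrix to CSV
#'
#' Matrices are written with a header row of column labels and a leading
#' column of row labels, using 17 significant digits so values round-trip
#' losslessly through [read_matrix_csv()].
#'
#' @param m Numeric matrix (e.g. `Ge`, `Ce`, covariates or slopes).
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  if (!is.matrix(m)) stop("`m` must be a matrix", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- env_labels(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- env_labels(ncol(m))
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(m))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix from CSV
#'
#' @param path CSV written by [write_matrix_csv()] (header row of labels,
#'   first column of row labels).
#'
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a run manifest
#'
#' Records all input parameters, seeds, package version, a timestamp and
#' the names of files produced, as pretty-printed JSON.
#'
#' @param params Named list of resolved parameters/seeds.
#' @param out_dir Directory the manifest describes.
#' @param files Character vector of output file names.
#'
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(params, out_dir, files = character()) {
  manifest <- list(
    package = "geisim",
    version = as.character(utils::packageVersion("geisim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params,
    files = files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write the artefacts of a simulated TPE
#'
#' Writes `Ge.csv`, `Ce.csv` and `variances.csv` plus a JSON manifest of
#' all parameters to `out_dir`.
#'
#' @param tpe An `env_covariance` from [simulate_tpe()].
#' @param out_dir Output directory (created if missing).
#'
#' @return Character vector of file paths, invisibly.
#' @export
write_tpe <- function(tpe, out_dir) {
  stopifnot(inherits(tpe, "env_covariance"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(tpe$matrix, file.path(out_dir, "Ge.csv"))
  write_matrix_csv(tpe$correlations, file.path(out_dir, "Ce.csv"))
  write_matrix_csv(matrix(tpe$variances, ncol = 1,
                          dimnames = list(names(tpe$variances), "variance")),
                   file.path(out_dir, "variances.csv"))
  params <- list(seed = tpe$seed, rank_hint = tpe$rank_hint)
  if (!is.null(tpe$variance_spec)) {
    params <- c(params, unclass(tpe$variance_spec))
  }
  if (!is.null(tpe$correlation_spec)) {
    params$correlation <- unclass(tpe$correlation_spec)
  }
  write_run_manifest(params, out_dir,
                     files = c("Ge.csv", "Ce.csv", "variances.csv"))
  invisible(file.path(out_dir, c("Ge.csv", "Ce.csv", "variances.csv",
                                 "manifest.json")))
}

#' Read a TPE covariance from an output directory
#'
#' Reconstructs an `env_covariance` from the `Ge.csv`/`Ce.csv` files
#' written by [write_tpe()] (or any user-supplied matrices in the same
#' layout). User-supplied covariances that are slightly indefinite can
#' be repaired first with [bend_to_psd()].
#'
#' @param dir Directory holding `Ge.csv` (and optionally `Ce.csv`).
#'
#' @return An `env_covariance` object.
#' @export
read_tpe <- function(dir) {
  Ge <- read_matrix_csv(file.path(dir, "Ge.csv"))
  variances <- diag(Ge)
  ce_path <- file.path(dir, "Ce.csv")
  if (file.exists(ce_path)) {
    Ce <- read_matrix_csv(ce_path)
  } else {
    d <- sqrt(variances)
    Ce <- Ge / tcrossprod(d)
    diag(Ce) <- 1
  }
  assemble_covariance(variances, Ce)
}

#' Load a breeding-programme configuration from YAML
#'
#' Reads a structured YAML file and validates it through
#' [programme_config()], so every constraint (non-increasing stage
#' sizes, per-stage environment counts, admissible strategy) is enforced
#' at load time; fields not present fall back to the documented
#' defaults.
#'
#' @param path YAML file path.
#'
#' @return A `programme_config` object.
#' @export
load_programme_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(programme_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(programme_config, raw)
}

#' Save a breeding-programme configuration to YAML
#'
#' @param config A `programme_config` object.
#' @param path Output YAML path.
#'
#' @return `path`, invisibly.
#' @export
save_programme_config <- function(config, path) {
  stopifnot(inherits(config, "programme_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Load TPE construction parameters from YAML
#'
#' Validates a flat YAML parameter file for [simulate_tpe()]; constraint
#' violations (e.g. `epsilon > 1 - rho`) are reported with the field and
#' the constraint.
#'
#' @param path YAML file path.
#'
#' @return Named list of validated parameters ready for
#'   [simulate_tpe()].
#' @export
load_tpe_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulate_tpe))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # run full validation via the spec constructors
  args <- modifyList(list(p = 100, shape = 1.5, scale = 1, rho = 0.5,
                          epsilon = NULL, gamma_skew = 0, k = 7), raw,
                     keep.null = TRUE)
  variance_spec(args$p, args$shape, args$scale)
  correlation_spec(args$p, args$rho, args$epsilon, args$gamma_skew, args$k,
                   enforce_rank = is.null(args$epsilon))
  raw
}
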