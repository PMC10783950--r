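read_delimited_matrix <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("failed to parse %s '%s': %s",
                                     what, path, conditionMessage(e))))
  if (nrow(df) < 1L || ncol(df) < 2L)
    stop(sprintf("%s '%s' needs an id column plus at least one marker column",
                 what, path))
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate ids in %s '%s': %s", what, path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value in %s '%s' at row %d (id '%s'), column '%s'",
                 what, path, bad[1L], ids[bad[1L]], colnames(num)[bad[2L]]))
  }
  num
}

#' Read a cell-by-marker expression matrix from delimited text
#'
#' Comma or tab dialect is chosen by extension (`.tsv`/`.txt` are
#' tab-separated, anything else comma-separated); the first column holds
#' cell ids and the header row marker names.
#'
#' @param path file path.
#' @return validated expression matrix.
#' @export
read_expression <- function(path) {
  expression_matrix(read_delimited_matrix(path, "expression matrix"))
}

#' Read a cell-type-by-marker prior profile matrix from delimited text
#'
#' Same dialect rules as [read_expression()]; the first column holds
#' cell-type names.
#'
#' @param path file path.
#' @return validated prior matrix.
#' @export
read_prior <- function(path) {
  prior_matrix(read_delimited_matrix(path, "prior matrix"))
}

#' Read cell centroid coordinates
#'
#' Expects columns `cell_id`, `x`, `y` (micrometers); extra columns are
#' ignored.
#'
#' @param path file path.
#' @return data.frame with `cell_id`, `x`, `y`.
#' @export
read_coordinates <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df)))
    stop(sprintf("coordinate file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell ids in coordinates")
  df[, need]
}

#' Write a matrix as delimited text with an id column
#'
#' @param x matrix with rownames.
#' @param path output path (`.tsv`/`.txt` write tabs, else commas).
#' @param id_name header for the id column.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(x, path, id_name = "id") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Recognized keys mirror [seg_control()] (`kappa`, `tau0`, `alpha0`,
#' `beta0`, `n_iterations`, `burn_in_fraction`, `seed`, `sampler_mode`,
#' `rho_step_init`, `thin_mu`, `thin_rho`) plus simulator settings for the
#' `simulate`/`study` subcommands.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

control_from_config <- function(config = list(), overrides = list()) {
  keys <- names(formals(seg_control))
  args <- config[intersect(names(config), keys)]
  for (nm in names(overrides)) if (!is.null(overrides[[nm]])) args[[nm]] <- overrides[[nm]]
  do.call(seg_control, args)
}

#' Write a run manifest
#'
#' Records the package version, timestamp, seed, configuration snapshot and
#' md5 digests of the input files next to every output directory, so a run
#' can be reproduced from the manifest alone.
#'
#' @param dir output directory.
#' @param config configuration list to snapshot.
#' @param inputs character vector of input file paths to digest.
#' @param seed the run seed (or NULL).
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, config = list(), inputs = character(),
                           seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "segentropy",
    version = as.character(packageVersion("segentropy")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = digests
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write the outputs of a fit to a directory
#'
#' Writes `rho_hat.csv` (cells x types), `mu_hat.csv` (types x markers),
#' `tau_hat.csv`, `entropy.csv` (cell id, entropy, partition label),
#' `summary.json` (average entropy, K, cell count, sampler settings) and
#' the trace report.
#'
#' @param fit a `"segfit"`.
#' @param dir output directory, created if needed.
#' @return invisibly, `dir`.
#' @export
write_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(fit$summary$rho_hat, file.path(dir, "rho_hat.csv"), "cell_id")
  write_matrix(fit$summary$mu_hat, file.path(dir, "mu_hat.csv"), "cell_type")
  write.csv(data.frame(marker = names(fit$summary$tau_hat),
                       tau_hat = fit$summary$tau_hat, row.names = NULL),
            file.path(dir, "tau_hat.csv"), row.names = FALSE)
  write.csv(fit$entropy$cells, file.path(dir, "entropy.csv"),
            row.names = FALSE)
  smry <- list(
    average_entropy = fit$entropy$average_entropy,
    k = fit$entropy$k, n_cells = fit$entropy$n,
    entropy_base = if (abs(fit$entropy$base - exp(1)) < 1e-12) "e" else fit$entropy$base,
    acceptance = fit$acceptance,
    control = fit$control[c("kappa", "tau0", "alpha0", "beta0",
                            "n_iterations", "burn_in_fraction",
                            "sampler_mode")],
    seed = fit$control$seed
  )
  jsonlite::write_json(smry, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(fit$trace)) write_trace_report(fit$trace, dir)
  invisible(dir)
}
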