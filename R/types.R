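#' Construct and validate a cell-by-marker expression matrix
#'
#' The observed matrix Y: one row per segmented cell, one column per protein
#' marker, mean per-cell channel intensities on an arbitrary (typically
#' range-normalized) scale. Values are used as given; callers are responsible
#' for putting Y and the prior profile matrix on a comparable scale.
#'
#' @param values numeric matrix, cells in rows, markers in columns.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames, else `cell_1..cell_I`.
#' @param marker_names character vector of unique marker names; defaults to
#'   existing colnames, else `marker_1..marker_J`.
#' @return a validated numeric matrix with cell ids as rownames and marker
#'   names as colnames.
#' @export
expression_matrix <- function(values, cell_ids = NULL, marker_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(values)
    if (is.null(marker_names)) marker_names <- paste0("marker_", seq_len(ncol(values)))
  }
  rownames(values) <- as.character(cell_ids)
  colnames(values) <- as.character(marker_names)
  validate_expression(values)
  values
}

#' Construct and validate a cell-type-by-marker prior profile matrix
#'
#' The user's belief P about the expected relative marker intensity of each
#' cell type (lineage), on the same scale as the expression matrix. Marker
#' columns must match the paired expression matrix after [align_markers()].
#'
#' @param values numeric matrix, cell types in rows, markers in columns.
#' @param cell_type_names,marker_names optional row/column identifiers.
#' @return a validated numeric matrix with type names as rownames.
#' @export
prior_matrix <- function(values, cell_type_names = NULL, marker_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_type_names)) {
    cell_type_names <- rownames(values)
    if (is.null(cell_type_names)) cell_type_names <- paste0("type_", seq_len(nrow(values)))
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(values)
    if (is.null(marker_names)) marker_names <- paste0("marker_", seq_len(ncol(values)))
  }
  rownames(values) <- as.character(cell_type_names)
  colnames(values) <- as.character(marker_names)
  validate_prior(values)
  values
}

validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("expression matrix needs at least 1 cell and 1 marker")
  if (anyNA(x) || !all(is.finite(x))) stop("expression matrix contains missing or non-finite values")
  if (anyDuplicated(rownames(x))) stop("duplicate cell ids in expression matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate marker names in expression matrix")
  invisible(x)
}

validate_prior <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("prior matrix must be a numeric matrix")
  if (nrow(x) < 2L) stop("prior matrix needs at least 2 cell types")
  if (anyNA(x) || !all(is.finite(x))) stop("prior matrix contains missing or non-finite values")
  if (anyDuplicated(rownames(x))) stop("duplicate cell-type names in prior matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate marker names in prior matrix")
  invisible(x)
}

#' Sampler and model hyperparameters
#'
#' All Normal distributions in the model are parameterized by mean and
#' precision (inverse variance): the emission precision per marker is
#' `tau_j`, the prior on each profile mean `mu_kj` has precision `tau0`, and
#' `tau_j` has a Gamma(shape `alpha0`, rate `beta0`) prior (mean
#' `alpha0/beta0`). The Dirichlet prior on each contribution vector uses the
#' symmetric concentration `kappa`; the default 0.1 encourages sparse
#' vectors, reflecting the assumption that most masks are correct.
#'
#' @param kappa symmetric Dirichlet concentration on contribution vectors.
#' @param tau0 precision of the Gaussian prior on profile means; the default
#'   10 (SD ~0.32) is weakly informative around unit-scale intensities.
#' @param alpha0,beta0 shape and rate of the Gamma prior on marker precisions.
#' @param n_iterations number of full MCMC sweeps.
#' @param burn_in_fraction fraction of the trace discarded before averaging.
#' @param seed optional integer seed; when given, every source of randomness
#'   in the fit flows from it.
#' @param sampler_mode `"conjugate"` draws `mu` and `tau` from their exact
#'   full conditionals (Gibbs); `"mh"` uses random-walk Metropolis steps for
#'   them as well. The contribution vectors always use Metropolis steps.
#' @param rho_step_init initial random-walk step (log-ratio scale) for the
#'   contribution update; per-cell step sizes are adapted during burn-in
#'   toward ~0.3 acceptance and frozen afterwards.
#' @param rho_warmup number of initial contribution-only sweeps (profile
#'   means and precisions held at their initial prior draws) run before the
#'   joint sweeps, so contribution vectors settle near their cell types
#'   while the profile means are still anchored at the prior matrix. Guards
#'   against components swapping identities during early burn-in.
#' @param mu_step,tau_step random-walk steps for `"mh"` mode (tau on the log
#'   scale).
#' @param thin_mu,thin_rho trace thinning for mu/tau and rho samples.
#' @param adapt_interval sweeps between step-size adaptations during burn-in.
#' @param verbose print progress every `progress_every` sweeps.
#' @param progress_every sweep interval for progress messages.
#' @return a list of class `"seg_control"`.
#' @export
seg_control <- function(kappa = 0.1, tau0 = 10, alpha0 = 2, beta0 = 1,
                        n_iterations = 10000L, burn_in_fraction = 0.5,
                        seed = NULL,
                        sampler_mode = c("conjugate", "mh"),
                        rho_step_init = 0.5, mu_step = 0.1, tau_step = 0.3,
                        rho_warmup = 100L,
                        thin_mu = 1L, thin_rho = 10L,
                        adapt_interval = 50L,
                        verbose = FALSE, progress_every = 1000L) {
  sampler_mode <- match.arg(sampler_mode)
  stopifnot(
    is.numeric(kappa), length(kappa) == 1L, kappa > 0,
    is.numeric(tau0), tau0 > 0,
    is.numeric(alpha0), alpha0 > 0,
    is.numeric(beta0), beta0 > 0,
    is.numeric(n_iterations), n_iterations >= 1,
    is.numeric(burn_in_fraction), burn_in_fraction > 0, burn_in_fraction < 1,
    is.numeric(rho_step_init), rho_step_init > 0,
    is.numeric(mu_step), mu_step > 0,
    is.numeric(tau_step), tau_step > 0,
    is.numeric(rho_warmup), rho_warmup >= 0,
    thin_mu >= 1, thin_rho >= 1, adapt_interval >= 1
  )
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(
    kappa = kappa, tau0 = tau0, alpha0 = alpha0, beta0 = beta0,
    n_iterations = as.integer(n_iterations),
    burn_in_fraction = burn_in_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    sampler_mode = sampler_mode,
    rho_step_init = rho_step_init, mu_step = mu_step, tau_step = tau_step,
    rho_warmup = as.integer(rho_warmup),
    thin_mu = as.integer(thin_mu), thin_rho = as.integer(thin_rho),
    adapt_interval = as.integer(adapt_interval),
    verbose = isTRUE(verbose), progress_every = as.integer(progress_every)
  ), class = "seg_control")
}

# Floor simplex entries at eps and renormalize: kappa < 1 places infinite
# Dirichlet density at the boundary, so densities are evaluated on the
# floored vector.
clamp_simplex <- function(x, eps = 1e-10) {
  x <- pmax(x, eps)
  x / sum(x)
}

validate_state <- function(state, tol = 1e-9) {
  stopifnot(is.list(state), all(c("mu", "tau", "rho") %in% names(state)))
  K <- nrow(state$mu); J <- ncol(state$mu)
  if (length(state$tau) != J) stop("tau length must equal number of markers")
  if (any(state$tau <= 0)) stop("all tau entries must be > 0")
  if (ncol(state$rho) != K) stop("rho columns must equal number of cell types")
  if (any(state$rho < 0)) stop("rho entries must be non-negative")
  if (any(abs(rowSums(state$rho) - 1) > tol)) stop("rho rows must sum to 1")
  if (!all(is.finite(state$mu)) || !all(is.finite(state$tau)) || !all(is.finite(state$rho)))
    stop("non-finite values in model state")
  invisible(state)
}
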