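#' Align the marker columns of an expression and a prior matrix
#'
#' Restricts both matrices to their shared markers, in the expression
#' matrix's column order. Markers present in only one input are dropped with
#' a warning listing them; fewer than 2 shared markers is an error.
#'
#' @param expr cell-by-marker expression matrix (see [expression_matrix()]).
#' @param prior cell-type-by-marker prior matrix (see [prior_matrix()]).
#' @return list with elements `expr` and `prior`, identical marker ordering.
#' @export
align_markers <- function(expr, prior) {
  validate_expression(expr)
  validate_prior(prior)
  em <- colnames(expr); pm <- colnames(prior)
  shared <- em[em %in% pm]
  if (length(shared) < 2L && !identical(em, pm)) {
    stop(sprintf(
      "fewer than 2 shared markers between expression [%s] and prior [%s]",
      paste(em, collapse = ", "), paste(pm, collapse = ", ")))
  }
  dropped <- setdiff(union(em, pm), shared)
  if (length(dropped)) {
    warning(sprintf("dropping markers present in only one input: %s",
                    paste(dropped, collapse = ", ")))
  }
  list(expr = expr[, shared, drop = FALSE], prior = prior[, shared, drop = FALSE])
}

#' Log emission density of one cell's expression vector
#'
#' The observation model: each marker intensity is Normal with mean
#' `sum_k rho_ik * mu_kj` (the contribution-weighted blend of type profiles)
#' and precision `tau_j`. Returns the sum of per-marker log densities.
#'
#' @param y_i numeric vector of length J, one cell's expression.
#' @param state model state: list with `mu` (K x J), `tau` (length J),
#'   `rho` (I x K, rows on the simplex).
#' @param i row index of the cell in `state$rho`.
#' @return scalar log density.
#' @export
log_emission <- function(y_i, state, i = 1L) {
  if (anyNA(y_i) || !all(is.finite(y_i))) stop("non-finite expression values")
  validate_state(state)
  m <- as.vector(state$rho[i, , drop = FALSE] %*% state$mu)
  sum(dnorm(y_i, mean = m, sd = 1 / sqrt(state$tau), log = TRUE))
}

# log density of a Dirichlet(alpha) at simplex point x (floored).
ddirichlet_log <- function(x, alpha) {
  x <- clamp_simplex(x)
  if (length(alpha) == 1L) alpha <- rep(alpha, length(x))
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' Joint log prior density of a model state
#'
#' Sums the log prior over all components: Normal(p_kj, precision tau0) on
#' each profile mean, Gamma(alpha0, rate beta0) on each marker precision,
#' and symmetric Dirichlet(kappa) on each cell's contribution vector (rows
#' floored at 1e-10 and renormalized, since kappa < 1 has infinite density
#' at the boundary).
#'
#' @param state model state (list with `mu`, `tau`, `rho`).
#' @param prior K x J prior profile matrix.
#' @param control hyperparameters from [seg_control()].
#' @return scalar log density.
#' @export
log_prior <- function(state, prior, control = seg_control()) {
  validate_state(state)
  lp_mu <- sum(dnorm(state$mu, mean = prior, sd = 1 / sqrt(control$tau0), log = TRUE))
  lp_tau <- sum(dgamma(state$tau, shape = control$alpha0, rate = control$beta0, log = TRUE))
  lp_rho <- sum(apply(state$rho, 1L, ddirichlet_log, alpha = control$kappa))
  lp_mu + lp_tau + lp_rho
}

#' Per-cell log likelihood of the whole matrix
#'
#' @param expr I x J expression matrix.
#' @param state model state.
#' @return numeric vector of length I, the per-cell log emission densities.
#' @export
log_emission_cells <- function(expr, state) {
  validate_state(state)
  cpp_loglik_rows(expr, state$mu, state$tau, state$rho)
}
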