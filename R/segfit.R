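#' Fit the segmentation-quality model to an expression matrix
#'
#' The hierarchical model: each observed marker intensity
#' `y_ij ~ Normal(sum_k rho_ik mu_kj, precision tau_j)`, with priors
#' `mu_kj ~ Normal(p_kj, precision tau0)`, `tau_j ~ Gamma(alpha0, beta0)` and
#' `rho_i ~ Dirichlet(kappa 1_K)`. `rho_i` is each cell's vector of
#' fractional contributions from the K cell-type profiles; its posterior
#' mean's Shannon entropy scores how cleanly one type explains the cell, and
#' the image's average entropy is the segmentation-quality score.
#'
#' Markers are aligned with [align_markers()] before fitting; posterior
#' point estimates average the post-burn-in trace.
#'
#' @param expr cell-by-marker expression matrix ([expression_matrix()]).
#' @param prior cell-type-by-marker profile matrix ([prior_matrix()]).
#' @param control hyperparameters and sampler settings ([seg_control()]).
#' @param coords optional data.frame of cell centroids (`cell_id`, `x`, `y`
#'   in micrometers) carried along for density diagnostics.
#' @param entropy_base logarithm base for the entropy report.
#' @param keep_trace retain the full MCMC trace in the returned object
#'   (set `FALSE` to save memory in large batch runs).
#' @return an object of class `"segfit"` with components `summary`
#'   (`mu_hat`, `tau_hat`, `rho_hat`), `entropy` (an [entropy_report()]),
#'   `trace` (unless dropped), `acceptance`, `control`, and the aligned
#'   inputs.
#' @seealso [entropy_report()], [run_sampler()], [simulate_well()]
#' @examples
#' cfg <- sim_config(n_cells = 60, n_markers = 4, n_types = 2, seed = 1)
#' ds <- simulate_well(cfg)
#' fit <- segfit(ds$expr, ds$truth_prior,
#'               seg_control(n_iterations = 300, seed = 1))
#' fit$entropy$average_entropy
#' @export
segfit <- function(expr, prior, control = seg_control(), coords = NULL,
                   entropy_base = exp(1), keep_trace = TRUE) {
  cl <- match.call()
  aligned <- align_markers(expr, prior)
  trace <- run_sampler(aligned$expr, aligned$prior, control)
  summ <- summarize_trace(trace)
  ent <- entropy_report(summ$rho_hat, base = entropy_base)
  out <- list(
    call = cl, expr = aligned$expr, prior = aligned$prior,
    control = control, summary = summ, entropy = ent,
    acceptance = trace$acceptance, rho_step_final = trace$rho_step_final,
    coords = coords,
    trace = if (keep_trace) trace else NULL
  )
  class(out) <- "segfit"
  out
}

#' @export
print.segfit <- function(x, ...) {
  cat("Segmentation-quality model fit\n")
  cat(sprintf("  %d cells x %d markers, K = %d cell types\n",
              nrow(x$expr), ncol(x$expr), nrow(x$prior)))
  cat(sprintf("  %d MCMC sweeps (%s mode), burn-in fraction %.2f\n",
              x$control$n_iterations, x$control$sampler_mode,
              x$control$burn_in_fraction))
  cat(sprintf("  average entropy: %.4f nats (max log K = %.4f)\n",
              x$entropy$average_entropy, log(nrow(x$prior))))
  invisible(x)
}

#' @export
summary.segfit <- function(object, ...) {
  ent <- object$entropy$cells$entropy
  structure(list(
    n_cells = nrow(object$expr), n_markers = ncol(object$expr),
    k = nrow(object$prior),
    average_entropy = object$entropy$average_entropy,
    entropy_quantiles = quantile(ent, c(0, 0.25, 0.5, 0.75, 1)),
    max_entropy = log(nrow(object$prior)),
    acceptance = object$acceptance,
    tau_hat = object$summary$tau_hat,
    control = object$control
  ), class = "summary.segfit")
}

#' @export
print.summary.segfit <- function(x, ...) {
  cat(sprintf("Fit of %d cells x %d markers with K = %d cell types\n",
              x$n_cells, x$n_markers, x$k))
  cat(sprintf("Average entropy %.4f nats (maximum log K = %.4f)\n",
              x$average_entropy, x$max_entropy))
  cat("Per-cell entropy quantiles:\n")
  print(round(x$entropy_quantiles, 4))
  cat(sprintf("Acceptance rate (rho block): %.2f\n", x$acceptance$rho))
  cat("Posterior mean marker precisions:\n")
  print(round(x$tau_hat, 2))
  invisible(x)
}

#' Extract posterior point estimates from a fit
#'
#' @param object a `"segfit"`.
#' @param which `"mu"` (profile means, default), `"tau"` (marker
#'   precisions) or `"rho"` (per-cell contributions).
#' @param ... unused.
#' @export
coef.segfit <- function(object, which = c("mu", "tau", "rho"), ...) {
  which <- match.arg(which)
  switch(which,
         mu = object$summary$mu_hat,
         tau = object$summary$tau_hat,
         rho = object$summary$rho_hat)
}

#' @export
fitted.segfit <- function(object, ...) {
  object$summary$rho_hat %*% object$summary$mu_hat
}

#' @export
residuals.segfit <- function(object, ...) {
  object$expr - fitted(object)
}

#' @export
logLik.segfit <- function(object, ...) {
  state <- list(mu = object$summary$mu_hat, tau = object$summary$tau_hat,
                rho = object$summary$rho_hat)
  ll <- sum(log_emission_cells(object$expr, state))
  attr(ll, "df") <- length(state$mu) + length(state$tau)
  class(ll) <- "logLik"
  ll
}

#' Simulate expression matrices from a fitted model
#'
#' Draws new cell-by-marker matrices from the emission model at the
#' posterior point estimates (same contributions, fresh Gaussian noise).
#'
#' @param object a `"segfit"`.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` matrices with the fit's dimnames.
#' @export
simulate.segfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- fitted(object)
  sds <- rep(1 / sqrt(object$summary$tau_hat), each = nrow(M))
  lapply(seq_len(nsim), function(s) {
    out <- M + matrix(rnorm(length(M), sd = sds), nrow(M), ncol(M))
    dimnames(out) <- dimnames(M)
    out
  })
}

#' Trace and entropy plots for a fit
#'
#' @param x a `"segfit"` (with its trace retained).
#' @param which `"trace"` for MCMC traces of mu and tau (and rho for a few
#'   cells), `"entropy"` for the per-cell entropy histogram.
#' @param markers marker indices to show traces for.
#' @param cells cell indices whose contribution traces are shown.
#' @param ... passed to plotting functions.
#' @export
plot.segfit <- function(x, which = c("trace", "entropy"),
                        markers = seq_len(min(4L, ncol(x$expr))),
                        cells = seq_len(min(2L, nrow(x$expr))), ...) {
  which <- match.arg(which)
  if (which == "entropy") {
    ent <- x$entropy$cells$entropy
    graphics::hist(ent, breaks = 30, xlab = "per-cell entropy (nats)",
                   main = "Entropy distribution", ...)
    abline(v = x$entropy$average_entropy, col = 2, lwd = 2)
    return(invisible(x))
  }
  if (is.null(x$trace)) stop("fit was run with keep_trace = FALSE")
  tr <- x$trace
  op <- par(mfrow = c(2, max(1L, length(markers))))
  on.exit(par(op), add = TRUE)
  for (j in markers) {
    matplot(tr$mu_iters, tr$mu_samples[, , j], type = "l", lty = 1,
            xlab = "iteration", ylab = "mu",
            main = sprintf("mu, %s", tr$marker_names[j]))
  }
  for (j in markers) {
    plot(tr$mu_iters, tr$tau_samples[, j], type = "l",
         xlab = "iteration", ylab = "tau",
         main = sprintf("tau, %s", tr$marker_names[j]))
  }
  invisible(x)
}
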