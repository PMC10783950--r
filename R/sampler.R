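#' Randomly initialize a model state from its priors
#'
#' Profile means are drawn from their Gaussian prior centered at the prior
#' matrix, marker precisions from their Gamma prior, and each contribution
#' vector from the symmetric Dirichlet(kappa); rows are floored and
#' renormalized so the simplex constraint holds exactly. Deterministic given
#' the RNG state.
#'
#' @param expr I x J expression matrix.
#' @param prior K x J prior profile matrix.
#' @param control hyperparameters from [seg_control()].
#' @return list with `mu` (K x J), `tau` (length J), `rho` (I x K).
#' @export
initialize_state <- function(expr, prior, control = seg_control()) {
  I <- nrow(expr); J <- ncol(prior); K <- nrow(prior)
  mu <- matrix(rnorm(K * J, mean = prior, sd = 1 / sqrt(control$tau0)), K, J,
               dimnames = dimnames(prior))
  tau <- rgamma(J, shape = control$alpha0, rate = control$beta0)
  g <- matrix(rgamma(I * K, shape = control$kappa, rate = 1), I, K)
  rho <- t(apply(g, 1L, clamp_simplex))
  state <- list(mu = mu, tau = tau, rho = rho)
  validate_state(state)
  state
}

#' Metropolis update of all contribution vectors
#'
#' One Metropolis step per cell on the additive log-ratio coordinates of
#' `rho_i`, targeting the full conditional
#' Dirichlet(kappa) x prod_j Normal(y_ij | sum_k rho_ik mu_kj, tau_j).
#' The number of accepted proposals is attached as attribute `"accepts"`.
#'
#' @param state model state.
#' @param expr expression matrix.
#' @param control hyperparameters.
#' @param step random-walk step size, a scalar or one value per cell
#'   (defaults to `control$rho_step_init`).
#' @return updated state with attribute `"accepts"` (0/1 per cell).
#' @export
update_rho <- function(state, expr, control = seg_control(),
                       step = control$rho_step_init) {
  step <- rep_len(step, nrow(expr))
  res <- cpp_step_rho(expr, state$mu, state$tau, state$rho, control$kappa, step)
  state$rho <- res$rho
  attr(state, "accepts") <- res$accepts
  state
}

#' Update the profile means
#'
#' Conjugate mode draws each `mu_kj` exactly from its Gaussian full
#' conditional (precision `tau0 + tau_j * sum_i rho_ik^2`); `"mh"` mode uses
#' an elementwise Gaussian random walk targeting the same conditional.
#'
#' @inheritParams update_rho
#' @param prior K x J prior profile matrix.
#' @return updated state; in `"mh"` mode with attribute `"accepts"`.
#' @export
update_mu <- function(state, expr, prior, control = seg_control()) {
  if (control$sampler_mode == "conjugate") {
    state$mu <- cpp_step_mu_gibbs(expr, state$mu, state$tau, state$rho,
                                  prior, control$tau0)
  } else {
    res <- cpp_step_mu_mh(expr, state$mu, state$tau, state$rho,
                          prior, control$tau0, control$mu_step)
    state$mu <- res$mu
    attr(state, "accepts") <- res$accepts
  }
  state
}

#' Update the marker precisions
#'
#' Conjugate mode draws each `tau_j` exactly from
#' Gamma(alpha0 + I/2, rate beta0 + SSR_j/2); `"mh"` mode uses a log-scale
#' random walk targeting the same conditional.
#'
#' @inheritParams update_mu
#' @return updated state; in `"mh"` mode with attribute `"accepts"`.
#' @export
update_tau <- function(state, expr, control = seg_control()) {
  if (control$sampler_mode == "conjugate") {
    state$tau <- cpp_step_tau_gibbs(expr, state$mu, state$rho,
                                    control$alpha0, control$beta0)
  } else {
    res <- cpp_step_tau_mh(expr, state$mu, state$rho, state$tau,
                           control$alpha0, control$beta0, control$tau_step)
    state$tau <- res$tau
    attr(state, "accepts") <- res$accepts
  }
  state
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Performs `control$rho_warmup` contribution-only sweeps (profile means
#' and precisions held at their initial prior draws, anchoring each
#' component to its prior profile while the contribution vectors settle),
#' followed by `control$n_iterations` full sweeps in the fixed order
#' rho -> mu -> tau, recording (thinned) traces of every block. Per-cell
#' contribution step sizes are adapted toward ~0.3 acceptance during
#' warm-up and burn-in and frozen afterwards, so the post-burn-in kernel is
#' valid Metropolis-Hastings. Fully reproducible given `control$seed`.
#'
#' @param expr I x J expression matrix (markers aligned with `prior`).
#' @param prior K x J prior profile matrix.
#' @param control hyperparameters from [seg_control()].
#' @return an object of class `"seg_trace"`: thinned sample arrays
#'   (`mu_samples` n x K x J, `tau_samples` n x J, `rho_samples` n x I x K
#'   with their iteration indices), acceptance rates per block, the final
#'   adapted step size, and the control list.
#' @export
run_sampler <- function(expr, prior, control = seg_control()) {
  validate_expression(expr)
  validate_prior(prior)
  if (!identical(colnames(expr), colnames(prior)))
    stop("marker columns of expr and prior differ; call align_markers() first")
  if (!is.null(control$seed)) set.seed(control$seed)

  I <- nrow(expr); J <- ncol(expr); K <- nrow(prior)
  n <- control$n_iterations
  burn <- floor(control$burn_in_fraction * n)
  state <- initialize_state(expr, prior, control)

  mu_iters <- seq(from = control$thin_mu, to = n, by = control$thin_mu)
  rho_iters <- seq(from = control$thin_rho, to = n, by = control$thin_rho)
  mu_samples <- array(NA_real_, c(length(mu_iters), K, J))
  tau_samples <- matrix(NA_real_, length(mu_iters), J)
  rho_samples <- array(NA_real_, c(length(rho_iters), I, K))

  steps <- rep(control$rho_step_init, I)
  acc_window <- numeric(I)
  acc_rho_total <- 0; acc_mu_total <- 0; acc_tau_total <- 0
  adapt_block <- 0L
  mi <- 0L; ri <- 0L

  adapt_steps <- function() {
    adapt_block <<- adapt_block + 1L
    rates <- acc_window / control$adapt_interval
    steps <<- pmin(pmax(steps * exp((rates - 0.3) / sqrt(adapt_block)),
                        0.05), 5)
    acc_window[] <<- 0
  }

  # contribution-only warm-up: mu/tau stay at their prior draws
  for (w in seq_len(control$rho_warmup)) {
    state <- update_rho(state, expr, control, step = steps)
    acc_window <- acc_window + attr(state, "accepts")
    if (w %% control$adapt_interval == 0L) adapt_steps()
  }

  for (it in seq_len(n)) {
    state <- update_rho(state, expr, control, step = steps)
    a <- attr(state, "accepts")
    acc_window <- acc_window + a
    acc_rho_total <- acc_rho_total + sum(a)

    state <- update_mu(state, expr, prior, control)
    if (control$sampler_mode == "mh") acc_mu_total <- acc_mu_total + attr(state, "accepts")

    state <- update_tau(state, expr, control)
    if (control$sampler_mode == "mh") acc_tau_total <- acc_tau_total + attr(state, "accepts")

    if (!all(is.finite(state$mu)) || !all(is.finite(state$tau)) ||
        !all(is.finite(state$rho))) {
      bad <- if (!all(is.finite(state$mu))) "mu" else if (!all(is.finite(state$tau))) "tau" else "rho"
      stop(sprintf("non-finite values in block '%s' at iteration %d", bad, it))
    }

    if (it <= burn && it %% control$adapt_interval == 0L) adapt_steps()

    if (it %% control$thin_mu == 0L) {
      mi <- mi + 1L
      mu_samples[mi, , ] <- state$mu
      tau_samples[mi, ] <- state$tau
    }
    if (it %% control$thin_rho == 0L) {
      ri <- ri + 1L
      rho_samples[ri, , ] <- state$rho
    }
    if (control$verbose && it %% control$progress_every == 0L) {
      message(sprintf("sweep %d/%d (rho acceptance %.2f, median step %.3f)",
                      it, n, acc_rho_total / (it * I), median(steps)))
    }
  }

  acceptance <- list(rho = acc_rho_total / (n * I))
  if (control$sampler_mode == "mh") {
    acceptance$mu <- acc_mu_total / (n * K * J)
    acceptance$tau <- acc_tau_total / (n * J)
  }
  structure(list(
    mu_samples = mu_samples, tau_samples = tau_samples,
    rho_samples = rho_samples,
    mu_iters = mu_iters, rho_iters = rho_iters,
    acceptance = acceptance, rho_step_final = steps,
    control = control, n_iterations = n,
    cell_ids = rownames(expr), marker_names = colnames(expr),
    type_names = rownames(prior)
  ), class = "seg_trace")
}

#' Posterior point estimates from an MCMC trace
#'
#' Averages the stored samples after discarding the burn-in (by default the
#' first half of the sweeps); averaged contribution rows are renormalized to
#' the simplex.
#'
#' @param trace a `"seg_trace"` from [run_sampler()].
#' @param burn_in_fraction fraction of sweeps to discard (defaults to the
#'   value the trace was run with).
#' @return list of class `"seg_summary"` with `mu_hat` (K x J), `tau_hat`
#'   (length J) and `rho_hat` (I x K, rows summing to 1).
#' @export
summarize_trace <- function(trace, burn_in_fraction = trace$control$burn_in_fraction) {
  if (trace$n_iterations < 2L) stop("trace must have at least 2 iterations")
  burn <- floor(burn_in_fraction * trace$n_iterations)
  keep_mu <- which(trace$mu_iters > burn)
  keep_rho <- which(trace$rho_iters > burn)
  if (!length(keep_mu) || !length(keep_rho))
    stop("no post-burn-in samples stored; lower thinning or burn_in_fraction")
  mu_hat <- apply(trace$mu_samples[keep_mu, , , drop = FALSE], c(2L, 3L), mean)
  tau_hat <- colMeans(trace$tau_samples[keep_mu, , drop = FALSE])
  rho_hat <- apply(trace$rho_samples[keep_rho, , , drop = FALSE], c(2L, 3L), mean)
  rho_hat <- rho_hat / rowSums(rho_hat)
  dimnames(mu_hat) <- list(trace$type_names, trace$marker_names)
  names(tau_hat) <- trace$marker_names
  dimnames(rho_hat) <- list(trace$cell_ids, trace$type_names)
  structure(list(mu_hat = mu_hat, tau_hat = tau_hat, rho_hat = rho_hat),
            class = "seg_summary")
}

#' Write trace plots and a thinned sample dump
#'
#' Writes `trace_plots.pdf` (per-marker traces of each profile mean and
#' precision, and contribution traces for a subset of cells) and
#' `trace_samples.csv` (long-format thinned samples) into `dir`.
#'
#' @param trace a `"seg_trace"`.
#' @param dir output directory, created if needed.
#' @param cells cell indices whose contribution traces are plotted
#'   (default: up to 4 cells); may be empty.
#' @return invisibly, the paths written.
#' @export
write_trace_report <- function(trace, dir, cells = seq_len(min(4L, length(trace$cell_ids)))) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  K <- dim(trace$mu_samples)[2L]; J <- dim(trace$mu_samples)[3L]
  pdf_path <- file.path(dir, "trace_plots.pdf")
  pdf(pdf_path, width = 8, height = 5)
  on.exit(dev.off(), add = TRUE)
  for (j in seq_len(J)) {
    matplot(trace$mu_iters, trace$mu_samples[, , j], type = "l", lty = 1,
            xlab = "iteration", ylab = "mu",
            main = sprintf("profile means, marker %s", trace$marker_names[j]))
    plot(trace$mu_iters, trace$tau_samples[, j], type = "l",
         xlab = "iteration", ylab = "tau",
         main = sprintf("precision, marker %s", trace$marker_names[j]))
  }
  for (i in cells) {
    matplot(trace$rho_iters, trace$rho_samples[, i, ], type = "l", lty = 1,
            ylim = c(0, 1), xlab = "iteration", ylab = "rho",
            main = sprintf("contributions, cell %s", trace$cell_ids[i]))
  }

  rows <- list()
  for (k in seq_len(K)) for (j in seq_len(J)) {
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = trace$mu_iters, variable = "mu",
      component = sprintf("%s:%s", trace$type_names[k], trace$marker_names[j]),
      value = trace$mu_samples[, k, j])
  }
  for (j in seq_len(J)) {
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = trace$mu_iters, variable = "tau",
      component = trace$marker_names[j], value = trace$tau_samples[, j])
  }
  for (i in cells) for (k in seq_len(K)) {
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = trace$rho_iters, variable = "rho",
      component = sprintf("%s:%s", trace$cell_ids[i], trace$type_names[k]),
      value = trace$rho_samples[, i, k])
  }
  dump_path <- file.path(dir, "trace_samples.csv")
  write.csv(do.call(rbind, rows), dump_path, row.names = FALSE)
  invisible(c(pdf_path, dump_path))
}
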