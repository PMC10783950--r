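# Independent numerical oracles used to check the MCMC sampler. These never
# call the sampler's own code paths: profile means are integrated out
# analytically (linear-Gaussian algebra) and the remaining low-dimensional
# integrals are done by prior-CDF midpoint quadrature.

# Posterior mean of both contribution vectors for the 2-cell, 1-marker,
# 2-type model. rho_i parameterized by its first component r_i in [0, 1];
# mu (2-vector) integrated analytically given tau; tau and (r1, r2) on
# quadrature grids transformed through their prior CDFs so nodes carry
# equal prior weight.
oracle_rho_mean_tiny <- function(y, p, kappa = 0.1, tau0 = 10, alpha0 = 2,
                                 beta0 = 1, n_rho = 120, n_tau = 60) {
  r_nodes <- qbeta((seq_len(n_rho) - 0.5) / n_rho, kappa, kappa)
  t_nodes <- qgamma((seq_len(n_tau) - 0.5) / n_tau, alpha0, rate = beta0)
  grid <- expand.grid(r1 = r_nodes, r2 = r_nodes, tau = t_nodes)
  r1 <- grid$r1; r2 <- grid$r2; tau <- grid$tau
  # marginal y | r, tau ~ N(R p, R R^T / tau0 + I / tau), R = (r_i, 1 - r_i)
  a <- (r1^2 + (1 - r1)^2) / tau0 + 1 / tau
  cc <- (r2^2 + (1 - r2)^2) / tau0 + 1 / tau
  b <- (r1 * r2 + (1 - r1) * (1 - r2)) / tau0
  d1 <- y[1] - (r1 * p[1] + (1 - r1) * p[2])
  d2 <- y[2] - (r2 * p[1] + (1 - r2) * p[2])
  det <- a * cc - b^2
  q <- (cc * d1^2 - 2 * b * d1 * d2 + a * d2^2) / det
  loglik <- -log(2 * pi) - 0.5 * log(det) - 0.5 * q
  w <- exp(loglik - max(loglik))
  c(rho11 = sum(w * r1) / sum(w), rho21 = sum(w * r2) / sum(w))
}

# Conditional posterior of a single cell's first contribution component
# given fixed profile means and precision (1 marker, 2 types): probability
# mass of r1 in the given bins, by quadrature on the Beta-CDF transformed
# grid.
oracle_rho_conditional_bins <- function(y, mu, tau, kappa = 0.1,
                                        breaks = seq(0, 1, by = 0.1),
                                        n = 4000) {
  r <- qbeta((seq_len(n) - 0.5) / n, kappa, kappa)
  ll <- dnorm(y, mean = r * mu[1] + (1 - r) * mu[2], sd = 1 / sqrt(tau),
              log = TRUE)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  bins <- cut(r, breaks = breaks, include.lowest = TRUE)
  tapply(w, bins, sum, default = 0)
}

# Monte-Carlo standard error by batch means (accounts for autocorrelation).
batch_se <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  sd(means) / sqrt(n_batches)
}

# Small simulated fixture shared across tests.
make_fixture <- function(n_cells = 100, n_markers = 6, n_types = 3,
                         noise_tau = 25, seed = 42) {
  cfg <- sim_config(n_cells = n_cells, n_markers = n_markers,
                    n_types = n_types, noise_tau = noise_tau, seed = seed)
  simulate_well(cfg)
}
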