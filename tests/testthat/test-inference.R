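make_tiny <- function() {
  list(expr = expression_matrix(matrix(c(0.3, 1.7), 2, 1), c("c1", "c2"), "m1"),
       prior = prior_matrix(matrix(c(0, 2), 2, 1), c("t1", "t2"), "m1"))
}

test_that("initialization is seeded, respects the simplex, and centers mu on the prior", {
  d <- make_fixture(n_cells = 20, n_markers = 4, n_types = 3)
  ctrl <- seg_control()

  set.seed(5); s1 <- initialize_state(d$expr, d$truth_prior, ctrl)
  set.seed(5); s2 <- initialize_state(d$expr, d$truth_prior, ctrl)
  expect_identical(s1, s2)

  set.seed(6)
  for (r in 1:50) {
    st <- initialize_state(d$expr, d$truth_prior, ctrl)
    expect_true(all(abs(rowSums(st$rho) - 1) < 1e-9))
    expect_true(all(st$rho >= 0), info = "simplex entries non-negative")
    expect_true(all(st$tau > 0))
  }

  # empirical mean of initialized mu over many draws approaches the prior
  # matrix within Monte-Carlo error 3 * (1 / sqrt(tau0)) / sqrt(n)
  set.seed(7)
  n <- 10000
  acc <- matrix(0, nrow(d$truth_prior), ncol(d$truth_prior))
  tiny <- d$expr[1, , drop = FALSE]
  for (r in seq_len(n)) acc <- acc + initialize_state(tiny, d$truth_prior, ctrl)$mu
  tol <- 3 * (1 / sqrt(ctrl$tau0)) / sqrt(n)
  expect_true(all(abs(acc / n - d$truth_prior) < tol))
})

test_that("contribution update concentrates on the matching type", {
  # one cell whose expression equals the second profile exactly
  expr <- expression_matrix(matrix(10, 1, 1), "c1", "m1")
  ctrl <- seg_control()
  st <- list(mu = matrix(c(0, 10), 2, 1), tau = 100,
             rho = matrix(c(0.5, 0.5), 1, 2))
  set.seed(8)
  draws <- numeric(5000)
  for (s in seq_along(draws)) {
    st <- update_rho(st, expr, ctrl, step = 0.8)
    draws[s] <- st$rho[1, 2]
  }
  expect_gt(mean(draws[1001:5000]), 0.95)
})

test_that("contribution update targets the exact conditional (grid oracle)", {
  # fixed profile means and precision; 1 cell, 1 marker, 2 types
  mu <- c(0, 3); tau <- 4; y <- 1.2; kappa <- 0.1
  expr <- expression_matrix(matrix(y, 1, 1), "c1", "m1")
  ctrl <- seg_control(kappa = kappa)
  st <- list(mu = matrix(mu, 2, 1), tau = tau, rho = matrix(0.5, 1, 2))
  set.seed(9)
  n <- 30000
  draws <- numeric(n)
  for (s in seq_len(n)) {
    st <- update_rho(st, expr, ctrl, step = 1.2)
    draws[s] <- st$rho[1, 1]
  }
  draws <- draws[5001:n]
  breaks <- seq(0, 1, by = 0.1)
  expected <- oracle_rho_conditional_bins(y, mu, tau, kappa, breaks)
  observed <- table(cut(draws, breaks, include.lowest = TRUE)) / length(draws)
  tv <- 0.5 * sum(abs(as.numeric(expected) - as.numeric(observed)))
  expect_lt(tv, 0.05)
})

test_that("profile-mean update matches its conjugate conditional", {
  ctrl <- seg_control()

  # component with zero contribution: conditional reduces to the prior
  expr <- expression_matrix(matrix(c(5, 5), 2, 1), c("c1", "c2"), "m1")
  prior <- prior_matrix(matrix(c(0, 3), 2, 1), c("t1", "t2"), "m1")
  st0 <- list(mu = matrix(c(0, 3), 2, 1), tau = 2,
              rho = matrix(c(1, 1, 0, 0), 2, 2))
  set.seed(10)
  draws <- vapply(1:4000, function(s)
    update_mu(st0, expr, prior, ctrl)$mu[2, 1], numeric(1))
  expect_equal(mean(draws), 3, tolerance = 4 * (1 / sqrt(10)) / sqrt(4000) * 3)
  expect_equal(sd(draws), 1 / sqrt(ctrl$tau0), tolerance = 0.03)

  # single fully-assigned cell: normal-normal conjugacy
  expr1 <- expression_matrix(matrix(2, 1, 1), "c1", "m1")
  prior1 <- prior_matrix(matrix(c(0, 99), 2, 1), c("t1", "t2"), "m1")
  tau <- 5
  st1 <- list(mu = matrix(c(0, 99), 2, 1), tau = tau,
              rho = matrix(c(1, 0), 1, 2))
  set.seed(11)
  draws <- vapply(1:4000, function(s)
    update_mu(st1, expr1, prior1, ctrl)$mu[1, 1], numeric(1))
  expect_equal(mean(draws), (ctrl$tau0 * 0 + tau * 2) / (ctrl$tau0 + tau),
               tolerance = 4 / sqrt(ctrl$tau0 + tau) / sqrt(4000) * 3)
  expect_equal(sd(draws), 1 / sqrt(ctrl$tau0 + tau), tolerance = 0.03)
})

test_that("precision update matches its conjugate conditional", {
  # ten cells with zero residuals: conditional is Gamma(alpha0 + 5, beta0)
  prior <- prior_matrix(matrix(c(1, 0), 2, 1), c("t1", "t2"), "m1")
  expr <- expression_matrix(matrix(1, 10, 1))
  st <- list(mu = matrix(c(1, 0), 2, 1), tau = 1,
             rho = matrix(rep(c(1, 0), each = 10), 10, 2))
  ctrl <- seg_control(alpha0 = 2, beta0 = 1)
  set.seed(12)
  draws <- vapply(1:4000, function(s)
    update_tau(st, expr, ctrl)$tau[1], numeric(1))
  expect_equal(mean(draws), 7, tolerance = 3 * sqrt(7) / sqrt(4000) * 3)
})

test_that("emission precision is recovered from simulated data", {
  d <- make_fixture(n_cells = 500, n_markers = 4, n_types = 3,
                    noise_tau = 25, seed = 21)
  fit <- segfit(d$expr, d$truth_prior,
                seg_control(n_iterations = 1500, seed = 3), keep_trace = FALSE)
  expect_true(all(abs(coef(fit, "tau") - 25) / 25 < 0.2))
})

test_that("conjugate and pure-Metropolis modes agree", {
  d <- make_fixture(n_cells = 40, n_markers = 2, n_types = 2,
                    noise_tau = 9, seed = 31)
  fit_c <- segfit(d$expr, d$truth_prior,
                  seg_control(n_iterations = 4000, seed = 13,
                              sampler_mode = "conjugate"))
  fit_m <- segfit(d$expr, d$truth_prior,
                  seg_control(n_iterations = 4000, seed = 13,
                              sampler_mode = "mh", mu_step = 0.05,
                              tau_step = 0.25))
  keep <- which(fit_c$trace$mu_iters > 2000)
  for (k in 1:2) for (j in 1:2) {
    x_c <- fit_c$trace$mu_samples[keep, k, j]
    x_m <- fit_m$trace$mu_samples[keep, k, j]
    tol <- max(0.03, 3 * sqrt(batch_se(x_c)^2 + batch_se(x_m)^2))
    expect_lt(abs(mean(x_c) - mean(x_m)), tol)
  }
  expect_true(all(unlist(fit_m$acceptance) > 0.05))
})

test_that("the sampler is deterministic given a seed and stores full traces", {
  tiny <- make_tiny()
  ctrl <- seg_control(n_iterations = 10, seed = 99, thin_rho = 1)
  t1 <- run_sampler(tiny$expr, tiny$prior, ctrl)
  t2 <- run_sampler(tiny$expr, tiny$prior, ctrl)
  expect_identical(t1$mu_samples, t2$mu_samples)
  expect_identical(t1$rho_samples, t2$rho_samples)
  expect_identical(t1$tau_samples, t2$tau_samples)
  expect_equal(dim(t1$mu_samples)[1], 10)
  expect_true(all(abs(apply(t1$rho_samples, 1, rowSums) - 1) < 1e-9))
})

test_that("the default iteration count is ten thousand sweeps", {
  tiny <- make_tiny()
  ctrl <- seg_control(seed = 1)
  expect_equal(ctrl$n_iterations, 10000L)
  tr <- run_sampler(tiny$expr, tiny$prior, ctrl)
  expect_equal(tr$n_iterations, 10000L)
  expect_equal(dim(tr$mu_samples)[1], 10000L)
})

test_that("trace summarization drops the first half and renormalizes rho", {
  tiny <- make_tiny()
  tr <- run_sampler(tiny$expr, tiny$prior,
                    seg_control(n_iterations = 20, seed = 2, thin_rho = 1))
  # overwrite with a deterministic ramp to check the burn-in arithmetic
  tr$mu_samples[] <- rep(1:20, times = 2)  # value = iteration index
  tr$n_iterations <- 20L
  tr$mu_iters <- 1:20
  s <- summarize_trace(tr, burn_in_fraction = 0.5)
  expect_equal(unname(s$mu_hat[1, 1]), mean(11:20))

  # n = 10, samples 1..10, burn-in half: mean of 6..10 = 8
  tr10 <- run_sampler(tiny$expr, tiny$prior,
                      seg_control(n_iterations = 10, seed = 2, thin_rho = 1))
  tr10$mu_samples[] <- rep(1:10, times = 2)
  s10 <- summarize_trace(tr10)
  expect_equal(unname(s10$mu_hat[1, 1]), 8)

  # constant trace summarizes to the constant; rho rows renormalized
  trc <- tr
  trc$mu_samples[] <- 1.5
  trc$rho_samples[] <- 0.5
  sc <- summarize_trace(trc)
  expect_true(all(sc$mu_hat == 1.5))
  expect_true(all(abs(rowSums(sc$rho_hat) - 1) < 1e-9))
})

test_that("contribution acceptance rate stays in a healthy band", {
  d <- make_fixture(n_cells = 150, n_markers = 6, n_types = 3, seed = 17)
  fit <- segfit(d$expr, d$truth_prior,
                seg_control(n_iterations = 1000, seed = 4), keep_trace = FALSE)
  expect_gt(fit$acceptance$rho, 0.1)
  expect_lt(fit$acceptance$rho, 0.9)
})

test_that("well-separated simulated types are recovered by the posterior", {
  d <- make_fixture(n_cells = 200, n_markers = 8, n_types = 3,
                    noise_tau = 100, seed = 23)
  fit <- segfit(d$expr, d$truth_prior,
                seg_control(n_iterations = 1500, seed = 6), keep_trace = FALSE)
  rho <- coef(fit, "rho")
  on_truth <- rho[cbind(seq_len(nrow(rho)), d$truth_types)]
  expect_gt(mean(on_truth > 0.9), 0.9)
})

test_that("trace report writes plots and a complete sample dump", {
  tiny <- make_tiny()
  tr <- run_sampler(tiny$expr, tiny$prior,
                    seg_control(n_iterations = 10, seed = 3, thin_rho = 2))
  dir <- withr::local_tempdir()
  write_trace_report(tr, dir, cells = 1L)
  expect_true(file.exists(file.path(dir, "trace_plots.pdf")))
  dump <- read.csv(file.path(dir, "trace_samples.csv"))
  expect_equal(sum(dump$variable == "mu" & dump$component == "t1:m1"), 10)
  expect_equal(sum(dump$variable == "rho" & dump$component == "c1:t1"), 5)

  # empty cell subset: mu/tau output only, no error
  dir2 <- withr::local_tempdir()
  expect_silent(write_trace_report(tr, dir2, cells = integer()))
  dump2 <- read.csv(file.path(dir2, "trace_samples.csv"))
  expect_false(any(dump2$variable == "rho"))
})
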