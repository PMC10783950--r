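test_that("synthetic profiles have block structure scaling with separation", {
  # two types, two markers: diagonal profiles at the separation value
  cfg <- sim_config(n_cells = 10, n_markers = 2, n_types = 2,
                    profile_separation = 3)
  p <- make_profiles(cfg)
  expect_equal(unname(unclass(p)), matrix(c(3, 0, 0, 3), 2, 2))

  # zero separation collapses all profiles
  cfg0 <- sim_config(n_cells = 10, n_markers = 5, n_types = 3,
                     profile_separation = 0)
  p0 <- make_profiles(cfg0)
  expect_true(all(p0 == p0[1, 1]))

  # full benchmark shape: all pairwise distances positive
  cfg13 <- sim_config(n_cells = 10, n_markers = 13, n_types = 10)
  d <- dist(make_profiles(cfg13))
  expect_true(all(d > 0))
})

test_that("forward simulation honours seed, proportions and the noiseless limit", {
  cfg <- sim_config(n_cells = 2000, n_markers = 6, n_types = 4, seed = 33)
  ds1 <- simulate_well(cfg)
  ds2 <- simulate_well(cfg)
  expect_identical(ds1$expr, ds2$expr)
  expect_identical(ds1$truth_types, ds2$truth_types)
  expect_length(ds1$error_log, 0)

  # uniform proportions: binomial concentration of type counts
  counts <- table(ds1$truth_types)
  expect_true(all(abs(counts - 500) < 3 * sqrt(2000 * 0.25 * 0.75)))

  # near-noiseless limit reproduces the profiles
  cfg_hi <- sim_config(n_cells = 50, n_markers = 6, n_types = 3,
                       noise_tau = 1e8, seed = 34)
  ds_hi <- simulate_well(cfg_hi)
  prof <- ds_hi$truth_prior[ds_hi$truth_types, ]
  expect_true(max(abs(ds_hi$expr - prof)) < 1e-3)
})

test_that("partial injection scales the chosen cells and logs them", {
  ds <- make_fixture(n_cells = 2000, n_markers = 4, seed = 35)
  set.seed(1)
  out <- inject_partial(ds, fraction = 0.2)
  expect_equal(nrow(out$expr), 2000)
  expect_length(out$error_log[[1]]$cell_ids, 400)
  expect_equal(out$error_log[[1]]$error_type, "partial")
  untouched <- setdiff(rownames(ds$expr), out$error_log[[1]]$cell_ids)
  expect_identical(out$expr[untouched, ], ds$expr[untouched, ])

  # deterministic hook: every value exactly halved at fraction 1
  out2 <- inject_partial(ds, fraction = 1, f_fixed = 0.5)
  expect_equal(unclass(out2$expr), unclass(ds$expr) * 0.5)

  # fraction 0 leaves the matrix untouched
  out0 <- inject_partial(ds, fraction = 0)
  expect_identical(out0$expr, ds$expr)
})

test_that("split injection conserves expression in the noiseless hook and counts cells", {
  ds <- make_fixture(n_cells = 2000, n_markers = 4, seed = 36)
  set.seed(2)
  out <- inject_split(ds, fraction = 0.25)
  expect_equal(nrow(out$expr), 2500)
  expect_equal(length(out$truth_types), 2500)

  set.seed(3)
  hook <- inject_split(ds, fraction = 0.1, s_fixed = 0.5, add_noise = FALSE)
  sel <- hook$error_log[[1]]$cell_ids
  frag_sum <- hook$expr[paste0(sel, ".s1"), ] + hook$expr[paste0(sel, ".s2"), ]
  expect_equal(unname(unclass(frag_sum)), unname(unclass(ds$expr[sel, ])),
               tolerance = 1e-12)
  # fragments inherit the parent's type
  expect_equal(hook$truth_types[match(paste0(sel, ".s1"), rownames(hook$expr))],
               ds$truth_types[match(sel, rownames(ds$expr))])
})

test_that("merge injection pairs different types, mixes expressions, and counts cells", {
  ds <- make_fixture(n_cells = 2000, n_markers = 4, seed = 37)
  set.seed(4)
  out <- inject_merge(ds, fraction = 0.5)
  expect_equal(nrow(out$expr), 1500)
  expect_length(out$error_log[[1]]$pairs, 500)
  ids <- rownames(ds$expr)
  cross <- vapply(out$error_log[[1]]$pairs, function(pr)
    ds$truth_types[match(pr[1], ids)] != ds$truth_types[match(pr[2], ids)],
    logical(1))
  expect_true(all(cross))

  # deterministic hook: merged cell is the midpoint of its parents
  set.seed(5)
  hook <- inject_merge(ds, fraction = 0.01, w_fixed = 0.5)
  pr <- hook$error_log[[1]]$pairs[[1]]
  mid <- 0.5 * ds$expr[pr[1], ] + 0.5 * ds$expr[pr[2], ]
  expect_equal(hook$expr[paste(pr, collapse = "+"), ], mid, tolerance = 1e-12)

  # single-type data: falls back to same-type pairs with a warning
  uni <- ds
  uni$truth_types[] <- 1L
  set.seed(6)
  expect_warning(inject_merge(uni, fraction = 0.1), "same-type")
})

test_that("cell-count bookkeeping holds across chained injections", {
  ds <- make_fixture(n_cells = 500, n_markers = 4, seed = 38)
  set.seed(7)
  n_split <- 50
  n_pairs <- 40
  out <- inject_split(ds, fraction = n_split / 500)
  out <- inject_merge(out, fraction = 2 * n_pairs / nrow(out$expr))
  expect_equal(nrow(out$expr), 500 + n_split - n_pairs)
  expect_equal(length(out$truth_types), nrow(out$expr))
})

test_that("the benchmark grid instantiates the published dataset counts", {
  g2 <- study_grid()  # both tested fractions per error type
  expect_equal(sum(g2$condition == "well"), 45)
  expect_equal(sum(g2$condition != "well"), 270)

  g1 <- study_grid(fractions = list(partial = 0.2, split = 0.25, merge = 0.25))
  expect_equal(sum(g1$condition == "well"), 45)
  expect_equal(nrow(g1), 180)
})

test_that("a reduced study run completes and reports matched percent increases", {
  res <- run_simulation_study(k_values = 3, replicates = 1, n_cells = 200,
                              n_markers = 13, n_iterations = 800,
                              fractions = list(partial = 0.2, split = 0.25,
                                               merge = 0.25),
                              seed = 11)
  expect_equal(nrow(res), 4)
  expect_setequal(res$condition, c("well", "partial", "split", "merge"))
  expect_true(all(is.finite(res$avg_entropy)))
  expect_true(is.na(res$pct_increase[res$condition == "well"]))
  expect_equal(res$n_cells_out[res$condition == "split"], 250)
  expect_equal(res$n_cells_out[res$condition == "merge"], 175)
})

test_that("injected merge errors raise average entropy in most seeded replicates", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_cells = 150, n_markers = 6, n_types = 3, seed = 400 + s)
    well <- simulate_well(cfg)
    set.seed(500 + s)
    err <- inject_merge(well, fraction = 0.25)
    fw <- segfit(well$expr, well$truth_prior,
                 seg_control(n_iterations = 800, seed = 600 + s),
                 keep_trace = FALSE)
    fe <- segfit(err$expr, err$truth_prior,
                 seg_control(n_iterations = 800, seed = 700 + s),
                 keep_trace = FALSE)
    if (fe$entropy$average_entropy > fw$entropy$average_entropy) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
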