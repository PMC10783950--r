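#' Configuration for the forward simulator
#'
#' The default grid reproduces the simulation benchmark: 13-marker
#' expression matrices of 2000 cells with the cell-type count enumerated
#' from 2 to 10, 5 replicates each (45 well-segmented matrices), to which
#' the three error injectors are applied. Profiles are synthetic lineage
#' profiles: each type dominantly expresses its own block of markers,
#' `profile_separation` above a common baseline, with Gaussian emission
#' noise of precision `noise_tau` (default 25, i.e. noise SD 0.2 —
#' well-separated at the default separation of 1 on a unit intensity scale).
#'
#' @param n_cells number of cells I.
#' @param n_markers number of markers J.
#' @param n_types number of cell types K (2..10 in the benchmark grid).
#' @param replicates replicates per K in the study grid.
#' @param type_proportions simplex of length K (default uniform).
#' @param profile_separation dominant-block elevation above baseline.
#' @param baseline baseline intensity of non-dominant markers.
#' @param noise_tau emission precision (scalar or length J).
#' @param seed optional integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 2000L, n_markers = 13L, n_types = 4L,
                       replicates = 5L, type_proportions = NULL,
                       profile_separation = 1, baseline = 0,
                       noise_tau = 25, seed = NULL) {
  stopifnot(n_cells >= 1, n_markers >= 1, n_types >= 2, replicates >= 1,
            profile_separation >= 0, all(noise_tau > 0))
  if (is.null(type_proportions)) type_proportions <- rep(1 / n_types, n_types)
  stopifnot(length(type_proportions) == n_types,
            abs(sum(type_proportions) - 1) < 1e-9, all(type_proportions >= 0))
  if (n_types > n_markers)
    warning("more cell types than markers; dominant markers will be shared")
  structure(list(
    n_cells = as.integer(n_cells), n_markers = as.integer(n_markers),
    n_types = as.integer(n_types), replicates = as.integer(replicates),
    type_proportions = type_proportions,
    profile_separation = profile_separation, baseline = baseline,
    noise_tau = noise_tau,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Synthetic lineage profiles
#'
#' Builds a K x J profile matrix in which each cell type dominantly
#' expresses its own contiguous block of markers (`baseline +
#' profile_separation`) and all others at `baseline` — the idealized
#' "one lineage marker per type" prior design. Pairwise Euclidean
#' separation scales linearly with `profile_separation`.
#'
#' @param cfg a [sim_config()].
#' @return K x J [prior_matrix()].
#' @export
make_profiles <- function(cfg) {
  K <- cfg$n_types; J <- cfg$n_markers
  blocks <- split(seq_len(J), sort(rep_len(seq_len(K), J)))
  vals <- matrix(cfg$baseline, K, J)
  for (k in seq_len(K)) vals[k, blocks[[min(k, length(blocks))]]] <-
      cfg$baseline + cfg$profile_separation
  prior_matrix(vals,
               cell_type_names = paste0("type_", seq_len(K)),
               marker_names = paste0("marker_", seq_len(J)))
}

#' Simulate a well-segmented expression matrix
#'
#' Forward simulation from the generative model: each cell's type is drawn
#' from `type_proportions`, its contribution vector is one-hot at that type,
#' and marker intensities are the type profile plus Gaussian noise of
#' precision `noise_tau`.
#'
#' @param cfg a [sim_config()].
#' @param profiles optional K x J profile matrix (default [make_profiles()]).
#' @return list of class `"sim_dataset"`: `expr` (I x J matrix),
#'   `truth_types` (integer vector), `truth_prior` (the generating
#'   profiles), `error_log` (empty list for a well dataset), `config`.
#' @export
simulate_well <- function(cfg, profiles = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(profiles)) profiles <- make_profiles(cfg)
  I <- cfg$n_cells; J <- cfg$n_markers; K <- cfg$n_types
  types <- sample.int(K, I, replace = TRUE, prob = cfg$type_proportions)
  sds <- rep(1 / sqrt(cfg$noise_tau), length.out = J)
  noise <- matrix(rnorm(I * J, sd = rep(sds, each = I)), I, J)
  Y <- profiles[types, , drop = FALSE] + noise
  expr <- expression_matrix(Y, cell_ids = paste0("cell_", seq_len(I)),
                            marker_names = colnames(profiles))
  structure(list(expr = expr, truth_types = types, truth_prior = profiles,
                 error_log = list(), config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d cells x %d markers, K = %d types\n",
              nrow(x$expr), ncol(x$expr), nrow(x$truth_prior)))
  if (length(x$error_log)) {
    for (e in x$error_log)
      cat(sprintf("  injected %s error affecting %d cells\n",
                  e$error_type, length(e$cell_ids)))
  } else cat("  well segmented (no errors injected)\n")
  invisible(x)
}

select_cells <- function(ds, fraction, cells) {
  ids <- rownames(ds$expr)
  if (!is.null(cells)) {
    if (is.numeric(cells)) cells <- ids[cells]
    stopifnot(all(cells %in% ids))
    return(as.character(cells))
  }
  stopifnot(fraction >= 0, fraction <= 1)
  n <- ceiling(fraction * nrow(ds$expr))
  if (n == 0L) character() else sample(ids, n)
}

#' Inject partial-segmentation errors
#'
#' Models masks that capture only part of a cell: each affected cell's
#' expression row is scaled by a factor drawn uniformly from `f_range`
#' (lost cell area lowers every channel's mean intensity). The cell count
#' is unchanged; affected ids are appended to the error log.
#'
#' @param ds a `"sim_dataset"`.
#' @param fraction fraction of cells to affect (subset drawn uniformly).
#' @param f_range range of the per-cell intensity-retention factor.
#' @param f_fixed deterministic factor overriding `f_range` (test hook).
#' @param cells explicit cell ids/indices to affect, overriding `fraction`.
#' @return modified `"sim_dataset"`.
#' @export
inject_partial <- function(ds, fraction, f_range = c(0.2, 0.6),
                           f_fixed = NULL, cells = NULL) {
  sel <- select_cells(ds, fraction, cells)
  if (length(sel)) {
    f <- if (is.null(f_fixed)) runif(length(sel), f_range[1], f_range[2])
         else rep(f_fixed, length(sel))
    ds$expr[sel, ] <- ds$expr[sel, , drop = FALSE] * f
  }
  ds$error_log <- c(ds$error_log,
                    list(list(error_type = "partial", cell_ids = sel)))
  ds
}

#' Inject split-segmentation errors
#'
#' Models one cell split into two masks: each affected cell is replaced by
#' two fragments with expressions `s * y` and `(1 - s) * y`,
#' `s ~ Uniform(s_range)`, each plus fresh emission noise. The cell count
#' increases by the number of split cells; both fragments inherit the
#' parent's true type and are logged.
#'
#' @param ds a `"sim_dataset"`.
#' @param fraction fraction of cells to split.
#' @param s_range range of the split proportion.
#' @param s_fixed deterministic split proportion (test hook).
#' @param add_noise add fresh Gaussian emission noise to the fragments
#'   (disable for the exact-conservation test hook).
#' @param cells explicit cells to split.
#' @return modified `"sim_dataset"`.
#' @export
inject_split <- function(ds, fraction, s_range = c(0.4, 0.6),
                         s_fixed = NULL, add_noise = TRUE, cells = NULL) {
  sel <- select_cells(ds, fraction, cells)
  if (length(sel)) {
    idx <- match(sel, rownames(ds$expr))
    s <- if (is.null(s_fixed)) runif(length(sel), s_range[1], s_range[2])
         else rep(s_fixed, length(sel))
    J <- ncol(ds$expr)
    sds <- rep(1 / sqrt(ds$config$noise_tau), length.out = J)
    noise <- function() {
      if (!add_noise) return(matrix(0, length(sel), J))
      matrix(rnorm(length(sel) * J, sd = rep(sds, each = length(sel))),
             length(sel), J)
    }
    parent <- ds$expr[idx, , drop = FALSE]
    frag1 <- parent * s + noise()
    frag2 <- parent * (1 - s) + noise()
    rownames(frag1) <- paste0(sel, ".s1")
    rownames(frag2) <- paste0(sel, ".s2")
    keep <- setdiff(seq_len(nrow(ds$expr)), idx)
    new_expr <- rbind(ds$expr[keep, , drop = FALSE], frag1, frag2)
    new_types <- c(ds$truth_types[keep],
                   ds$truth_types[idx], ds$truth_types[idx])
    ds$expr <- expression_matrix(new_expr)
    ds$truth_types <- new_types
  }
  ds$error_log <- c(ds$error_log,
                    list(list(error_type = "split", cell_ids = sel)))
  ds
}

#' Inject merge-segmentation errors
#'
#' Models neighboring cells merged into one mask: disjoint pairs of cells —
#' preferentially of *different* true types, since cross-type merges are
#' what corrupt expression profiles — are each replaced by one cell with
#' expression `w * y_a + (1 - w) * y_b`, `w ~ Uniform(w_range)`. Pairs are
#' formed until `ceiling(fraction * I)` original cells are consumed (one
#' merge consumes two); if cross-type pairs run out, same-type pairs are
#' used with a warning.
#'
#' @param ds a `"sim_dataset"`.
#' @param fraction fraction of original cells consumed by merges.
#' @param w_range range of the mixing weight.
#' @param w_fixed deterministic mixing weight (test hook).
#' @param cells explicit pool of cells eligible for merging.
#' @return modified `"sim_dataset"`.
#' @export
inject_merge <- function(ds, fraction, w_range = c(0.4, 0.6),
                         w_fixed = NULL, cells = NULL) {
  ids <- rownames(ds$expr)
  pool <- if (is.null(cells)) sample(ids) else {
    if (is.numeric(cells)) cells <- ids[cells]
    sample(as.character(cells))
  }
  n_consumed <- ceiling(fraction * nrow(ds$expr))
  n_pairs <- floor(min(n_consumed, length(pool)) / 2)
  pairs <- list(); used <- character()
  fallback <- FALSE
  remaining <- pool
  while (length(pairs) < n_pairs && length(remaining) >= 2L) {
    a <- remaining[1L]
    ta <- ds$truth_types[match(a, ids)]
    partner_pos <- which(ds$truth_types[match(remaining[-1L], ids)] != ta)[1L]
    if (is.na(partner_pos)) {
      b <- remaining[2L]  # no cross-type partner left
      fallback <- TRUE
    } else b <- remaining[-1L][partner_pos]
    pairs[[length(pairs) + 1L]] <- c(a, b)
    used <- c(used, a, b)
    remaining <- setdiff(remaining, c(a, b))
  }
  if (fallback)
    warning("not enough cross-type pairs; some same-type pairs merged")
  if (length(pairs)) {
    w <- if (is.null(w_fixed)) runif(length(pairs), w_range[1], w_range[2])
         else rep(w_fixed, length(pairs))
    merged <- t(vapply(seq_along(pairs), function(m) {
      pr <- pairs[[m]]
      w[m] * ds$expr[pr[1L], ] + (1 - w[m]) * ds$expr[pr[2L], ]
    }, numeric(ncol(ds$expr))))
    rownames(merged) <- vapply(pairs, function(pr) paste(pr, collapse = "+"),
                               character(1))
    # merged cell keeps the majority-weight parent's true type
    merged_types <- vapply(seq_along(pairs), function(m) {
      pr <- pairs[[m]]
      ds$truth_types[match(if (w[m] >= 0.5) pr[1L] else pr[2L], ids)]
    }, integer(1))
    keep <- !(ids %in% used)
    ds$expr <- expression_matrix(rbind(ds$expr[keep, , drop = FALSE], merged))
    ds$truth_types <- c(ds$truth_types[keep], merged_types)
  }
  ds$error_log <- c(ds$error_log,
                    list(list(error_type = "merge", cell_ids = used,
                              pairs = pairs)))
  ds
}

#' Enumerate the simulation study grid
#'
#' One row per dataset: every (K, replicate) combination yields a well
#' dataset plus one error dataset per error type and fraction. The default
#' fractions are the two tested per error type; passing a single fraction
#' per type gives the smaller one-fraction-per-type design.
#'
#' @param k_values cell-type counts.
#' @param replicates replicates per K.
#' @param fractions named list of affected-cell fractions per error type.
#' @return data.frame with columns `k`, `replicate`, `condition`, `fraction`.
#' @export
study_grid <- function(k_values = 2:10, replicates = 5L,
                       fractions = list(partial = c(0.2, 0.5),
                                        split = c(0.25, 0.5),
                                        merge = c(0.25, 0.5))) {
  base <- expand.grid(k = k_values, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list(data.frame(base, condition = "well", fraction = NA_real_))
  for (cond in names(fractions)) for (f in fractions[[cond]]) {
    rows[[length(rows) + 1L]] <- data.frame(base, condition = cond, fraction = f)
  }
  out <- do.call(rbind, rows)
  out[order(out$k, out$replicate), , drop = FALSE]
}

#' Run the simulation benchmark
#'
#' For every (K, replicate) cell of the grid, simulates a well-segmented
#' dataset, corrupts copies of it with each error condition, fits the model
#' to each (using the generating profiles as the prior matrix), and reports
#' average entropies and percent increases over the matched well fit. The
#' two partial fractions are nested: the smaller affected set is a subset
#' of the larger, matching a design in which an additional share of cells
#' is corrupted on top of the first.
#'
#' @param k_values cell-type counts to simulate.
#' @param replicates replicates per K.
#' @param n_cells,n_markers dataset dimensions.
#' @param fractions named list of fractions per error type (as in
#'   [study_grid()]).
#' @param n_iterations MCMC sweeps per fit.
#' @param profile_separation,noise_tau,baseline generator settings.
#' @param seed master seed; every dataset and fit seed derives from it.
#' @param verbose print one line per fitted dataset.
#' @return data.frame with one row per fitted dataset: `k`, `replicate`,
#'   `condition`, `fraction`, `n_cells_out`, `avg_entropy`, `pct_increase`
#'   (NA for well rows).
#' @export
run_simulation_study <- function(k_values = 2:10, replicates = 5L,
                                 n_cells = 2000L, n_markers = 13L,
                                 fractions = list(partial = c(0.2, 0.5),
                                                  split = c(0.25, 0.5),
                                                  merge = c(0.25, 0.5)),
                                 n_iterations = 10000L,
                                 profile_separation = 1, noise_tau = 25,
                                 baseline = 0,
                                 seed = 1L, verbose = FALSE) {
  results <- list()
  dataset_counter <- 0L
  for (k in k_values) for (r in seq_len(replicates)) {
    dataset_counter <- dataset_counter + 1L
    ds_seed <- as.integer((seed * 10007L + dataset_counter * 337L) %% .Machine$integer.max)
    cfg <- sim_config(n_cells = n_cells, n_markers = n_markers, n_types = k,
                      profile_separation = profile_separation,
                      noise_tau = noise_tau, baseline = baseline,
                      seed = ds_seed)
    well <- simulate_well(cfg)

    variants <- list(list(condition = "well", fraction = NA_real_, ds = well))
    set.seed(ds_seed + 1L)
    if (!is.null(fractions$partial)) {
      fr <- sort(fractions$partial)
      sel_max <- sample(rownames(well$expr), ceiling(max(fr) * n_cells))
      for (f in fr) {
        sel <- sel_max[seq_len(ceiling(f * n_cells))]  # nested subsets
        variants[[length(variants) + 1L]] <-
          list(condition = "partial", fraction = f,
               ds = inject_partial(well, f, cells = sel))
      }
    }
    for (f in fractions$split) {
      variants[[length(variants) + 1L]] <-
        list(condition = "split", fraction = f, ds = inject_split(well, f))
    }
    for (f in fractions$merge) {
      variants[[length(variants) + 1L]] <-
        list(condition = "merge", fraction = f, ds = inject_merge(well, f))
    }

    well_entropy <- NA_real_
    for (v in variants) {
      fit_seed <- as.integer((ds_seed + 7919L *
        match(v$condition, c("well", "partial", "split", "merge")) +
        1000 * max(v$fraction, 0, na.rm = TRUE)) %% .Machine$integer.max)
      ctrl <- seg_control(n_iterations = n_iterations, seed = fit_seed,
                          thin_rho = max(10L, n_iterations %/% 200L))
      fit <- tryCatch(
        segfit(v$ds$expr, v$ds$truth_prior, ctrl, keep_trace = FALSE),
        error = function(e) stop(sprintf(
          "fit failed for dataset K=%d rep=%d condition=%s: %s",
          k, r, v$condition, conditionMessage(e))))
      h <- fit$entropy$average_entropy
      if (v$condition == "well") well_entropy <- h
      results[[length(results) + 1L]] <- data.frame(
        k = k, replicate = r, condition = v$condition, fraction = v$fraction,
        n_cells_out = nrow(v$ds$expr), avg_entropy = h,
        pct_increase = if (v$condition == "well") NA_real_
                       else percent_increase(h, well_entropy))
      if (verbose)
        message(sprintf("K=%d rep=%d %s%s: avg entropy %.4f", k, r,
                        v$condition,
                        if (is.na(v$fraction)) "" else sprintf("@%.2f", v$fraction),
                        h))
    }
  }
  do.call(rbind, results)
}
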