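#' Shannon entropy of one contribution vector
#'
#' `-sum_k p_k log p_k` with `0 log 0 := 0`. A cell explained entirely by one
#' cell type has entropy 0; a cell needing an even mixture of all K types
#' attains the maximum `log K`.
#'
#' @param p numeric vector on the simplex (checked to within 1e-6).
#' @param base logarithm base; `exp(1)` (nats, default) or 2 (bits).
#' @return non-negative scalar.
#' @export
cell_entropy <- function(p, base = exp(1)) {
  if (anyNA(p) || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("contribution vector is not on the simplex")
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Per-cell and average entropy of an image
#'
#' The package's quality score: per-cell Shannon entropies of the posterior
#' contribution estimates, their arithmetic mean (the image-level score),
#' and a low/high partition by entropy quantile. A well-segmented image has
#' entropies close to 0.
#'
#' @param rho_hat I x K matrix of posterior mean contributions, rows on the
#'   simplex (e.g. `coef(fit, "rho")` or `summarize_trace(trace)$rho_hat`).
#' @param cell_ids optional cell identifiers (default: rownames).
#' @param base entropy logarithm base.
#' @param normalized divide entropies by `log K` so scores are comparable
#'   across different K.
#' @param low_fraction quantile for the low/high-entropy partition.
#' @return object of class `"entropy_report"`: data.frame `cells` with
#'   columns `cell_id`, `entropy`, `partition`, plus fields
#'   `average_entropy`, `k`, `n`, `base`, `normalized`.
#' @export
entropy_report <- function(rho_hat, cell_ids = rownames(rho_hat),
                           base = exp(1), normalized = FALSE,
                           low_fraction = 0.25) {
  rho_hat <- as.matrix(rho_hat)
  if (nrow(rho_hat) < 1L) stop("need at least one cell")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(rho_hat)))
  ent <- apply(rho_hat, 1L, cell_entropy, base = base)
  K <- ncol(rho_hat)
  if (normalized) ent <- ent / (log(K) / log(base))
  part <- entropy_partition(ent, low_fraction = low_fraction)
  structure(list(
    cells = data.frame(cell_id = as.character(cell_ids), entropy = ent,
                       partition = part, row.names = NULL),
    average_entropy = mean(ent),
    k = K, n = nrow(rho_hat), base = base, normalized = normalized,
    low_fraction = low_fraction
  ), class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("Entropy report: %d cells, K = %d cell types\n", x$n, x$k))
  cat(sprintf("  average entropy: %.4f %s(max log K = %.4f)\n",
              x$average_entropy,
              if (x$normalized) "(normalized) " else "",
              if (x$normalized) 1 else log(x$k) / log(x$base)))
  cat(sprintf("  low-entropy partition: %d of %d cells (fraction %.2f)\n",
              sum(x$cells$partition == "low"), x$n, x$low_fraction))
  invisible(x)
}

#' Partition cells into low/high entropy groups
#'
#' Labels the `low_fraction` of cells with the lowest entropy `"low"` and
#' the rest `"high"`; ties are broken by stable cell order.
#'
#' @param entropy numeric vector of per-cell entropies.
#' @param low_fraction fraction in (0, 1) labeled `"low"`.
#' @return character vector of labels aligned with `entropy`.
#' @export
entropy_partition <- function(entropy, low_fraction = 0.25) {
  stopifnot(low_fraction > 0, low_fraction < 1)
  n_low <- ceiling(low_fraction * length(entropy))
  out <- rep("high", length(entropy))
  out[order(entropy)[seq_len(n_low)]] <- "low"
  out
}

#' Compare average entropies between two segmentation conditions
#'
#' Tests whether the set of image-level average entropies differs between a
#' reference ("well") and an alternative (typically error-introduced)
#' condition. The default is the unpaired Wilcoxon rank-sum test; a paired
#' signed-rank variant and Student's t-test (used for per-ROI comparisons)
#' are available.
#'
#' @param well,err numeric vectors of average entropies per image.
#' @param paired use the paired variant (requires equal lengths).
#' @param method `"wilcoxon"` or `"t"`.
#' @return list of class `"seg_comparison"`: `statistic`, `p_value`,
#'   `direction` (which condition has the higher mean), `degenerate`
#'   (all values identical), `method`, `paired`.
#' @export
compare_conditions <- function(well, err, paired = FALSE,
                               method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(length(well) >= 3L, length(err) >= 3L)
  if (paired && length(well) != length(err))
    stop("paired comparison requires equal-length vectors")
  degenerate <- length(unique(c(well, err))) == 1L
  direction <- if (mean(err) > mean(well)) "err > well"
               else if (mean(err) < mean(well)) "err < well" else "equal"
  if (degenerate) {
    res <- list(statistic = NA_real_, p_value = 1)
  } else if (method == "wilcoxon") {
    ht <- suppressWarnings(wilcox.test(err, well, paired = paired, exact = FALSE))
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- t.test(err, well, paired = paired)
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  structure(c(res, list(direction = direction, degenerate = degenerate,
                        method = method, paired = paired)),
            class = "seg_comparison")
}

#' @export
print.seg_comparison <- function(x, ...) {
  cat(sprintf("%s%s test: statistic %s, p-value %.3g, direction %s%s\n",
              if (x$paired) "paired " else "", x$method,
              format(x$statistic), x$p_value, x$direction,
              if (x$degenerate) " (degenerate: all values identical)" else ""))
  invisible(x)
}

#' Percent increase in average entropy
#'
#' `100 * (avg_err - avg_well) / avg_well`. Negative values are possible:
#' poorer segmentation can identify fewer, easier cells and thereby lower
#' the average entropy.
#'
#' @param avg_err average entropy under the (error) condition of interest.
#' @param avg_well reference average entropy; must be positive.
#' @return percent change.
#' @export
percent_increase <- function(avg_err, avg_well) {
  if (any(avg_well <= 0)) stop("reference average entropy must be > 0")
  100 * (avg_err - avg_well) / avg_well
}

#' Local cell density from centroid coordinates
#'
#' Number of *other* cells within `radius` micrometers of each cell
#' (Euclidean distance; the focal cell is not counted). Used to check that
#' entropy is not confounded by cellular density.
#'
#' @param coords data.frame with columns `cell_id`, `x`, `y` (micrometers).
#' @param radius neighborhood radius in micrometers (default 8).
#' @return named integer vector of counts per cell.
#' @export
local_density <- function(coords, radius = 8) {
  stopifnot(all(c("cell_id", "x", "y") %in% names(coords)))
  if (anyDuplicated(coords$cell_id)) stop("duplicate cell ids in coordinates")
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y)))
    stop("non-finite coordinates")
  n <- nrow(coords)
  if (n == 1L) {
    out <- 0L
  } else {
    d <- as.matrix(dist(coords[, c("x", "y")]))
    out <- as.integer(rowSums(d <= radius) - 1L)
  }
  names(out) <- as.character(coords$cell_id)
  out
}
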