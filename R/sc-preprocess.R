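#' Variance/maximum gene filter for single-cell matrices
#'
#' Removes genes with both low variance and low maximal expression across
#' cells (a gene is kept if it passes either criterion). When thresholds
#' are not given they default to the 10th percentile of the respective
#' per-gene distribution, so roughly the jointly-flattest genes go.
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param min_variance variance threshold (genes with variance strictly
#'   below it fail that criterion).
#' @param min_max maximum-value threshold.
#' @return filtered [expression_matrix()].
#' @export
filter_genes_sc <- function(x, min_variance = NULL, min_max = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$orientation != "cells_by_genes")
    stop("filter_genes_sc() expects cells_by_genes orientation")
  v <- x$values
  gvar <- apply(v, 2, stats::var)
  gmax <- apply(v, 2, max)
  if (is.null(min_variance))
    min_variance <- stats::quantile(gvar, 0.10, names = FALSE)
  if (is.null(min_max))
    min_max <- stats::quantile(gmax, 0.10, names = FALSE)
  fail <- gvar < min_variance & gmax < min_max
  if (all(fail)) stop("all genes fail the variance/max filter")
  if (any(fail))
    message(sprintf("filter_genes_sc: removed %d of %d genes",
                    sum(fail), length(fail)))
  expression_matrix(v[, !fail, drop = FALSE], orientation = x$orientation)
}

#' Gate specification for in-silico sorting
#'
#' @param marker gene id to gate on.
#' @param op `"gt"` (strictly greater) or `"ge"`.
#' @param threshold expression threshold (default 0: any positive
#'   expression on log-scale data).
#' @return list of class `gate_spec`.
#' @export
gate_spec <- function(marker, op = c("gt", "ge"), threshold = 0) {
  op <- match.arg(op)
  structure(list(marker = marker, op = op, threshold = threshold),
            class = "gate_spec")
}

#' In-silico gating on marker genes
#'
#' Retains the cells passing all gates (conjunction), emulating the
#' flow-cytometric selection of e.g. CD4+CD3E+ cells from an unannotated
#' suspension. An empty gate list is the identity.
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param gates list of [gate_spec()]s (or marker-name character vector,
#'   expanded to default `> 0` gates).
#' @return list with `x` (gated matrix), `labels` (per-cell logical of the
#'   original matrix) and `attrition` (per-gate data.frame of cells in/out).
#' @export
in_silico_gate <- function(x, gates) {
  stopifnot(inherits(x, "expr_mat"))
  if (is.character(gates)) gates <- lapply(gates, gate_spec)
  if (inherits(gates, "gate_spec")) gates <- list(gates)
  v <- x$values
  keep <- rep(TRUE, nrow(v))
  attrition <- data.frame(marker = character(0), op = character(0),
                          threshold = numeric(0),
                          cells_in = integer(0), cells_out = integer(0))
  for (g in gates) {
    if (!g$marker %in% colnames(v))
      stop("gate marker absent from matrix: ", g$marker)
    pass <- if (g$op == "gt") v[, g$marker] > g$threshold else
      v[, g$marker] >= g$threshold
    attrition <- rbind(attrition, data.frame(
      marker = g$marker, op = g$op, threshold = g$threshold,
      cells_in = sum(keep), cells_out = sum(keep & pass)))
    keep <- keep & pass
  }
  if (!any(keep)) {
    stop("no cell passes the gates:\n",
         paste(utils::capture.output(print(attrition)), collapse = "\n"))
  }
  labels <- stats::setNames(keep, rownames(v))
  list(x = expression_matrix(v[keep, , drop = FALSE],
                             orientation = x$orientation),
       labels = labels, attrition = attrition)
}

#' PCA + k-means outlier removal
#'
#' Projects cells onto the leading principal components (centered, not
#' scaled), clusters them with k-means (fixed seed, multiple restarts)
#' and removes the cells of the outlier cluster: the smallest cluster, or
#' the cluster whose centroid is farthest from the grand centroid. A
#' guard refuses to silently discard more than `max_drop_fraction` of the
#' cells. Degenerate geometry (all centroids coincide under
#' `farthest_centroid`) keeps every cell.
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param n_components number of principal components.
#' @param k number of k-means clusters (>= 2).
#' @param drop_policy `"smallest_cluster"` or `"farthest_centroid"`.
#' @param seed random seed for the k-means restarts (required).
#' @param n_init number of k-means restarts.
#' @param max_drop_fraction error if the dropped cluster exceeds this
#'   fraction of cells.
#' @return filtered [expression_matrix()] with attribute `"removed"`
#'   listing the removed cell ids.
#' @export
pca_kmeans_outlier_removal <- function(x, n_components = 10, k = 2,
                                       drop_policy = c("smallest_cluster",
                                                       "farthest_centroid"),
                                       seed, n_init = 10,
                                       max_drop_fraction = 0.2) {
  drop_policy <- match.arg(drop_policy)
  stopifnot(inherits(x, "expr_mat"))
  if (missing(seed)) stop("pca_kmeans_outlier_removal() requires a seed")
  v <- x$values
  if (k < 2) stop("k must be >= 2")
  if (k >= nrow(v)) stop("k must be smaller than the number of cells")
  n_components <- min(n_components, nrow(v) - 1, ncol(v))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  scores <- pc$x
  if (nrow(unique(scores)) <= k) {
    message("pca_kmeans_outlier_removal: fewer than k distinct cell ",
            "profiles; keeping all cells")
    out <- x
    attr(out, "removed") <- character(0)
    return(out)
  }
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_init)
  drop_cluster <- if (drop_policy == "smallest_cluster") {
    which.min(km$size)
  } else {
    grand <- colMeans(scores)
    d <- sqrt(rowSums(sweep(km$centers, 2, grand)^2))
    if (max(d) - min(d) < 1e-12) {
      message("pca_kmeans_outlier_removal: centroid distances tied; ",
              "keeping all cells")
      NA_integer_
    } else which.max(d)
  }
  if (is.na(drop_cluster)) {
    out <- x
    attr(out, "removed") <- character(0)
    return(out)
  }
  drop <- km$cluster == drop_cluster
  if (mean(drop) > max_drop_fraction)
    stop(sprintf(
      "outlier cluster holds %.1f%% of cells (> %.0f%% allowed); %s",
      100 * mean(drop), 100 * max_drop_fraction,
      "raise max_drop_fraction explicitly to proceed"))
  message(sprintf("pca_kmeans_outlier_removal: removed %d of %d cells",
                  sum(drop), length(drop)))
  out <- expression_matrix(v[!drop, , drop = FALSE],
                           orientation = x$orientation)
  attr(out, "removed") <- rownames(v)[drop]
  out
}
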