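#' EM Gaussian-mixture clustering of cell scores
#'
#' Fits a Gaussian mixture to the ordination scores by
#' expectation-maximization (via mclust) and assigns each cell to its
#' maximum-a-posteriori component. When `K` is a range the number of
#' components (and covariance model) is chosen by BIC.
#'
#' @param scores cells x axes numeric matrix (rownames = cell ids).
#' @param K number of clusters, or an integer range for BIC selection.
#' @param seed random seed (mclust's initialisation is deterministic, but
#'   the seed keeps any stochastic model variants reproducible).
#' @return list with `labels` (named integer vector), `centroids`
#'   (K x axes matrix, rows named "1".."K"), `K`, and the mclust `fit`.
#' @export
em_cluster <- function(scores, K, seed = 1) {
  scores <- as.matrix(scores)
  if (max(K) >= nrow(scores))
    stop("K must be smaller than the number of cells")
  set.seed(seed)
  fit <- mclust::Mclust(scores, G = K, verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed for K = ",
                         paste(range(K), collapse = ".."))
  labels <- fit$classification
  names(labels) <- rownames(scores)
  centroids <- t(fit$parameters$mean)
  if (is.null(dim(centroids))) centroids <- matrix(centroids, ncol = 1)
  rownames(centroids) <- as.character(seq_len(nrow(centroids)))
  colnames(centroids) <- colnames(scores)
  list(labels = labels, centroids = centroids, K = fit$G, fit = fit)
}

# Deterministic Prim MST over Euclidean centroid distances; ties break
# by lexicographic (from, to) cluster order.
prim_mst <- function(centroids) {
  n <- nrow(centroids)
  ids <- rownames(centroids)
  d <- as.matrix(stats::dist(centroids))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  while (sum(in_tree) < n) {
    best <- NULL; best_w <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      w <- d[i, j]
      if (w < best_w ||
          (w == best_w && (is.null(best) ||
                           ids[i] < ids[best[1]] ||
                           (ids[i] == ids[best[1]] && ids[j] < ids[best[2]])))) {
        best <- c(i, j); best_w <- w
      }
    }
    edges <- rbind(edges, c(ids[best[1]], ids[best[2]]))
    in_tree[best[2]] <- TRUE
  }
  edges
}

#' Build lineages from cluster centroids
#'
#' Constructs the Euclidean minimum spanning tree over the cluster
#' centroids, roots it, and extracts one lineage per leaf as the ordered
#' root-to-leaf cluster path. The root is either a fixed cluster id or
#' the cluster whose centroid points most along a named explanatory
#' arrow (the resting/naive pole in the motivating analyses). Clusters of
#' MST degree >= 3 lying on >= 2 lineages are flagged as bifurcation
#' points.
#'
#' @param centroids K x axes matrix with cluster ids as rownames.
#' @param root cluster id, or `NULL` to use `arrows`/`root_variable`.
#' @param arrows biplot matrix (variables x axes) of the ordination.
#' @param root_variable name of the arrow marking the root pole.
#' @return object of class `lineage_model`: `centroids`, `mst_edges`,
#'   `root`, `lineages` (named list of ordered cluster-id paths),
#'   `bifurcation_clusters`, `degrees`.
#' @export
build_lineages <- function(centroids, root = NULL, arrows = NULL,
                           root_variable = NULL) {
  centroids <- as.matrix(centroids)
  if (is.null(rownames(centroids)))
    rownames(centroids) <- as.character(seq_len(nrow(centroids)))
  if (nrow(centroids) < 2) stop("need >= 2 cluster centroids")
  ids <- rownames(centroids)
  if (is.null(root)) {
    if (is.null(arrows) || is.null(root_variable))
      stop("supply either a root cluster id or arrows + root_variable")
    arrow <- arrows[root_variable, seq_len(ncol(centroids))]
    cosim <- apply(centroids, 1, function(ce) {
      nc <- sqrt(sum(ce^2)); na <- sqrt(sum(arrow^2))
      if (nc == 0 || na == 0) -Inf else sum(ce * arrow) / (nc * na)
    })
    root <- ids[which.max(cosim)]
  }
  root <- as.character(root)
  if (!root %in% ids) stop("root cluster '", root, "' not a centroid id")
  edges <- prim_mst(centroids)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  degrees <- vapply(adj, length, integer(1))
  leaves <- ids[degrees == 1 & ids != root]
  if (length(leaves) == 0) leaves <- ids[ids != root]  # 2-node tree edge case
  paths <- lapply(sort(leaves), function(leaf) {
    # unique tree path root -> leaf by DFS
    stack <- list(root); seen <- character(0)
    path <- character(0)
    dfs <- function(node, trail) {
      if (node == leaf) return(trail)
      for (nb in sort(adj[[node]])) {
        if (nb %in% trail) next
        res <- dfs(nb, c(trail, nb))
        if (!is.null(res)) return(res)
      }
      NULL
    }
    dfs(root, root)
  })
  names(paths) <- paste0("lineage_", sort(leaves))
  on_lineages <- table(unlist(lapply(paths, unique)))
  bif <- ids[degrees >= 3 & ids %in%
               names(on_lineages)[on_lineages >= 2]]
  structure(list(centroids = centroids, mst_edges = edges, root = root,
                 lineages = paths, bifurcation_clusters = bif,
                 degrees = degrees),
            class = "lineage_model")
}

#' @exportS3Method print lineage_model
print.lineage_model <- function(x, ...) {
  cat(sprintf("<lineage_model> %d clusters, root %s, %d lineage(s)\n",
              nrow(x$centroids), x$root, length(x$lineages)))
  for (nm in names(x$lineages))
    cat("  ", nm, ": ", paste(x$lineages[[nm]], collapse = " -> "), "\n",
        sep = "")
  if (length(x$bifurcation_clusters))
    cat("  bifurcation at:",
        paste(x$bifurcation_clusters, collapse = ", "), "\n")
  invisible(x)
}

# orthogonal projection of points onto a polyline; returns arc lengths
project_onto_polyline <- function(pts, path_coords) {
  seg <- diff(path_coords)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  apply(pts, 1, function(pt) {
    best_d <- Inf; best_arc <- 0
    for (i in seq_len(nrow(seg))) {
      if (lens[i] == 0) next
      a <- path_coords[i, ]
      t <- sum((pt - a) * seg[i, ]) / lens[i]^2
      t <- min(max(t, 0), 1)
      pr <- a + t * seg[i, ]
      dd <- sum((pt - pr)^2)
      if (dd < best_d - 1e-15) {
        best_d <- dd; best_arc <- cum[i] + t * lens[i]
      }
    }
    best_arc
  })
}

#' Per-cell pseudotime along each lineage
#'
#' Each lineage's ordered centroids define a piecewise-linear curve;
#' cells belonging to the lineage's clusters are orthogonally projected
#' onto the curve and their pseudotime is the arc length from the root,
#' rescaled to [0, 1] per lineage. Cells in clusters off a lineage carry
#' no value for it.
#'
#' @param scores cells x axes matrix used for the clustering.
#' @param labels named per-cell cluster labels (as from [em_cluster()]).
#' @param model a [build_lineages()] result.
#' @return data.frame with columns `cell`, `lineage`, `cluster`, `t`.
#' @export
assign_pseudotime <- function(scores, labels, model) {
  scores <- as.matrix(scores)
  cells <- rownames(scores)
  labels <- as.character(labels[cells])
  out <- list()
  for (nm in names(model$lineages)) {
    path <- model$lineages[[nm]]
    member <- labels %in% path
    if (!any(member)) next
    coords <- model$centroids[path, , drop = FALSE]
    arc <- project_onto_polyline(scores[member, , drop = FALSE], coords)
    total <- sum(sqrt(rowSums(diff(coords)^2)))
    t <- if (total > 0) arc / total else rep(0, length(arc))
    out[[nm]] <- data.frame(cell = cells[member], lineage = nm,
                            cluster = labels[member], t = t,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Gene-module trajectory along pseudotime
#'
#' Standardizes each module gene across cells (zero-variance genes
#' contribute 0), sums the z-scores per cell, and summarises the module
#' value in equal-width pseudotime bins per lineage.
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param genes [gene_set()] or character vector; absent members are
#'   reported and skipped.
#' @param pseudotime data.frame from [assign_pseudotime()].
#' @param n_bins number of pseudotime bins.
#' @return data.frame with `lineage`, `bin`, `t_mid`, `mean`, `sd`, `n`,
#'   and the per-cell module values in attribute `"module"`.
#' @export
module_trajectory <- function(x, genes, pseudotime, n_bins = 10) {
  stopifnot(inherits(x, "expr_mat"))
  members <- if (inherits(genes, "gene_set")) genes$members else
    as.character(genes)
  present <- intersect(members, colnames(x$values))
  absent <- setdiff(members, present)
  if (length(absent))
    message("module_trajectory: skipping ", length(absent),
            " absent gene(s): ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "")
  if (length(present) == 0) stop("no module gene present in the matrix")
  sub <- x$values[, present, drop = FALSE]
  z <- apply(sub, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  module <- stats::setNames(rowSums(z), rownames(sub))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  res <- list()
  for (nm in unique(pseudotime$lineage)) {
    pt <- pseudotime[pseudotime$lineage == nm, ]
    bin <- cut(pt$t, breaks, include.lowest = TRUE, labels = FALSE)
    vals <- module[pt$cell]
    for (b in sort(unique(bin))) {
      vb <- vals[bin == b]
      res[[length(res) + 1]] <- data.frame(
        lineage = nm, bin = b,
        t_mid = (breaks[b] + breaks[b + 1]) / 2,
        mean = mean(vb), sd = stats::sd(vb), n = length(vb))
    }
  }
  out <- do.call(rbind, res)
  attr(out, "module") <- module
  out
}

# density-valley threshold: deepest minimum between the two outermost
# modes of the kernel density; falls back to the median when unimodal
density_valley <- function(v) {
  if (length(unique(v)) < 3) return(stats::median(v))
  d <- stats::density(v)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) < 2) return(stats::median(v))
  lo <- min(is_max); hi <- max(is_max)
  valley <- lo + which.min(y[lo:hi]) - 1
  d$x[valley]
}

#' Flow-cytometry-style quadrant gate on two genes
#'
#' Counts cells in the four quadrants of a 2D expression plot.
#' Thresholds default to the valley of the kernel density of each gene
#' (the empirical between-modes heuristic used for gating plots).
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param gene_x,gene_y gene ids for the two axes.
#' @param tx,ty thresholds; `NULL` derives them from the density valley.
#' @return list with `counts` (2 x 2 matrix), `percent`, `labels`
#'   (per-cell quadrant: `"x+y+"`, `"x+y-"`, `"x-y+"`, `"x-y-"`),
#'   `thresholds`.
#' @export
quadrant_gate <- function(x, gene_x, gene_y, tx = NULL, ty = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  for (g in c(gene_x, gene_y))
    if (!g %in% colnames(x$values))
      stop("gate gene absent from matrix: ", g)
  vx <- x$values[, gene_x]; vy <- x$values[, gene_y]
  if (is.null(tx)) tx <- density_valley(vx)
  if (is.null(ty)) ty <- density_valley(vy)
  qx <- vx > tx; qy <- vy > ty
  labels <- paste0(ifelse(qx, "x+", "x-"), ifelse(qy, "y+", "y-"))
  names(labels) <- rownames(x$values)
  counts <- matrix(c(sum(qx & qy), sum(qx & !qy),
                     sum(!qx & qy), sum(!qx & !qy)), 2, 2, byrow = TRUE,
                   dimnames = list(c("x+", "x-"), c("y+", "y-")))
  list(counts = counts, percent = 100 * counts / length(vx),
       labels = labels, thresholds = c(x = tx, y = ty))
}

#' Cardinalities of all Venn regions of named gene sets
#'
#' Enumerates every region of the Venn partition of 2-5 sets: for each
#' nonempty subset of set names, the number of elements belonging to
#' exactly those sets (`exclusive`) and to at least those sets
#' (`intersection`), plus a pairwise-overlap matrix.
#'
#' @param sets named list of [gene_set()]s or character vectors.
#' @return list with `exclusive` and `intersection` (named counts, region
#'   names like `"A&B"`), and `pairwise` overlap matrix.
#' @export
set_intersections <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets")
  if (length(sets) > 5) stop("more than 5 sets; Venn regions blow up")
  members <- lapply(sets, function(s)
    unique(if (inherits(s, "gene_set")) s$members else as.character(s)))
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("sets must be named")
  universe <- unique(unlist(members))
  memb <- vapply(members, function(m) universe %in% m,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL,
                                                            names(members)))
  s <- length(members)
  nm <- names(members)
  exclusive <- intersection <- integer(0)
  for (mask in seq_len(2^s - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(s) - 1)))
    region <- paste(nm[inset], collapse = "&")
    exact <- apply(memb, 1, function(row) all(row == inset))
    atleast <- apply(memb, 1, function(row) all(row[inset]))
    exclusive[region] <- sum(exact)
    intersection[region] <- sum(atleast)
  }
  pairwise <- matrix(0L, s, s, dimnames = list(nm, nm))
  for (i in seq_len(s)) for (j in seq_len(s))
    pairwise[i, j] <- length(intersect(members[[i]], members[[j]]))
  list(exclusive = exclusive, intersection = intersection,
       pairwise = pairwise)
}
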