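#' Simulation configuration for the fixture generators
#'
#' Collects the knobs shared by [simulate_bulk_contrast()] and
#' [simulate_single_cells()] with validation. The defaults describe the
#' study conditions the analyses assume: microarray-like log-normal bulk
#' intensities with a 4-standard-deviation activation effect, and
#' negative-binomial single-cell counts (dispersion 0.3) over four T cell
#' populations with one exclusive marker and four partially leaky decoys
#' each, optionally arranged on a bifurcating latent trajectory.
#'
#' @param seed mandatory integer seed.
#' @param n_genes number of genes.
#' @param n_cells number of cells (single-cell generator).
#' @param populations list of `list(name, size, n_markers, n_decoys,
#'   marker_mu, activation)` entries; `activation` is a 0/1 level driving
#'   the gradient genes.
#' @param activation list `(n_gradient_genes, effect_size)`; the effect is
#'   a log-scale multiplier between activation levels 0 and 1.
#' @param trajectory `NULL`, or `list(topology = "chain"|"bifurcating",
#'   n_clusters, cluster_sd)` describing the latent 2D layout.
#' @param noise list `(distribution, dispersion, sd)`:
#'   `negative_binomial` dispersion for counts, Gaussian `sd` on the log2
#'   scale for bulk intensities.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 300,
                       n_cells = 500,
                       populations = NULL,
                       activation = list(n_gradient_genes = 40,
                                         effect_size = 1.5),
                       trajectory = NULL,
                       noise = list(distribution = "negative_binomial",
                                    dispersion = 0.3, sd = 0.5)) {
  if (missing(seed)) stop("sim_config() requires a seed")
  if (is.null(populations))
    populations <- list(
      list(name = "activated_FOXP3pos", size = ceiling(n_cells / 4),
           n_markers = 1, n_decoys = 4, n_program = 15, marker_mu = 30,
           activation = 1),
      list(name = "activated_FOXP3neg", size = ceiling(n_cells / 4),
           n_markers = 1, n_decoys = 4, n_program = 15, marker_mu = 30,
           activation = 1),
      list(name = "resting_FOXP3pos", size = ceiling(n_cells / 4),
           n_markers = 1, n_decoys = 4, n_program = 15, marker_mu = 30,
           activation = 0),
      list(name = "resting_FOXP3neg",
           size = n_cells - 3 * ceiling(n_cells / 4),
           n_markers = 1, n_decoys = 4, n_program = 15, marker_mu = 30,
           activation = 0))
  sizes <- vapply(populations, `[[`, numeric(1), "size")
  if (any(sizes <= 0)) stop("population sizes must be positive")
  if (sum(sizes) != n_cells)
    stop("population sizes must sum to n_cells")
  if (!is.null(trajectory)) {
    if (!trajectory$topology %in% c("chain", "bifurcating"))
      stop("trajectory topology must be 'chain' or 'bifurcating'")
    if (is.null(trajectory$n_clusters))
      trajectory$n_clusters <- if (trajectory$topology == "bifurcating")
        6L else 4L
    if (is.null(trajectory$cluster_sd)) trajectory$cluster_sd <- 0.25
    if (trajectory$topology == "bifurcating" && trajectory$n_clusters < 4)
      stop("a bifurcating trajectory needs >= 4 clusters")
  }
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_cells = n_cells, populations = populations,
                 activation = activation, trajectory = trajectory,
                 noise = noise),
            class = "sim_config")
}

#' Simulate a paired activated-vs-resting bulk contrast
#'
#' Emulates a microarray comparison of stimulated vs untreated T cells:
#' per-gene baseline log2 intensities are drawn normal (log-normal
#' intensities), induced genes are shifted by `effect_sd` noise standard
#' deviations (alternating sign), and replicate noise is Gaussian on the
#' log2 scale. Values below zero are clipped to zero.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per group (>= 2 for inference).
#' @param n_deg number of truly induced/repressed genes.
#' @param effect_sd effect size in units of the replicate noise SD (the
#'   log2 fold change is `effect_sd * noise_sd`).
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log2 means.
#' @param seed mandatory seed.
#' @return list with `activated` and `resting` [expression_matrix()]s
#'   (shared gene universe), `truth` ([gene_set()] of induced genes),
#'   `lfc_truth` (named signed log2 fold changes of the truth genes).
#' @export
simulate_bulk_contrast <- function(n_genes = 1000, n_per_group = 3,
                                   n_deg = 200, effect_sd = 4,
                                   noise_sd = 0.5,
                                   baseline_mean = 7, baseline_sd = 1.5,
                                   seed) {
  if (missing(seed)) stop("simulate_bulk_contrast() requires a seed")
  if (n_per_group < 2) stop("need >= 2 replicates per group")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  lfc <- numeric(n_genes)
  if (n_deg > 0) {
    idx <- seq_len(n_deg)
    lfc[idx] <- effect_sd * noise_sd * rep_len(c(1, -1), n_deg)
  }
  draw <- function(shift) {
    m <- matrix(stats::rnorm(n_genes * n_per_group, base + shift, noise_sd),
                n_genes, n_per_group)
    # clip to a small positive floor so the paired matrices keep the
    # same gene universe (no all-zero rows to drop on one side only)
    pmax(m, 0.01)
  }
  A <- draw(lfc); B <- draw(0)
  dimnames(A) <- list(genes, paste0("act", seq_len(n_per_group)))
  dimnames(B) <- list(genes, paste0("rest", seq_len(n_per_group)))
  truth <- genes[lfc != 0]
  list(activated = expression_matrix(A),
       resting = expression_matrix(B),
       truth = if (length(truth)) gene_set("induced", truth) else NULL,
       lfc_truth = stats::setNames(lfc[lfc != 0], truth))
}

# 2D cluster-centre layouts for the latent trajectories
trajectory_layout <- function(topology, n_clusters) {
  if (topology == "chain") {
    cbind(x = 1.4 * (seq_len(n_clusters) - 1), y = 0)
  } else {
    n_trunk <- 2L
    n_arm <- (n_clusters - n_trunk) %/% 2L
    n_arm2 <- n_clusters - n_trunk - n_arm
    trunk <- cbind(1.4 * (seq_len(n_trunk) - 1), 0)
    fork <- trunk[n_trunk, ]
    armA <- cbind(fork[1] + 1.2 * seq_len(n_arm),
                  fork[2] + 1.0 * seq_len(n_arm))
    armB <- cbind(fork[1] + 1.2 * seq_len(n_arm2),
                  fork[2] - 1.0 * seq_len(n_arm2))
    rbind(trunk, armA, armB)
  }
}

# membership of trajectory clusters in the root->leaf branches
trajectory_branches <- function(topology, n_clusters) {
  if (topology == "chain") {
    list(A = seq_len(n_clusters))
  } else {
    n_trunk <- 2L
    n_arm <- (n_clusters - n_trunk) %/% 2L
    list(A = c(seq_len(n_trunk), n_trunk + seq_len(n_arm)),
         B = c(seq_len(n_trunk),
               n_trunk + n_arm + seq_len(n_clusters - n_trunk - n_arm)))
  }
}

# arc position of a point along a polyline (generator-side truth; kept
# deliberately simple and separate from the pseudotime implementation)
polyline_arc <- function(pt, path) {
  seg <- diff(path)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  best <- c(Inf, 0)
  for (i in seq_len(nrow(seg))) {
    a <- path[i, ]; d <- seg[i, ]
    t <- sum((pt - a) * d) / sum(d^2)
    t <- min(max(t, 0), 1)
    pr <- a + t * d
    dist <- sum((pt - pr)^2)
    if (dist < best[1]) best <- c(dist, cum[i] + t * lens[i])
  }
  best[2]
}

#' Simulate a single-cell matrix with planted populations and trajectory
#'
#' Cells are grouped into the configured populations; each population
#' gets exclusive marker genes (high mean inside the population,
#' essentially silent outside) and partially leaky decoy genes (high
#' inside, moderate in one other population). Gradient genes rise or fall
#' with the activation level (or, when a trajectory is configured, with
#' latent time), and the remaining background genes are population-blind.
#' Counts are negative binomial. With a trajectory, cells also receive
#' latent 2D coordinates around cluster centres arranged as a chain or a
#' bifurcating Y, and a latent arc-length time along their branch.
#'
#' @param config a [sim_config()].
#' @return list with `x` (cells-by-genes [expression_matrix()]),
#'   `populations` (named factor), `markers` (named list population ->
#'   exclusive marker ids), `decoys` (named list), `gradient_genes`,
#'   `latent` (`NULL`, or data.frame cell/cluster/branch/time/coords),
#'   `config`.
#' @export
simulate_single_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  sizes <- vapply(pops, `[[`, numeric(1), "size")
  pop_names <- vapply(pops, `[[`, character(1), "name")
  n_cells <- config$n_cells
  cells <- sprintf("cell%04d", seq_len(n_cells))
  pop_of <- factor(rep(pop_names, sizes), levels = pop_names)
  names(pop_of) <- cells
  act_level <- stats::setNames(
    vapply(pops, `[[`, numeric(1), "activation"), pop_names)

  # latent trajectory coordinates
  latent <- NULL
  t_norm <- act_level[as.character(pop_of)]  # default driver of gradients
  if (!is.null(config$trajectory)) {
    tr <- config$trajectory
    centers <- trajectory_layout(tr$topology, tr$n_clusters)
    branches <- trajectory_branches(tr$topology, tr$n_clusters)
    cl <- sort(rep_len(seq_len(tr$n_clusters), n_cells))
    coords <- centers[cl, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_cells, 0, tr$cluster_sd), n_cells, 2)
    branch_of <- vapply(cl, function(ci) {
      hits <- names(branches)[vapply(branches, function(b) ci %in% b,
                                     logical(1))]
      if (length(hits) > 1) "trunk" else hits
    }, character(1))
    time <- numeric(n_cells)
    for (bn in names(branches)) {
      path <- centers[branches[[bn]], , drop = FALSE]
      on_b <- branch_of == bn | branch_of == "trunk"
      # trunk cells get their (shared) trunk arc from branch A only
      fill <- if (bn == names(branches)[1]) on_b else branch_of == bn
      time[fill] <- vapply(which(fill), function(i)
        polyline_arc(coords[i, ], path), numeric(1))
    }
    latent <- data.frame(cell = cells, cluster = cl, branch = branch_of,
                         time = time, dim1 = coords[, 1],
                         dim2 = coords[, 2])
    t_norm <- time / max(time)
    names(t_norm) <- cells
  }

  # gene plan
  n_grad <- config$activation$n_gradient_genes
  markers <- list(); decoys <- list()
  gene_mu <- NULL  # genes x cells mean matrix built column-block-wise
  mu_rows <- list()
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    in_pop <- pop_of == p$name
    other <- pop_names[pop_names != p$name][(i - 1) %% (length(pops) - 1) + 1]
    in_other <- pop_of == other
    mk <- sprintf("MARKER_%s", p$name)
    markers[[p$name]] <- mk
    mu_rows[[mk]] <- ifelse(in_pop, p$marker_mu, 0.02)
    if (p$n_decoys > 0) {
      dk <- sprintf("DECOY_%s_%d", p$name, seq_len(p$n_decoys))
      decoys[[p$name]] <- dk
      for (d in dk)
        mu_rows[[d]] <- ifelse(in_pop, p$marker_mu * 0.7,
                               ifelse(in_other, p$marker_mu * 0.35, 0.5))
    }
    # the differentiation program driven by the population's lineage
    # factor: a block of genes moderately elevated in the population,
    # expressed at baseline elsewhere (each population is a
    # transcriptional state, not a single marker)
    n_prog <- if (is.null(p$n_program)) 15L else p$n_program
    if (n_prog > 0) {
      pk <- sprintf("PROG_%s_%02d", p$name, seq_len(n_prog))
      prog_base <- exp(stats::rnorm(n_prog, log(4), 0.3))
      for (g in seq_len(n_prog))
        mu_rows[[pk[g]]] <- ifelse(in_pop, 4 * prog_base[g], prog_base[g])
    }
  }
  grad_genes <- character(0)
  if (n_grad > 0) {
    grad_genes <- sprintf("GRAD_%03d", seq_len(n_grad))
    dir <- rep_len(c(1, -1), n_grad)
    for (g in seq_len(n_grad)) {
      base <- exp(stats::rnorm(1, log(6), 0.3))
      mu_rows[[grad_genes[g]]] <-
        base * exp(dir[g] * config$activation$effect_size * t_norm)
    }
  }
  n_special <- length(mu_rows)
  n_bg <- config$n_genes - n_special
  if (n_bg < 0) stop("n_genes too small for the configured markers/decoys")
  if (n_bg > 0) {
    bg <- sprintf("BG_%04d", seq_len(n_bg))
    bg_base <- exp(stats::rnorm(n_bg, log(5), 0.6))
    for (g in seq_len(n_bg)) mu_rows[[bg[g]]] <- rep(bg_base[g], n_cells)
  }
  mu <- do.call(rbind, mu_rows)          # genes x cells
  colnames(mu) <- cells
  disp <- config$noise$dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / disp),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  x <- expression_matrix(t(counts), orientation = "cells_by_genes")
  list(x = x,
       populations = pop_of[rownames(x$values)],
       markers = markers, decoys = decoys,
       gradient_genes = grad_genes,
       latent = if (!is.null(latent))
         latent[latent$cell %in% rownames(x$values), ] else NULL,
       config = config)
}
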