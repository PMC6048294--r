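#' Explanatory variable matrix
#'
#' Carrier for the per-row covariates Z that constrain the ordination
#' (per-gene activation/differentiation signatures in the conventional
#' orientation, per-cell gene expression in SC4A orientation). Columns are
#' standardized to mean 0, variance 1 (unweighted moments) unless already
#' flagged as standardized.
#'
#' @param Z numeric matrix (or vector) of covariates, rows aligned with the
#'   paired expression matrix.
#' @param names variable names (defaults to `colnames(Z)`).
#' @param standardize standardize columns now; set `FALSE` if `Z` is
#'   already standardized or deliberately raw.
#' @return object of class `expl_mat`: list with `Z`, `names`,
#'   `standardized`.
#' @export
explanatory_matrix <- function(Z, names = NULL, standardize = TRUE) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (is.null(names)) names <- colnames(Z)
  if (is.null(names)) names <- paste0("z", seq_len(ncol(Z)))
  colnames(Z) <- names
  if (ncol(Z) == 0) stop("explanatory matrix has no columns")
  if (anyNA(Z)) stop("explanatory values must not contain NA")
  if (standardize) {
    sds <- apply(Z, 2, stats::sd)
    if (any(sds == 0))
      stop("constant explanatory column(s): ",
           paste(names[sds == 0], collapse = ", "))
    Z <- scale(Z)
    attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  }
  structure(list(Z = Z, names = names, standardized = standardize),
            class = "expl_mat")
}

as_expl_Z <- function(Z, standardize = TRUE) {
  if (inherits(Z, "expl_mat")) Z$Z
  else explanatory_matrix(Z, standardize = standardize)$Z
}

#' Chi-square standardized residuals
#'
#' Forms the residual abundance matrix P = X/n - r c^T and its chi-square
#' standardization S = D_r^{-1/2} P D_c^{-1/2}. The squared Frobenius norm
#' of S is the total inertia of the table (the chi-square statistic
#' divided by n).
#'
#' @param x [expression_matrix()] or nonnegative matrix.
#' @param masses [compute_masses()] of `x` (computed if missing).
#' @return list of class `cca_resid` with `P`, `S`, `total_inertia`,
#'   `masses`.
#' @export
cca_standardize <- function(x, masses = compute_masses(x)) {
  v <- as_expr_values(x)
  if (any(masses$r <= 0) || any(masses$c <= 0))
    stop("zero row/column masses; validate the matrix first")
  P <- v / masses$n - outer(masses$r, masses$c)
  S <- P / sqrt(outer(masses$r, masses$c))
  structure(list(P = P, S = S, total_inertia = sum(S^2), masses = masses),
            class = "cca_resid")
}

#' Project standardized residuals onto the explanatory space
#'
#' Weighted least-squares projection of S onto the covariates: with
#' W = D_r^{1/2} Z, the projector Q = W (W^T W)^{-1} W^T restricts S to the
#' constrained space S* = Q S. The projector is applied through an
#' orthonormal basis of col(W) (never materialising the p x p matrix Q);
#' rank deficiency in Z is resolved by a singular-value cutoff at
#' 1e-10 x the largest singular value, with a collinearity warning.
#'
#' @param resid [cca_standardize()] result.
#' @param Z [explanatory_matrix()] (or matrix, standardized on the fly),
#'   row-aligned with the expression matrix.
#' @param masses mass structure (defaults to the one stored in `resid`).
#' @return list of class `cca_space`: `S_star`, `basis` (p x rank,
#'   orthonormal), `rank`, `constrained_inertia`, plus the projected
#'   coordinate matrix `Tmat` = basis^T S used by [cca_decompose()].
#' @export
cca_project <- function(resid, Z, masses = resid$masses) {
  Zm <- as_expl_Z(Z)
  if (nrow(Zm) != nrow(resid$S))
    stop("explanatory matrix rows (", nrow(Zm),
         ") do not match expression rows (", nrow(resid$S),
         "); see harmonize_genes()")
  W <- Zm * sqrt(masses$r)
  sv <- svd(W, nv = 0)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!any(keep)) stop("explanatory matrix is numerically zero")
  if (sum(keep) < ncol(Zm))
    warning(sprintf(
      "collinear explanatory columns: rank %d < k = %d; using pseudo-inverse",
      sum(keep), ncol(Zm)), call. = FALSE)
  basis <- sv$u[, keep, drop = FALSE]
  Tmat <- crossprod(basis, resid$S)
  S_star <- basis %*% Tmat
  dimnames(S_star) <- dimnames(resid$S)
  structure(list(S_star = S_star, basis = basis, rank = sum(keep),
                 Tmat = Tmat, constrained_inertia = sum(Tmat^2)),
            class = "cca_space")
}

# Apply the projector Q to an arbitrary p x m matrix (for idempotency
# checks and diagnostics).
cca_apply_projection <- function(space, M) {
  space$basis %*% crossprod(space$basis, M)
}

# zero-guarded reciprocal for D_alpha^{-1} on degenerate axes
safe_recip <- function(a, tol) ifelse(a > tol, 1 / a, 0)

#' Eigendecomposition of the constrained space
#'
#' Singular value decomposition S* = U D_alpha V^T, retaining
#' J = min(p - 1, m - 1, k) axes; eigenvalues are lambda_j = alpha_j^2 and
#' partition the constrained inertia. Sample (column) scores are the
#' principal coordinates D_c^{-1/2} V D_alpha; gene scores are weighted
#' averages G_wa = D_r^{-1} P V D_alpha^{-1} (D_r^{-1} P V when a single
#' explanatory variable is used). Axis signs are fixed so that the
#' largest-magnitude entry of each left singular vector is positive,
#' making solutions reproducible.
#'
#' @param space [cca_project()] result.
#' @param resid [cca_standardize()] result (supplies P for the WA scores).
#' @param n_vars number of explanatory variables k.
#' @param masses mass structure.
#' @return object of class `cca_sol`; see [cca()] for the fields.
#' @export
cca_decompose <- function(space, resid, n_vars,
                          masses = resid$masses) {
  p <- nrow(resid$S); m <- ncol(resid$S)
  J_nominal <- min(p - 1, m - 1, n_vars)
  sv <- svd(space$Tmat)
  alpha <- sv$d
  tol <- max(alpha, 0) * 1e-9
  n_nonzero <- sum(alpha > max(tol, 1e-14))
  J <- min(J_nominal, n_nonzero)
  if (J == 0) {
    sol <- structure(list(
      U = matrix(0, p, 0, dimnames = list(rownames(resid$S), NULL)),
      V = matrix(0, m, 0, dimnames = list(colnames(resid$S), NULL)),
      alpha = numeric(0), lam = numeric(0), J = 0L,
      sample_scores = matrix(0, m, 0,
                             dimnames = list(colnames(resid$S), NULL)),
      gene_scores_wa = matrix(0, p, 0,
                              dimnames = list(rownames(resid$S), NULL)),
      biplot = NULL, inertia_fraction = numeric(0),
      total_inertia = resid$total_inertia,
      constrained_inertia = space$constrained_inertia,
      k = n_vars, masses = masses), class = "cca_sol")
    return(sol)
  }
  alpha <- alpha[seq_len(J)]
  U <- space$basis %*% sv$u[, seq_len(J), drop = FALSE]
  V <- sv$v[, seq_len(J), drop = FALSE]
  # deterministic axis orientation
  for (j in seq_len(J)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rownames(U) <- rownames(resid$S)
  rownames(V) <- colnames(resid$S)
  axes <- paste0("Axis", seq_len(J))
  colnames(U) <- colnames(V) <- axes
  lam <- alpha^2
  sample_scores <- sweep(V, 1, sqrt(masses$c), "/") %*% diag(alpha, J)
  PV <- (resid$P %*% V) / masses$r
  gwa <- if (n_vars == 1) PV else PV %*% diag(safe_recip(alpha, tol), J)
  dimnames(sample_scores) <- list(colnames(resid$S), axes)
  dimnames(gwa) <- list(rownames(resid$S), axes)
  structure(list(U = U, V = V, alpha = alpha, lam = lam, J = J,
                 sample_scores = sample_scores, gene_scores_wa = gwa,
                 biplot = NULL,
                 inertia_fraction = lam / sum(lam),
                 total_inertia = resid$total_inertia,
                 constrained_inertia = space$constrained_inertia,
                 k = n_vars, masses = masses),
            class = "cca_sol")
}

#' Biplot correlations of explanatory variables with the ordination axes
#'
#' Each variable is carried into the chi-square metric of the gene space
#' (d_n = D_r^{1/2} z_n, the same weighting in which the singular vectors
#' live) and its Pearson correlation with every left singular vector u_j
#' gives the biplot arrow coordinates. With a single explanatory variable
#' the single biplot value is exactly +1 or -1 and only carries the
#' direction of correlation.
#'
#' @param Z [explanatory_matrix()] used in the fit.
#' @param solution [cca_decompose()] result.
#' @param masses mass structure of the fit.
#' @return k x J correlation matrix (rows named by variable).
#' @export
cca_biplot <- function(Z, solution, masses = solution$masses) {
  Zm <- as_expl_Z(Z)
  if (solution$J < 1) return(NULL)
  D <- Zm * sqrt(masses$r)
  rho <- matrix(0, ncol(Zm), solution$J,
                dimnames = list(colnames(Zm),
                                colnames(solution$U)))
  for (n in seq_len(ncol(Zm))) {
    if (stats::sd(D[, n]) == 0) {
      warning("explanatory variable '", colnames(Zm)[n],
              "' has zero weighted variance; biplot row set to 0",
              call. = FALSE)
      next
    }
    for (j in seq_len(solution$J)) {
      uj <- solution$U[, j]
      rho[n, j] <- if (stats::sd(uj) == 0) 0 else stats::cor(D[, n], uj)
    }
  }
  rho
}

#' Canonical correspondence analysis of an expression matrix
#'
#' Full pipeline: chi-square standardization, weighted projection onto the
#' explanatory space, SVD, scores and biplot correlations. The result is
#' deterministic (axis signs fixed by the largest-entry convention).
#'
#' @param x [expression_matrix()] (genes x samples; or cells x genes in
#'   SC4A orientation).
#' @param Z [explanatory_matrix()] or numeric matrix/vector of row
#'   covariates; a plain matrix is standardized to mean 0 / variance 1.
#' @param standardize_z standardize a plain-matrix `Z` (ignored for
#'   `expl_mat` input).
#' @return object of class `cca_sol` with fields `U`, `V`, `alpha`, `lam`,
#'   `J`, `sample_scores` (m x J principal coordinates),
#'   `gene_scores_wa` (p x J weighted-average scores), `biplot` (k x J
#'   correlations), `inertia_fraction`, `total_inertia`,
#'   `constrained_inertia`, `k`, `masses`.
#' @examples
#' set.seed(1)
#' X <- matrix(rpois(60, 20), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' z <- rnorm(10)
#' fit <- cca(expression_matrix(X), z)
#' fit$lam
#' @export
cca <- function(x, Z, standardize_z = TRUE) {
  xm <- if (inherits(x, "expr_mat")) x else expression_matrix(x)
  Ze <- if (inherits(Z, "expl_mat")) Z else
    explanatory_matrix(Z, standardize = standardize_z)
  if (!is.null(rownames(Ze$Z)) &&
      !identical(rownames(Ze$Z), rownames(xm$values))) {
    if (all(rownames(xm$values) %in% rownames(Ze$Z))) {
      Ze$Z <- Ze$Z[rownames(xm$values), , drop = FALSE]
    } else {
      stop("explanatory rows do not cover the expression rows; ",
           "see harmonize_genes()")
    }
  }
  masses <- compute_masses(xm)
  resid <- cca_standardize(xm, masses)
  space <- cca_project(resid, Ze, masses)
  sol <- cca_decompose(space, resid, n_vars = ncol(Ze$Z), masses = masses)
  sol$biplot <- cca_biplot(Ze, sol, masses)
  sol$var_names <- Ze$names
  sol
}

#' Unconstrained correspondence analysis
#'
#' Plain CA of the table: SVD of the chi-square standardized residuals
#' without any projection. Column principal coordinates reproduce
#' chi-square distances between column profiles.
#'
#' @inheritParams cca
#' @return `cca_sol` with J = min(p - 1, m - 1) axes and no biplot.
#' @export
ca <- function(x) {
  xm <- if (inherits(x, "expr_mat")) x else expression_matrix(x)
  masses <- compute_masses(xm)
  resid <- cca_standardize(xm, masses)
  p <- nrow(resid$S); m <- ncol(resid$S)
  space <- structure(list(S_star = resid$S, basis = diag(1, p),
                          rank = p, Tmat = resid$S,
                          constrained_inertia = resid$total_inertia),
                     class = "cca_space")
  cca_decompose(space, resid, n_vars = min(p - 1, m - 1), masses = masses)
}

#' @exportS3Method print cca_sol
print.cca_sol <- function(x, ...) {
  cat(sprintf(
    "<cca_sol> J = %d axes, k = %d variable(s)\n", x$J, x$k))
  cat(sprintf("  total inertia %.6g, constrained %.6g (%.1f%%)\n",
              x$total_inertia, x$constrained_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  if (x$J > 0)
    cat("  eigenvalues:", paste(signif(x$lam, 6), collapse = " "), "\n")
  invisible(x)
}

#' Sample scores under alternative ordination scalings
#'
#' @param solution a `cca_sol`.
#' @param scaling `"site"` (principal coordinates, D_c^{-1/2} V D_alpha;
#'   the scaling stored in the solution), `"species"` (standard
#'   coordinates, D_c^{-1/2} V) or `"symmetric"`
#'   (D_c^{-1/2} V D_alpha^{1/2}).
#' @return m x J score matrix.
#' @export
cca_sample_scores <- function(solution,
                              scaling = c("site", "species", "symmetric")) {
  scaling <- match.arg(scaling)
  if (solution$J == 0) return(solution$sample_scores)
  V <- sweep(solution$V, 1, sqrt(solution$masses$c), "/")
  switch(scaling,
         site = V %*% diag(solution$alpha, solution$J),
         species = V,
         symmetric = V %*% diag(sqrt(solution$alpha), solution$J))
}

#' Per-sample activation score from a 1D solution
#'
#' With a single explanatory variable the solution is one-dimensional and
#' the Axis 1 sample score multiplied by the (+1/-1) biplot value is an
#' activation score: samples loaded on genes that rise with the variable
#' score high regardless of the arbitrary axis orientation.
#'
#' @param solution a `cca_sol` fitted with k = 1.
#' @return named numeric vector of per-sample scores.
#' @export
activation_score <- function(solution) {
  if (solution$k != 1)
    stop("activation_score() requires a 1D (k = 1) solution; ",
         "use the per-axis sample scores for k > 1")
  samples <- rownames(solution$sample_scores)
  if (solution$J == 0) {
    out <- rep(0, nrow(solution$sample_scores))
    names(out) <- samples
    return(out)
  }
  s <- solution$sample_scores[, 1] * sign(solution$biplot[1, 1])
  names(s) <- samples
  s
}

#' Partition the gene space into activation modules
#'
#' Genes in the lowest quantile of Axis 1 weighted-average scores (the
#' pole correlated with the activation variable) are designated activation
#' (Tact) genes and split by the sign of their Axis 2 score into
#' Foxp3-correlated (Axis 2 >= 0, Treg-shared) and Runx1-correlated
#' (Axis 2 < 0, Tmem-specific) modules. Ties at the Axis 1 threshold are
#' included; Axis 2 zeros go to the Foxp3 side.
#'
#' @param solution a `cca_sol` with at least two axes.
#' @param axis1_quantile fraction of genes taken from the low Axis 1 pole.
#' @return list of [gene_set()]s: `tact`, `tact_foxp3`, `tact_runx1`.
#' @export
partition_gene_space <- function(solution, axis1_quantile = 0.25) {
  if (solution$J < 2)
    stop("gene-space partition needs a solution with >= 2 axes")
  g <- solution$gene_scores_wa
  thr <- stats::quantile(g[, 1], axis1_quantile, names = FALSE)
  tact_idx <- g[, 1] <= thr
  ids <- rownames(g)
  foxp3 <- ids[tact_idx & g[, 2] >= 0]
  runx1 <- ids[tact_idx & g[, 2] < 0]
  list(tact = gene_set("tact", ids[tact_idx]),
       tact_foxp3 = if (length(foxp3)) gene_set("tact_foxp3", foxp3) else
         structure(list(name = "tact_foxp3", members = character(0)),
                   class = "gene_set"),
       tact_runx1 = if (length(runx1)) gene_set("tact_runx1", runx1) else
         structure(list(name = "tact_runx1", members = character(0)),
                   class = "gene_set"))
}

#' Export a CCA solution as TSV tables plus a JSON summary
#'
#' Writes `sample_scores.tsv`, `gene_scores.tsv`, `eigenvalues.tsv`,
#' `biplot.tsv` (when present) and `summary.json` into `dir`.
#'
#' @param solution a `cca_sol`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cca_solution <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(m, f) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(solution$sample_scores, "sample_scores.tsv")
  wtsv(solution$gene_scores_wa, "gene_scores.tsv")
  if (!is.null(solution$biplot)) wtsv(solution$biplot, "biplot.tsv")
  utils::write.table(
    data.frame(axis = seq_len(solution$J), alpha = solution$alpha,
               lambda = solution$lam,
               inertia_fraction = solution$inertia_fraction),
    file.path(dir, "eigenvalues.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(J = solution$J, k = solution$k,
         total_inertia = solution$total_inertia,
         constrained_inertia = solution$constrained_inertia,
         inertia_fraction = solution$inertia_fraction),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
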