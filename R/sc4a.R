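# Angle between two score-space vectors, in [0, pi]. For 2D vectors the
# dot/cross form atan2(|u x v|, u . v) is used; higher dimensions fall
# back to the clamped arccosine of the normalized dot product.
vector_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(pi / 2)
  if (length(a) == 2) {
    atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b))
  } else {
    acos(min(1, max(-1, sum(a * b) / (na * nb))))
  }
}

# CCA of a cells-by-genes matrix with a subset of its own genes as
# explanatory variables; those columns are removed from the analysed
# matrix so the variables never explain themselves.
sc4a_gene_cca <- function(x, genes) {
  stopifnot(inherits(x, "expr_mat"))
  v <- x$values
  missing <- setdiff(genes, colnames(v))
  if (length(missing))
    stop("explanatory gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  Zraw <- v[, genes, drop = FALSE]
  xr <- expression_matrix(v[, setdiff(colnames(v), genes), drop = FALSE],
                          orientation = x$orientation)
  Zraw <- Zraw[rownames(xr$values), , drop = FALSE]
  cca(xr, explanatory_matrix(Zraw, names = genes, standardize = TRUE))
}

#' Preliminary SC4A ordination
#'
#' Conventional CCA in the single-cell orientation: cells are rows and
#' genes are columns, so the weighted-average scores are per-cell scores
#' and the column principal coordinates are gene scores. The explanatory
#' variables are external per-cell covariates (e.g. activated/resting
#' signatures projected onto cells); variables that are themselves
#' columns of the matrix must go through [final_sc4a()]-style fitting
#' which removes them from the analysed columns, so sharing names with
#' the matrix is an error here.
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param variables [explanatory_matrix()] over cells (rows = cells).
#' @return a [cca()] solution; `gene_scores_wa` holds the per-cell scores.
#' @export
preliminary_cca <- function(x, variables) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$orientation != "cells_by_genes")
    stop("preliminary_cca() expects cells_by_genes orientation")
  Ze <- if (inherits(variables, "expl_mat")) variables else
    explanatory_matrix(variables)
  leak <- intersect(Ze$names, colnames(x$values))
  if (length(leak))
    stop("explanatory variable(s) also present as matrix columns: ",
         paste(leak, collapse = ", "),
         "; remove them from the matrix or fit with gene variables")
  cca(x, Ze)
}

#' Define cell populations from an ordination and a marker gene
#'
#' Cells are split into activated vs resting by the sign of their Axis 1
#' activation score (Axis 1 cell score times the sign of the chosen
#' variable's Axis 1 biplot value, so that positive means correlated with
#' activation; exact zeros count as resting), and into marker-positive vs
#' -negative by strictly positive marker expression, yielding the four-way
#' labels `activated_<marker>pos` etc.
#'
#' @param solution a cells-as-rows `cca_sol` (e.g. [preliminary_cca()]).
#' @param marker marker gene name used in the labels (e.g. `"FOXP3"`).
#' @param marker_values named per-cell expression of the marker.
#' @param activation_variable biplot row (name or index) that represents
#'   activation; its Axis 1 sign orients the score.
#' @return named factor of per-cell labels, with the numeric activation
#'   scores in attribute `"activation_score"`.
#' @export
define_populations <- function(solution, marker, marker_values,
                               activation_variable = 1) {
  if (solution$J < 1) stop("solution has no axes")
  cells <- rownames(solution$gene_scores_wa)
  if (is.null(names(marker_values)))
    stop("marker_values must be named by cell")
  if (!all(cells %in% names(marker_values)))
    stop("marker '", marker, "' values missing for some cells")
  sgn <- sign(solution$biplot[activation_variable, 1])
  if (sgn == 0) sgn <- 1
  score <- solution$gene_scores_wa[, 1] * sgn
  act <- score > 0
  pos <- marker_values[cells] > 0
  lab <- paste0(ifelse(act, "activated", "resting"), "_",
                marker, ifelse(pos, "pos", "neg"))
  out <- factor(lab)
  names(out) <- cells
  attr(out, "activation_score") <- stats::setNames(score, cells)
  out
}

#' Rank candidate explanatory genes by correlation to each population
#'
#' For every population the centroid of its member cells in the
#' ordination is computed, genes are ranked by the cosine similarity of
#' their score vector to that centroid, and the top `per_population`
#' genes are pooled (deduplicated) across populations. A user-supplied
#' candidate list short-circuits the ranking after a presence check.
#'
#' @param solution a cells-as-rows `cca_sol`.
#' @param populations named factor of per-cell labels.
#' @param per_population genes kept per population (the preliminary
#'   screen typically uses 5-10).
#' @param user_candidates optional character vector overriding the
#'   automatic choice.
#' @return character vector of candidate gene ids.
#' @export
candidate_genes <- function(solution, populations, per_population = 5,
                            user_candidates = NULL) {
  gene_scores <- solution$sample_scores    # columns are genes here
  if (!is.null(user_candidates)) {
    missing <- setdiff(user_candidates, rownames(gene_scores))
    if (length(missing))
      stop("user candidate(s) not in the solution: ",
           paste(missing, collapse = ", "))
    return(user_candidates)
  }
  if (per_population < 1) stop("per_population must be >= 1")
  cells <- rownames(solution$gene_scores_wa)
  populations <- populations[cells]
  out <- character(0)
  for (pop in levels(droplevels(populations))) {
    centroid <- colMeans(solution$gene_scores_wa[populations == pop, ,
                                                 drop = FALSE])
    cosim <- apply(gene_scores, 1, function(g) {
      ng <- sqrt(sum(g^2)); nc <- sqrt(sum(centroid^2))
      if (ng == 0 || nc == 0) -Inf else sum(g * centroid) / (ng * nc)
    })
    out <- c(out, names(sort(cosim, decreasing = TRUE))[
      seq_len(min(per_population, length(cosim)))])
  }
  unique(out)
}

#' Combinatorial CCA tournament over candidate genes
#'
#' Every unordered pair of candidate genes is used as the explanatory
#' pair of a CCA (the pair's columns removed from the analysed matrix).
#' In each pairwise solution the genes' biplot arrows and each
#' population's centroid of member-cell scores are compared in the first
#' two axes: the gene with the smaller arrow-centroid angle wins the pair
#' for that population (ties break to the lexicographically smaller gene
#' id). A per-gene F1 is computed from the classification rule that a
#' cell is called target-population when its score vector is closer in
#' angle to that gene's arrow than to the competitor's and its projection
#' on the arrow is positive. Genes are ranked per population by mean F1
#' (ties by mean angle) and, separately, by mean angle; when the two
#' rankings disagree the choice is surfaced rather than guessed.
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param candidates >= 2 (and <= 25, a combinatorial guard) gene ids.
#' @param populations named factor of per-cell labels (>= 2 levels);
#'   each population is scored one-vs-rest.
#' @param prefer `"f1"` or `"angle"`: which ranking selects the
#'   representative gene when the two disagree; or a named character
#'   vector of manual per-population choices.
#' @return object of class `sc4a_tournament`: `records` (data.frame with
#'   population, gene, wins, mean_angle, f1), `rankings`, `selected`
#'   (named vector, one gene per population), `agreement` (per-population
#'   logical: did F1 and angle rankings agree).
#' @export
combinatorial_cca <- function(x, candidates, populations,
                              prefer = "f1") {
  stopifnot(inherits(x, "expr_mat"))
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < 2) stop("need >= 2 candidate genes")
  if (length(candidates) > 25)
    stop("more than 25 candidates; the pairwise tournament is ",
         "combinatorially guarded -- pre-select a shorter list")
  missing <- setdiff(candidates, colnames(x$values))
  if (length(missing))
    stop("candidate(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  populations <- droplevels(as.factor(populations))
  if (nlevels(populations) < 2) stop("need >= 2 populations")
  pops <- levels(populations)
  pairs <- utils::combn(candidates, 2)
  acc <- list()  # per population x gene accumulators
  key <- function(pop, g) paste0(pop, "\r", g)
  add <- function(pop, g, win, angle, f1) {
    k <- key(pop, g)
    a <- acc[[k]]
    if (is.null(a)) a <- c(wins = 0, angle_sum = 0, f1_sum = 0, n = 0)
    a["wins"] <- a["wins"] + win
    a["angle_sum"] <- a["angle_sum"] + angle
    a["f1_sum"] <- a["f1_sum"] + f1
    a["n"] <- a["n"] + 1
    acc[[k]] <<- a
  }
  f1_score <- function(pred, truth) {
    tp <- sum(pred & truth)
    if (tp == 0) return(0)
    prec <- tp / sum(pred); rec <- tp / sum(truth)
    2 * prec * rec / (prec + rec)
  }
  for (pi in seq_len(ncol(pairs))) {
    g1 <- pairs[1, pi]; g2 <- pairs[2, pi]
    sol <- sc4a_gene_cca(x, c(g1, g2))
    if (sol$J < 1) next
    naxes <- min(sol$J, 2)
    arrows <- sol$biplot[, seq_len(naxes), drop = FALSE]
    cell_scores <- sol$gene_scores_wa[, seq_len(naxes), drop = FALSE]
    cells <- rownames(cell_scores)
    memb <- populations[cells]
    a1 <- arrows[g1, ]; a2 <- arrows[g2, ]
    ang_cells_1 <- apply(cell_scores, 1, vector_angle, b = a1)
    ang_cells_2 <- apply(cell_scores, 1, vector_angle, b = a2)
    proj1 <- cell_scores %*% a1
    proj2 <- cell_scores %*% a2
    pred1 <- ang_cells_1 < ang_cells_2 & proj1 > 0
    pred2 <- ang_cells_2 < ang_cells_1 & proj2 > 0
    for (pop in pops) {
      centroid <- colMeans(cell_scores[memb == pop, , drop = FALSE])
      ang1 <- vector_angle(a1, centroid)
      ang2 <- vector_angle(a2, centroid)
      if (ang1 == ang2)
        message("combinatorial_cca: angle tie between ", g1, " and ", g2,
                " for ", pop, "; broken lexicographically")
      win1 <- ang1 < ang2 || (ang1 == ang2)  # g1 <= g2 lexicographically
      truth <- memb == pop
      add(pop, g1, as.numeric(win1), ang1, f1_score(pred1, truth))
      add(pop, g2, as.numeric(!win1), ang2, f1_score(pred2, truth))
    }
  }
  records <- do.call(rbind, lapply(names(acc), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    a <- acc[[k]]
    data.frame(population = parts[1], gene = parts[2],
               wins = unname(a["wins"]),
               mean_angle = unname(a["angle_sum"] / a["n"]),
               f1 = unname(a["f1_sum"] / a["n"]))
  }))
  rankings <- list(); selected <- character(0); agreement <- logical(0)
  for (pop in pops) {
    rec <- records[records$population == pop, ]
    by_f1 <- rec$gene[order(-rec$f1, rec$mean_angle, rec$gene)]
    by_angle <- rec$gene[order(rec$mean_angle, -rec$f1, rec$gene)]
    rankings[[pop]] <- list(by_f1 = by_f1, by_angle = by_angle)
    agree <- by_f1[1] == by_angle[1]
    agreement[pop] <- agree
    choice <- if (length(prefer) > 1 || !prefer %in% c("f1", "angle")) {
      if (is.null(names(prefer)) || !pop %in% names(prefer))
        stop("manual 'prefer' must name every population")
      prefer[[pop]]
    } else if (prefer == "f1") by_f1[1] else by_angle[1]
    selected[pop] <- choice
  }
  structure(list(records = records, rankings = rankings,
                 selected = selected, agreement = agreement,
                 prefer = prefer, candidates = candidates),
            class = "sc4a_tournament")
}

#' @exportS3Method print sc4a_tournament
print.sc4a_tournament <- function(x, ...) {
  cat("<sc4a_tournament>", length(x$candidates), "candidates,",
      length(x$selected), "populations\n")
  for (pop in names(x$selected))
    cat(sprintf("  %s -> %s%s\n", pop, x$selected[[pop]],
                if (x$agreement[[pop]]) "" else "  (F1/angle disagree)"))
  invisible(x)
}

#' Final SC4A solution
#'
#' CCA of the single-cell matrix using the tournament-selected genes
#' (one per population) as explanatory variables; the selected columns
#' are removed from the analysed matrix. Duplicate selections collapse
#' with a warning (reducing k).
#'
#' @param x cells-by-genes [expression_matrix()].
#' @param selected character vector of selected genes (typically the
#'   `selected` field of [combinatorial_cca()]).
#' @return a `cca_sol`; `gene_scores_wa` holds per-cell scores,
#'   `sample_scores` the gene scores, `biplot` the variable arrows.
#' @export
final_sc4a <- function(x, selected) {
  selected <- as.character(selected)
  if (anyDuplicated(selected)) {
    warning("duplicate selected genes collapsed; k reduced to ",
            length(unique(selected)), call. = FALSE)
    selected <- unique(selected)
  }
  sc4a_gene_cca(x, selected)
}
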