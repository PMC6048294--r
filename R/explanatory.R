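#' Differential contrast between two sample groups
#'
#' Computes per-gene log2 fold changes and significance for an
#' activated-vs-resting (or transduced-vs-empty-vector) comparison on
#' log2-scale expression. `method = "welch"` is a two-sample
#' unequal-variance t-test; `method = "moderated"` uses limma's empirical
#' Bayes moderated t-statistic, which stabilises gene-wise variances with
#' few replicates. P-values are Benjamini-Hochberg adjusted.
#'
#' @param A,B matrices (genes x replicates, log2 scale) for the two
#'   groups, or [expression_matrix()] objects. Gene universes must match;
#'   see [harmonize_genes()].
#' @param method `"welch"` or `"moderated"`.
#' @return data.frame of class `contrast_result` with columns `gene`,
#'   `log2fc` (mean A - mean B), `stat`, `p`, `fdr`. With a single
#'   replicate per group only `log2fc` is defined (`stat`/`p`/`fdr` NA).
#' @export
differential_contrast <- function(A, B, method = c("welch", "moderated")) {
  method <- match.arg(method)
  A <- as_expr_values(A); B <- as_expr_values(B)
  if (!identical(rownames(A), rownames(B)))
    stop("gene universes of the two groups differ; see harmonize_genes()")
  log2fc <- rowMeans(A) - rowMeans(B)
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2 || nB < 2) {
    res <- data.frame(gene = rownames(A), log2fc = log2fc,
                      stat = NA_real_, p = NA_real_, fdr = NA_real_,
                      row.names = NULL)
    class(res) <- c("contrast_result", class(res))
    return(res)
  }
  if (method == "welch") {
    vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
    se2 <- vA / nA + vB / nB
    stat <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
                 nA + nB - 2)
    p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    p[se2 == 0] <- 1
  } else {
    design <- cbind(mean = 1,
                    diff = c(rep(1, nA), rep(0, nB)))
    fit <- limma::eBayes(limma::lmFit(cbind(A, B), design))
    stat <- fit$t[, "diff"]
    p <- fit$p.value[, "diff"]
  }
  res <- data.frame(gene = rownames(A), log2fc = log2fc, stat = stat,
                    p = p, fdr = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  class(res) <- c("contrast_result", class(res))
  res
}

#' Build a standardized explanatory variable from a contrast
#'
#' Differentially expressed genes are selected by FDR and absolute log2
#' fold change (defaults FDR < 0.01, |log2FC| > 1); the variable takes the
#' log2 fold change on selected genes and 0 elsewhere, so that
#' non-differential genes carry no signal while the variable stays
#' row-aligned with the full gene universe. The column is then
#' standardized to mean 0, variance 1.
#'
#' @param contrast a [differential_contrast()] result.
#' @param fdr_max FDR cutoff (strict `<`).
#' @param abs_lfc_min absolute log2 fold-change cutoff (strict `>`).
#' @param top_n optionally keep only the `top_n` passing genes with the
#'   smallest p-values.
#' @param name variable name.
#' @return list with `variable` (one-column [explanatory_matrix()], rows
#'   named by gene) and `genes` (the contributing [gene_set()]).
#' @export
build_variable <- function(contrast, fdr_max = 0.01, abs_lfc_min = 1.0,
                           top_n = NULL, name = "variable") {
  pass_fdr <- !is.na(contrast$fdr) & contrast$fdr < fdr_max
  pass_lfc <- abs(contrast$log2fc) > abs_lfc_min
  pass <- pass_fdr & pass_lfc
  if (!any(pass))
    stop(sprintf(
      "no gene passes the filters: %d/%d pass FDR < %g, %d/%d pass |log2FC| > %g, 0 pass both",
      sum(pass_fdr), nrow(contrast), fdr_max,
      sum(pass_lfc), nrow(contrast), abs_lfc_min))
  if (!is.null(top_n) && sum(pass) > top_n) {
    idx <- which(pass)
    keep <- idx[order(contrast$p[idx])][seq_len(top_n)]
    pass <- seq_len(nrow(contrast)) %in% keep
  }
  v <- ifelse(pass, contrast$log2fc, 0)
  Z <- matrix(v, ncol = 1, dimnames = list(contrast$gene, name))
  list(variable = explanatory_matrix(Z, names = name, standardize = TRUE),
       genes = gene_set(name, contrast$gene[pass]))
}

#' Align datasets on a shared gene universe
#'
#' Takes the row intersection of every input (expression matrices,
#' explanatory matrices, or contrast results) and reorders all of them
#' identically, reporting per-input dropped genes. `mode = "casefold"`
#' matches identifiers case-insensitively (useful across mouse/human
#' symbol conventions) while keeping the first input's spelling.
#'
#' @param ... two or more inputs with gene rownames (or a single list).
#' @param mode `"exact"` or `"casefold"`.
#' @return list with `datasets` (aligned inputs, same order as supplied)
#'   and `dropped` (per-input character vectors of removed genes).
#' @export
harmonize_genes <- function(..., mode = c("exact", "casefold")) {
  mode <- match.arg(mode)
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !inherits(inputs[[1]], c("expr_mat", "expl_mat", "contrast_result")))
    inputs <- inputs[[1]]
  if (length(inputs) < 2) stop("harmonize_genes() needs >= 2 inputs")
  ids_of <- function(x) {
    if (inherits(x, "expr_mat")) rownames(x$values)
    else if (inherits(x, "expl_mat")) rownames(x$Z)
    else if (inherits(x, "contrast_result")) x$gene
    else rownames(as.matrix(x))
  }
  key <- function(ids) if (mode == "casefold") toupper(ids) else ids
  all_ids <- lapply(inputs, ids_of)
  shared_keys <- Reduce(intersect, lapply(all_ids, key))
  if (length(shared_keys) == 0) stop("no shared genes across inputs")
  # keep the first input's ordering and spelling
  first_keys <- key(all_ids[[1]])
  shared_keys <- first_keys[first_keys %in% shared_keys]
  dropped <- lapply(all_ids, function(ids) ids[!key(ids) %in% shared_keys])
  subset_one <- function(x, ids) {
    rows <- match(shared_keys, key(ids))
    if (inherits(x, "expr_mat")) {
      expression_matrix(x$values[rows, , drop = FALSE],
                        orientation = x$orientation)
    } else if (inherits(x, "expl_mat")) {
      x$Z <- x$Z[rows, , drop = FALSE]
      x
    } else if (inherits(x, "contrast_result")) {
      x[rows, , drop = FALSE]
    } else {
      as.matrix(x)[rows, , drop = FALSE]
    }
  }
  aligned <- Map(subset_one, inputs, all_ids)
  list(datasets = aligned, dropped = dropped)
}
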