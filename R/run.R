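# Reproducibility manifest: input hashes, parameters, seed, version.
write_manifest <- function(out_dir, workflow, inputs, params, seed) {
  hashes <- lapply(inputs, function(p)
    if (is.character(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL)
  jsonlite::write_json(
    list(workflow = workflow,
         package = "sc4a",
         version = as.character(utils::packageVersion("sc4a")),
         seed = seed, inputs = inputs, input_md5 = hashes,
         params = params, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the conventional CCA workflow
#'
#' Reads (or accepts) a main expression matrix and one or more
#' explanatory variables, fits the constrained ordination, exports the
#' solution tables, and optionally the activation scores (k = 1) and the
#' Axis 1/Axis 2 gene-space partition (k >= 2).
#'
#' @param main [expression_matrix()] or path to one.
#' @param variables [explanatory_matrix()], a path to a two-column
#'   gene/value TSV, or a list of either.
#' @param out_dir output directory.
#' @param partition also write the Tact/Tact-Foxp3/Tact-Runx1 gene
#'   partition (needs >= 2 axes).
#' @param axis1_quantile quantile for the partition.
#' @return the fitted `cca_sol`, invisibly.
#' @export
run_cca <- function(main, variables, out_dir, partition = FALSE,
                    axis1_quantile = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (is.character(main)) { inputs$main <- main
    main <- read_expression(main) }
  if (is.character(variables)) inputs$variables <- variables
  Z <- load_variables(variables)
  h <- harmonize_genes(main, Z)
  sol <- cca(h$datasets[[1]], h$datasets[[2]])
  export_cca_solution(sol, out_dir)
  if (sol$k == 1) {
    sc <- activation_score(sol)
    utils::write.table(data.frame(sample = names(sc), score = sc),
                       file.path(out_dir, "activation_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (partition) {
    part <- partition_gene_space(sol, axis1_quantile)
    for (nm in names(part))
      writeLines(part[[nm]]$members,
                 file.path(out_dir, paste0(nm, "_genes.txt")))
  }
  write_manifest(out_dir, "cca", inputs,
                 list(k = sol$k, partition = partition,
                      axis1_quantile = axis1_quantile), seed = NULL)
  invisible(sol)
}

load_variables <- function(variables) {
  read_one <- function(v) {
    if (inherits(v, "expl_mat")) return(v)
    if (is.character(v)) {
      tab <- utils::read.table(v, header = TRUE, sep = "\t",
                               row.names = 1, check.names = FALSE)
      return(explanatory_matrix(as.matrix(tab), standardize = FALSE))
    }
    explanatory_matrix(v)
  }
  if (is.list(variables) && !inherits(variables, "expl_mat")) {
    parts <- lapply(variables, read_one)
    Z <- do.call(cbind, lapply(parts, function(p) p$Z))
    explanatory_matrix(Z, standardize = FALSE)
  } else read_one(variables)
}

#' Run the SC4A workflow end to end
#'
#' Preprocess (gene filter, gating, outlier removal) -> preliminary CCA
#' -> population definition -> combinatorial tournament -> final
#' solution, exporting every intermediate.
#'
#' @param x cells-by-genes [expression_matrix()] or path.
#' @param variables per-cell [explanatory_matrix()] for the preliminary
#'   ordination (e.g. activated/resting signatures).
#' @param marker marker gene for population definition (e.g. "FOXP3").
#' @param out_dir output directory.
#' @param gates list of [gate_spec()]s (or marker names) applied first;
#'   `NULL` skips gating.
#' @param candidates optional candidate list; `NULL` ranks automatically.
#' @param per_population candidates kept per population.
#' @param prefer ranking preference passed to [combinatorial_cca()];
#'   when the F1 and angle rankings disagree for a population and
#'   `prefer` was not set explicitly, the run stops and asks for it.
#' @param seed seed for the outlier-removal k-means.
#' @param outlier_removal apply [pca_kmeans_outlier_removal()].
#' @param activation_variable biplot row representing activation.
#' @return list with `solution` (final `cca_sol`), `tournament`,
#'   `populations`, `preliminary`, invisibly.
#' @export
run_sc4a <- function(x, variables, marker, out_dir, gates = NULL,
                     candidates = NULL, per_population = 5,
                     prefer = NULL, seed, outlier_removal = FALSE,
                     activation_variable = 1) {
  if (missing(seed)) stop("run_sc4a() requires a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (is.character(x)) { inputs$x <- x
    x <- read_expression(x, orientation = "cells_by_genes") }
  if (!is.null(gates)) x <- in_silico_gate(x, gates)$x
  if (outlier_removal)
    x <- pca_kmeans_outlier_removal(x, seed = seed)
  prelim <- preliminary_cca(x, variables)
  if (!marker %in% colnames(x$values))
    stop("marker gene absent from matrix: ", marker)
  pops <- define_populations(prelim, marker, x$values[, marker],
                             activation_variable = activation_variable)
  cand <- candidate_genes(prelim, pops, per_population = per_population,
                          user_candidates = candidates)
  tour <- combinatorial_cca(x, cand, pops,
                            prefer = if (is.null(prefer)) "f1" else prefer)
  if (is.null(prefer) && !all(tour$agreement))
    stop("F1 and angle rankings disagree for: ",
         paste(names(tour$agreement)[!tour$agreement], collapse = ", "),
         "; rerun with prefer = 'f1', 'angle', or a manual choice")
  final <- final_sc4a(x, tour$selected)
  export_cca_solution(final, out_dir)
  utils::write.table(
    transform(tour$records, mean_angle_deg = mean_angle * 180 / pi),
    file.path(out_dir, "tournament.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell = names(pops), population = as.character(pops),
               activation_score = attr(pops, "activation_score")),
    file.path(out_dir, "populations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(tour$selected),
                       file.path(out_dir, "selected_genes.json"),
                       auto_unbox = TRUE)
  write_manifest(out_dir, "sc4a", inputs,
                 list(marker = marker, per_population = per_population,
                      prefer = prefer, outlier_removal = outlier_removal),
                 seed = seed)
  invisible(list(solution = final, tournament = tour, populations = pops,
                 preliminary = prelim))
}

#' Run the lineage / pseudotime workflow
#'
#' Clusters the per-cell scores of a final SC4A solution with a Gaussian
#' mixture, builds the centroid MST and lineages, assigns pseudotime and
#' writes module trajectories and quadrant gates.
#'
#' @param solution final `cca_sol` (cells as rows).
#' @param x cells-by-genes [expression_matrix()] for module/gate
#'   expression.
#' @param out_dir output directory.
#' @param K cluster count or range (BIC selection).
#' @param root_variable explanatory arrow marking the root (resting)
#'   pole; alternatively pass `root` (a cluster id).
#' @param root optional fixed root cluster id.
#' @param modules named list of [gene_set()]s to trace along pseudotime.
#' @param gates list of `list(gene_x, gene_y)` pairs for quadrant gates.
#' @param n_bins pseudotime bins for the module curves.
#' @param seed clustering seed.
#' @return list with `model`, `labels`, `pseudotime`, `trajectories`,
#'   invisibly.
#' @export
run_lineage <- function(solution, x, out_dir, K = 2:8,
                        root_variable = NULL, root = NULL,
                        modules = NULL, gates = NULL, n_bins = 10,
                        seed) {
  if (missing(seed)) stop("run_lineage() requires a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- solution$gene_scores_wa
  cl <- em_cluster(scores, K, seed = seed)
  model <- build_lineages(cl$centroids, root = root,
                          arrows = solution$biplot,
                          root_variable = root_variable)
  pt <- assign_pseudotime(scores, cl$labels, model)
  utils::write.table(pt, file.path(out_dir, "pseudotime.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(root = model$root,
         clusters = rownames(model$centroids),
         edges = apply(model$mst_edges, 1, paste, collapse = "-"),
         lineages = model$lineages,
         bifurcation_clusters = model$bifurcation_clusters),
    file.path(out_dir, "lineages.json"), auto_unbox = TRUE)
  trajectories <- NULL
  if (!is.null(modules)) {
    trajectories <- do.call(rbind, lapply(names(modules), function(nm) {
      tr <- module_trajectory(x, modules[[nm]], pt, n_bins = n_bins)
      cbind(module = nm, tr)
    }))
    utils::write.table(trajectories,
                       file.path(out_dir, "module_trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gates)) {
    for (g in gates) {
      q <- quadrant_gate(x, g$gene_x, g$gene_y, g$tx, g$ty)
      utils::write.table(
        as.data.frame(as.table(q$counts)),
        file.path(out_dir, sprintf("gate_%s_%s.tsv", g$gene_x, g$gene_y)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_manifest(out_dir, "lineage", list(),
                 list(K = K, root_variable = root_variable, root = root,
                      n_bins = n_bins), seed = seed)
  invisible(list(model = model, labels = cl$labels, pseudotime = pt,
                 trajectories = trajectories))
}

#' Run the fixture simulator and write standard files
#'
#' @param out_dir output directory.
#' @param kind `"bulk"` (paired contrast) or `"single_cell"`.
#' @param seed mandatory seed.
#' @param ... forwarded to [simulate_bulk_contrast()] or [sim_config()].
#' @return the simulation object, invisibly.
#' @export
run_simulate <- function(out_dir, kind = c("bulk", "single_cell"), seed,
                         ...) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("run_simulate() requires a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "bulk") {
    sim <- simulate_bulk_contrast(seed = seed, ...)
    write_expression(sim$activated, file.path(out_dir, "activated.tsv"))
    write_expression(sim$resting, file.path(out_dir, "resting.tsv"))
    jsonlite::write_json(list(truth = sim$truth$members,
                              lfc = as.list(sim$lfc_truth)),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    sim <- simulate_single_cells(sim_config(seed = seed, ...))
    write_expression(sim$x, file.path(out_dir, "cells.tsv"))
    utils::write.table(
      data.frame(cell = names(sim$populations),
                 population = as.character(sim$populations)),
      file.path(out_dir, "populations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$latent))
      utils::write.table(sim$latent, file.path(out_dir, "latent.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(markers = sim$markers, decoys = sim$decoys,
                              gradient_genes = sim$gradient_genes),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  write_manifest(out_dir, paste0("simulate_", kind), list(),
                 list(...), seed = seed)
  invisible(sim)
}
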