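blob_scores <- function(centers, n_per, sd = 0.1, seed = 1) {
  set.seed(seed)
  K <- nrow(centers)
  coords <- centers[rep(seq_len(K), each = n_per), , drop = FALSE] +
    matrix(rnorm(2 * K * n_per, 0, sd), K * n_per, 2)
  rownames(coords) <- sprintf("c%03d", seq_len(K * n_per))
  colnames(coords) <- c("Axis1", "Axis2")
  list(scores = coords, truth = rep(seq_len(K), each = n_per))
}

test_that("EM clustering recovers well-separated Gaussian blobs", {
  centers <- rbind(c(0, 0), c(4, 0), c(2, 4))
  aris <- vapply(1:5, function(seed) {
    b <- blob_scores(centers, 40, sd = 0.3, seed = seed)
    cl <- em_cluster(b$scores, K = 3, seed = seed)
    mclust::adjustedRandIndex(cl$labels, b$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.95))
})

test_that("K = 1 returns a single cluster at the mean", {
  b <- blob_scores(rbind(c(1, 2)), 50, sd = 0.5, seed = 2)
  cl <- em_cluster(b$scores, K = 1, seed = 2)
  expect_equal(unname(cl$K), 1L)
  expect_equal(unname(cl$centroids[1, ]), unname(colMeans(b$scores)),
               tolerance = 1e-6)
  expect_error(em_cluster(b$scores[1:3, ], K = 5), "smaller")
})

test_that("BIC selects the planted number of components", {
  hits <- vapply(1:10, function(seed) {
    b <- blob_scores(rbind(c(0, 0), c(5, 0), c(2.5, 5)), 50, sd = 0.3,
                     seed = seed + 10)
    cl <- em_cluster(b$scores, K = 1:6, seed = seed)
    cl$K == 3
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("collinear centroids give a single unbranched lineage", {
  centroids <- rbind(`1` = c(0, 0), `2` = c(1, 0), `3` = c(2, 0))
  model <- build_lineages(centroids, root = "1")
  expect_equal(nrow(model$mst_edges), 2L)
  expect_length(model$lineages, 1)
  expect_equal(model$lineages[[1]], c("1", "2", "3"))
  expect_length(model$bifurcation_clusters, 0)
})

test_that("a Y-shaped layout flags the hub as the bifurcation", {
  centroids <- rbind(`1` = c(-1, 0), `2` = c(0, 0),
                     `3` = c(1, 1), `4` = c(1, -1))
  model <- build_lineages(centroids, root = "1")
  expect_equal(nrow(model$mst_edges), 3L)
  expect_equal(unname(model$degrees["2"]), 3L)
  expect_equal(model$bifurcation_clusters, "2")
  expect_length(model$lineages, 2)
  expect_equal(model$lineages$lineage_3, c("1", "2", "3"))
  expect_equal(model$lineages$lineage_4, c("1", "2", "4"))
})

test_that("root selection can follow an explanatory arrow", {
  centroids <- rbind(`1` = c(-2, 0), `2` = c(0, 0), `3` = c(2, 0))
  arrows <- matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE,
                   dimnames = list(c("CCR7", "CTLA4"), NULL))
  m <- build_lineages(centroids, arrows = arrows, root_variable = "CCR7")
  expect_equal(m$root, "1")
  m2 <- build_lineages(centroids, arrows = arrows, root_variable = "CTLA4")
  expect_equal(m2$root, "3")
})

test_that("cells at the centroids take the normalized arc-length pseudotime", {
  centroids <- rbind(`1` = c(0, 0), `2` = c(3, 0), `3` = c(3, 4))
  model <- build_lineages(centroids, root = "1")
  scores <- centroids
  rownames(scores) <- c("a", "b", "c")
  labels <- c(a = "1", b = "2", c = "3")
  pt <- assign_pseudotime(scores, labels, model)
  expect_equal(pt$t[match(c("a", "b", "c"), pt$cell)],
               c(0, 3 / 7, 1), tolerance = 1e-12)
})

test_that("reversing the root reverses pseudotime", {
  centroids <- rbind(`1` = c(0, 0), `2` = c(1, 0), `3` = c(2, 0))
  b <- blob_scores(centroids, 30, sd = 0.05, seed = 5)
  labels <- setNames(as.character(b$truth), rownames(b$scores))
  fwd <- assign_pseudotime(b$scores, labels,
                           build_lineages(centroids, root = "1"))
  rev <- assign_pseudotime(b$scores, labels,
                           build_lineages(centroids, root = "3"))
  m <- match(fwd$cell, rev$cell)
  expect_equal(rev$t[m], 1 - fwd$t, tolerance = 1e-10)
})

test_that("pseudotime is invariant to rigid rotation of the score space", {
  centroids <- rbind(`1` = c(0, 0), `2` = c(2, 1), `3` = c(4, 0))
  b <- blob_scores(centroids, 25, sd = 0.1, seed = 6)
  labels <- setNames(as.character(b$truth), rownames(b$scores))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pt1 <- assign_pseudotime(b$scores, labels,
                           build_lineages(centroids, root = "1"))
  pt2 <- assign_pseudotime(b$scores %*% R, labels,
                           build_lineages(centroids %*% R, root = "1"))
  expect_equal(pt1$t, pt2$t, tolerance = 1e-10)
})

test_that("module curves are flat for constant genes and monotone for
           monotone genes", {
  set.seed(7)
  n <- 120
  t <- seq(0, 1, length.out = n)
  cells <- sprintf("c%03d", 1:n)
  m <- cbind(flat = rep(4, n),
             rising = 10 * t + rnorm(n, 0, 0.01),
             noise = runif(n, 1, 2))
  rownames(m) <- cells
  x <- expression_matrix(m, orientation = "cells_by_genes")
  pt <- data.frame(cell = cells, lineage = "lineage_1",
                   cluster = "1", t = t)
  tr <- module_trajectory(x, c("flat"), pt, n_bins = 5)
  expect_equal(tr$mean, rep(0, 5))  # zero-variance gene contributes 0
  tr2 <- module_trajectory(x, gene_set("mod", "rising"), pt, n_bins = 5)
  expect_true(all(diff(tr2$mean) > 0))
  expect_message(module_trajectory(x, c("rising", "gone"), pt),
                 "absent")
  expect_error(module_trajectory(x, "gone", pt), "no module gene")
})

test_that("branch-specific modules rise on their own lineage only", {
  sim <- simulate_single_cells(sim_config(
    seed = 51, trajectory = list(topology = "bifurcating")))
  scores <- as.matrix(sim$latent[, c("dim1", "dim2")])
  rownames(scores) <- sim$latent$cell
  cl <- em_cluster(scores, K = 6, seed = 51)
  root <- rownames(cl$centroids)[which.min(rowSums(cl$centroids^2))]
  model <- build_lineages(cl$centroids, root = root)
  pt <- assign_pseudotime(scores, cl$labels, model)
  # plant two complementary modules on the branch membership
  v <- sim$x$values
  onA <- sim$latent$branch[match(rownames(v), sim$latent$cell)] == "A"
  v <- cbind(v, BR_A = ifelse(onA, 20, 1), BR_B = ifelse(onA, 1, 20))
  x <- expression_matrix(v, orientation = "cells_by_genes")
  # identify which lineage follows branch A by its cells
  linA <- names(which.max(vapply(model$lineages, function(p) {
    cells <- pt$cell[pt$lineage == paste0("lineage_", p[length(p)])]
    mean(onA[match(cells, rownames(v))])
  }, numeric(1))))
  trA <- module_trajectory(x, "BR_A", pt, n_bins = 4)
  rise <- function(tr, lin) {
    sub <- tr[tr$lineage == lin, ]
    sub$mean[nrow(sub)] - sub$mean[1]
  }
  lins <- unique(trA$lineage)
  deltas <- vapply(lins, function(l) rise(trA, l), numeric(1))
  # the module rises strongly along exactly one lineage
  expect_equal(sum(deltas > 1), 1L)
})

test_that("quadrant gates tally cells like a brute-force count", {
  m <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2,
              dimnames = list(paste0("c", 1:4), c("GX", "GY")))
  x <- expression_matrix(matrix(c(1, 1, 0.01, 0.01, 1, 0.01, 1, 0.01),
                                4, 2,
                                dimnames = dimnames(m)),
                         orientation = "cells_by_genes")
  q <- quadrant_gate(x, "GX", "GY", tx = 0.5, ty = 0.5)
  expect_equal(as.vector(q$counts), rep(1L, 4))
  expect_equal(sum(q$percent), 100)
  # thresholds below all values put everything double-positive
  qq <- quadrant_gate(x, "GX", "GY", tx = -1, ty = -1)
  expect_equal(qq$counts["x+", "y+"], 4L)
  # random brute-force tally
  set.seed(8)
  vals <- matrix(runif(400), 200, 2,
                 dimnames = list(sprintf("c%03d", 1:200), c("A", "B")))
  xx <- expression_matrix(vals, orientation = "cells_by_genes")
  qr <- quadrant_gate(xx, "A", "B", tx = 0.4, ty = 0.6)
  expect_equal(qr$counts["x+", "y+"],
               sum(vals[, 1] > 0.4 & vals[, 2] > 0.6))
  expect_equal(sum(qr$counts), 200)
  expect_error(quadrant_gate(xx, "A", "NOPE"), "absent")
})

test_that("Venn region cardinalities match brute-force enumeration", {
  res <- set_intersections(list(a = c("A", "B", "C"), b = c("B", "C", "D")))
  expect_equal(unname(res$pairwise["a", "b"]), 2L)
  expect_equal(unname(res$intersection[["a&b"]]), 2L)
  expect_equal(unname(res$exclusive[["a"]]), 1L)
  dis <- set_intersections(list(u = c("A"), v = c("B"), w = c("C")))
  expect_true(all(dis$intersection[grepl("&", names(dis$intersection))]
                  == 0))
  set.seed(9)
  sets <- lapply(1:3, function(i) sample(LETTERS, 12))
  names(sets) <- c("s1", "s2", "s3")
  r <- set_intersections(sets)
  # brute force over elements
  uni <- unique(unlist(sets))
  for (el in uni) {
    inset <- vapply(sets, function(s) el %in% s, logical(1))
    region <- paste(names(sets)[inset], collapse = "&")
    expect_gte(r$exclusive[[region]], 1L)
  }
  expect_equal(sum(r$exclusive), length(uni))
  expect_error(set_intersections(list(a = "A")), ">= 2")
  expect_error(set_intersections(setNames(as.list(LETTERS[1:6]),
                                          letters[1:6])), "5")
})
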