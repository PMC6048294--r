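toy_x <- function() expression_matrix(
  matrix(c(10, 0, 0, 10), 2, 2,
         dimnames = list(c("g1", "g2"), c("s1", "s2"))))

test_that("chi-square standardization matches hand computation", {
  r <- cca_standardize(toy_x())
  expect_equal(unname(r$S),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2), tolerance = 1e-12)
  expect_equal(r$total_inertia, 1.0, tolerance = 1e-12)
  # oracle: chi-square statistic / n on the 2x2 table
  expect_equal(r$total_inertia,
               unname(suppressWarnings(
                 chisq.test(matrix(c(10, 0, 0, 10), 2),
                            correct = FALSE))$statistic) / 20,
               tolerance = 1e-10)
  expect_lt(max(abs(rowSums(r$P))), 1e-12)
  expect_lt(max(abs(colSums(r$P))), 1e-12)
})

test_that("a table of perfect independence has zero inertia", {
  r <- c(0.2, 0.3, 0.5); cc <- c(0.4, 0.6)
  X <- 100 * outer(r, cc)
  dimnames(X) <- list(paste0("g", 1:3), paste0("s", 1:2))
  res <- cca_standardize(expression_matrix(X))
  expect_lt(max(abs(res$P)), 1e-14)
  expect_lt(res$total_inertia, 1e-24)
})

test_that("total inertia equals the brute-force element-wise sum", {
  for (seed in 1:5) {
    X <- rand_table(6, 5, seed)
    expect_equal(cca_standardize(expression_matrix(X))$total_inertia,
                 brute_inertia(X), tolerance = 1e-10)
  }
})

test_that("projection is idempotent and full-span projection is identity", {
  X <- rand_table(8, 6, 11)
  resid <- cca_standardize(expression_matrix(X))
  Z <- matrix(rnorm(8 * 2), 8, 2)
  sp <- cca_project(resid, explanatory_matrix(Z))
  once <- sp$basis %*% crossprod(sp$basis, resid$S)
  twice <- sp$basis %*% crossprod(sp$basis, once)
  expect_lt(max(abs(twice - once)), 1e-10 * sqrt(sum(resid$S^2)))
  expect_lte(sp$constrained_inertia, resid$total_inertia + 1e-10)
  # k >= p unstandardized random columns span the whole space
  Zfull <- explanatory_matrix(matrix(rnorm(8 * 8), 8, 8),
                              standardize = FALSE)
  spf <- cca_project(resid, Zfull)
  expect_equal(spf$S_star, resid$S, tolerance = 1e-10)
})

test_that("a variable with no weighted projection onto S constrains nothing", {
  # S has left null space spanned by sqrt(r); pick z with Dr^(1/2) z in it
  X <- rand_table(6, 4, 3)
  resid <- cca_standardize(expression_matrix(X))
  z <- rep(1, 6)   # Dr^(1/2) 1 is exactly the left null direction
  sp <- cca_project(resid, explanatory_matrix(matrix(z, ncol = 1),
                                              standardize = FALSE))
  expect_lt(sp$constrained_inertia, 1e-20)
  sol <- cca_decompose(sp, resid, n_vars = 1)
  expect_equal(sol$J, 0L)
})

test_that("eigenvalues are squared singular values partitioning inertia", {
  X <- rand_table(9, 6, 21)
  Z <- matrix(rnorm(9 * 3), 9, 3)
  resid <- cca_standardize(expression_matrix(X))
  sp <- cca_project(resid, explanatory_matrix(Z))
  sol <- cca_decompose(sp, resid, n_vars = 3)
  expect_equal(sol$lam, sol$alpha^2, tolerance = 1e-12)
  expect_equal(sum(sol$lam), sp$constrained_inertia, tolerance = 1e-10)
  expect_equal(sol$J, 3L)
  expect_equal(sum(sol$inertia_fraction), 1, tolerance = 1e-12)
  # orthonormality
  expect_equal(crossprod(sol$U), diag(1, sol$J), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(sol$V), diag(1, sol$J), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("constrained CCA with a full-rank Z reproduces plain CA", {
  toy <- toy_x()
  fit <- cca(toy, matrix(rnorm(4), 2, 2), standardize_z = FALSE)
  expect_equal(fit$lam, c(Axis1 = 1.0), tolerance = 1e-10,
               ignore_attr = TRUE)
  X <- rand_table(10, 7, 31)
  fit2 <- cca(expression_matrix(X), matrix(rnorm(100), 10, 10),
              standardize_z = FALSE)
  # independent oracle: direct SVD of the standardized residuals
  n <- sum(X); r <- rowSums(X) / n; cc <- colSums(X) / n
  S <- (X / n - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)$d
  expect_equal(fit2$alpha, sv[seq_len(fit2$J)], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("eigenvalues match vegan's constrained ordination", {
  skip_if_not_installed("vegan")
  for (seed in c(5, 17)) {
    X <- rand_table(12, 7, seed)
    set.seed(seed + 100)
    Z <- matrix(rnorm(12 * 2), 12, 2)
    # vegan centers covariates with row-mass weights; align the inputs
    r <- rowSums(X) / sum(X)
    Zc <- sweep(Z, 2, colSums(Z * r))
    fit <- cca(expression_matrix(X),
               explanatory_matrix(Zc, standardize = FALSE))
    vfit <- vegan::cca(X ~ Zc[, 1] + Zc[, 2])
    expect_equal(unname(fit$lam), unname(vfit$CCA$eig), tolerance = 1e-10)
    expect_equal(fit$total_inertia, vfit$tot.chi, tolerance = 1e-10)
  }
})

test_that("J is the minimum of p-1, m-1 and k", {
  X <- rand_table(6, 4, 41)
  expect_equal(cca(expression_matrix(X), matrix(rnorm(6), 6, 1))$J, 1L)
  expect_equal(cca(expression_matrix(X), matrix(rnorm(12), 6, 2))$J, 2L)
  # k larger than m-1: J capped at m-1 = 3
  expect_equal(cca(expression_matrix(X),
                   matrix(rnorm(6 * 5), 6, 5))$J, 3L)
})

test_that("column principal coordinates reproduce chi-square distances", {
  for (seed in 1:5) {
    X <- rand_table(9, 5, seed + 60)
    sol <- ca(expression_matrix(X))
    sc <- sol$sample_scores
    for (j in 1:4) for (l in (j + 1):5) {
      expect_equal(sqrt(sum((sc[j, ] - sc[l, ])^2)),
                   brute_chisq_dist(X, j, l), tolerance = 1e-8)
    }
  }
})

test_that("1D biplot values are +/-1 and negate with the variable", {
  X <- rand_table(10, 5, 71)
  z <- rnorm(10)
  fit <- cca(expression_matrix(X), matrix(z, ncol = 1))
  expect_equal(abs(fit$biplot[1, 1]), 1, tolerance = 1e-6)
  fit_neg <- cca(expression_matrix(X), matrix(-z, ncol = 1))
  expect_equal(fit_neg$biplot[1, 1], -fit$biplot[1, 1], tolerance = 1e-6)
})

test_that("a constant weighted variable yields a zero biplot row", {
  X <- rand_table(6, 4, 81)
  r <- rowSums(X) / sum(X)
  Z <- cbind(informative = rnorm(6), flat = 1 / sqrt(r))  # weighted z constant
  resid <- cca_standardize(expression_matrix(X))
  Ze <- explanatory_matrix(Z, standardize = FALSE)
  sp <- cca_project(resid, Ze)
  sol <- cca_decompose(sp, resid, n_vars = 2)
  expect_warning(rho <- cca_biplot(Ze, sol), "zero weighted variance")
  expect_equal(unname(rho["flat", ]), rep(0, sol$J))
})

test_that("solutions are invariant to joint row permutation", {
  X <- rand_table(12, 6, 91)
  z <- rnorm(12)
  fit <- cca(expression_matrix(X), matrix(z, ncol = 1,
                                          dimnames = list(rownames(X),
                                                          "z")))
  perm <- sample(12)
  fit_p <- cca(expression_matrix(X[perm, ]),
               matrix(z[perm], ncol = 1,
                      dimnames = list(rownames(X)[perm], "z")))
  expect_equal(fit_p$lam, fit$lam, tolerance = 1e-10)
  expect_equal(fit_p$sample_scores, fit$sample_scores, tolerance = 1e-8)
  expect_equal(fit_p$gene_scores_wa[rownames(X), , drop = FALSE],
               fit$gene_scores_wa, tolerance = 1e-8)
})

test_that("an uninformative variable captures little inertia", {
  fracs <- vapply(1:20, function(seed) {
    X <- rand_table(200, 8, seed + 300)
    set.seed(seed + 400)
    fit <- cca(expression_matrix(X), matrix(rnorm(200), ncol = 1))
    fit$constrained_inertia / fit$total_inertia
  }, numeric(1))
  expect_lt(mean(fracs), 0.05)
})

test_that("activation scores rank samples by loading on high-z genes", {
  # genes 1:5 induced by the variable; samples s1,s2 loaded on them
  X <- matrix(2, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  X[1:5, 1:2] <- 30
  X[6:10, 3:4] <- 30
  z <- c(rep(3, 5), rep(-3, 5))
  fit <- cca(expression_matrix(X), matrix(z, ncol = 1))
  sc <- activation_score(fit)
  expect_gt(min(sc[c("s1", "s2")]), max(sc[c("s3", "s4")]))
  # negating z reverses the meaning of the variable: the biplot sign
  # flips while the data-anchored axis stays put, so scores negate and
  # keep meaning "positively correlated with the (new) variable"
  fit_neg <- cca(expression_matrix(X), matrix(-z, ncol = 1))
  expect_equal(activation_score(fit_neg), -sc, tolerance = 1e-8)
  expect_error(activation_score(cca(expression_matrix(X),
                                    matrix(rnorm(20), 10, 2))), "k = 1")
})

test_that("identical column profiles give all-zero activation scores", {
  X <- matrix(rep(c(5, 1, 3), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  fit <- cca(expression_matrix(X), matrix(rnorm(3), ncol = 1))
  expect_equal(unname(activation_score(fit)), rep(0, 4))
})

test_that("gene-space partition takes the low Axis 1 quartile and splits by Axis 2", {
  set.seed(5)
  n <- 100
  sol <- structure(list(
    J = 2L, k = 2L,
    gene_scores_wa = cbind(Axis1 = rnorm(n), Axis2 = rnorm(n))),
    class = "cca_sol")
  rownames(sol$gene_scores_wa) <- sprintf("g%03d", 1:n)
  part <- partition_gene_space(sol)
  expect_length(part$tact$members, 25)
  expect_setequal(c(part$tact_foxp3$members, part$tact_runx1$members),
                  part$tact$members)
  # zero on Axis 2 goes to the Foxp3 (positive) side
  sol$gene_scores_wa[, 2] <- 0
  part0 <- partition_gene_space(sol)
  expect_length(part0$tact_runx1$members, 0)
  expect_error(partition_gene_space(structure(list(J = 1L),
                                              class = "cca_sol")),
               ">= 2 axes")
})

test_that("planted co-loading genes land in the Foxp3 partition", {
  # deterministic blocks: genes 1:20 are activation genes (high in the
  # activated samples s1:s4); genes 1:10 peak in the Foxp3-like samples
  # s1:s2 and genes 11:20 in the Runx1-like samples s3:s4
  X <- matrix(5, 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8)))
  X[1:20, 1:4] <- X[1:20, 1:4] + 20
  X[1:10, 1:2] <- X[1:10, 1:2] + 15
  X[11:20, 3:4] <- X[11:20, 3:4] + 15
  tact <- c(rep(2, 20), rep(0, 20))
  foxp3 <- c(rep(2, 10), rep(-2, 10), rep(0, 20))
  fit <- cca(expression_matrix(X), cbind(tact = tact, foxp3 = foxp3))
  # orient axes for the check: Axis 1 low = activation pole, Axis 2
  # positive = Foxp3 pole (sign conventions are data-driven)
  g <- fit$gene_scores_wa
  a1 <- if (mean(g[1:20, 1]) < mean(g[21:40, 1])) 1 else -1
  a2 <- if (mean(g[1:10, 2]) > mean(g[11:20, 2])) 1 else -1
  fit$gene_scores_wa[, 1] <- a1 * g[, 1]
  fit$gene_scores_wa[, 2] <- a2 * g[, 2]
  part <- partition_gene_space(fit, axis1_quantile = 0.5)
  expect_setequal(part$tact$members, sprintf("g%02d", 1:20))
  expect_setequal(part$tact_foxp3$members, sprintf("g%02d", 1:10))
  expect_setequal(part$tact_runx1$members, sprintf("g%02d", 11:20))
})

test_that("alternative sample-score scalings differ only by alpha powers", {
  X <- rand_table(8, 5, 101)
  fit <- cca(expression_matrix(X), matrix(rnorm(16), 8, 2))
  site <- cca_sample_scores(fit, "site")
  species <- cca_sample_scores(fit, "species")
  expect_equal(site, species %*% diag(fit$alpha, fit$J),
               tolerance = 1e-10, ignore_attr = TRUE)
})
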