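# shared fixture builders and independent oracles

rand_table <- function(p, m, seed, lambda = 15) {
  set.seed(seed)
  matrix(rpois(p * m, lambda) + 1, p, m,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%03d", seq_len(m))))
}

# brute-force total inertia: sum over cells of (X/n - r c)^2 / (r c)
brute_inertia <- function(X) {
  n <- sum(X); r <- rowSums(X) / n; cc <- colSums(X) / n
  sum((X / n - outer(r, cc))^2 / outer(r, cc))
}

# brute-force chi-square distance between column profiles j and l
brute_chisq_dist <- function(X, j, l) {
  r <- rowSums(X) / sum(X)
  pj <- X[, j] / sum(X[, j]); pl <- X[, l] / sum(X[, l])
  sqrt(sum((pj - pl)^2 / r))
}

# step-up Benjamini-Hochberg, written directly from the definition:
# adj_(i) = min_{j >= i} (n / j) p_(j), capped at 1
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min((n / seq(i, n)) * ps[seq(i, n)]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# mean silhouette width for a 2-group labelling of rows of `scores`
mean_silhouette <- function(scores, groups) {
  d <- as.matrix(dist(scores))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# small two-block fixture: samples 1:2 loaded on genes 1:3, samples 3:4
# on genes 4:6, light uniform background
block_fixture <- function() {
  X <- matrix(2, 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  X[1:3, 1:2] <- 20
  X[4:6, 3:4] <- 20
  X
}
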