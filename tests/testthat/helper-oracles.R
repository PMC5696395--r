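# Independent brute-force oracles used to validate the implementation.
# These deliberately use a different route than the package code: explicit
# path enumeration on the tree, explicit dense inverses and determinants.

# Shared root-to-MRCA path length for every tip pair, by enumerating the
# edges on each root-to-tip path and summing the lengths of the common ones.
oracle_covariance <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  path_edges <- lapply(tips, function(tip) {
    nodes <- ape::nodepath(tree, from = root,
                           to = match(tip, tree$tip.label))
    paste(nodes[-length(nodes)], nodes[-1])
  })
  C <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      C[i, j] <- sum(tree$edge.length[match(shared, edge_key)])
    }
  }
  C
}

# Blomberg's K straight from the defining formula with explicit inverses.
oracle_k <- function(x, C) {
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  a <- drop(t(one) %*% Cinv %*% x) / drop(t(one) %*% Cinv %*% one)
  r <- x - a
  mse0 <- drop(t(r) %*% r) / (n - 1)
  mse <- drop(t(r) %*% Cinv %*% r) / (n - 1)
  er <- (sum(diag(C)) - n / drop(t(one) %*% Cinv %*% one)) / (n - 1)
  (mse0 / mse) / er
}

oracle_gls_mean <- function(x, C) {
  Cinv <- solve(C)
  one <- rep(1, length(x))
  drop(t(one) %*% Cinv %*% x) / drop(t(one) %*% Cinv %*% one)
}

# Profile log-likelihood of lambda with explicit dense algebra.
oracle_loglik_lambda <- function(lam, x, C) {
  n <- length(x)
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cinv <- solve(Cl)
  one <- rep(1, n)
  a <- drop(t(one) %*% Cinv %*% x) / drop(t(one) %*% Cinv %*% one)
  r <- x - a
  s2 <- drop(t(r) %*% Cinv %*% r) / n
  -0.5 * (n * log(2 * pi * s2) + determinant(Cl)$modulus[1] + n)
}

# Negative log-likelihood of the measurement-error model at a given rate.
oracle_negll_sigma2 <- function(s2, x, C, se) {
  n <- length(x)
  V <- s2 * C + diag(se^2, n)
  Vinv <- solve(V)
  one <- rep(1, n)
  a <- drop(t(one) %*% Vinv %*% x) / drop(t(one) %*% Vinv %*% one)
  r <- x - a
  0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
           drop(t(r) %*% Vinv %*% r))
}

# Random ultrametric tree from an independent generator (ape's coalescent).
random_ultrametric_tree <- function(n) {
  ape::rcoal(n, tip.label = sprintf("s%02d", seq_len(n)))
}

# Small valid measurement table with planted structure for filter tests.
toy_fa_table <- function() {
  tibble::tibble(
    sample_id = paste0("m", 1:10),
    species = rep(c("sp a", "sp b"), each = 5),
    site = "x", habitat = "y",
    `16:0` = c(30, 32, 28, 31, 29, 35, 33, 34, 36, 32),
    `18:1w9` = c(50, 48, 52, 49, 51, 45, 47, 46, 44, 48),
    `18:2w6,9` = c(19.6, 19.6, 19.6, 19.6, 14.6, 19.6, 19.6, 19.6, 19.6, 19.6),
    `20:5w3` = c(0, 0, 0, 0, 5, 0, 0, 0, 0, 0),     # single occurrence
    `17:0` = rep(0.4, 10)                            # < 1% everywhere
  )
}
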