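test_that("K = 1 on equal-depth star trees, for any non-constant trait", {
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  C <- phylo_covariance(star)
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(5, sd = runif(1, 0.1, 10))
    expect_equal(blomberg_k(x, C)$K, 1, tolerance = 1e-12)
  }
  expect_error(blomberg_k(rep(2, 5), C), "constant")
})

test_that("K is invariant to affine trait maps and branch rescaling", {
  set.seed(42)
  tr <- random_ultrametric_tree(9)
  C <- phylo_covariance(tr)
  x <- rnorm(9)
  k0 <- blomberg_k(x, C)$K
  expect_equal(blomberg_k(3.7 * x - 11, C)$K, k0, tolerance = 1e-10)
  expect_equal(blomberg_k(x, 5.1 * C)$K, k0, tolerance = 1e-10)
})

test_that("K, GLS mean and lambda likelihood match dense oracles", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    tr <- random_ultrametric_tree(n)
    C <- phylo_covariance(tr)
    x <- rnorm(n)
    expect_equal(blomberg_k(x, C)$K, oracle_k(x, C), tolerance = 1e-10)
    expect_equal(phylo_mean(x, C), oracle_gls_mean(x, C), tolerance = 1e-12)
    for (lam in c(0, 0.4, 1)) {
      expect_equal(phylofa:::lambda_loglik(lam, x, C),
                   oracle_loglik_lambda(lam, x, C), tolerance = 1e-10)
    }
  }
})

test_that("K agrees with phytools::phylosig as an independent cross-check", {
  skip_if_not_installed("phytools")
  set.seed(44)
  tr <- random_ultrametric_tree(15)
  C <- phylo_covariance(tr)
  x <- setNames(rnorm(15), rownames(C))
  expect_equal(blomberg_k(x, C)$K,
               as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-8)
  lam <- pagel_lambda(x, tr)
  ph <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(lam$logL, ph$logL, tolerance = 1e-6)
  expect_equal(lam$lambda, ph$lambda, tolerance = 1e-4)
})

test_that("measurement-error K reduces to plain K at se = 0 and fits sigma2", {
  set.seed(45)
  tr <- random_ultrametric_tree(5)
  C <- phylo_covariance(tr)
  x <- rnorm(5)
  k_plain <- blomberg_k(x, C)
  k_zero <- blomberg_k(x, C, se = rep(0, 5))
  expect_identical(k_zero$K, k_plain$K)
  expect_false(k_zero$se_used)

  se <- c(0.1, 0.3, 0.2, 0.05, 0.4)
  k_se <- blomberg_k(x, C, se)
  # sigma2_hat matches an independent grid/optimize oracle to 1e-6 relative
  g <- exp(seq(log(k_se$sigma2_hat) - 2, log(k_se$sigma2_hat) + 2,
               length.out = 2001))
  vals <- vapply(g, oracle_negll_sigma2, numeric(1), x = x, C = C, se = se)
  expect_equal(k_se$sigma2_hat, g[which.min(vals)],
               tolerance = 1e-3)  # grid resolution
  o <- optimize(oracle_negll_sigma2, range(g), x = x, C = C, se = se,
                tol = 1e-12)
  expect_equal(k_se$sigma2_hat, o$minimum, tolerance = 1e-6)
  expect_error(blomberg_k(x, C, se = c(-1, 0, 0, 0, 0)), "negative")
})

test_that("accounting for se pulls K of noisy BM traits back toward 1", {
  set.seed(46)
  tr <- random_ultrametric_tree(40)
  C <- phylo_covariance(tr)
  n_rep <- 150
  X <- simulate_bm(tr, sigma2 = 1, n_traits = n_rep, seed = 460)
  se <- rep(sqrt(0.3), 40)
  noisy <- X + matrix(rnorm(length(X), sd = se[1]), nrow(X))
  k_naive <- k_se <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    k_naive[i] <- blomberg_k(noisy[, i], C)$K
    # a few replicates legitimately push the rate MLE to the zero boundary
    k_se[i] <- suppressWarnings(blomberg_k(noisy[, i], C, se)$K)
  }
  expect_lt(abs(mean(k_se) - 1), abs(mean(k_naive) - 1))
  expect_lt(mean(k_naive), 1)  # ignoring error deflates K
})

test_that("permutation test behaves at its boundaries and under signal", {
  # on an equal-depth star every permutation gives K = 1 = K_obs, so the
  # add-one estimator returns 1 even with a single permutation
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  Cs <- phylo_covariance(star)
  pt <- permutation_test_k(c(1, 2, 3, 5), Cs, n_perm = 1, seed = 1)
  expect_equal(pt$p_perm, 1)

  # strong BM signal on a deep balanced tree is detected
  bal <- ape::stree(32, type = "balanced")
  bal$edge.length <- rep(1, nrow(bal$edge))
  C <- phylo_covariance(bal)
  hits <- 0
  for (i in 1:10) {
    x <- simulate_bm(bal, n_traits = 1, seed = 470 + i)[, 1]
    pt <- permutation_test_k(x, C, n_perm = 300, seed = i)
    hits <- hits + (pt$p_perm <= 0.01)
  }
  expect_gte(hits, 8)

  # fixed vs per-perm sigma2 handling give compatible answers
  tr <- random_ultrametric_tree(12)
  Ct <- phylo_covariance(tr)
  x <- simulate_bm(tr, n_traits = 1, seed = 48)[, 1]
  se <- rep(0.2, 12)
  p1 <- permutation_test_k(x, Ct, se, n_perm = 400, seed = 5)$p_perm
  p2 <- permutation_test_k(x, Ct, se, n_perm = 400, seed = 5,
                           sigma2_refit = "per_perm")$p_perm
  expect_lt(abs(p1 - p2), 0.1)
})

test_that("BM simulation test classifies and computes the two-tailed p", {
  set.seed(49)
  tr <- random_ultrametric_tree(12)
  C <- phylo_covariance(tr)
  sim <- bm_simulation_test(1, tr, n_sim = 2000, seed = 490)
  expect_lt(sim$sim_q025, sim$sim_q975)
  expect_equal(sim$bm_class, "consistent")

  # K at the simulated median -> p ~ 1
  k_null <- phylofa:::k_many(simulate_bm(tr, n_traits = 2000, seed = 491),
                             phylofa:::k_context(C))
  med <- exp(median(log(k_null)))
  sim_med <- bm_simulation_test(med, tr, n_sim = 2000, seed = 490)
  expect_gt(sim_med$p_sim, 0.9)
  expect_equal(sim_med$bm_class, "consistent")

  # far-out K values are classified on the correct side
  expect_equal(bm_simulation_test(1e-3, tr, n_sim = 500,
                                  seed = 492)$bm_class, "lower")
  expect_equal(bm_simulation_test(1e3, tr, n_sim = 500,
                                  seed = 492)$bm_class, "higher")
  expect_warning(bm_simulation_test(1, tr, n_sim = 50, seed = 1),
                 "unstable")
  expect_error(bm_simulation_test(-1, tr), "positive")
})

test_that("lambda ML maximizes the profile likelihood within [0, lambda_max]", {
  set.seed(50)
  tr <- random_ultrametric_tree(20)
  C <- phylo_covariance(tr)
  for (i in 1:5) {
    x <- setNames(rnorm(20), rownames(C))
    fit <- pagel_lambda(x, tr)
    expect_gte(fit$logL, fit$logL0)
    expect_gte(fit$logL, phylofa:::lambda_loglik(1, unname(x), C) - 1e-9)
    expect_true(fit$lambda >= 0 && fit$lambda <= lambda_max(tr))
    expect_true(fit$p_lr >= 0 && fit$p_lr <= 1)
  }
})

test_that("lambda likelihood is flat on an equal-depth star and reported so", {
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  x <- setNames(c(0.3, -1, 2, 0.5, 1.1), LETTERS[1:5])
  fit <- pagel_lambda(x, star)
  expect_true(fit$flat)
  expect_true(is.na(fit$lambda))
  expect_equal(fit$logL, fit$logL0)
})

test_that("p-value adjustments match hand-computed step procedures", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # order preserved, NA passed through without shrinking the family
  p <- c(0.03, NA, 0.01)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], stats::p.adjust(c(0.03, 0.01), "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("dual decision requires both adjusted tests, strictly below alpha", {
  d <- dual_decision(c(0.003, 0.07, 0.05), c(0.0005, 0.01, 0.05),
                     alpha = 0.05)
  expect_equal(d$signal_present, c(TRUE, FALSE, FALSE))
  expect_equal(d$k_significant, c(TRUE, FALSE, FALSE))
  expect_equal(d$lambda_significant, c(TRUE, TRUE, FALSE))
})

test_that("tidy and glance methods expose the fit components", {
  set.seed(51)
  tr <- random_ultrametric_tree(8)
  C <- phylo_covariance(tr)
  x <- setNames(rnorm(8), rownames(C))
  k <- blomberg_k(x, C)
  expect_equal(tidy(k)$K, k$K)
  expect_named(glance(k), c("K", "n", "se_used"))
  lam <- pagel_lambda(x, tr)
  expect_equal(tidy(lam)$logL, lam$logL)
  expect_equal(glance(lam)$lambda, lam$lambda)
})
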