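# Blomberg's K: the ratio of the observed (MSE0/MSE) contrast of trait
# variance about the phylogenetic mean to its Brownian-motion expectation on
# the tree. K = 1 matches the BM expectation; K > 1 means relatives resemble
# each other more than BM predicts. The measurement-error variant estimates
# the BM rate by ML under covariance sigma2 * C + diag(se^2) and folds the
# standardized error variances into the covariance structure.

# Align a named trait vector (and optional se) with the rows of C.
align_to_C <- function(x, C, se = NULL) {
  taxa <- rownames(C)
  if (!is.null(names(x))) {
    nm <- harmonize_species(names(x))
    if (!setequal(nm, taxa)) {
      stop_phylofa(sprintf(
        "trait names do not match covariance taxa (missing: %s)",
        paste(setdiff(taxa, nm), collapse = ", ")))
    }
    ord <- match(taxa, nm)
    x <- x[ord]
    if (!is.null(se)) se <- se[ord]
  } else if (length(x) != nrow(C)) {
    stop_phylofa("unnamed trait vector of wrong length")
  }
  list(x = unname(x), se = if (is.null(se)) NULL else unname(se))
}

# Precomputed quantities reused across many K evaluations on the same C.
k_context <- function(C) {
  R <- chol(C)
  Cinv <- chol2inv(R)
  w <- rowSums(Cinv)            # Cinv %*% 1
  s <- sum(w)                   # 1' Cinv 1
  n <- nrow(C)
  list(Cinv = Cinv, w = w, s = s, n = n,
       expected_ratio = (sum(diag(C)) - n / s) / (n - 1))
}

# K for every column of X given a context; the workhorse for permutation and
# simulation nulls (fully vectorized across columns).
k_many <- function(X, ctx) {
  a <- drop(crossprod(ctx$w, X)) / ctx$s
  R <- X - rep(1, ctx$n) %o% a
  mse0 <- colSums(R * R) / (ctx$n - 1)
  mse <- colSums(R * (ctx$Cinv %*% R)) / (ctx$n - 1)
  (mse0 / mse) / ctx$expected_ratio
}

#' Phylogenetic (GLS) mean of a trait
#'
#' The generalized-least-squares estimate of the root state under covariance
#' `C`: `a_hat = (1' C^-1 1)^-1 1' C^-1 x`.
#'
#' @param x Trait vector (named by species or aligned with `C`).
#' @param C Phylogenetic covariance matrix from [phylo_covariance()].
#' @return A single number.
#' @export
phylo_mean <- function(x, C) {
  al <- align_to_C(x, C)
  ctx <- k_context(C)
  sum(ctx$w * al$x) / ctx$s
}

#' Blomberg's K, with or without measurement error
#'
#' Plain K is `(MSE0/MSE) / expected_ratio` with `MSE0` the trait variance
#' about the phylogenetic mean under an identity structure, `MSE` the
#' GLS variance under `C`, and `expected_ratio = (tr(C) - n/(1'C^-1 1)) /
#' (n - 1)` its Brownian-motion expectation. When per-species standard
#' errors are supplied, the BM rate `sigma2` is first estimated by maximum
#' likelihood under covariance `sigma2 * C + diag(se^2)` and K is computed
#' with the error-inflated structure `C + diag(se^2) / sigma2_hat`. A zero
#' `se` vector reduces exactly to the plain statistic.
#'
#' @param x Trait vector, named by species or aligned with `C`.
#' @param C Phylogenetic covariance matrix (canonical sorted taxon order).
#' @param se Optional vector of per-species standard errors (same order).
#' @return An object of class `blomberg_k`: list with `K`, `mse0`, `mse`,
#'   `expected_ratio`, `a_hat`, `sigma2_hat` (NA without `se`), `n`,
#'   `se_used`.
#' @export
blomberg_k <- function(x, C, se = NULL) {
  al <- align_to_C(x, C, se)
  x <- al$x; se <- al$se
  n <- nrow(C)
  if (n < 3) stop_phylofa("Blomberg's K needs at least 3 species")
  if (sd(x) == 0) stop_phylofa("constant trait: K is undefined (0/0)")
  if (!is.null(se) && any(se < 0)) stop_phylofa("negative standard error")
  se_used <- !is.null(se) && any(se > 0)
  sigma2_hat <- NA_real_
  Cw <- C
  if (se_used) {
    sigma2_hat <- ml_sigma2(x, C, se)
    Cw <- C + diag(se^2 / sigma2_hat, n)
  }
  ctx <- k_context(Cw)
  a <- sum(ctx$w * x) / ctx$s
  r <- x - a
  mse0 <- sum(r * r) / (n - 1)
  mse <- drop(crossprod(r, ctx$Cinv %*% r)) / (n - 1)
  structure(
    list(K = (mse0 / mse) / ctx$expected_ratio, mse0 = mse0, mse = mse,
         expected_ratio = ctx$expected_ratio, a_hat = a,
         sigma2_hat = sigma2_hat, n = n, se_used = se_used),
    class = "blomberg_k")
}

# Profile ML of the BM rate under V(s2) = s2 * C + diag(se^2), with the GLS
# mean profiled out. One-dimensional search on log(s2) around the plain GLS
# rate estimate; errors if the optimum sticks to the search boundary.
ml_sigma2 <- function(x, C, se) {
  n <- length(x)
  negll <- function(log_s2) {
    V <- exp(log_s2) * C + diag(se^2, n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Vinv_x <- backsolve(R, forwardsolve(t(R), x))
    Vinv_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
    a <- sum(Vinv_x) / sum(Vinv_1)
    r <- x - a
    Vinv_r <- backsolve(R, forwardsolve(t(R), r))
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(r * Vinv_r))
  }
  ctx0 <- k_context(C)
  a0 <- sum(ctx0$w * x) / ctx0$s
  r0 <- x - a0
  s2_0 <- max(drop(crossprod(r0, ctx0$Cinv %*% r0)) / n, 1e-12)
  lo <- log(s2_0) - 18
  hi <- log(s2_0) + 18
  grid <- seq(lo, hi, length.out = 25)
  vals <- vapply(grid, negll, numeric(1))
  j <- which.min(vals)
  opt <- optimize(negll,
                  interval = c(grid[max(1, j - 1)], grid[min(25, j + 1)]),
                  tol = 1e-10)
  if (j == 1 && (opt$minimum < lo + 1e-4 || vals[1] <= opt$objective)) {
    # likelihood monotone decreasing in sigma2: the MLE sits on the zero
    # boundary — all trait variance is attributed to measurement error
    warn(paste("BM rate ML estimate at the zero boundary;",
               "trait variance is fully attributed to measurement error"))
    return(exp(lo))
  }
  if (opt$minimum > hi - 1e-6) {
    stop_phylofa(sprintf(
      "sigma2 ML search did not converge (log sigma2 at upper bound %.2f; grid range [%.2f, %.2f])",
      opt$minimum, lo, hi))
  }
  exp(opt$minimum)
}

#' Permutation test of phylogenetic signal (H0: K = 0 structure)
#'
#' Shuffles the assignment of (trait, se) pairs to tips uniformly at random
#' `n_perm` times and recomputes K each time. The p-value uses the add-one
#' estimator `(1 + #(K_perm >= K_obs)) / (n_perm + 1)`, one-tailed (large K
#' indicates signal).
#'
#' With measurement error, each permutation carries its (trait, se) pair to
#' the permuted tip and K is recomputed with the permuted error diagonal;
#' by default the error-standardizing rate `sigma2_hat` is held at the
#' observed ML estimate across permutations (the standardization metric is
#' fixed under the null), `sigma2_refit = "per_perm"` re-estimates it for
#' every permutation instead.
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of randomizations (default 10000).
#' @param seed Optional integer seed.
#' @param sigma2_refit `"fixed"` (default) or `"per_perm"`: how the BM rate
#'   in the error-standardized structure is handled across permutations
#'   (ignored without `se`).
#' @return A list with `p_perm`, `K_obs`, `n_perm`.
#' @export
permutation_test_k <- function(x, C, se = NULL, n_perm = 10000, seed = NULL,
                               sigma2_refit = c("fixed", "per_perm")) {
  if (n_perm < 1) stop_phylofa("n_perm must be >= 1")
  sigma2_refit <- match.arg(sigma2_refit)
  obs <- blomberg_k(x, C, se)
  al <- align_to_C(x, C, se)
  n <- nrow(C)
  k_perm <- with_seed(seed, {
    if (!obs$se_used) {
      ctx <- k_context(C)
      idx <- replicate(n_perm, sample.int(n))
      X <- matrix(al$x[idx], n, n_perm)
      k_many(X, ctx)
    } else if (sigma2_refit == "fixed") {
      d <- al$se^2 / obs$sigma2_hat
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        k_many(matrix(al$x[p], n, 1), k_context(C + diag(d[p], n)))
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        blomberg_k(al$x[p], C, al$se[p])$K
      }, numeric(1))
    }
  })
  list(p_perm = (1 + sum(k_perm >= obs$K)) / (n_perm + 1),
       K_obs = obs$K, n_perm = n_perm)
}

#' Brownian-motion simulation test of K (H0: K = 1)
#'
#' Simulates `n_sim` BM traits on the tree, computes plain K for each, and
#' compares the observed K with the 2.5% and 97.5% quantiles of the
#' log-transformed simulated K values. `bm_class` is `"lower"` or
#' `"higher"` when `log(K_obs)` falls outside those quantiles, otherwise
#' `"consistent"`. The two-tailed p doubles the smaller tail:
#' `p_sim = min(1, 2 * min(F, 1 - F))` with `F` the fraction of simulated
#' log-K values at or below `log(K_obs)`. Simulated traits carry no
#' measurement error, so the simulated K values use the plain statistic; set
#' `se` (and optionally `sigma2_hat`) to add replicate noise to the
#' simulated traits instead.
#'
#' @param K_obs Observed K (positive).
#' @param tree Ultrametric `phylo` object used for the null simulations.
#' @param n_sim Number of BM simulations (default 5000; fewer than 100 gives
#'   unstable quantiles and a warning).
#' @param seed Optional integer seed.
#' @param se Optional per-species standard errors; when supplied, normal
#'   noise with these sds is added to each simulated trait and K is
#'   recomputed with the same `se` (off by default).
#' @param sigma2 BM rate for the simulations (immaterial for plain K).
#' @return A list with `p_sim`, `sim_q025`, `sim_q975`, `bm_class`,
#'   `n_sim`.
#' @export
bm_simulation_test <- function(K_obs, tree, n_sim = 5000, seed = NULL,
                               se = NULL, sigma2 = 1) {
  if (!is.numeric(K_obs) || K_obs <= 0) stop_phylofa("K_obs must be positive")
  if (n_sim < 100) warn("n_sim < 100: simulated K quantiles are unstable")
  C <- phylo_covariance(tree)
  use_se <- !is.null(se) && any(se > 0)
  k_sim <- with_seed(seed, {
    X <- simulate_mvn_traits(C, sigma2, n_sim)
    if (!use_se) {
      k_many(X, k_context(C))
    } else {
      se <- align_to_C(setNames(se, rownames(C)), C)$x
      X <- X + matrix(rnorm(length(X), sd = se), nrow(X), ncol(X))
      vapply(seq_len(n_sim), function(i) blomberg_k(X[, i], C, se)$K,
             numeric(1))
    }
  })
  lk <- log(k_sim)
  q <- quantile(lk, c(0.025, 0.975), names = FALSE)
  f <- mean(lk <= log(K_obs))
  bm_class <- if (log(K_obs) < q[1]) "lower"
              else if (log(K_obs) > q[2]) "higher" else "consistent"
  list(p_sim = min(1, 2 * min(f, 1 - f)),
       sim_q025 = exp(q[1]), sim_q975 = exp(q[2]),
       bm_class = bm_class, n_sim = n_sim)
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (n = %d%s)\n", x$K, x$n,
              if (x$se_used)
                sprintf(", with measurement error; sigma2_hat = %.4g",
                        x$sigma2_hat) else ""))
  invisible(x)
}
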