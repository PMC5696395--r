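# Pagel's lambda by maximum likelihood: scale the off-diagonal phylogenetic
# covariances by lambda, profile out the GLS mean and the rate, and maximize
# the remaining one-dimensional likelihood over [0, lambda_max]. The
# likelihood-ratio test compares the fit at lambda_hat with lambda = 0 (star
# phylogeny, no signal).

# Profile log-likelihood of lambda for trait x under C(lambda).
lambda_loglik <- function(lam, x, C) {
  n <- length(x)
  Cl <- lambda_transform(C, lam)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  solve_R <- function(v) backsolve(R, forwardsolve(t(R), v))
  Cinv_1 <- solve_R(rep(1, n))
  a <- sum(solve_R(x)) / sum(Cinv_1)
  r <- x - a
  s2 <- drop(crossprod(r, solve_R(r))) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Estimates lambda on `[0, lambda_max(tree)]` by a 25-point coarse grid
#' pre-scan followed by bounded scalar optimization (tolerance 1e-8), with
#' the endpoints always evaluated so the reported maximum can sit on the
#' boundary. The likelihood-ratio p-value is the upper chi-squared (1 df)
#' tail at `2 * (logL - logL0)` with `logL0` the fit at `lambda = 0`
#' (boundary mixture effects at `lambda = 0` are ignored, matching common
#' practice). On an equal-depth star tree the likelihood is constant in
#' lambda; the flat condition is reported (`flat = TRUE`, `lambda = NA`)
#' rather than an arbitrary estimate. `at_ceiling` flags estimates that hit
#' `lambda_max` — on small trees many ML estimates sit exactly on this
#' ceiling.
#'
#' @param x Trait vector named by species (or aligned with the sorted tips).
#' @param tree Ultrametric `phylo` object.
#' @return An object of class `pagel_lambda`: list with `lambda`, `sigma2`,
#'   `a_hat`, `logL`, `logL0`, `p_lr`, `lambda_max`, `at_ceiling`, `flat`,
#'   `n`.
#' @export
pagel_lambda <- function(x, tree) {
  C <- phylo_covariance(tree)
  al <- align_to_C(x, C)
  x <- al$x
  n <- nrow(C)
  if (n < 3) stop_phylofa("Pagel's lambda needs at least 3 species")
  if (sd(x) == 0) stop_phylofa("constant trait: lambda is undefined")
  lmax <- lambda_max(tree)
  ll <- function(lam) lambda_loglik(lam, x, C)
  grid <- seq(0, lmax, length.out = 25)
  vals <- vapply(grid, ll, numeric(1))
  if (all(!is.finite(vals))) {
    stop_phylofa(sprintf(
      "lambda likelihood not computable anywhere on [0, %.3f]; grid values: %s",
      lmax, paste(sprintf("%.3g", vals), collapse = ", ")))
  }
  flat <- diff(range(vals[is.finite(vals)])) < 1e-8
  logL0 <- ll(0)
  if (flat) {
    lam_hat <- NA_real_
    logL <- max(vals[is.finite(vals)])
  } else {
    j <- which.max(vals)
    opt <- optimize(ll, interval = c(grid[max(1, j - 1)],
                                     grid[min(length(grid), j + 1)]),
                    maximum = TRUE, tol = 1e-8)
    cand <- rbind(c(opt$maximum, opt$objective),
                  c(0, logL0), c(lmax, ll(lmax)), c(grid[j], vals[j]))
    best <- cand[which.max(cand[, 2]), ]
    lam_hat <- best[1]
    logL <- best[2]
  }
  # profile estimates at the optimum
  lam_eval <- if (flat) 1 else lam_hat
  Cl <- lambda_transform(C, lam_eval)
  ctx <- k_context(Cl)
  a <- sum(ctx$w * x) / ctx$s
  r <- x - a
  s2 <- drop(crossprod(r, ctx$Cinv %*% r)) / n
  lr <- max(0, 2 * (logL - logL0))
  structure(
    list(lambda = lam_hat, sigma2 = s2, a_hat = a, logL = logL,
         logL0 = logL0, p_lr = pchisq(lr, df = 1, lower.tail = FALSE),
         lambda_max = lmax,
         at_ceiling = isTRUE(!flat && lam_hat >= lmax - 1e-6),
         flat = flat, n = n),
    class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  if (x$flat) {
    cat("Pagel's lambda: likelihood flat in lambda (star-like tree)\n")
  } else {
    cat(sprintf(
      "Pagel's lambda = %.4f%s (logL = %.3f, logL0 = %.3f, LR p = %.4g)\n",
      x$lambda, if (x$at_ceiling) " [at lambda_max ceiling]" else "",
      x$logL, x$logL0, x$p_lr))
  }
  invisible(x)
}

#' Benjamini-Hochberg and Holm p-value adjustment
#'
#' Thin wrappers around [stats::p.adjust()] that validate the input range
#' and preserve input order; `NA` entries stay `NA` and do not count toward
#' the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) adjust_checked(p, "BH")

#' @rdname bh_adjust
#' @export
holm_adjust <- function(p) adjust_checked(p, "holm")

adjust_checked <- function(p, method) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_phylofa("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = method)
  out
}

#' Dual-criterion phylogenetic signal decision
#'
#' Signal in a trait is accepted only when both the (adjusted) permutation
#' test of Blomberg's K and the (adjusted) likelihood-ratio test of Pagel's
#' lambda are significant, with strict inequality at level `alpha`.
#'
#' @param p_perm_adj Adjusted permutation p-value(s) for K.
#' @param p_lr_adj Adjusted likelihood-ratio p-value(s) for lambda.
#' @param alpha Significance level (default 0.05).
#' @return A tibble: `k_significant`, `lambda_significant`,
#'   `signal_present`.
#' @export
dual_decision <- function(p_perm_adj, p_lr_adj, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  k_sig <- !is.na(p_perm_adj) & p_perm_adj < alpha
  l_sig <- !is.na(p_lr_adj) & p_lr_adj < alpha
  tibble(k_significant = k_sig, lambda_significant = l_sig,
         signal_present = k_sig & l_sig)
}
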