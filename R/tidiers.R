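# broom-style tidiers for the fitted objects.

#' Tidy a Blomberg's K fit
#'
#' @param x A `blomberg_k` object.
#' @param ... Unused.
#' @return One-row tibble: `K`, `mse0`, `mse`, `expected_ratio`, `a_hat`,
#'   `sigma2_hat`, `se_used`, `n`.
#' @method tidy blomberg_k
#' @export
tidy.blomberg_k <- function(x, ...) {
  tibble(K = x$K, mse0 = x$mse0, mse = x$mse,
         expected_ratio = x$expected_ratio, a_hat = x$a_hat,
         sigma2_hat = x$sigma2_hat, se_used = x$se_used, n = x$n)
}

#' @rdname tidy.blomberg_k
#' @method glance blomberg_k
#' @export
glance.blomberg_k <- function(x, ...) {
  tibble(K = x$K, n = x$n, se_used = x$se_used)
}

#' Tidy a Pagel's lambda fit
#'
#' @param x A `pagel_lambda` object.
#' @param ... Unused.
#' @return One-row tibble: `lambda`, `sigma2`, `a_hat`, `logL`, `logL0`,
#'   `p_lr`, `lambda_max`, `at_ceiling`, `flat`, `n`.
#' @method tidy pagel_lambda
#' @export
tidy.pagel_lambda <- function(x, ...) {
  tibble(lambda = x$lambda, sigma2 = x$sigma2, a_hat = x$a_hat,
         logL = x$logL, logL0 = x$logL0, p_lr = x$p_lr,
         lambda_max = x$lambda_max, at_ceiling = x$at_ceiling,
         flat = x$flat, n = x$n)
}

#' @rdname tidy.pagel_lambda
#' @method glance pagel_lambda
#' @export
glance.pagel_lambda <- function(x, ...) {
  tibble(lambda = x$lambda, logL = x$logL, p_lr = x$p_lr, n = x$n)
}

#' Tidy a species-mean PCA
#'
#' @param x An `fa_pca` object.
#' @param ... Unused.
#' @return Eigenvalue table: `axis`, `eigenvalue`, `explained`,
#'   `broken_stick`, `retained`.
#' @method tidy fa_pca
#' @export
tidy.fa_pca <- function(x, ...) {
  p <- length(x$eigenvalues)
  tibble(axis = seq_len(p), eigenvalue = x$eigenvalues,
         explained = x$explained, broken_stick = x$broken_stick,
         retained = seq_len(p) %in% x$retained)
}

#' @rdname tidy.fa_pca
#' @method glance fa_pca
#' @export
glance.fa_pca <- function(x, ...) {
  tibble(n_species = length(x$species), n_traits = length(x$traits),
         n_retained = length(x$retained),
         total_variance = sum(x$eigenvalues))
}

#' Tidy a full analysis: the per-trait signal report
#'
#' @param x An `fa_analysis` object.
#' @param ... Unused.
#' @return The signal report tibble (one row per trait per family).
#' @method tidy fa_analysis
#' @export
tidy.fa_analysis <- function(x, ...) {
  as_tibble(x$signal)
}

#' @rdname tidy.fa_analysis
#' @method glance fa_analysis
#' @export
glance.fa_analysis <- function(x, ...) {
  sig <- x$signal
  tibble(n_species = length(x$pca$species),
         n_traits_tested = sum(!is.na(sig$K)),
         n_signal = sum(sig$signal_present, na.rm = TRUE),
         n_dropped_fas = nrow(x$dropped_fas),
         mode = x$config$mode)
}
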