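# Eigen-decomposition PCA on species-mean logit FA profiles, broken-stick
# axis retention, projection of individual measurements, and FA-axis
# correlations.

#' Broken-stick expected variance fractions
#'
#' `b_k = (1/p) * sum(1/i, i = k..p)`; the fractions are strictly decreasing
#' and sum to 1. A PCA axis is worth keeping when it explains more variance
#' than its broken-stick expectation.
#'
#' @param p Number of pieces (axes).
#' @return Numeric vector `b_1..b_p`.
#' @export
#' @examples
#' broken_stick(3)  # 11/18, 5/18, 2/18
broken_stick <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p < 1) {
    stop_phylofa("p must be a positive integer")
  }
  p <- as.integer(p)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' PCA of species-mean trait profiles by eigen-decomposition
#'
#' Eigendecomposes the covariance matrix (divisor n - 1) of the species-mean
#' matrix; species scores are the centered means multiplied by the
#' eigenvectors. Individual observations can be projected with the same
#' center and eigenvectors via [project_observations()] to examine
#' intraspecific variation. Eigenvector signs are fixed by making the
#' largest-magnitude loading of each axis positive, so reports are
#' reproducible.
#'
#' @param x Species-by-trait input: a numeric matrix with species rownames,
#'   or a tibble with a `species` column and numeric trait columns.
#' @return An object of class `fa_pca`: list with `center`, `eigenvalues`,
#'   `eigenvectors`, `explained`, `broken_stick`, `species_scores`,
#'   `retained` (leading axes beating the broken stick), `species`, `traits`.
#' @export
pca_species_means <- function(x) {
  if (is_tibble(x) || is.data.frame(x)) {
    stopifnot("species" %in% names(x))
    sp <- as.character(x$species)
    x <- as.matrix(x[setdiff(names(x), "species")])
    rownames(x) <- sp
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2 || ncol(x) < 2) stop_phylofa("need >= 2 species and >= 2 traits")
  if (anyNA(x)) stop_phylofa("missing values in trait matrix")
  S <- cov(x)
  if (all(abs(S) < .Machine$double.eps)) stop_phylofa("zero-variance (rank-0) trait matrix")
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # sign convention: largest-|loading| entry positive per axis
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  center <- colMeans(x)
  scores <- sweep(x, 2, center) %*% vecs
  p <- length(vals)
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_len(p))
  rownames(vecs) <- colnames(x)
  explained <- vals / sum(vals)
  bs <- broken_stick(p)
  run <- explained > bs
  retained <- if (!run[1]) integer(0) else seq_len(rle(run)$lengths[1])
  structure(
    list(center = center, eigenvalues = vals, eigenvectors = vecs,
         explained = explained, broken_stick = bs,
         species_scores = scores, retained = retained,
         species = rownames(x), traits = colnames(x)),
    class = "fa_pca")
}

#' Leading PCA axes that beat the broken-stick expectation
#'
#' Returns the leading consecutive run of axes (starting at PC1) whose
#' explained fraction exceeds the broken-stick fraction.
#'
#' @param pca An `fa_pca` object.
#' @return Integer vector of retained axis indices (possibly empty).
#' @export
select_axes <- function(pca) {
  stopifnot(inherits(pca, "fa_pca"))
  pca$retained
}

#' Project observations onto species-mean PCA axes
#'
#' Uses the species-mean center and eigenvectors, so observation scores are
#' directly comparable with species scores.
#'
#' @param pca An `fa_pca` object.
#' @param obs A numeric matrix or tibble of observations over the same trait
#'   columns (extra non-trait columns are carried through).
#' @return A tibble: carried-through metadata plus one column per PC.
#' @export
project_observations <- function(pca, obs) {
  if (is_tibble(obs) || is.data.frame(obs)) {
    meta <- obs[setdiff(names(obs), pca$traits)]
    m <- as.matrix(obs[pca$traits])
  } else {
    meta <- NULL
    m <- obs[, pca$traits, drop = FALSE]
  }
  scores <- sweep(m, 2, pca$center) %*% pca$eigenvectors
  scores <- as_tibble(scores)
  if (is.null(meta) || ncol(meta) == 0) scores else dplyr::bind_cols(meta, scores)
}

#' Pearson correlations between traits and PCA axis scores
#'
#' Two-sided Pearson tests for every (trait, axis) pair, with Holm's
#' step-down adjustment across the whole family of pairs. Zero-variance
#' traits yield `NA` (explicit undefined marker).
#'
#' @param traits Tibble/matrix of trait values (rows aligned with `scores`).
#' @param scores Tibble/matrix of axis scores.
#' @return A tibble: `trait`, `axis`, `r`, `p`, `p_holm`.
#' @export
correlate_with_axes <- function(traits, scores) {
  traits <- as.data.frame(traits)
  scores <- as.data.frame(scores)
  stopifnot(nrow(traits) == nrow(scores), nrow(traits) >= 3)
  grid <- expand.grid(trait = names(traits), axis = names(scores),
                      stringsAsFactors = FALSE)
  res <- purrr::pmap_dfr(grid, function(trait, axis) {
    x <- traits[[trait]]
    y <- scores[[axis]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(trait = trait, axis = axis, r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    tibble(trait = trait, axis = axis,
           r = unname(ct$estimate), p = ct$p.value)
  })
  res$p_holm <- holm_adjust(res$p)
  res
}
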