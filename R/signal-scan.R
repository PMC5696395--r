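# Per-trait phylogenetic signal scan: Blomberg's K with measurement error,
# permutation null, conditional BM-simulation null, Pagel's lambda with the
# likelihood-ratio test, family-wise BH adjustment, and the dual decision.

#' Scan a family of traits for phylogenetic signal
#'
#' For every trait column: Blomberg's K (with per-species standard errors
#' when supplied), the tip-randomization permutation test (H0: no signal),
#' Pagel's lambda with its likelihood-ratio test, and — for traits whose
#' unadjusted permutation p is below `alpha` — the BM-simulation test
#' (H0: K = 1) with the 2.5%/97.5% log-K quantiles. Permutation and
#' likelihood-ratio p-values are then adjusted across the scanned family
#' (Benjamini-Hochberg by default) and combined into the dual decision:
#' signal is accepted only when both adjusted tests are significant.
#'
#' Traits with zero variance across species are reported as all-`NA` rows
#' with a message rather than an error, so one degenerate index does not
#' abort a scan.
#'
#' @param traits Tibble with a `species` column and one numeric column per
#'   trait (species means), or a species-by-trait matrix.
#' @param tree Ultrametric `phylo` object; pruned to the trait species.
#' @param se Optional tibble/matrix of per-species standard errors with the
#'   same shape as `traits`.
#' @param n_perm Permutations for the K test (default 10000).
#' @param n_sim BM simulations for the K = 1 test (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"BH"` (default) or `"holm"`: family-wise adjustment.
#' @param seed Optional integer seed; per-trait sub-seeds are derived as
#'   `seed + 1000 * trait_index + 1` (permutation) and `+ 2` (simulation).
#' @return A tibble of class `fa_signal_scan`, one row per trait:
#'   `trait`, `K`, `p_perm`, `p_perm_adj`, `p_sim`, `sim_q025`, `sim_q975`,
#'   `bm_class`, `lambda`, `logL`, `logL0`, `p_lr`, `p_lr_adj`,
#'   `k_significant`, `lambda_significant`, `signal_present`,
#'   `lambda_at_ceiling`.
#' @export
signal_scan <- function(traits, tree, se = NULL, n_perm = 10000,
                        n_sim = 5000, alpha = 0.05, adjust = c("BH", "holm"),
                        seed = NULL) {
  adjust <- match.arg(adjust)
  tm <- as_species_matrix(traits)
  sm <- if (is.null(se)) NULL else as_species_matrix(se)
  sp <- harmonize_species(rownames(tm))
  rownames(tm) <- sp
  if (!is.null(sm)) {
    stopifnot(identical(dim(sm), dim(tm)))
    rownames(sm) <- harmonize_species(rownames(sm))
    sm <- sm[sp, colnames(tm), drop = FALSE]
  }
  tip_map <- match(sp, harmonize_species(tree$tip.label))
  if (anyNA(tip_map)) {
    stop_phylofa(sprintf("species not in tree: %s",
                         paste(sp[is.na(tip_map)], collapse = ", ")))
  }
  tree <- prune_to_taxa(tree, tree$tip.label[tip_map])
  C <- phylo_covariance(tree)
  ord <- match(harmonize_species(rownames(C)), sp)
  tm <- tm[ord, , drop = FALSE]
  if (!is.null(sm)) sm <- sm[ord, , drop = FALSE]

  na_row <- function(trait) tibble(
    trait = trait, K = NA_real_, p_perm = NA_real_, p_sim = NA_real_,
    sim_q025 = NA_real_, sim_q975 = NA_real_, bm_class = NA_character_,
    lambda = NA_real_, logL = NA_real_, logL0 = NA_real_, p_lr = NA_real_,
    lambda_at_ceiling = NA)

  rows <- purrr::map_dfr(seq_len(ncol(tm)), function(j) {
    trait <- colnames(tm)[j]
    x <- tm[, j]
    if (anyNA(x) || sd(x) == 0) {
      inform(sprintf(
        "trait '%s' is constant or undefined across species; skipped", trait))
      return(na_row(trait))
    }
    se_j <- if (is.null(sm)) NULL else sm[, j]
    k <- blomberg_k(x, C, se_j)
    pt <- permutation_test_k(x, C, se_j, n_perm = n_perm,
                             seed = derive_seed(seed, 1000 * j + 1))
    lam <- pagel_lambda(setNames(x, rownames(C)), tree)
    sim <- if (pt$p_perm < alpha) {
      bm_simulation_test(k$K, tree, n_sim = n_sim,
                         seed = derive_seed(seed, 1000 * j + 2))
    } else {
      list(p_sim = NA_real_, sim_q025 = NA_real_, sim_q975 = NA_real_,
           bm_class = NA_character_)
    }
    tibble(trait = trait, K = k$K, p_perm = pt$p_perm, p_sim = sim$p_sim,
           sim_q025 = sim$sim_q025, sim_q975 = sim$sim_q975,
           bm_class = sim$bm_class,
           lambda = lam$lambda, logL = lam$logL, logL0 = lam$logL0,
           p_lr = if (lam$flat) NA_real_ else lam$p_lr,
           lambda_at_ceiling = lam$at_ceiling)
  })

  adj <- if (adjust == "BH") bh_adjust else holm_adjust
  rows$p_perm_adj <- adj(rows$p_perm)
  rows$p_lr_adj <- adj(rows$p_lr)
  dec <- dual_decision(rows$p_perm_adj, rows$p_lr_adj, alpha = alpha)
  out <- dplyr::bind_cols(rows, dec)
  out <- relocate(out, "p_perm_adj", .after = "p_perm")
  out <- relocate(out, "p_lr_adj", .after = "p_lr")
  out <- relocate(out, "lambda_at_ceiling", .after = "signal_present")
  class(out) <- c("fa_signal_scan", class(out))
  attr(out, "params") <- list(n_perm = n_perm, n_sim = n_sim, alpha = alpha,
                              adjust = adjust, seed = seed,
                              n_species = nrow(tm))
  out
}

# Coerce a tibble with `species` column (or a matrix with rownames) to a
# species-by-trait numeric matrix.
as_species_matrix <- function(x) {
  if (is_tibble(x) || is.data.frame(x)) {
    stopifnot("species" %in% names(x))
    sp <- as.character(x$species)
    m <- as.matrix(x[setdiff(names(x), "species")])
    rownames(m) <- sp
    return(m)
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  x
}
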