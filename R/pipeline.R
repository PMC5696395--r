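# End-to-end orchestration: preprocessing, ordination, indices, and the
# three-family signal scan (PC scores, individual FAs, FA indices), each
# family adjusted for multiple testing separately.

#' Run the full FA phylogenetic-signal analysis
#'
#' Field mode: rare-FA elimination and renormalization, column-wise adjusted
#' logit transform, species means with standard errors, eigen-PCA of the
#' species means with broken-stick retention, FA-axis Pearson correlations
#' (Holm-adjusted), FA indices, and the signal scan (Blomberg's K with
#' measurement error + permutation + conditional BM-simulation test, Pagel's
#' lambda + likelihood-ratio test, BH adjustment within each trait family,
#' dual decision) on (1) species mean PC scores, (2) species mean logit FA
#' proportions, and (3) species mean FA indices.
#'
#' Combined mode: own measurements are first merged with literature tables
#' via [merge_literature()] (biomarker/C20-unsaturated/16:0/18:0 subset,
#' zero imputation, one data point per species and context), then the same
#' pipeline runs on the species means over data points.
#'
#' @param table Measurement tibble (see [read_fa_table()]).
#' @param tree Rooted ultrametric `phylo` object.
#' @param mode `"field"` or `"combined"`.
#' @param lit List of literature tibbles (combined mode).
#' @param min_pct,min_occurrence Rare-FA filter settings.
#' @param eps Logit boundary adjustment.
#' @param n_perm,n_sim,alpha,adjust Signal-scan settings (see
#'   [signal_scan()]).
#' @param n_axes Number of leading PC axes scanned for signal (default 4,
#'   the typical reporting choice); the broken-stick retention decision is
#'   reported alongside in the PCA table whatever this is set to.
#' @param allow_prune If `FALSE` (default), any mismatch between table
#'   species and tree tips is an error listing the reconciliation; if
#'   `TRUE`, the tree is pruned to the shared species and unmatched table
#'   species are dropped with a warning.
#' @param seed Integer seed for the permutation/simulation nulls.
#' @return An object of class `fa_analysis`: list with `signal` (one tibble,
#'   `family` column distinguishing `pc_scores` / `fatty_acids` /
#'   `fa_indices`), `pca`, `correlations`, `species_traits`, `indices`,
#'   `observation_scores`, `dropped_fas`, `excluded_species`, `config`.
#' @export
run_analysis <- function(table, tree, mode = c("field", "combined"),
                         lit = list(), min_pct = 1, min_occurrence = 2,
                         eps = 0.025, n_perm = 10000, n_sim = 5000,
                         alpha = 0.05, adjust = "BH", n_axes = 4,
                         allow_prune = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  validate_phylogeny(tree)
  table <- as_tibble(table)
  table$species <- harmonize_species(table$species)
  excluded <- character(0)

  if (mode == "combined") {
    table <- merge_literature(table, lit, tree_tips = tree$tip.label,
                              min_pct = min_pct,
                              min_occurrence = min_occurrence)
    dropped <- dropped_fas(table)
    excluded <- attr(table, "excluded_species")
    table <- table[!table$species %in% excluded, ]
    if (!"sample_id" %in% names(table)) {
      table$sample_id <- sprintf("dp%03d", seq_len(nrow(table)))
    }
  } else {
    table <- filter_rare(table, min_pct = min_pct,
                         min_occurrence = min_occurrence)
    dropped <- dropped_fas(table)
    table <- renormalize(table)
  }

  # reconcile species with tree tips
  tips <- harmonize_species(tree$tip.label)
  only_table <- setdiff(unique(table$species), tips)
  only_tree <- setdiff(tips, unique(table$species))
  if (!allow_prune && (length(only_table) > 0 || length(only_tree) > 0)) {
    stop_phylofa(paste0(
      "species/tree mismatch (set allow_prune = TRUE to prune):",
      if (length(only_table)) paste0("\n  in table only: ",
                                     paste(only_table, collapse = ", ")),
      if (length(only_tree)) paste0("\n  in tree only: ",
                                    paste(only_tree, collapse = ", "))))
  }
  if (allow_prune) {
    if (length(only_table) > 0) {
      warn(sprintf("dropping table species absent from tree: %s",
                   paste(only_table, collapse = ", ")))
      excluded <- union(excluded, only_table)
      table <- table[!table$species %in% only_table, ]
    }
    if (length(only_tree) > 0) {
      tree <- prune_to_taxa(tree,
                            tree$tip.label[tips %in% unique(table$species)])
    }
  }

  fas <- fa_columns(table)
  logit_tbl <- logit_fa_table(table, eps = eps)
  fa_stats <- species_stats(logit_tbl, fas)
  fa_mat <- species_matrices(fa_stats)

  # ordination on species-mean logit profiles
  pca <- pca_species_means(fa_mat$mean)
  obs_scores <- project_observations(pca, logit_tbl)
  n_axes_scan <- min(max(n_axes, length(pca$retained)),
                     length(pca$eigenvalues))
  axes <- paste0("PC", seq_len(n_axes_scan))
  score_stats <- species_stats(obs_scores, axes)
  score_mat <- species_matrices(score_stats)
  correlations <- correlate_with_axes(
    as.data.frame(fa_mat$mean),
    as.data.frame(pca$species_scores[, axes, drop = FALSE]))

  # indices on renormalized % profiles, per measurement, then species means;
  # fa_number is recomputed from the species mean profile (se = 0)
  idx_tbl <- compute_indices(table)
  idx_cols <- setdiff(names(idx_tbl), .fa_meta_cols)
  idx_stats <- suppressMessages(species_stats(idx_tbl, idx_cols))
  idx_mat <- species_matrices(idx_stats)
  mean_profile <- suppressMessages(species_stats(table, fas)) |>
    select("species", "trait", "mean") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "mean")
  mean_profile <- renormalize(mean_profile, fas = fas)
  fa_number_mean <- rowSums(as.matrix(mean_profile[fas]) > 0)
  idx_mat$mean[match(mean_profile$species, rownames(idx_mat$mean)),
               "fa_number"] <- fa_number_mean
  idx_mat$se[, "fa_number"] <- 0

  scan <- function(m, s, offset) {
    signal_scan(m, tree, se = s, n_perm = n_perm, n_sim = n_sim,
                alpha = alpha, adjust = adjust,
                seed = derive_seed(seed, offset))
  }
  sig_pc <- scan(score_mat$mean[, axes, drop = FALSE],
                 score_mat$se[, axes, drop = FALSE], 0)
  sig_fa <- scan(fa_mat$mean, fa_mat$se, 100000)
  sig_idx <- suppressMessages(scan(idx_mat$mean, idx_mat$se, 200000))
  signal <- bind_rows(
    mutate(as_tibble(sig_pc), family = "pc_scores", .before = 1),
    mutate(as_tibble(sig_fa), family = "fatty_acids", .before = 1),
    mutate(as_tibble(sig_idx), family = "fa_indices", .before = 1))

  structure(
    list(signal = signal, pca = pca, correlations = correlations,
         species_traits = fa_stats, indices = idx_stats,
         observation_scores = obs_scores,
         dropped_fas = dropped, excluded_species = excluded,
         tree = tree,
         config = list(mode = mode, min_pct = min_pct,
                       min_occurrence = min_occurrence, eps = eps,
                       n_perm = n_perm, n_sim = n_sim, alpha = alpha,
                       adjust = adjust, n_axes = n_axes, seed = seed)),
    class = "fa_analysis")
}

#' @export
print.fa_analysis <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("FA phylogenetic-signal analysis (%s mode)\n", cfg$mode))
  cat(sprintf("  %d species, %d retained FAs, %d dropped\n",
              length(x$pca$species), length(x$pca$traits),
              nrow(x$dropped_fas)))
  cat(sprintf("  broken-stick retained axes: %s\n",
              if (length(x$pca$retained)) paste(x$pca$retained, collapse = ", ")
              else "none"))
  sig <- x$signal[!is.na(x$signal$signal_present) & x$signal$signal_present, ]
  cat(sprintf("  traits with signal (both tests, alpha = %g): %d\n",
              cfg$alpha, nrow(sig)))
  if (nrow(sig) > 0) {
    cat(paste0("    ", sig$family, ": ", sig$trait, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write the analysis report bundle as TSV files
#'
#' Emits the machine-readable signal report (one row per trait, full
#' precision), a 3-decimal pretty report, the PCA eigenvalue/loadings/scores
#' tables, the FA-axis correlation table, and a run log with parameters,
#' dropped FAs and excluded species.
#'
#' @param x An `fa_analysis` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "fa_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(as_tibble(tbl), file.path(dir, name))
  }
  w(x$signal, "signal_report.tsv")
  pretty <- x$signal |>
    mutate(across(dplyr::where(is.numeric), ~ round(.x, 3)))
  w(pretty, "signal_report_rounded.tsv")
  w(tidy(x$pca), "pca_eigenvalues.tsv")
  w(as_tibble(x$pca$eigenvectors, rownames = "trait"), "pca_loadings.tsv")
  w(as_tibble(x$pca$species_scores, rownames = "species"),
    "pca_species_scores.tsv")
  w(x$correlations, "fa_pc_correlations.tsv")
  w(x$dropped_fas, "dropped_fas.tsv")
  cfg <- x$config
  log_lines <- c(
    sprintf("mode: %s", cfg$mode),
    sprintf("min_pct: %g", cfg$min_pct),
    sprintf("min_occurrence: %d", cfg$min_occurrence),
    sprintf("eps: %g", cfg$eps),
    sprintf("n_perm: %d", cfg$n_perm),
    sprintf("n_sim: %d", cfg$n_sim),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("adjust: %s", cfg$adjust),
    sprintf("n_axes: %d", cfg$n_axes),
    sprintf("seed: %s", cfg$seed %||% "NULL"),
    sprintf("excluded_species: %s",
            paste(x$excluded_species, collapse = ", ")))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
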