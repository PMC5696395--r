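# Compositional FA tables: one row per measurement, metadata columns plus one
# column per FA holding the proportion in % of total FAs.

.fa_meta_cols <- c("sample_id", "species", "site", "habitat",
                   "n_individuals_pooled", "reference", "treatment")

#' Names of the FA proportion columns of a measurement table
#'
#' Everything that is not a recognized metadata column (`sample_id`,
#' `species`, `site`, `habitat`, `n_individuals_pooled`, `reference`,
#' `treatment`) is treated as a FA proportion column.
#'
#' @param table A measurement tibble.
#' @return Character vector of FA column names.
#' @export
fa_columns <- function(table) {
  setdiff(names(table), .fa_meta_cols)
}

#' Read a FA measurement table from CSV/TSV
#'
#' Requires metadata columns `sample_id`, `species`, `site`, `habitat`; all
#' remaining columns are FA proportions in % of total. Species labels are
#' normalized with [harmonize_species()].
#'
#' @param path CSV or TSV file path (delimiter guessed from the extension).
#' @return A tibble.
#' @export
read_fa_table <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "species", "site", "habitat")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    stop_phylofa(sprintf("missing metadata columns: %s",
                         paste(missing, collapse = ", ")))
  }
  tbl$species <- harmonize_species(tbl$species)
  tbl
}

#' Eliminate rare fatty acids from a measurement table
#'
#' Drops FA columns detected (proportion > 0) in fewer than `min_occurrence`
#' measurements, and FA columns whose mean proportion across all measurements
#' is below `min_pct` percent. Both rules are evaluated against the original
#' table simultaneously. The dropped columns and the rule(s) that removed
#' them are recorded in the `"dropped_fas"` attribute (see
#' [dropped_fas()]).
#'
#' @param table Measurement tibble with FA proportions in %.
#' @param min_pct Minimum mean proportion (%) to keep a FA (default 1).
#' @param min_occurrence Minimum number of measurements with the FA present
#'   (default 2, i.e. FAs seen in a single measurement are dropped).
#' @return The filtered tibble with attribute `dropped_fas`.
#' @export
filter_rare <- function(table, min_pct = 1, min_occurrence = 2) {
  fas <- fa_columns(table)
  if (nrow(table) == 0 || length(fas) == 0) {
    stop_phylofa("empty FA table")
  }
  X <- as.matrix(table[fas])
  occ <- colSums(X > 0)
  mean_pct <- colMeans(X)
  rare_occ <- occ < min_occurrence
  rare_abund <- mean_pct < min_pct
  drop <- rare_occ | rare_abund
  log <- tibble(
    fa = fas[drop],
    reason = ifelse(rare_occ[drop] & rare_abund[drop], "occurrence+abundance",
                    ifelse(rare_occ[drop], "occurrence", "abundance")),
    n_detected = occ[drop],
    mean_pct = mean_pct[drop]
  )
  out <- table[, c(setdiff(names(table), fas), fas[!drop])]
  attr(out, "dropped_fas") <- log
  out
}

#' Log of FAs removed by [filter_rare()]
#'
#' @param table A table returned by [filter_rare()].
#' @return A tibble with columns `fa`, `reason`, `n_detected`, `mean_pct`.
#' @export
dropped_fas <- function(table) {
  attr(table, "dropped_fas") %||%
    tibble(fa = character(), reason = character(),
           n_detected = numeric(), mean_pct = numeric())
}

#' Rescale each measurement so retained FAs sum to 100%
#'
#' Idempotent; errors on any all-zero row (no FA detected).
#'
#' @param table Measurement tibble with FA proportions.
#' @param fas FA columns to rescale (default: all FA columns).
#' @return The renormalized tibble (row sums of FA columns = 100).
#' @export
renormalize <- function(table, fas = fa_columns(table)) {
  X <- as.matrix(table[fas])
  if (any(X < 0)) stop_phylofa("negative FA proportion")
  totals <- rowSums(X)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)
    ids <- if ("sample_id" %in% names(table)) table$sample_id[bad] else bad
    stop_phylofa(sprintf("all-zero FA row(s): %s",
                         paste(ids, collapse = ", ")))
  }
  table[fas] <- as_tibble(X * (100 / totals))
  table
}

#' Adjusted logit transform for compositional proportions
#'
#' Maps a proportion vector `p` in `[0, 1]` to `log(p' / (1 - p'))`. When the
#' vector contains an exact 0 or 1 the whole vector is first remapped to
#' `p' = eps + (1 - 2 * eps) * p` (the usual adjusted-logit convention,
#' applied column-wise); otherwise `p' = p` and the transform inverts exactly
#' through the logistic function.
#'
#' @param p Numeric vector of proportions on the unit scale (not %).
#' @param eps Boundary adjustment (default 0.025).
#' @return Numeric vector of logits.
#' @export
#' @examples
#' logit_transform(c(0.2, 0.8))
#' logit_transform(c(0, 0.5), eps = 0.025)
logit_transform <- function(p, eps = 0.025) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_phylofa("proportions must lie in [0, 1]")
  }
  if (any(p == 0 | p == 1)) p <- eps + (1 - 2 * eps) * p
  log(p / (1 - p))
}

#' Logit-transform the FA columns of a renormalized measurement table
#'
#' Divides the % proportions by 100 and applies [logit_transform()] column by
#' column (the boundary adjustment is decided per FA column).
#'
#' @inheritParams filter_rare
#' @param eps Boundary adjustment passed to [logit_transform()].
#' @return A tibble with the same shape, FA columns in logit units.
#' @export
logit_fa_table <- function(table, eps = 0.025) {
  fas <- fa_columns(table)
  table[fas] <- lapply(table[fas], function(col) {
    logit_transform(col / 100, eps = eps)
  })
  table
}

#' Per-species trait means and standard errors
#'
#' Averages each value column over all measurements of a species,
#' irrespective of site and habitat, and reports the standard error of the
#' mean. Species represented by a single measurement get `se = 0` (no
#' within-species variance estimate exists; measurement-error-aware
#' statistics then degrade gracefully to their plain forms for those tips).
#'
#' @param table Measurement tibble with a `species` column.
#' @param value_cols Columns to summarise (default: all FA columns).
#' @return A long tibble: `species`, `trait`, `mean`, `se`, `n_obs`.
#' @export
species_stats <- function(table, value_cols = fa_columns(table)) {
  long <- tidyr::pivot_longer(table[c("species", value_cols)],
                              cols = all_of(value_cols),
                              names_to = "trait", values_to = "value")
  out <- long |>
    group_by(.data$species, .data$trait) |>
    summarise(
      mean = mean(.data$value),
      se = ifelse(dplyr::n() > 1, sd(.data$value) / sqrt(dplyr::n()), 0),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  singletons <- unique(out$species[out$n_obs == 1])
  if (length(singletons) > 0) {
    inform(sprintf("single-measurement species (se set to 0): %s",
                   paste(singletons, collapse = ", ")))
  }
  out
}

#' Wide species-by-trait matrices of means and standard errors
#'
#' Convenience pivot of [species_stats()] output into aligned numeric
#' matrices (rows = species in sorted order).
#'
#' @param stats A tibble from [species_stats()].
#' @return A list with matrices `mean` and `se` and vector `n_obs`.
#' @export
species_matrices <- function(stats) {
  traits <- unique(stats$trait)
  wide_m <- tidyr::pivot_wider(stats[c("species", "trait", "mean")],
                               names_from = "trait", values_from = "mean")
  wide_s <- tidyr::pivot_wider(stats[c("species", "trait", "se")],
                               names_from = "trait", values_from = "se")
  ord <- order(wide_m$species)
  m <- as.matrix(wide_m[ord, traits])
  s <- as.matrix(wide_s[ord, traits])
  rownames(m) <- rownames(s) <- wide_m$species[ord]
  n_obs <- stats |> distinct(.data$species, .data$n_obs)
  list(mean = m, se = s,
       n_obs = setNames(n_obs$n_obs, n_obs$species)[rownames(m)])
}
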