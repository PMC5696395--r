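# Combined-dataset construction: merging own field measurements with FA
# profiles compiled from the literature. Different studies measure different
# FA sets, so the combined table is restricted to the FAs reported reasonably
# consistently (biomarkers, C20 unsaturated FAs, and the major saturated FAs
# 16:0 and 18:0), and FAs a source did not report are imputed as zero on the
# assumption that they occurred in trace amounts only.

#' Default FA subset for the combined dataset
#'
#' Keeps absolute and relative biomarker FAs, C20 unsaturated FAs, and the
#' saturated FAs 16:0 and 18:0.
#'
#' @param fa_names Character vector of FA column names.
#' @return Logical vector: keep this FA?
#' @export
combined_fa_subset <- function(fa_names) {
  d <- parse_fa_name(fa_names)
  d$biomarker_class != "none" |
    (d$carbons == 20 & d$double_bonds >= 1) |
    d$canonical %in% c("16:0", "18:0")
}

#' Merge own and literature FA tables into species-by-context data points
#'
#' Own measurements are averaged per species per site and habitat; each
#' literature row is taken as one species-by-context data point (literature
#' tables carry species-level means per treatment or site). Columns are
#' restricted to `fa_subset`, FAs missing from any source are imputed as 0,
#' then the rare-FA filter and renormalization are applied to the combined
#' table. Species whose harmonized name is absent from `tree_tips` are kept
#' through preprocessing but flagged for exclusion from signal testing.
#'
#' @param own Own measurement tibble (metadata + FA % columns).
#' @param lit A list of literature tibbles (each: `species`, optional
#'   `site`/`habitat`/`reference`/`treatment`, FA % columns).
#' @param fa_subset Predicate on FA names (default [combined_fa_subset()]);
#'   `NULL` keeps every FA.
#' @param tree_tips Optional character vector of tree tip labels used to
#'   flag unmatched species.
#' @param min_pct,min_occurrence Rare-FA filter settings (see
#'   [filter_rare()]).
#' @return A renormalized tibble of species-by-context data points with
#'   attributes `dropped_fas` and `excluded_species`.
#' @export
merge_literature <- function(own, lit = list(), fa_subset = combined_fa_subset,
                             tree_tips = NULL, min_pct = 1,
                             min_occurrence = 2) {
  own_points <- own |>
    mutate(species = harmonize_species(.data$species)) |>
    group_by(.data$species, .data$site, .data$habitat) |>
    summarise(across(all_of(fa_columns(own)), mean), .groups = "drop") |>
    mutate(reference = "own", .before = 1)

  lit_points <- lapply(lit, function(tbl) {
    tbl <- as_tibble(tbl)
    tbl$species <- harmonize_species(tbl$species)
    if (!"site" %in% names(tbl)) tbl$site <- NA_character_
    if (!"habitat" %in% names(tbl)) tbl$habitat <- NA_character_
    if (!"reference" %in% names(tbl)) tbl$reference <- "literature"
    tbl
  })

  all_points <- bind_rows(c(list(own_points), lit_points))
  all_points[fa_columns(all_points)] <-
    lapply(all_points[fa_columns(all_points)],
           function(col) ifelse(is.na(col), 0, col))

  # canonicalize FA names; sources that spelled the same FA differently
  # (unicode omega vs ASCII w) end up in one column
  fas <- fa_columns(all_points)
  can <- canonical_fa_name(fas)
  meta <- setdiff(names(all_points), fas)
  X <- t(rowsum(t(as.matrix(all_points[fas])), group = can))
  all_points <- dplyr::bind_cols(all_points[meta], as_tibble(X))

  if (!is.null(fa_subset)) {
    keep <- fa_subset(fa_columns(all_points))
    drop <- fa_columns(all_points)[!keep]
    all_points <- all_points[, setdiff(names(all_points), drop)]
  }

  out <- filter_rare(all_points, min_pct = min_pct,
                     min_occurrence = min_occurrence)
  log <- dropped_fas(out)
  out <- renormalize(out)

  excluded <- character(0)
  if (!is.null(tree_tips)) {
    tips <- harmonize_species(tree_tips)
    excluded <- sort(unique(out$species[!out$species %in% tips]))
    if (length(excluded) > 0) {
      warn(sprintf(
        "species not matched to tree tips (retained for preprocessing, excluded from signal): %s",
        paste(excluded, collapse = ", ")))
    }
  }
  attr(out, "dropped_fas") <- log
  attr(out, "excluded_species") <- excluded
  out
}
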