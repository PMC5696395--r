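# Trophic and physiological FA indices computed from renormalized profiles.

#' Fatty-acid indices of compositional profiles
#'
#' Computes, for each measurement row of a renormalized table (FA columns
#' summing to 100%), the standard soil food-web FA indices:
#' \describe{
#'   \item{fa_number}{count of FAs with proportion > 0}
#'   \item{bacterial_sum}{summed % of the absolute bacterial biomarkers}
#'   \item{pf_ratio}{plant-to-fungal marker ratio, 18:1w9 / 18:2w6,9}
#'   \item{bf_ratio}{bacterial_sum / 18:2w6,9}
#'   \item{bp_ratio}{bacterial_sum / 18:1w9}
#'   \item{ui}{Unsaturation Index: abundance-weighted mean number of double
#'     bonds, `sum(f_i * d_i)` with `f_i` the unit-scale fraction}
#'   \item{sfa_sum, mufa_sum, pufa_sum}{class sums (partition the 100%)}
#'   \item{c20pufa_sum}{summed % of C20 FAs with >= 2 double bonds}
#'   \item{us_ratio}{(mufa_sum + pufa_sum) / sfa_sum}
#' }
#' Cyclopropane and methyl-branched FAs count as saturated (no double bond).
#' Ratios with a zero denominator are returned as `NA` (an explicit
#' undefined-value marker, never silently 0).
#'
#' @param table Renormalized measurement tibble (or a single profile row).
#' @param descriptors Optional descriptor tibble from [parse_fa_name()]
#'   matching the FA columns; parsed from the column names by default.
#' @return A tibble: the metadata columns of `table` plus one column per
#'   index.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = "s1", species = "sp", site = "a",
#'                       habitat = "f", `18:1w9` = 50, `18:2w6,9` = 25,
#'                       `16:0` = 25)
#' compute_indices(tbl)
compute_indices <- function(table, descriptors = NULL) {
  fas <- fa_columns(table)
  if (is.null(descriptors)) descriptors <- parse_fa_name(fas)
  stopifnot(nrow(descriptors) == length(fas))
  X <- as.matrix(table[fas])
  sums <- rowSums(X)
  if (any(abs(sums - 100) > 1e-6)) {
    stop_phylofa("profiles must be renormalized to sum to 100% first")
  }
  d <- descriptors
  bact <- d$biomarker_class == "bacterial"
  plant <- d$biomarker_class == "plant_relative"
  fung <- d$biomarker_class == "fungal_relative"
  sfa <- d$saturation_class == "SFA"
  mufa <- d$saturation_class == "MUFA"
  pufa <- d$saturation_class == "PUFA"
  c20p <- d$carbons == 20 & d$double_bonds >= 2

  row_sum <- function(mask) {
    if (!any(mask)) rep(0, nrow(X)) else rowSums(X[, mask, drop = FALSE])
  }
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

  bacterial_sum <- row_sum(bact)
  plant_p <- row_sum(plant)
  fungal_p <- row_sum(fung)
  sfa_sum <- row_sum(sfa)
  mufa_sum <- row_sum(mufa)
  pufa_sum <- row_sum(pufa)

  meta <- table[setdiff(names(table), fas)]
  dplyr::bind_cols(meta, tibble(
    fa_number = rowSums(X > 0),
    bacterial_sum = bacterial_sum,
    pf_ratio = safe_ratio(plant_p, fungal_p),
    bf_ratio = safe_ratio(bacterial_sum, fungal_p),
    bp_ratio = safe_ratio(bacterial_sum, plant_p),
    ui = as.vector(X %*% d$double_bonds) / 100,
    sfa_sum = sfa_sum,
    mufa_sum = mufa_sum,
    pufa_sum = pufa_sum,
    c20pufa_sum = row_sum(c20p),
    us_ratio = safe_ratio(mufa_sum + pufa_sum, sfa_sum)
  ))
}
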