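# Fatty-acid nomenclature: parsing shorthand names like "18:2w6,9", "cy17:0",
# "a15:0" or "2-OH 10:0" into structured descriptors, and the trophic
# biomarker classification used throughout soil food-web FA work.

# Absolute bacterial biomarkers are synthesized only by prokaryotes; 18:1w9
# and 18:2w6,9 are relative plant and fungal markers (high proportions under
# plant- or fungus-based diets).
.bacterial_fas <- c("a15:0", "i15:0", "16:1w5", "16:1w7", "i16:0", "i17:0",
                    "cy17:0", "18:1w7", "cy19:0")
.plant_fa <- "18:1w9"
.fungal_fa <- "18:2w6,9"

#' Parse fatty-acid shorthand names
#'
#' Understands the `[prefix]C:D[wK(,M...)]` grammar: carbon count, number of
#' double bonds, optional omega double-bond positions (unicode `ω` and
#' ASCII `w` both accepted), and the prefixes `i` (iso), `a` (anteiso), `cy`
#' (cyclopropane), and `2-OH` (hydroxy). Emits the canonical ASCII form used
#' for all joins (e.g. `"18:2w6,9"`). Cyclopropane and methyl-branched FAs
#' carry no double bond and therefore count as saturated.
#'
#' @param name Character vector of FA names.
#' @return A tibble with one row per name: `raw_name`, `canonical`,
#'   `carbons`, `double_bonds`, `prefix`, `omega_positions` (list column),
#'   `saturation_class` (`SFA`/`MUFA`/`PUFA`), and `biomarker_class`
#'   (`bacterial`, `plant_relative`, `fungal_relative`, `none`).
#' @export
#' @examples
#' parse_fa_name(c("16:0", "18:2ω6,9", "cy17:0", "2-OH 10:0"))
parse_fa_name <- function(name) {
  raw <- as.character(name)
  x <- gsub("ω", "w", raw)
  x <- gsub("[‐‑‒–—]", "-", x)  # unicode hyphens
  x <- gsub("[[:space:]]+", "", x)
  pat <- "^(i|a|cy|2-OH)?([0-9]+):([0-9]+)(?:w([0-9]+(?:,[0-9]+)*))?$"
  m <- regmatches(x, regexec(pat, x))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    stop_phylofa(sprintf("unparseable FA name(s): %s",
                         paste(unique(raw[bad]), collapse = ", ")))
  }
  parts <- do.call(rbind, lapply(m, function(g) g[2:5]))
  prefix_raw <- parts[, 1]
  carbons <- as.integer(parts[, 2])
  db <- as.integer(parts[, 3])
  omega_txt <- parts[, 4]
  canonical <- paste0(prefix_raw, carbons, ":", db,
                      ifelse(nzchar(omega_txt), paste0("w", omega_txt), ""))
  prefix <- c(i = "iso", a = "anteiso", cy = "cyclo", `2-OH` = "2-OH")[prefix_raw]
  prefix[is.na(prefix)] <- "none"
  omega <- lapply(strsplit(omega_txt, ","), function(v) {
    v <- v[nzchar(v)]
    if (length(v) == 0) integer(0) else as.integer(v)
  })
  sat <- ifelse(db == 0, "SFA", ifelse(db == 1, "MUFA", "PUFA"))
  bio <- rep("none", length(canonical))
  bio[canonical %in% .bacterial_fas] <- "bacterial"
  bio[canonical == .plant_fa] <- "plant_relative"
  bio[canonical == .fungal_fa] <- "fungal_relative"
  tibble(
    raw_name = raw, canonical = canonical, carbons = carbons,
    double_bonds = db, prefix = unname(prefix), omega_positions = omega,
    saturation_class = sat, biomarker_class = bio
  )
}

#' Canonical ASCII form of fatty-acid names
#'
#' @param name Character vector of FA names.
#' @return Character vector of canonical names (e.g. `"18:2w6,9"`).
#' @export
canonical_fa_name <- function(name) {
  parse_fa_name(name)$canonical
}

#' Fatty-acid classification table
#'
#' Loads the packaged FA classification table (canonical name, carbons,
#' double bonds, prefix, biomarker class) or a user-supplied CSV with the
#' same columns, for users who want to override the default classification.
#'
#' @param path Optional path to a replacement CSV.
#' @return A tibble with columns `canonical_name`, `carbons`,
#'   `double_bonds`, `prefix`, `biomarker_class`.
#' @export
fa_classification <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fa_classification.csv",
                        package = "phylofa", mustWork = TRUE)
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
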