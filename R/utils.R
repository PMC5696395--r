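# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one user seed drives many independent
# operation calls via documented additive offsets, kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483587L)
}

#' Normalize species labels for joining trait tables to tree tips
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace, and
#' replaces underscores with spaces, so that `"Allacma_fusca"` and
#' `" Allacma fusca "` refer to the same species. All joins between trait
#' tables and tree tip labels go through this normalization.
#'
#' @param x Character vector of species labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' harmonize_species(c("Allacma_fusca", " Sminthurus  viridis "))
harmonize_species <- function(x) {
  x <- gsub("_", " ", as.character(x), fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

stop_phylofa <- function(msg, class = "phylofa_error") {
  abort(msg, class = class)
}
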