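# Seeded synthetic data with known ground truth: Yule trees, traits evolved
# under a given lambda, and replicate-level compositional FA tables in which
# some FAs are phylogenetically conserved (Brownian motion on the latent
# log-abundance scale) and others labile (white noise across species).

#' Simulate a Yule (pure-birth) ultrametric tree
#'
#' Starts from a root bifurcation, waits an exponential time with rate
#' `k * birth_rate` while `k` lineages are alive, splits a uniformly chosen
#' lineage, and appends a final `Exp(n * birth_rate)` segment after the last
#' split, so the expected height is `sum(1/(k * birth_rate), k = 2..n)`.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate (events per unit time).
#' @param seed Optional integer seed; the same seed gives an identical tree.
#' @return An ultrametric `phylo` object with tips `t1..tn`.
#' @export
yule_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop_phylofa("need at least 2 species")
  with_seed(seed, {
    # node bookkeeping: internal nodes indexed in creation order, root = 1
    parent_of <- c(0L)          # parent internal index per internal node
    height_of <- c(0)           # root-to-node time
    active_parent <- c(1L, 1L)  # spawning internal node per active lineage
    t <- 0
    k <- 2L
    while (k < n_species) {
      t <- t + rexp(1, rate = k * birth_rate)
      j <- sample.int(k, 1)
      parent_of <- c(parent_of, active_parent[j])
      height_of <- c(height_of, t)
      m <- length(parent_of)
      active_parent <- c(active_parent[-j], m, m)
      k <- k + 1L
    }
    t_end <- t + rexp(1, rate = n_species * birth_rate)
    # assemble Newick bottom-up: children of each internal node
    kids <- vector("list", length(parent_of))
    for (m in seq_along(parent_of)[-1]) {
      kids[[parent_of[m]]] <- c(kids[[parent_of[m]]], m)
    }
    tip_parent <- active_parent
    tip_label <- paste0("t", seq_len(n_species))
    for (i in seq_len(n_species)) {
      kids[[tip_parent[i]]] <- c(kids[[tip_parent[i]]], -i)
    }
    build <- function(m) {
      parts <- vapply(kids[[m]], function(ch) {
        if (ch < 0) {
          sprintf("%s:%.10f", tip_label[-ch], t_end - height_of[m])
        } else {
          sprintf("%s:%.10f", build(ch), height_of[ch] - height_of[m])
        }
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    parse_newick(paste0(build(1), ";"))
  })
}

#' Simulate traits under a lambda-transformed Brownian model
#'
#' Draws from a multivariate normal with covariance
#' `sigma2 * lambda_transform(C, lambda)`: `lambda = 1` reproduces plain
#' Brownian motion, `lambda = 0` independent normals with the tip-depth
#' variances.
#'
#' @param tree A `phylo` object.
#' @param lambda True lambda in `[0, 1]`.
#' @param sigma2 Rate parameter.
#' @param n_traits Number of independent traits.
#' @param seed Optional integer seed.
#' @return A tips-by-traits matrix (canonical sorted taxon order).
#' @export
simulate_lambda_traits <- function(tree, lambda, sigma2 = 1, n_traits = 1,
                                   seed = NULL) {
  if (lambda < 0 || lambda > 1) stop_phylofa("lambda must be in [0, 1]")
  C <- lambda_transform(phylo_covariance(tree), lambda)
  simulate_mvn_traits(C, sigma2, n_traits, seed)
}

# Synthetic FAs carry real nomenclature so the whole pipeline (parsing,
# biomarker classes, indices) runs unchanged on generated data. The first
# names are the frequent physiologically relevant FAs (these receive the
# conserved/BM block under the defaults), followed by the bacterial
# biomarkers and rarer FAs (labile under the defaults) — emulating
# phylogenetically structured membrane/storage FAs versus diet-driven
# markers.
synthetic_fa_names <- function(n_fas) {
  vocab <- c("16:0", "18:1w9", "18:2w6,9", "18:0", "20:5w3", "20:4w6",
             "16:1w7", "14:0", "18:1w7", "20:1w9",
             "a15:0", "i15:0", "16:1w5", "i16:0", "i17:0", "cy17:0",
             "cy19:0", "15:0", "17:0", "20:2w6,9",
             "20:3w6", "22:1w9", "22:2", "12:0", "14:1", "2-OH10:0",
             "19:0", "23:0", "24:1", "10:0", "8:0", "17:1w8")
  if (n_fas > length(vocab)) {
    stop_phylofa(sprintf("at most %d synthetic FAs supported", length(vocab)))
  }
  vocab[seq_len(n_fas)]
}

#' Specification for the synthetic FA study generator
#'
#' The defaults mirror the scale of a field study of springtail FA profiles:
#' a few dozen species, ~20 FAs, a few replicate measurements per species.
#' Half of the FAs evolve with strong phylogenetic structure (Brownian
#' motion on the latent log-abundance scale, `lambda_true = 1`) and half are
#' labile (species values drawn independently, `lambda_true = 0`);
#' within-species replicate noise yields per-species standard errors.
#'
#' @param n_species Number of species (tips).
#' @param birth_rate Yule speciation rate for the tree.
#' @param n_fas Number of fatty acids.
#' @param n_conserved Number of FAs evolving under BM (the rest are labile).
#' @param bm_rate BM rate on the latent log-abundance scale.
#' @param replicate_noise_sd Within-species replicate sd (latent scale).
#' @param n_replicates Replicate measurements per species.
#' @param seed Integer seed driving the whole generator.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 40, birth_rate = 1, n_fas = 20,
                           n_conserved = n_fas %/% 2, bm_rate = 1,
                           replicate_noise_sd = 0.25, n_replicates = 3,
                           seed = 1) {
  stopifnot(n_species >= 2, n_fas >= 2, n_conserved >= 0,
            n_conserved <= n_fas, bm_rate > 0, replicate_noise_sd >= 0)
  if (n_replicates < 1) stop_phylofa("n_replicates must be >= 1")
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 n_fas = n_fas, n_conserved = n_conserved,
                 bm_rate = bm_rate, replicate_noise_sd = replicate_noise_sd,
                 n_replicates = n_replicates, seed = seed),
            class = "synthetic_spec")
}

#' Generate a replicate-level compositional FA table with known ground truth
#'
#' Latent species-level log abundances: conserved FAs evolve by Brownian
#' motion on the tree, labile FAs are drawn independently per species (both
#' around a fixed per-FA baseline so the composition is uneven, as real FA
#' profiles are). Each replicate adds independent normal noise on the latent
#' scale; rows are closed to proportions summing to 100% by exponentiating
#' and renormalizing (softmax), which keeps the Brownian assumption on the
#' latent logit-like scale the downstream analysis tests.
#'
#' @param spec A [synthetic_spec()].
#' @param tree Optional tree with `spec$n_species` tips; simulated from the
#'   spec's seed by default.
#' @return A list of class `synthetic_fa_data`: `table` (measurement
#'   tibble), `truth` (per-FA tibble: `fa`, `lambda_true`, `conserved`),
#'   `latent` (species x FA latent matrix), `tree`, `spec`.
#' @export
synthetic_fa_table <- function(spec, tree = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(tree)) {
    tree <- yule_tree(spec$n_species, spec$birth_rate,
                      seed = derive_seed(spec$seed, 101))
  }
  if (length(tree$tip.label) != spec$n_species) {
    stop_phylofa("tree tip count does not match spec$n_species")
  }
  n_sp <- spec$n_species
  n_fa <- spec$n_fas
  fa_names <- synthetic_fa_names(n_fa)
  conserved <- seq_len(n_fa) <= spec$n_conserved

  baseline <- with_seed(derive_seed(spec$seed, 202),
                        rnorm(n_fa, mean = 0, sd = 1))
  latent <- matrix(0, n_sp, n_fa,
                   dimnames = list(sort(tree$tip.label), fa_names))
  if (any(conserved)) {
    latent[, conserved] <- simulate_bm(tree, sigma2 = spec$bm_rate,
                                       n_traits = sum(conserved),
                                       seed = derive_seed(spec$seed, 303))
  }
  if (any(!conserved)) {
    latent[, !conserved] <- simulate_lambda_traits(
      tree, lambda = 0, sigma2 = spec$bm_rate, n_traits = sum(!conserved),
      seed = derive_seed(spec$seed, 404))
  }
  latent <- sweep(latent, 2, baseline, `+`)

  reps <- with_seed(derive_seed(spec$seed, 505), {
    lapply(seq_len(spec$n_replicates), function(r) {
      latent + matrix(rnorm(n_sp * n_fa, sd = spec$replicate_noise_sd),
                      n_sp, n_fa)
    })
  })
  rows <- lapply(seq_len(spec$n_replicates), function(r) {
    E <- exp(reps[[r]])
    P <- 100 * E / rowSums(E)
    dplyr::bind_cols(
      tibble(sample_id = sprintf("%s_r%d", rownames(latent), r),
             species = rownames(latent), site = "sim", habitat = "sim"),
      as_tibble(P))
  })
  table <- arrange(bind_rows(rows), .data$species, .data$sample_id)
  structure(
    list(table = table,
         truth = tibble(fa = fa_names,
                        lambda_true = as.numeric(conserved),
                        conserved = conserved),
         latent = latent, tree = tree, spec = spec),
    class = "synthetic_fa_data")
}

#' Write a synthetic FA dataset to CSV files
#'
#' Writes the measurement table in the same CSV dialect [read_fa_table()]
#' reads, a ground-truth sidecar (per-FA `lambda_true`), and the tree as
#' Newick.
#'
#' @param data A `synthetic_fa_data` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_fa_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(data$table, file.path(dir, "fa_table.csv"))
  readr::write_csv(data$truth, file.path(dir, "ground_truth.csv"))
  write_newick(data$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
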