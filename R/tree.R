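# Tree handling: Newick I/O, phylogenetic covariance, the lambda branch-length
# transform, and Brownian-motion simulation. Trees are ape "phylo" objects;
# every matrix/vector pairing uses the canonical taxon order sort(tip.label).

#' Parse a Newick string into a validated rooted phylogeny
#'
#' Wraps [ape::read.tree()] and validates the result: unique tip labels, a
#' single root, and a branch length on every edge. Internal node labels and
#' support values are tolerated and ignored.
#'
#' @param text A Newick string (terminated by `;`).
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop_phylofa(sprintf(
      "unbalanced parentheses in Newick: %d '(' vs %d ')'", n_open, n_close))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_phylofa(sprintf("could not parse Newick text: %s",
                         substr(text, 1, 60)))
  }
  validate_phylogeny(tree)
  tree
}

#' Read a phylogeny from a Newick file
#'
#' @param path Path to a Newick file; the first tree in the file is used.
#' @return An object of class `phylo`.
#' @export
read_phylogeny <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Write a phylogeny to a Newick string or file
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_phylofa("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_phylofa(sprintf("duplicate tip labels: %s",
                         paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_phylofa("every edge must carry a branch length")
  }
  if (any(tree$edge.length < 0)) stop_phylofa("negative branch length")
  # a parsed Newick always has a definite basal node, which we take as the
  # root; a basal polytomy is a hard polytomy (e.g. a star phylogeny), not
  # an unrooted tree
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1) stop_phylofa("tree must have a single root")
  invisible(tree)
}

# Root-to-node path lengths, indexed by ape node number. A root edge (the
# stem retained when pruning) shifts every depth.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree) + (tree$root.edge %||% 0)
}

#' Tree height (maximum root-to-tip path length)
#'
#' @param tree A `phylo` object.
#' @return A single nonnegative number in branch-length units.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_along(tree$tip.label)])
}

#' Test whether a rooted tree is ultrametric
#'
#' All root-to-tip distances must agree within a relative tolerance
#' (relative to tree height). Chronogram exports typically lose some decimal
#' precision, hence the tolerant default.
#'
#' @param tree A `phylo` object.
#' @param rtol Relative tolerance on tip depths (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric_tree <- function(tree, rtol = 1e-6) {
  validate_phylogeny(tree)
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  h <- max(d)
  if (h == 0) return(TRUE)
  (max(d) - min(d)) / h <= rtol
}

#' Phylogenetic covariance matrix of a rooted tree
#'
#' Returns the n x n Brownian-motion covariance matrix `C`: `C[i, i]` is the
#' root-to-tip path length of tip i and `C[i, j]` the root-to-MRCA path
#' length of tips i and j. Rows and columns follow the canonical taxon order
#' `sort(tip.label)` so that every downstream matrix/vector pairing is
#' unambiguous.
#'
#' @param tree A `phylo` object (rooted, with branch lengths).
#' @return A symmetric numeric matrix with taxon dimnames in sorted order.
#' @export
#' @examples
#' phylo_covariance(parse_newick("((A:1,B:1):1,C:2);"))
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  # a retained stem (root edge) is shared ancestry of every tip pair
  C <- C + (tree$root.edge %||% 0)
  ord <- sort(rownames(C))
  C[ord, ord, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` is the Brownian-motion structure, `lambda = 0` a
#' star phylogeny.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Nonnegative multiplier.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop_phylofa("lambda must be a single nonnegative number")
  }
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

#' Largest admissible lambda for an ultrametric tree
#'
#' The lambda transform corresponds to a valid tree only while every scaled
#' off-diagonal covariance stays below the tip depth, i.e. up to
#' `lambda_max = height / (depth of the deepest internal node other than the
#' root)`. For a star tree the bound is 1 by convention. Ultrametric trees
#' with internal structure always have `lambda_max >= 1`.
#'
#' @param tree An ultrametric `phylo` object.
#' @param rtol Ultrametricity tolerance passed to [is_ultrametric_tree()].
#' @return A single number `>= 1`.
#' @export
lambda_max <- function(tree, rtol = 1e-6) {
  if (!is_ultrametric_tree(tree, rtol = rtol)) {
    stop_phylofa("lambda_max is defined for ultrametric trees only")
  }
  n_tip <- length(tree$tip.label)
  d <- node_depths(tree)
  internal <- d[(n_tip + 1):length(d)]
  root_depth <- min(internal)  # stem length if a root edge is present
  inner <- internal[internal > root_depth + .Machine$double.eps]
  if (root_depth > 0) inner <- c(inner, root_depth)
  if (length(inner) == 0) return(1)
  tree_height(tree) / max(inner)
}

# Lower-triangular-ish factor L with L %*% t(L) = C, tolerant of
# positive-semidefinite C (zero-length branches, lambda = 0 stars).
cov_factor <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Draws `n_traits` independent trait vectors from a multivariate normal with
#' mean 0 and covariance `sigma2 * C`, with `C` the phylogenetic covariance
#' of the tree. The default rate `sigma2 = 1` is immaterial for Blomberg's K,
#' which is scale-invariant.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param n_traits Number of independent replicate traits.
#' @param seed Optional integer seed; fixing it makes the draw reproducible.
#' @return A numeric matrix, tips (canonical sorted order) x traits, with
#'   taxon rownames.
#' @export
simulate_bm <- function(tree, sigma2 = 1, n_traits = 1, seed = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.numeric(n_traits) || n_traits < 1) {
    stop_phylofa("n_traits must be a positive integer")
  }
  C <- phylo_covariance(tree)
  simulate_mvn_traits(C, sigma2, n_traits, seed)
}

simulate_mvn_traits <- function(C, sigma2, n_traits, seed = NULL) {
  n <- nrow(C)
  L <- cov_factor(C) * sqrt(sigma2)
  X <- with_seed(seed, {
    Z <- matrix(rnorm(n * n_traits), n, n_traits)
    L %*% Z
  })
  rownames(X) <- rownames(C)
  colnames(X) <- paste0("trait_", seq_len(n_traits))
  X
}

#' Prune a phylogeny to a subset of tips
#'
#' Returns the induced subtree: degree-2 nodes are collapsed with branch
#' lengths summed, and the path from the original root down to the MRCA of
#' the kept tips is retained as the root edge (it is shared ancestry of
#' every kept pair). The covariance of the pruned tree therefore equals the
#' corresponding submatrix of the full covariance, and ultrametricity is
#' preserved.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to keep (at least 2).
#' @return A `phylo` object with `length(taxa)` tips.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0) {
    stop_phylofa(sprintf("taxa not in tree: %s", paste(unknown, collapse = ", ")))
  }
  if (length(taxa) < 2) stop_phylofa("need at least 2 taxa to keep")
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop) == 0) return(tree)
  stem <- node_depths(tree)[ape::getMRCA(tree, taxa)]
  out <- ape::keep.tip(tree, taxa)
  out$root.edge <- stem
  out
}
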