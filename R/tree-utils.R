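# Ultrametric trees are plain ape "phylo" objects; the helpers here validate
# ultrametricity, expose node ages, and build a UPGMA tree from distances.

#' Validate a rooted ultrametric tree
#'
#' Checks that the tree is rooted, binary (polytomies are resolved into
#' zero-length bifurcations with a warning), has branch lengths, and that all
#' root-to-tip path lengths agree within `tol * T_root`. Errors name the most
#' discordant pair of tips.
#'
#' @param tree an `ape::phylo` object.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return the (possibly dichotomised) tree, invisibly classed as before.
#' @export
validate_ultrametric <- function(tree, tol = 1e-6) {
  if (is.null(tree$edge.length)) stop2("tree has no branch lengths")
  if (!ape::is.rooted(tree)) stop2("tree must be rooted")
  if (!ape::is.binary(tree)) {
    warn2("polytomies resolved into zero-length bifurcations")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  t_root <- max(depths)
  spread <- max(depths) - min(depths)
  if (spread > tol * t_root) {
    worst <- c(tree$tip.label[which.max(depths)],
               tree$tip.label[which.min(depths)])
    stop2(sprintf(
      "tree is not ultrametric: tips '%s' (depth %.6g) and '%s' (depth %.6g)",
      worst[1], max(depths), worst[2], min(depths)))
  }
  tree
}

#' Read and validate an ultrametric Newick tree
#'
#' @param path Newick file path.
#' @param tol relative ultrametricity tolerance, see [validate_ultrametric()].
#' @return an `ape::phylo` tree that passed validation.
#' @export
read_ultrametric_tree <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop2("tree file not found: ", path)
  validate_ultrametric(ape::read.tree(path), tol = tol)
}

#' Node ages of an ultrametric tree
#'
#' Ages (time before present, tips at 0) of all internal nodes, in the order
#' of `ape::branching.times`.
#'
#' @param tree a validated ultrametric tree.
#' @return named numeric vector of ages, one per internal node.
#' @export
node_ages <- function(tree) {
  bt <- ape::branching.times(tree)
  # guard against tiny negative ages from floating-point depth differences
  pmax(bt, 0)
}

#' Branching times, oldest first
#'
#' The ordered ages of the N-1 internal nodes of an N-tip ultrametric tree;
#' the first element is the root age.
#'
#' @param tree a validated ultrametric tree.
#' @return numeric vector of ages in decreasing order.
#' @export
branching_times <- function(tree) {
  stopifnot(length(tree$tip.label) >= 2)
  sort(as.numeric(node_ages(tree)), decreasing = TRUE)
}

#' UPGMA tree from a K2P distance matrix
#'
#' Average-linkage agglomeration on the distance matrix; node age is half the
#' merge distance, so the result is ultrametric by construction. Rows are
#' ordered lexicographically by id first, which makes tie-breaking (smallest
#' id pair among equal distances) deterministic. A desk-scale stand-in for a
#' clock tree when none is supplied.
#'
#' @param dm a [k2p_distance_matrix()] result.
#' @return an `ape::phylo` ultrametric tree.
#' @export
upgma_tree <- function(dm) {
  d <- dm$d
  if (any(is.na(d[upper.tri(d)]))) {
    stop2("distance matrix has undefined (saturated) pairs; exclude those ",
          "samples before building a UPGMA tree")
  }
  ord <- order(dm$ids)
  d <- d[ord, ord]
  tree <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  validate_ultrametric(tree)
}
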