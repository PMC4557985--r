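# Refined single linkage (RESL), the clustering behind barcode index numbers
# (BINs): single linkage at 2.2% K2P, Markov-clustering refinement within each
# component, and a 4.4% founder rule that gives highly divergent sequences
# their own cluster. This is a local implementation: no reconciliation against
# the global BOLD registry is attempted.

#' Single-linkage clusters at a distance threshold
#'
#' Builds a graph with an edge for every pair at distance `<= threshold` and
#' returns its connected components. Undefined (saturated) distances are
#' treated as above the threshold, with a warning.
#'
#' @param dm a [k2p_distance_matrix()] result.
#' @param threshold linkage threshold as a proportion; default 0.022 (2.2%).
#' @return a [partition()] with provenance `"BIN"`.
#' @export
single_linkage_components <- function(dm, threshold = 0.022) {
  stopifnot(threshold > 0, threshold < 1)
  d <- dm$d
  ut <- upper.tri(d)
  if (any(is.na(d[ut]))) {
    warn2("undefined distances treated as above the linkage threshold")
  }
  adj <- !is.na(d) & d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  partition(stats::setNames(paste0("C", comp), dm$ids), "BIN")
}

#' Split isolated sequences into founder clusters
#'
#' Any sample whose minimum distance to every other sample exceeds
#' `founder_threshold` (strictly) becomes its own singleton cluster — it
#' "founds a new BIN" — regardless of prior membership.
#'
#' @param dm a [k2p_distance_matrix()] result.
#' @param p a [partition()] over the same samples.
#' @param founder_threshold proportion; default 0.044 (twice the 2.2% linkage
#'   threshold).
#' @return the updated [partition()].
#' @export
founder_rule <- function(dm, p, founder_threshold = 0.044) {
  d <- dm$d
  diag(d) <- NA
  min_d <- apply(d, 1, function(r) if (all(is.na(r))) Inf else
    min(r, na.rm = TRUE))
  lab <- unclass(p)[dm$ids]
  founders <- dm$ids[min_d > founder_threshold]
  for (id in founders) lab[id] <- paste0("F_", id)
  partition(lab, attr(p, "provenance"))
}

#' Markov-clustering refinement within single-linkage components
#'
#' Within each multi-member cluster of `p`, builds a similarity graph with
#' edge weights `max(0, 1 - d / founder_threshold)` and runs Markov
#' clustering (expansion 2, configurable inflation) to convergence. The
#' attractors of the limit matrix define refined clusters; components may be
#' split but never merged. A component whose MCL run does not converge is
#' kept unrefined with a warning.
#'
#' @param dm a [k2p_distance_matrix()] result.
#' @param p a [partition()] of the same samples (normally single-linkage
#'   components).
#' @param inflation MCL inflation parameter; default 2.0. Larger values give
#'   finer clusters.
#' @param founder_threshold scale of the similarity transform; default 0.044.
#' @param max_iter iteration cap; default 100.
#' @return the refined [partition()].
#' @export
mcl_refine <- function(dm, p, inflation = 2.0, founder_threshold = 0.044,
                       max_iter = 100) {
  stopifnot(inflation > 1)
  lab <- unclass(p)[dm$ids]
  out <- lab
  for (g in unique(lab)) {
    members <- dm$ids[lab == g]
    if (length(members) < 2) next
    d <- dm$d[members, members, drop = FALSE]
    s <- pmax(1 - d / founder_threshold, 0)  # first arg keeps the dims
    s[is.na(d)] <- 0
    sub <- mcl_clusters(s, inflation = inflation, max_iter = max_iter)
    if (is.null(sub)) {
      warn2("MCL did not converge for a component of ", length(members),
            " sequences; kept unrefined")
      next
    }
    if (max(sub) > 1) {
      out[members] <- paste0(g, ".", sub)
    }
  }
  partition(out, attr(p, "provenance"))
}

# Markov clustering on a symmetric nonnegative similarity matrix.
# Returns integer cluster memberships, or NULL on non-convergence.
mcl_clusters <- function(s, inflation = 2.0, max_iter = 100, tol = 1e-8) {
  n <- nrow(s)
  diag(s) <- 1  # self-loops stabilise the flow
  M <- sweep(s, 2, colSums(s), "/")
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M                # expansion
    M2 <- M2^inflation           # inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      # attractors: rows with mass on the diagonal; each column is assigned
      # to the attractor holding most of its flow
      attractors <- which(diag(M) > tol)
      if (!length(attractors)) return(NULL)
      assign <- apply(M[attractors, , drop = FALSE], 2, which.max)
      return(as.integer(factor(attractors[assign])))
    }
  }
  NULL
}

#' Assign barcode index numbers (BINs)
#'
#' The full RESL composition: single linkage at `threshold`, Markov-clustering
#' refinement within each component, then the founder rule at
#' `founder_threshold`. Cluster labels are `BIN_0001`, `BIN_0002`, ... in
#' order of first member appearance in the input, which makes the result
#' deterministic.
#'
#' @param dm a [k2p_distance_matrix()] result (sequences should already have
#'   passed the length filter).
#' @param threshold single-linkage threshold; default 0.022.
#' @param founder_threshold founder-rule threshold; default 0.044.
#' @param inflation MCL inflation; default 2.0.
#' @return a [partition()] with provenance `"BIN"`.
#' @export
assign_bins <- function(dm, threshold = 0.022, founder_threshold = 0.044,
                        inflation = 2.0) {
  p <- single_linkage_components(dm, threshold)
  p <- mcl_refine(dm, p, inflation = inflation,
                  founder_threshold = founder_threshold)
  p <- founder_rule(dm, p, founder_threshold)
  relabel_by_appearance(p, "BIN_%04d", "BIN")
}

# rename clusters in order of first appearance of a member
relabel_by_appearance <- function(p, fmt, provenance) {
  lab <- unclass(p)
  first <- lab[!duplicated(lab)]
  new <- stats::setNames(sprintf(fmt, seq_along(first)), first)
  partition(stats::setNames(new[lab], names(lab)), provenance)
}
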