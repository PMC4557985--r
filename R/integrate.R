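# Integrative consensus: morphology, BIN and GMYC partitions are combined by
# their common refinement ("distinct by at least one method"), and each final
# OTU is labelled by which methods distinguish it:
#   A - all three methods agree on the group;
#   B - morphologically distinct, lumped by at least one genetic method;
#   C - split by both genetic methods, lumped by morphology;
#   D - split by exactly one genetic method, lumped by morphology;
#   X - lumped by every method individually (possible only when partitions
#       cross); never silently folded into A-D.

#' Common refinement (meet) of three partitions
#'
#' Two samples share a final OTU iff they share a cluster in all three input
#' partitions: every split made by any method is honoured.
#'
#' @param morph,bin,gmyc [partition()]s over the same sample set.
#' @return a [partition()] with provenance `"consensus"`, labels `OTU_001`,
#'   ... in order of first appearance.
#' @export
meet_partition <- function(morph, bin, gmyc) {
  ids <- names(morph)
  sym <- c(setdiff(ids, names(bin)), setdiff(names(bin), ids),
           setdiff(ids, names(gmyc)), setdiff(names(gmyc), ids))
  if (length(sym)) {
    stop2("partitions cover different samples; symmetric difference: ",
          paste(unique(sym), collapse = ", "))
  }
  key <- paste(unclass(morph)[ids], unclass(bin)[ids], unclass(gmyc)[ids],
               sep = "\r")
  relabel_by_appearance(partition(stats::setNames(key, ids), "consensus"),
                        "OTU_%03d", "consensus")
}

#' Does a partition distinguish a sample group?
#'
#' `TRUE` iff the group is exactly one whole cluster of `p`: the cluster of
#' `p` containing the group equals the group. A group spanning several
#' clusters, or properly contained in a larger cluster, is not distinguished.
#'
#' @param group character vector of sample ids, nonempty.
#' @param p a [partition()] containing all members of `group`.
#' @return logical scalar.
#' @export
distinguishes <- function(group, p) {
  stopifnot(length(group) >= 1, all(group %in% names(p)))
  labs <- unique(unclass(p)[group])
  if (length(labs) > 1) return(FALSE)
  cluster <- names(p)[unclass(p) == labs]
  setequal(cluster, group)
}

#' Label consensus OTUs with agreement patterns
#'
#' For each OTU of the final (meet) partition, computes the flags
#' `(M, B, G) = distinguishes(OTU, method)` and assigns the pattern: A if
#' `M & B & G`; B if `M` and not both genetic methods; C if `!M & B & G`;
#' D if `!M` and exactly one genetic method; X if no method distinguishes the
#' OTU on its own.
#'
#' @param final the [meet_partition()] of the other three.
#' @param morph,bin,gmyc the input [partition()]s.
#' @return an object of class `consensus_result`: list with `otus` (data
#'   frame: `otu`, `n`, `pattern`, `by_morphology`, `by_bin`, `by_gmyc`),
#'   `tallies` (named counts over patterns present), `partition` (the final
#'   partition), and `members` (list of id vectors per OTU).
#' @export
classify_patterns <- function(final, morph, bin, gmyc) {
  sets <- cluster_sets(final)
  ord <- order(vapply(sets, function(s) min(match(s, names(final))),
                      numeric(1)))
  sets <- sets[ord]
  rows <- lapply(names(sets), function(o) {
    g <- sets[[o]]
    M <- distinguishes(g, morph)
    B <- distinguishes(g, bin)
    G <- distinguishes(g, gmyc)
    pattern <- if (M && B && G) "A"
      else if (M) "B"
      else if (B && G) "C"
      else if (xor(B, G)) "D"
      else "X"
    data.frame(otu = o, n = length(g), pattern = pattern,
               by_morphology = M, by_bin = B, by_gmyc = G)
  })
  otus <- do.call(rbind, rows)
  tallies <- table(factor(otus$pattern, levels = c("A", "B", "C", "D", "X")))
  tallies <- tallies[tallies > 0 | names(tallies) %in% c("A", "B", "C", "D")]
  structure(list(otus = otus, tallies = as.table(tallies), partition = final,
                 members = sets),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d OTUs\n", nrow(x$otus)))
  print(x$tallies)
  invisible(x)
}

#' Consensus tallies report
#'
#' Total OTU count, per-pattern tallies and the percentage of pattern-A OTUs
#' (all methods in agreement), rounded half-up to the nearest integer. Accepts
#' either a [classify_patterns()] result or a named tally vector such as
#' `c(A = 30, B = 19, C = 14, D = 10)`.
#'
#' @param r a `consensus_result` or a named numeric vector of pattern counts.
#' @return list with `total`, `tallies` and `pattern_a_share_pct`.
#' @export
consensus_report <- function(r) {
  tallies <- if (inherits(r, "consensus_result")) {
    stats::setNames(as.numeric(r$tallies), names(r$tallies))
  } else {
    if (!length(r) || is.null(names(r))) stop2("empty or unnamed tallies")
    stats::setNames(as.numeric(r), names(r))
  }
  total <- sum(tallies)
  if (total == 0) stop2("no OTUs to report")
  a <- if ("A" %in% names(tallies)) tallies[["A"]] else 0
  list(total = total, tallies = as.list(tallies),
       pattern_a_share_pct = round_half_up(100 * a / total))
}
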