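#' Intra- and inter-group divergence summary
#'
#' Summarises a K2P distance matrix against a morphospecies partition:
#' per-group maximum and mean intra-group distance (groups of one are skipped
#' for intra statistics), per-group nearest-neighbour distance (the minimum
#' distance from any member to any sample outside the group; singletons
#' included), and the fraction of groups whose nearest-neighbour distance
#' exceeds a threshold. Undefined (saturated) pairs are excluded.
#'
#' @param dm a [k2p_distance_matrix()] result.
#' @param labels a [partition()] assigning samples to morphospecies; every
#'   labelled sample must be present in `dm`.
#' @param threshold divergence threshold as a proportion, e.g. `0.02`.
#' @return an object of class `divergence_summary`: a list with a per-group
#'   data frame (`groups`), `max_intra`, `min_inter`,
#'   `fraction_above_threshold`, `threshold`, and the raw `intra` / `inter`
#'   distance vectors for plotting.
#' @export
divergence_summary <- function(dm, labels, threshold = 0.02) {
  stopifnot(threshold > 0, threshold < 1)
  missing_ids <- setdiff(names(labels), dm$ids)
  if (length(missing_ids)) {
    stop2("labelled samples absent from distance matrix: ",
          paste(missing_ids, collapse = ", "))
  }
  ids <- intersect(dm$ids, names(labels))
  grp <- unclass(labels)[ids]
  groups <- unique(grp)
  per <- lapply(groups, function(g) {
    inside <- ids[grp == g]
    outside <- ids[grp != g]
    dd <- dm$d[inside, inside, drop = FALSE]
    intra <- dd[upper.tri(dd)]
    intra <- intra[!is.na(intra)]
    nn <- if (length(outside)) {
      cross <- dm$d[inside, outside, drop = FALSE]
      if (all(is.na(cross))) NA_real_ else min(cross, na.rm = TRUE)
    } else NA_real_
    data.frame(group = g, n = length(inside),
               max_intra = if (length(intra)) max(intra) else NA_real_,
               mean_intra = if (length(intra)) mean(intra) else NA_real_,
               nn_inter = nn)
  })
  per <- do.call(rbind, per)
  intra_all <- unlist(lapply(groups, function(g) {
    inside <- ids[grp == g]
    dd <- dm$d[inside, inside, drop = FALSE]
    v <- dd[upper.tri(dd)]
    v[!is.na(v)]
  }))
  inter_ok <- per$nn_inter[!is.na(per$nn_inter)]
  structure(list(
    groups = per,
    max_intra = if (length(intra_all)) max(intra_all) else NA_real_,
    min_inter = if (length(inter_ok)) min(inter_ok) else NA_real_,
    fraction_above_threshold =
      if (length(inter_ok)) mean(per$nn_inter > threshold, na.rm = TRUE)
      else NA_real_,
    threshold = threshold,
    intra = as.numeric(intra_all), inter = as.numeric(inter_ok)),
    class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("divergence_summary: %d groups\n", nrow(x$groups)))
  cat(sprintf("  max intra %.4f | min nearest-neighbour inter %.4f\n",
              x$max_intra, x$min_inter))
  cat(sprintf("  %.1f%% of groups beyond %.1f%%\n",
              100 * x$fraction_above_threshold, 100 * x$threshold))
  invisible(x)
}

#' Barcoding-gap report
#'
#' A barcoding gap is present when the intra- and inter-group distance
#' distributions do not overlap: the global maximum intra-group distance is
#' strictly smaller than the global minimum nearest-neighbour inter-group
#' distance. Ties count as overlap.
#'
#' @param summary a [divergence_summary()].
#' @return a list with `gap_present`, `max_intra`, `min_inter` and the two
#'   distance distributions (`intra`, `inter`).
#' @export
barcoding_gap_report <- function(summary) {
  if (!length(summary$intra) || !length(summary$inter)) {
    stop2("both intra and inter distance distributions must be nonempty")
  }
  list(gap_present = summary$max_intra < summary$min_inter,
       max_intra = summary$max_intra, min_inter = summary$min_inter,
       intra = summary$intra, inter = summary$inter)
}
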