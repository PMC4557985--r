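#' Create a partition of samples into clusters
#'
#' A partition assigns every sample id to exactly one cluster. Partitions are
#' produced by morphospecies labels, BIN clustering ([assign_bins()]), the
#' GMYC model ([entities_at_threshold()]) and the final consensus
#' ([meet_partition()]). Cluster labels are opaque strings; only the grouping
#' they induce matters.
#'
#' @param labels character vector of cluster labels, named by sample id.
#' @param provenance one of `"morphology"`, `"BIN"`, `"GMYC"`, `"consensus"`
#'   or any short tag recording where the partition came from.
#' @return an object of class `partition`: a named character vector with a
#'   `provenance` attribute.
#' @examples
#' p <- partition(c(a = "sp1", b = "sp1", c = "sp2"), "morphology")
#' n_clusters(p)
#' @export
partition <- function(labels, provenance = "unknown") {
  ids <- names(labels)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop2("partition labels must be named by non-empty sample ids")
  }
  if (anyDuplicated(ids)) {
    stop2("duplicate sample ids in partition: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyNA(labels)) stop2("partition labels must not be NA")
  structure(as.character(stats::setNames(as.character(labels), ids)),
            names = ids, provenance = provenance, class = "partition")
}

#' @rdname partition
#' @param p a `partition`.
#' @export
n_clusters <- function(p) length(unique(unclass(p)))

#' @rdname partition
#' @export
cluster_sets <- function(p) {
  split(names(p), unclass(p))
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition (%s): %d samples in %d clusters\n",
              attr(x, "provenance"), length(x), n_clusters(x)))
  invisible(x)
}

#' Read a two-column TSV of sample to cluster assignments
#'
#' Expects a header line; the first column is the sample id, the second the
#' cluster label (e.g. a morphospecies name).
#'
#' @param path TSV file path.
#' @param provenance provenance tag for the resulting partition.
#' @return a [partition()].
#' @export
read_partition <- function(path, provenance = "morphology") {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(tab) < 2) stop2("partition table needs two columns: ", path)
  partition(stats::setNames(tab[[2]], tab[[1]]), provenance)
}

#' Write a partition as a two-column TSV
#'
#' @param p a [partition()].
#' @param path output file path.
#' @param col_name header name for the cluster column.
#' @export
write_partition <- function(p, path, col_name = "cluster") {
  tab <- data.frame(sample_id = names(p), cluster = unclass(p),
                    stringsAsFactors = FALSE)
  names(tab)[2] <- col_name
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
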