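#' Construct an aligned barcode matrix
#'
#' The basic container for an aligned nucleotide matrix: a character matrix
#' with one row per sequence and one column per alignment position, residues
#' upper-cased, plus optional morphospecies labels.
#'
#' @param seqs character vector of aligned sequences (all the same length),
#'   named by sample id, or a character matrix of single residues with row
#'   names.
#' @param labels optional named character vector mapping sample ids to
#'   morphospecies names; must be a subset of the sequence ids.
#' @return an object of class `aligned_matrix` with elements `seq` (character
#'   matrix), `ids`, `n_columns` and `labels` (named vector or `NULL`).
#' @export
aligned_matrix <- function(seqs, labels = NULL) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop2("sequences must be named by sample id")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- ids[which(lens != lens[1])[1]]
      stop2("alignment is ragged: record '", bad, "' has length ",
            nchar(seqs[bad]), ", expected ", lens[1])
    }
    m <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                byrow = TRUE, dimnames = list(ids, NULL))
  }
  ids <- rownames(m)
  if (nrow(m) == 0) ids <- character(0)
  else if (is.null(ids) || any(!nzchar(ids))) {
    stop2("sample ids missing or empty")
  }
  if (anyDuplicated(ids)) {
    stop2("duplicate sample ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(labels)) {
    extra <- setdiff(names(labels), ids)
    if (length(extra)) {
      warn2("label ids not in alignment, ignored: ",
            paste(extra, collapse = ", "))
      labels <- labels[setdiff(names(labels), extra)]
    }
    if (!length(labels)) labels <- NULL
  }
  structure(list(seq = m, ids = ids, n_columns = ncol(m), labels = labels),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("aligned_matrix: %d sequences x %d columns%s\n",
              length(x$ids), x$n_columns,
              if (is.null(x$labels)) "" else
                sprintf(" (%d labelled)", length(x$labels))))
  invisible(x)
}

#' Read an aligned FASTA matrix, optionally with morphospecies labels
#'
#' All records must have the same aligned length. Labels come from a TSV with
#' header columns `sample_id` and `morphospecies` and are attached by exact id
#' match; label ids absent from the FASTA are dropped with a warning.
#'
#' @param path FASTA file of aligned sequences.
#' @param label_path optional TSV path.
#' @return an [aligned_matrix()].
#' @export
read_alignment <- function(path, label_path = NULL) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  recs <- ape::read.FASTA(path)
  seqs <- vapply(as.character(recs), paste, character(1), collapse = "")
  names(seqs) <- names(recs)
  labels <- NULL
  if (!is.null(label_path)) {
    tab <- utils::read.delim(label_path, header = TRUE,
                             colClasses = "character")
    labels <- stats::setNames(tab[[2]], tab[[1]])
  }
  aligned_matrix(seqs, labels)
}

#' Write an aligned matrix as FASTA
#'
#' @param m an [aligned_matrix()].
#' @param path output path.
#' @export
write_alignment <- function(m, path) {
  lines <- character(2 * length(m$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", m$ids)
  lines[c(FALSE, TRUE)] <- apply(m$seq, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# count of informative (non-gap, non-N, non-missing) residues per sequence
ungapped_lengths <- function(m) {
  miss <- m$seq %in% c("-", "N", "?")
  dim(miss) <- dim(m$seq)
  stats::setNames(rowSums(!miss), m$ids)
}

#' Filter sequences by ungapped length
#'
#' Retains records whose count of non-gap, non-N residues is strictly greater
#' than `min_ungapped`, mirroring the "longer than 500 bp" rule used for BIN
#' membership. Order is preserved.
#'
#' @param m an [aligned_matrix()].
#' @param min_ungapped minimum ungapped length (exclusive); default 500.
#' @return the filtered [aligned_matrix()].
#' @export
filter_by_length <- function(m, min_ungapped = 500) {
  stopifnot(min_ungapped >= 1)
  keep <- ungapped_lengths(m) > min_ungapped
  if (!any(keep)) warn2("no sequences longer than ", min_ungapped, " bp")
  labels <- m$labels
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% m$ids[keep]]
    if (!length(labels)) labels <- NULL
  }
  aligned_matrix(m$seq[keep, , drop = FALSE], labels)
}

#' Screen sequences for internal stop codons
#'
#' Translates each ungapped sequence in the three forward reading frames under
#' the vertebrate mitochondrial genetic code (which counts AGA/AGG as stops,
#' in addition to TAA/TAG) and counts internal stop codons per frame: stops in
#' any complete codon other than the final one. A sequence passes if at least
#' one frame is free of internal stops; the lowest such frame is reported.
#' Codons containing ambiguity codes are not counted as stops.
#'
#' @param m an [aligned_matrix()].
#' @return a data frame with one row per sequence: `sample_id`,
#'   `ungapped_length`, `stops_frame0/1/2`, `frame` (chosen frame or `NA`),
#'   `pass`, and `untranslatable` for sequences shorter than one codon.
#' @export
screen_stop_codons <- function(m) {
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  stops <- names(code)[code == "*"]
  res <- lapply(m$ids, function(id) {
    s <- m$seq[id, ]
    s <- s[!(s %in% c("-", "?"))]
    n <- length(s)
    if (n < 3) {
      return(data.frame(sample_id = id, ungapped_length = n,
                        stops_frame0 = NA_integer_, stops_frame1 = NA_integer_,
                        stops_frame2 = NA_integer_, frame = NA_integer_,
                        pass = FALSE, untranslatable = TRUE))
    }
    counts <- vapply(0:2, function(f) {
      len <- n - f
      ncod <- len %/% 3
      if (ncod < 1) return(NA_integer_)
      starts <- f + 1 + 3 * (seq_len(ncod) - 1)
      codons <- paste0(s[starts], s[starts + 1], s[starts + 2])
      internal <- codons[-ncod]  # stops in the final codon are terminal
      sum(internal %in% stops)
    }, integer(1))
    ok <- which(!is.na(counts) & counts == 0)
    data.frame(sample_id = id, ungapped_length = n,
               stops_frame0 = counts[1], stops_frame1 = counts[2],
               stops_frame2 = counts[3],
               frame = if (length(ok)) ok[1] - 1L else NA_integer_,
               pass = length(ok) > 0, untranslatable = FALSE)
  })
  do.call(rbind, res)
}

#' Classify alignment columns as conserved, variable or excluded
#'
#' Per column, the set of unambiguous bases (A, C, G, T) observed across
#' sequences is collected; gaps and ambiguity codes count as missing. A column
#' with exactly one distinct base is conserved, with two or more variable, and
#' with none excluded.
#'
#' @param m an [aligned_matrix()].
#' @return a list with counts `conserved`, `variable`, `excluded`; they sum to
#'   `m$n_columns`.
#' @export
site_classification <- function(m) {
  stopifnot(m$n_columns >= 1)
  n_distinct <- apply(m$seq, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")]))
  })
  out <- list(conserved = sum(n_distinct == 1),
              variable = sum(n_distinct >= 2),
              excluded = sum(n_distinct == 0))
  stopifnot(out$conserved + out$variable + out$excluded == m$n_columns)
  out
}

#' Pooled base composition of an alignment
#'
#' Counts of A, C, G and T pooled over all cells of the matrix (gaps and
#' ambiguity codes excluded), divided by their total.
#'
#' @param m an [aligned_matrix()].
#' @return named numeric vector of frequencies for A, C, G, T summing to 1.
#' @export
base_composition <- function(m) {
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(m$seq == b),
                   numeric(1))
  tot <- sum(counts)
  if (tot == 0) stop2("no unambiguous bases in the matrix")
  counts / tot
}

#' Summary statistics for an aligned matrix
#'
#' Convenience wrapper bundling the matrix dimensions, site classification and
#' base composition, as written by the pipeline's QC stage.
#'
#' @param m an [aligned_matrix()].
#' @return a list suitable for JSON serialisation.
#' @export
matrix_summary <- function(m) {
  sites <- site_classification(m)
  list(n_seqs = length(m$ids), n_columns = m$n_columns,
       conserved = sites$conserved, variable = sites$variable,
       excluded = sites$excluded,
       base_frequencies = as.list(base_composition(m)))
}
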