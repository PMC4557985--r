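# shared oracles and fixture builders (all fixtures are built in code)

# do two partitions induce the same grouping, ignoring label names?
same_grouping <- function(a, b) {
  ids <- names(a)
  if (!setequal(ids, names(b))) return(FALSE)
  ka <- unclass(a)[ids]
  kb <- unclass(b)[ids]
  identical(outer(ka, ka, "=="), outer(kb, kb, "=="))
}

# independent brute-force K2P counter: explicit site loop and base-pair
# classification, no shared code with the package implementation
brute_k2p <- function(a, b) {
  sa <- strsplit(toupper(a), "")[[1]]
  sb <- strsplit(toupper(b), "")[[1]]
  purines <- c("A", "G")
  pyrimidines <- c("C", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(sa)) {
    x <- sa[i]; y <- sb[i]
    if (!(x %in% c(purines, pyrimidines))) next
    if (!(y %in% c(purines, pyrimidines))) next
    n <- n + 1L
    if (x == y) next
    both_pur <- x %in% purines && y %in% purines
    both_pyr <- x %in% pyrimidines && y %in% pyrimidines
    if (both_pur || both_pyr) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0) return(list(d = NA_real_, P = NA_real_, Q = NA_real_,
                          n_sites = 0L))
  P <- ts / n; Q <- tv / n
  d <- if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) NA_real_ else
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  list(d = d, P = P, Q = Q, n_sites = n)
}

# build a k2p_dist object from an explicit distance matrix (for clustering
# and tree tests where only d matters)
fake_dm <- function(d) {
  ids <- rownames(d)
  stopifnot(!is.null(ids), isSymmetric(unname(d)))
  structure(list(ids = ids, d = d, P = d * 0, Q = d * 0,
                 n_sites = matrix(100L, nrow(d), ncol(d),
                                  dimnames = dimnames(d)),
                 labels = NULL),
            class = "k2p_dist")
}

# symmetric matrix from pair assignments: dist_mat(ids, default, a=..., ...)
# where extra args are named "id1|id2" = value
dist_mat <- function(ids, default, pairs = list()) {
  d <- matrix(default, length(ids), length(ids), dimnames = list(ids, ids))
  diag(d) <- 0
  for (key in names(pairs)) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    d[p[1], p[2]] <- d[p[2], p[1]] <- pairs[[key]]
  }
  d
}

random_partition <- function(ids, k) {
  partition(stats::setNames(paste0("g", sample.int(k, length(ids),
                                                   replace = TRUE)), ids),
            "random")
}

write_temp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(c(rbind(paste0(">", names(seqs)), seqs)), path)
  path
}
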