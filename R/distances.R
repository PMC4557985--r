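#' Kimura 2-parameter distance for one pair of aligned sequences
#'
#' Sites where either sequence is a gap or an ambiguity code are dropped
#' (pairwise deletion). Over the jointly unambiguous sites, `P` is the
#' proportion of transitions (A<->G, C<->T) and `Q` the proportion of
#' transversions; the distance is
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).}
#' When an argument of a logarithm is non-positive the distance is saturated
#' and reported as `NA`.
#'
#' @param a,b aligned sequences: character strings or vectors of single
#'   residues, equal length.
#' @return a list with `d`, `P`, `Q` and `n_sites`. `d` is `NA` when
#'   saturated or when no site is jointly unambiguous.
#' @examples
#' k2p_pair("ACGT", "GCGT")  # one transition over 4 sites
#' @export
k2p_pair <- function(a, b) {
  ea <- encode_bases(a)
  eb <- encode_bases(b)
  if (length(ea) != length(eb)) stop2("sequences differ in aligned length")
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0) return(list(d = NA_real_, P = NA_real_, Q = NA_real_,
                          n_sites = 0L))
  ea <- ea[ok]; eb <- eb[ok]
  diff <- ea != eb
  # encoding A=1, G=3 (odd = purine), C=2, T=4 (even = pyrimidine):
  # a substitution is a transition iff it stays within purines or pyrimidines
  ts <- sum(diff & (ea %% 2L == eb %% 2L))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, P = P, Q = Q, n_sites = as.integer(n))
}

# A=1, C=2, G=3, T=4, everything else (gap, N, IUPAC ambiguity) NA
encode_bases <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  match(toupper(x), c("A", "C", "G", "T"))
}

#' All-pairs K2P distance matrix
#'
#' Computes [k2p_pair()] for every pair of sequences in an alignment.
#' Saturated pairs (where the K2P logarithm is undefined) are flagged with a
#' warning and carry `NA` distances; downstream summaries exclude them.
#'
#' @param m an [aligned_matrix()].
#' @return an object of class `k2p_dist`: a list of symmetric matrices `d`,
#'   `P`, `Q`, `n_sites` with `ids` row/column names, plus the `labels`
#'   carried over from the alignment.
#' @export
k2p_distance_matrix <- function(m) {
  n <- length(m$ids)
  stopifnot(n >= 2)
  E <- matrix(encode_bases(t(m$seq)), nrow = n, byrow = TRUE)
  dn <- list(m$ids, m$ids)
  d <- P <- Q <- matrix(0, n, n, dimnames = dn)
  ns <- matrix(0L, n, n, dimnames = dn)
  diag(ns) <- as.integer(rowSums(!is.na(E)))
  saturated <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- k2p_pair_encoded(E[i, ], E[j, ])
      d[i, j] <- d[j, i] <- p$d
      P[i, j] <- P[j, i] <- p$P
      Q[i, j] <- Q[j, i] <- p$Q
      ns[i, j] <- ns[j, i] <- p$n_sites
      if (is.na(p$d) && p$n_sites > 0) saturated <- saturated + 1L
    }
  }
  if (saturated > 0) {
    warn2(saturated, " pair(s) saturated (K2P undefined); excluded from ",
          "summaries")
  }
  structure(list(ids = m$ids, d = d, P = P, Q = Q, n_sites = ns,
                 labels = m$labels),
            class = "k2p_dist")
}

# k2p_pair on pre-encoded integer vectors (hot path for the all-pairs loop)
k2p_pair_encoded <- function(ea, eb) {
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0) return(list(d = NA_real_, P = NA_real_, Q = NA_real_,
                          n_sites = 0L))
  ea <- ea[ok]; eb <- eb[ok]
  diff <- ea != eb
  ts <- sum(diff & (ea %% 2L == eb %% 2L))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, P = P, Q = Q, n_sites = as.integer(n))
}

#' @export
print.k2p_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("k2p_dist: %d sequences, %d pairs (%d undefined)\n",
              length(x$ids), length(off), sum(is.na(off))))
  if (any(!is.na(off))) {
    cat(sprintf("  d range: %.4f - %.4f\n", min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Pooled transition/transversion ratio
#'
#' Pooled transition count divided by pooled transversion count over all
#' defined pairs (counts reconstructed from the per-pair proportions and site
#' counts).
#'
#' @param dm a [k2p_distance_matrix()] result.
#' @return the ratio, or `Inf` (with a warning) when no transversions were
#'   observed; `NaN` if neither class was observed.
#' @export
ts_tv_ratio <- function(dm) {
  ut <- upper.tri(dm$d)
  ok <- ut & !is.na(dm$P)
  ts <- sum(dm$P[ok] * dm$n_sites[ok])
  tv <- sum(dm$Q[ok] * dm$n_sites[ok])
  if (tv == 0) {
    if (ts == 0) return(NaN)
    warn2("no transversions observed; ts/tv ratio undefined (Inf)")
    return(Inf)
  }
  ts / tv
}
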