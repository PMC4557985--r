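# Single-threshold general mixed Yule-coalescent (GMYC) model.
#
# An ultrametric tree of multiple species and populations shows a shift in
# branching rate at the species boundary: older branching events reflect
# diversification (Yule process), younger ones within-population coalescence.
# The model places a single threshold age T*, treats every lineage crossing T*
# as one entity, and scores each inter-event interval with the combined event
# rate
#   b_i = lambda1 * n_i^p1  +  lambda2 * sum_j [m_ij (m_ij - 1)]^p2
# where n_i is the count of diversification lineages (frozen at the number of
# threshold-crossing lineages once past T*) and m_ij the lineage count within
# entity j. The log-likelihood sums ln(b_i) - b_i * x_i over intervals that
# terminate in an observed branching event.

#' Candidate threshold ages for the single-threshold GMYC scan
#'
#' Midpoints between consecutive distinct internal-node ages, plus one
#' candidate older than the root (all tips in one entity) and one younger
#' than the youngest node (every tip its own entity).
#'
#' @param tree a validated ultrametric tree with at least 3 tips.
#' @return numeric vector of candidate ages, decreasing.
#' @export
candidate_thresholds <- function(tree) {
  stopifnot(length(tree$tip.label) >= 3)
  ages <- branching_times(tree)
  u <- distinct_ages(ages)
  upper <- if (length(u) >= 2) u[1] + (u[1] - u[2]) / 2 else 1.5 * u[1]
  lower <- u[length(u)] / 2
  # zero-age nodes (identical sequences under UPGMA) cannot be split:
  # keep the youngest candidate just above age zero
  if (lower <= 0) lower <- 1e-9 * u[1]
  mids <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  sort(c(upper, mids, lower), decreasing = TRUE)
}

# collapse ages equal within a relative tolerance
distinct_ages <- function(ages, rel_tol = 1e-9) {
  u <- sort(unique(ages), decreasing = TRUE)
  if (length(u) < 2) return(u)
  keep <- c(TRUE, diff(u) < -rel_tol * u[1])
  u[keep]
}

#' Delimit entities at a threshold age
#'
#' Each lineage (branch) crossing the threshold age defines one entity whose
#' members are the tips descending from it; singleton entities are permitted.
#' A threshold at or above the root age yields a single entity.
#'
#' @param tree a validated ultrametric tree.
#' @param threshold age (time before present), `> 0`.
#' @return a [partition()] with provenance `"GMYC"`, labels `GMYC_001`, ... in
#'   order of first member appearance among the tips.
#' @export
entities_at_threshold <- function(tree, threshold) {
  stopifnot(threshold > 0)
  tips <- tree$tip.label
  cl <- threshold_clusters(tree, threshold)
  lab <- character(length(tips))
  names(lab) <- tips
  for (j in seq_along(cl)) lab[tips[cl[[j]]$tips]] <- paste0("E", j)
  relabel_by_appearance(partition(lab, "GMYC"), "GMYC_%03d", "GMYC")
}

# Lineages crossing the threshold: list of clusters, each with $tips (tip
# indices) and $coal_nodes (internal node numbers inside the cluster, i.e.
# events younger than the threshold), ordered by decreasing stem age.
threshold_clusters <- function(tree, threshold) {
  ntip <- length(tree$tip.label)
  bt <- node_ages(tree)
  age_of <- function(nd) ifelse(nd <= ntip, 0, bt[as.character(nd)])
  root <- ntip + 1L
  if (age_of(root) <= threshold) {
    ints <- (ntip + 1L):(ntip + tree$Nnode)
    return(list(list(tips = seq_len(ntip), coal_nodes = ints)))
  }
  pa <- age_of(tree$edge[, 1])
  ca <- age_of(tree$edge[, 2])
  crossing <- tree$edge[pa > threshold & ca <= threshold, 2]
  lapply(crossing, function(c0) {
    if (c0 <= ntip) return(list(tips = c0, coal_nodes = integer(0)))
    desc <- phangorn::Descendants(tree, c0, type = "all")
    list(tips = sort(desc[desc <= ntip]),
         coal_nodes = c(c0, desc[desc > ntip]))
  })
}

#' Inter-event interval table for a threshold
#'
#' Orders all internal-node events from the root toward the present and
#' records, per interval, the waiting time `x`, the diversification lineage
#' count `n`, and the within-entity lineage counts `m` (one column per
#' entity). Only intervals terminating in an observed event are tabulated;
#' the final interval (youngest node to present) carries no event. Zero
#' waiting times arising from tied node ages are floored at
#' `1e-9 * T_root` so all intervals are positive.
#'
#' @param tree a validated ultrametric tree.
#' @param threshold age in `(0, T_root]`; values above the root give a
#'   pure-coalescent table with a single entity.
#' @return an object of class `gmyc_intervals`: list with `x`, `n` (numeric
#'   vectors), `m` (interval x entity matrix), `event_type` (`"yule"` or
#'   `"coalescent"` for each interval's terminating event), `k` (number of
#'   entities), `t_root` and `threshold`.
#' @export
interval_table <- function(tree, threshold) {
  ntip <- length(tree$tip.label)
  stopifnot(threshold > 0, ntip >= 2)
  bt <- node_ages(tree)
  t_root <- max(bt)
  clusters <- threshold_clusters(tree, threshold)
  k <- length(clusters)
  # map each internal node to its event type / cluster
  nodes <- as.integer(names(bt))
  cluster_of <- integer(ntip + tree$Nnode)
  for (j in seq_along(clusters)) cluster_of[clusters[[j]]$coal_nodes] <- j
  ord <- order(bt, decreasing = TRUE)
  ages <- as.numeric(bt[ord])
  type <- ifelse(cluster_of[nodes[ord]] == 0L, "yule", "coalescent")
  clus <- cluster_of[nodes[ord]]

  n_events <- length(ages)
  n_yule <- 1L
  m <- rep(1L, k)
  x <- n <- numeric(max(n_events - 1, 0))
  M <- matrix(0L, max(n_events - 1, 0), k)
  etype <- character(max(n_events - 1, 0))
  # process the oldest event (terminates no interval), then record/update
  if (type[1] == "yule") n_yule <- n_yule + 1L else
    m[clus[1]] <- m[clus[1]] + 1L
  if (n_events >= 2) {
    for (i in 2:n_events) {
      x[i - 1] <- ages[i - 1] - ages[i]
      n[i - 1] <- n_yule
      M[i - 1, ] <- m
      etype[i - 1] <- type[i]
      if (type[i] == "yule") n_yule <- n_yule + 1L else
        m[clus[i]] <- m[clus[i]] + 1L
    }
  }
  x <- pmax(x, 1e-9 * t_root)
  mm <- M * (M - 1L)
  structure(list(x = x, n = n, m = M, mm = mm, event_type = etype, k = k,
                 t_root = t_root, threshold = threshold),
            class = "gmyc_intervals")
}

#' Mixed Yule-coalescent log-likelihood
#'
#' Evaluates the combined-rate log-likelihood on an interval table: per
#' interval `b = lambda1 * n^p1 + lambda2 * sum_j [m_j (m_j - 1)]^p2` (terms
#' with `m_j = 1` contribute 0, for any `p2`), and
#' `lnL = sum(log(b) - b * x)`.
#'
#' @param it an [interval_table()].
#' @param lambda1,p1 diversification rate (`> 0`) and scaling exponent.
#' @param lambda2,p2 coalescent rate (`> 0`) and scaling exponent.
#' @return the log-likelihood; `-Inf` when some interval has zero total rate.
#' @export
mixed_loglik <- function(it, lambda1, p1, lambda2, p2) {
  stopifnot(lambda1 > 0, lambda2 > 0)
  if (!length(it$x)) return(0)
  coal <- coal_term(it$mm, p2)
  b <- lambda1 * it$n^p1 + lambda2 * coal
  if (any(b <= 0)) return(-Inf)
  sum(log(b) - b * it$x)
}

# rowSums of (m(m-1))^p2 with the m = 1 (mm = 0) terms forced to zero,
# which matters at p2 = 0 where R would evaluate 0^0 = 1
coal_term <- function(mm, p2) {
  v <- mm^p2
  v[mm == 0] <- 0
  rowSums(v)
}

#' Single-process null log-likelihood
#'
#' One rate law for the whole tree: during the interval terminating at the
#' i-th oldest event there are `i` lineages, and `b_i = lambda0 * i^p0`.
#'
#' @param tree a validated ultrametric tree.
#' @param lambda0 rate, `> 0`.
#' @param p0 scaling exponent.
#' @return the log-likelihood.
#' @export
null_loglik <- function(tree, lambda0, p0) {
  stopifnot(lambda0 > 0)
  it <- null_intervals(tree)
  b <- lambda0 * it$n^p0
  if (any(b <= 0)) return(-Inf)
  sum(log(b) - b * it$x)
}

null_intervals <- function(tree) {
  ages <- branching_times(tree)
  nev <- length(ages)
  if (nev < 2) return(list(x = numeric(0), n = numeric(0)))
  x <- pmax(ages[-nev] - ages[-1], 1e-9 * ages[1])
  list(x = x, n = 2:nev)
}

# ---- maximum-likelihood machinery ------------------------------------------

# Maximise the mixed likelihood over (lambda1, p1, lambda2, p2) for one
# interval table. Rates are optimised on the log scale within (1e-8, 1e6);
# exponents are boxed in [0, 3]. Nelder-Mead from multiple starts (closed-form
# rate initialisation at p = 1, plus p in {0.5, 2}); one-parameter profiles
# fall back to golden-section search. Unidentifiable parameters (no
# coalescent events; constant lineage counts) are held fixed.
ml_mixed <- function(it, p_grid = c(0.5, 2), maxit = 500, reltol = 1e-10,
                     fix_p1 = NULL, fix_p2 = NULL) {
  has_coal <- any(it$mm > 0)
  n_const <- length(unique(it$n)) == 1
  rate_init <- function(p1, p2) {
    ny <- sum(it$event_type == "yule")
    nc <- sum(it$event_type == "coalescent")
    A <- it$n^p1
    B <- coal_term(it$mm, p2)
    l1 <- clamp_rate(max(ny, 0.5) / sum(A * it$x))
    l2 <- if (has_coal) clamp_rate(max(nc, 0.5) / sum(B * it$x + 1e-12))
          else 1
    c(l1, l2)
  }
  free <- c(lambda1 = TRUE, p1 = is.null(fix_p1) && !n_const,
            lambda2 = has_coal, p2 = is.null(fix_p2) && has_coal)
  base_init <- rate_init(fix_p1 %||% 1, fix_p2 %||% 1)
  base_full <- c(log(base_init[1]), fix_p1 %||% 1,
                 log(base_init[2]), fix_p2 %||% 1)
  obj <- function(th) {
    # th holds the free parameters in order lambda1, p1, lambda2, p2
    full <- base_full
    full[which(free)] <- th
    if (full[2] < 0 || full[2] > 3 || full[4] < 0 || full[4] > 3)
      return(1e10)
    l1 <- exp(full[1]); l2 <- exp(full[3])
    if (l1 < 1e-8 || l1 > 1e6 || l2 < 1e-8 || l2 > 1e6) return(1e10)
    -mixed_loglik(it, l1, full[2], l2, full[4])
  }
  starts <- list()
  for (pv in c(1, p_grid)) {
    li <- rate_init(pv, pv)
    starts[[length(starts) + 1]] <-
      c(log(li[1]), pv, log(li[2]), pv)[which(free)]
  }
  best <- optimise_multistart(obj, starts, maxit = maxit, reltol = reltol)
  full <- base_full
  full[which(free)] <- best$par
  list(loglik = -best$value, lambda1 = exp(full[1]), p1 = full[2],
       lambda2 = if (has_coal) exp(full[3]) else NA_real_,
       p2 = if (has_coal) full[4] else NA_real_)
}

# Maximise the null likelihood over (lambda0, p0); p0 may be profiled fixed.
ml_null <- function(tree, maxit = 500, reltol = 1e-10, fix_p0 = NULL) {
  it <- null_intervals(tree)
  obj <- function(th) {
    p0 <- if (is.null(fix_p0)) th[2] else fix_p0
    if (p0 < 0 || p0 > 3) return(1e10)
    l0 <- exp(th[1])
    if (l0 < 1e-8 || l0 > 1e6) return(1e10)
    b <- l0 * it$n^p0
    -sum(log(b) - b * it$x)
  }
  p_starts <- if (is.null(fix_p0)) c(0, 1, 2) else fix_p0
  starts <- lapply(p_starts, function(pv) {
    s <- c(log(clamp_rate(length(it$x) / sum(it$n^pv * it$x))), pv)
    if (is.null(fix_p0)) s else s[1]
  })
  best <- optimise_multistart(obj, starts, maxit = maxit, reltol = reltol)
  list(loglik = -best$value, lambda0 = exp(best$par[1]),
       p0 = if (is.null(fix_p0)) best$par[2] else fix_p0)
}

clamp_rate <- function(x) min(max(x, 1e-7), 1e5)

optimise_multistart <- function(obj, starts, maxit, reltol) {
  best <- NULL
  for (s in starts) {
    fit <- if (length(s) == 1) {
      o <- stats::optimize(function(z) obj(z), interval = s + c(-8, 8),
                           tol = 1e-10)
      list(par = o$minimum, value = o$objective)
    } else {
      o <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
      list(par = o$par, value = o$value)
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Fit the single-threshold GMYC model
#'
#' Scans every candidate threshold ([candidate_thresholds()]), maximises the
#' mixed likelihood at each, selects the maximum-likelihood threshold (ties
#' broken toward the older threshold, i.e. fewer entities), tests it against
#' the single-process null by a likelihood-ratio test, and reports the entity
#' partition with a confidence set of entity counts.
#'
#' @param tree a validated ultrametric tree with at least 3 tips.
#' @param lr_df degrees of freedom for the chi-square LR test; default 3.
#' @param ci_window log-likelihood window for the confidence set; default 2.
#' @param p_grid extra exponent starts for the optimiser.
#' @return an object of class `gmyc_fit`: list with `scan` (per-threshold
#'   data frame: `age`, `loglik`, `n_entities`, parameter columns),
#'   `threshold_age`, `threshold_norm` (`-age / T_root`), the ML parameters,
#'   `null` (parameters and log-likelihood), `LR`, `df`, `p_value`,
#'   `entities` (a [partition()]), `n_entities`, `n_singletons`,
#'   `confidence_counts` (entity counts within `ci_window` of the maximum)
#'   and `t_root`.
#' @export
fit_single_threshold <- function(tree, lr_df = 3, ci_window = 2,
                                 p_grid = c(0.5, 2)) {
  tree <- validate_ultrametric(tree)
  stopifnot(length(tree$tip.label) >= 3)
  cands <- candidate_thresholds(tree)
  rows <- lapply(cands, function(h) {
    it <- interval_table(tree, h)
    fit <- tryCatch(ml_mixed(it, p_grid = p_grid), error = function(e) NULL)
    if (is.null(fit)) {
      warn2(sprintf("optimiser failed at threshold %.6g; dropped", h))
      return(NULL)
    }
    data.frame(age = h, loglik = fit$loglik, n_entities = it$k,
               lambda1 = fit$lambda1, p1 = fit$p1,
               lambda2 = fit$lambda2, p2 = fit$p2)
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || !nrow(scan)) stop2("no threshold could be fitted")
  scan <- scan[order(-scan$age), ]
  best_i <- which.max(scan$loglik)  # first max = oldest age on ties
  null <- ml_null(tree)
  lr <- 2 * (scan$loglik[best_i] - null$loglik)
  t_root <- max(branching_times(tree))
  thr <- scan$age[best_i]
  entities <- entities_at_threshold(tree, min(thr, t_root * (1 + 1e-9)))
  in_window <- scan$loglik >= scan$loglik[best_i] - ci_window
  structure(list(
    scan = scan,
    threshold_age = thr,
    threshold_norm = -thr / t_root,
    lambda1 = scan$lambda1[best_i], p1 = scan$p1[best_i],
    lambda2 = scan$lambda2[best_i], p2 = scan$p2[best_i],
    loglik = scan$loglik[best_i],
    null = null,
    LR = lr, df = lr_df,
    p_value = stats::pchisq(max(lr, 0), df = lr_df, lower.tail = FALSE),
    entities = entities,
    n_entities = n_clusters(entities),
    n_singletons = sum(table(unclass(entities)) == 1),
    confidence_counts = sort(unique(scan$n_entities[in_window])),
    ci_window = ci_window,
    t_root = t_root), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("single-threshold GMYC fit\n")
  cat(sprintf("  threshold age %.6g (%.3g T), lnL %.4f vs null %.4f\n",
              x$threshold_age, x$threshold_norm, x$loglik, x$null$loglik))
  cat(sprintf("  LR = %.3f (df %d), p = %.4g\n", x$LR, x$df, x$p_value))
  cat(sprintf("  %d entities (%d singletons); confidence set %d-%d\n",
              x$n_entities, x$n_singletons, min(x$confidence_counts),
              max(x$confidence_counts)))
  invisible(x)
}
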