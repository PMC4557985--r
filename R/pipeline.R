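#' Pipeline configuration
#'
#' Paths and thresholds for a full delimitation run. Defaults follow the
#' standard barcode-analysis settings: a 500 bp length filter, 2.2% single
#' linkage with a 4.4% founder rule and MCL inflation 2, a chi-square df of 3
#' for the GMYC likelihood-ratio test and a 2 log-likelihood-unit confidence
#' window.
#'
#' @param fasta path to the aligned FASTA matrix.
#' @param labels path to the morphospecies TSV (`sample_id`, `morphospecies`).
#' @param tree optional path to an ultrametric Newick tree; when `NULL` a
#'   UPGMA tree is built from the K2P distances.
#' @param out_dir output directory for all artifacts.
#' @param min_len length-filter threshold (exclusive), default 500.
#' @param sl_threshold single-linkage threshold, default 0.022.
#' @param founder_threshold founder-rule threshold, default 0.044.
#' @param inflation MCL inflation, default 2.
#' @param divergence_threshold threshold for the divergence-fraction summary,
#'   default 0.02.
#' @param lr_df,ci_window GMYC test df and confidence window.
#' @param seed RNG seed recorded in the manifest.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, labels, tree = NULL, out_dir = ".",
                            min_len = 500, sl_threshold = 0.022,
                            founder_threshold = 0.044, inflation = 2.0,
                            divergence_threshold = 0.02,
                            lr_df = 3, ci_window = 2.0, seed = 1) {
  stopifnot(min_len >= 1, sl_threshold > 0, sl_threshold < 1,
            founder_threshold > 0, founder_threshold < 1, inflation > 1,
            lr_df >= 1, ci_window > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full delimitation pipeline
#'
#' Stages: alignment QC (length filter, stop-codon screen, matrix summary),
#' K2P distances with divergence and barcoding-gap summaries, tree (read or
#' UPGMA), BIN clustering, single-threshold GMYC, and the three-way consensus.
#' Every intermediate is written under `cfg$out_dir`; warnings raised by any
#' stage are collected into the summary so data issues are visible.
#'
#' @param cfg a [pipeline_config()].
#' @return the run summary (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # qc
  aln <- collect(read_alignment(cfg$fasta, cfg$labels))
  aln <- collect(filter_by_length(aln, cfg$min_len))
  qc <- screen_stop_codons(aln)
  utils::write.table(qc, file.path(cfg$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  msum <- matrix_summary(aln)

  if (is.null(aln$labels)) stop2("no morphospecies labels cover the ",
                                 "filtered sequences")
  morph <- partition(aln$labels, "morphology")

  # distances
  dm <- collect(k2p_distance_matrix(aln))
  write_distance_tables(dm, cfg$out_dir)
  div <- divergence_summary(dm, morph, cfg$divergence_threshold)
  gap <- barcoding_gap_report(div)

  # tree
  tree <- if (is.null(cfg$tree)) {
    collect(upgma_tree(dm))
  } else {
    read_ultrametric_tree(cfg$tree)
  }
  ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))

  # bin
  bins <- collect(assign_bins(dm, cfg$sl_threshold, cfg$founder_threshold,
                              cfg$inflation))
  write_partition(bins, file.path(cfg$out_dir, "bins.tsv"), "bin")

  # gmyc
  fit <- collect(fit_single_threshold(tree, lr_df = cfg$lr_df,
                                      ci_window = cfg$ci_window))
  write_partition(fit$entities, file.path(cfg$out_dir, "gmyc_entities.tsv"),
                  "gmyc_entity")
  utils::write.table(fit$scan, file.path(cfg$out_dir, "gmyc_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # integrate: all three partitions restricted to the common samples
  ids <- names(morph)
  bins2 <- partition(unclass(bins)[ids], "BIN")
  gmyc2 <- partition(unclass(fit$entities)[ids], "GMYC")
  final <- meet_partition(morph, bins2, gmyc2)
  consensus <- classify_patterns(final, morph, bins2, gmyc2)
  otu_tab <- merge(data.frame(sample_id = ids, otu_id = unclass(final)),
                   consensus$otus, by.x = "otu_id", by.y = "otu")
  utils::write.table(otu_tab[order(otu_tab$sample_id), ],
                     file.path(cfg$out_dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- consensus_report(consensus)

  summary <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    matrix = msum,
    qc_pass = sum(qc$pass), qc_fail = sum(!qc$pass),
    divergence = list(max_intra = div$max_intra, min_inter = div$min_inter,
                      fraction_above_threshold =
                        div$fraction_above_threshold,
                      gap_present = gap$gap_present),
    ts_tv = ts_tv_ratio(dm),
    counts = list(morphospecies = n_clusters(morph),
                  bins = n_clusters(bins),
                  gmyc_entities = fit$n_entities,
                  gmyc_singletons = fit$n_singletons,
                  otus = report$total),
    gmyc = list(threshold_age = fit$threshold_age,
                threshold_norm = fit$threshold_norm,
                LR = fit$LR, p_value = fit$p_value,
                confidence_counts = fit$confidence_counts),
    patterns = report$tallies,
    pattern_a_share_pct = report$pattern_a_share_pct,
    warnings = warnings_seen)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}

write_distance_tables <- function(dm, out_dir) {
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  long <- data.frame(id1 = dm$ids[ut[, 1]], id2 = dm$ids[ut[, 2]],
                     d = dm$d[ut], P = dm$P[ut], Q = dm$Q[ut],
                     n_sites = dm$n_sites[ut])
  utils::write.table(long, file.path(out_dir, "distances_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(dm$d, 6), file.path(out_dir, "distances.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(NULL)
}
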