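test_that("k2p_pair reproduces closed-form hand values", {
  id <- k2p_pair("ACGT", "ACGT")
  expect_equal(id$d, 0)
  expect_equal(id$P, 0)
  expect_equal(id$Q, 0)
  expect_equal(id$n_sites, 4L)

  # one A<->G transition over 4 sites: d = -0.5 ln(0.5)
  p <- k2p_pair("ACGT", "GCGT")
  expect_equal(p$P, 0.25)
  expect_equal(p$Q, 0)
  expect_equal(p$d, -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(p$d, 0.346574, tolerance = 1e-5)

  # constructed P = 0.1, Q = 0.05 over 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  q <- k2p_pair(a, b)
  expect_equal(q$P, 0.1)
  expect_equal(q$Q, 0.05)
  expect_equal(q$d, -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
})

test_that("pairwise deletion and saturation handling", {
  p <- k2p_pair("AC-TN", "ACGTA")
  expect_equal(p$n_sites, 3L)
  expect_equal(p$d, 0)

  sat <- k2p_pair("AAAA", "CCCC")  # Q = 1: log undefined
  expect_true(is.na(sat$d))
  expect_equal(sat$Q, 1)

  none <- k2p_pair("--NN", "AAAA")
  expect_equal(none$n_sites, 0L)
  expect_true(is.na(none$d))
})

test_that("k2p_pair equals the brute-force site counter on random pairs", {
  set.seed(202)
  for (i in 1:100) {
    a <- paste(sample(c("A", "C", "G", "T", "-", "N"), 50, replace = TRUE,
                      prob = c(rep(.22, 4), .06, .06)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-", "N"), 50, replace = TRUE,
                      prob = c(rep(.22, 4), .06, .06)), collapse = "")
    expect_equal(k2p_pair(a, b), brute_k2p(a, b))
  }
})

test_that("distance matrix is symmetric, zero-diagonal and matches dist.dna", {
  d <- make_dataset(sim_config(seed = 5, k_species = 4,
                               samples_per_species = 3))
  dm <- k2p_distance_matrix(d$alignment)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, length(dm$ids)))
  # d >= p-distance (P + Q) wherever defined
  ut <- upper.tri(dm$d)
  expect_true(all(dm$d[ut] >= dm$P[ut] + dm$Q[ut] - 1e-12, na.rm = TRUE))

  # independent route: ape's K80 with pairwise deletion
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(d$alignment$seq)),
                                 model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[dm$ids, dm$ids]), tolerance = 1e-10)
})

test_that("all-identical and permuted inputs behave as expected", {
  m <- aligned_matrix(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  dm <- k2p_distance_matrix(m)
  expect_true(all(dm$d == 0))

  d <- make_dataset(sim_config(seed = 6, k_species = 3,
                               samples_per_species = 2))
  dm1 <- k2p_distance_matrix(d$alignment)
  perm <- sample(d$alignment$ids)
  dm2 <- k2p_distance_matrix(aligned_matrix(d$alignment$seq[perm, ]))
  expect_equal(dm2$d[dm1$ids, dm1$ids], dm1$d)
})

test_that("K2P approaches the p-distance at low divergence", {
  set.seed(77)
  tr <- ape::read.tree(text = "(a:0.0025,b:0.0025);")  # d_true = 0.005
  for (i in 1:5) {
    m <- simulate_sequences(tr, L = 4000, rate = 1, kappa = 2)
    p <- k2p_pair(paste(m$seq["a", ], collapse = ""),
                  paste(m$seq["b", ], collapse = ""))
    if (p$d > 0) expect_lt(abs(p$d - (p$P + p$Q)) / p$d, 0.02)
  }
})

test_that("ts/tv ratio pools counts and flags degenerate cases", {
  m <- aligned_matrix(c(a = "AAAACC", b = "GGAAAC"))  # 2 ts (A>G), 1 tv (C>A)
  expect_equal(ts_tv_ratio(k2p_distance_matrix(m)), 2)

  ident <- k2p_distance_matrix(aligned_matrix(c(a = "ACGT", b = "ACGT")))
  expect_true(is.nan(ts_tv_ratio(ident)))

  only_ts <- k2p_distance_matrix(aligned_matrix(c(a = "AAAA", b = "GAAA")))
  expect_warning(r <- ts_tv_ratio(only_ts), "transversions")
  expect_identical(r, Inf)
})

test_that("observed ts/tv increases with the simulation kappa", {
  tr <- ape::read.tree(text = "(a:0.5,b:0.5);")
  ratios <- vapply(c(1, 2, 5), function(kp) {
    set.seed(300 + kp)
    m <- simulate_sequences(tr, L = 20000, rate = 0.05, kappa = kp)
    ts_tv_ratio(k2p_distance_matrix(m))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("divergence summary: hand-enumerated two-group case", {
  d <- dist_mat(c("a1", "a2", "b1"), 0.05, list("a1|a2" = 0.01))
  dm <- fake_dm(d)
  labs <- partition(c(a1 = "A", a2 = "A", b1 = "B"), "morphology")
  s <- divergence_summary(dm, labs, threshold = 0.02)
  expect_equal(s$max_intra, 0.01)
  expect_equal(s$min_inter, 0.05)
  expect_equal(s$fraction_above_threshold, 1.0)
  g <- s$groups[s$groups$group == "B", ]
  expect_true(is.na(g$max_intra))  # singleton: no intra pairs
  expect_equal(g$nn_inter, 0.05)
})

test_that("divergence summary degenerate and error cases", {
  d <- dist_mat(c("a1", "a2"), 0.01)
  s <- divergence_summary(fake_dm(d), partition(c(a1 = "A", a2 = "A"),
                                                "morphology"))
  expect_true(is.na(s$min_inter))
  expect_equal(length(s$inter), 0)
  expect_error(barcoding_gap_report(s), "nonempty")

  expect_error(
    divergence_summary(fake_dm(d), partition(c(a1 = "A", zz = "B"),
                                             "morphology")),
    "zz")
})

test_that("divergence fraction is invariant to ordering and relabeling", {
  set.seed(41)
  d <- make_dataset(sim_config(seed = 41, k_species = 5,
                               samples_per_species = 3))
  dm <- k2p_distance_matrix(d$alignment)
  s1 <- divergence_summary(dm, d$truth, 0.02)
  relab <- partition(stats::setNames(paste0("XX_", unclass(d$truth)),
                                     names(d$truth)), "morphology")
  shuffled <- relab[sample(length(relab))]
  s2 <- divergence_summary(dm, partition(shuffled, "morphology"), 0.02)
  expect_equal(s2$fraction_above_threshold, s1$fraction_above_threshold)
  expect_equal(s2$max_intra, s1$max_intra)
})

test_that("barcoding gap verdict uses strict inequality", {
  base <- list(intra = c(0.01), inter = c(0.05), max_intra = 0.01,
               min_inter = 0.05)
  expect_true(barcoding_gap_report(structure(base,
    class = "divergence_summary"))$gap_present)
  overlap <- structure(list(intra = 0.085, inter = 0.008, max_intra = 0.085,
                            min_inter = 0.008), class = "divergence_summary")
  expect_false(barcoding_gap_report(overlap)$gap_present)
  tie <- structure(list(intra = 0.02, inter = 0.02, max_intra = 0.02,
                        min_inter = 0.02), class = "divergence_summary")
  expect_false(barcoding_gap_report(tie)$gap_present)
})
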