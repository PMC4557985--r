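four_tip <- function() ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")

test_that("candidate thresholds bracket the distinct node ages", {
  expect_equal(candidate_thresholds(four_tip()), c(2.5, 1.5, 0.5))
  # all nodes at the same age: one interior candidate plus the above-root one
  flat <- ape::read.tree(text = "((a:1,b:1):0,(c:1,d:1):0);")
  cands <- candidate_thresholds(flat)
  expect_equal(cands, c(1.5, 0.5))
  expect_equal(sum(cands < 1), 1)
})

test_that("interval table matches the hand construction at threshold 1.5", {
  it <- interval_table(four_tip(), 1.5)
  expect_equal(it$k, 2)  # clusters {a,b} and {c,d}
  expect_equal(length(it$x), 2)
  expect_equal(it$x[1], 1)           # root (age 2) to first age-1 event
  expect_equal(it$n, c(2, 2))        # frozen at the 2 crossing lineages
  expect_equal(it$m[1, ], c(1, 1))   # both clusters still single lineages
  expect_equal(sort(it$m[2, ]), c(1, 2))  # first cluster has coalesced
  expect_equal(it$event_type, c("coalescent", "coalescent"))
})

test_that("interval table degenerates correctly at extreme thresholds", {
  tr <- simulate_species_tree(6, seed = 4)
  bt <- branching_times(tr)
  below <- interval_table(tr, min(bt) / 2)
  expect_equal(below$k, 6)                       # all singleton clusters
  expect_true(all(below$event_type == "yule"))
  expect_true(all(below$mm == 0))
  expect_equal(below$n, 2:5)                     # lineages through time

  above <- interval_table(tr, max(bt) * 1.5)
  expect_equal(above$k, 1)
  expect_true(all(above$event_type == "coalescent"))
  expect_true(all(above$n == 1))
})

test_that("mixed log-likelihood: direct substitution and rescaling identity", {
  tr3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  it <- interval_table(tr3, 0.5)  # single interval, x = 1, n = 2, pure Yule
  expect_equal(mixed_loglik(it, 1, 1, 1, 1), log(2) - 2, tolerance = 1e-12)

  # rescaling time by c and rates by 1/c shifts lnL by -(#events) * log(c)
  tr <- simulate_species_tree(8, seed = 15)
  cc <- 3.7
  trs <- tr
  trs$edge.length <- tr$edge.length * cc
  h <- mean(branching_times(tr)[2:3])
  l1 <- mixed_loglik(interval_table(tr, h), 0.8, 1.3, 2.0, 0.7)
  l2 <- mixed_loglik(interval_table(trs, h * cc), 0.8 / cc, 1.3, 2.0 / cc,
                     0.7)
  n_ev <- length(interval_table(tr, h)$x)
  expect_equal(l2, l1 - n_ev * log(cc), tolerance = 1e-8)
})

test_that("entities with one lineage contribute no coalescent rate, even at
           p2 = 0", {
  tr <- simulate_species_tree(6, seed = 8)
  below <- interval_table(tr, min(branching_times(tr)) / 2)
  # every m is 1: the likelihood must not depend on lambda2 or p2 at all
  expect_equal(mixed_loglik(below, 1.2, 0.9, 5, 0),
               mixed_loglik(below, 1.2, 0.9, 0.01, 2))
  # with real coalescent events lambda2 does matter
  g <- graft_coalescents(tr, 3, 0.05, seed = 8)
  mid <- interval_table(g$tree, min(branching_times(tr)) / 2)
  expect_false(isTRUE(all.equal(mixed_loglik(mid, 1, 1, 1, 0),
                                mixed_loglik(mid, 1, 1, 2, 0))))
})

test_that("numeric optimiser matches the closed-form rate oracles", {
  tr <- simulate_species_tree(12, seed = 33)
  bt <- branching_times(tr)

  # pure Yule (threshold below all nodes), p1 fixed at 1:
  # lambda-hat = (#events) / sum(n_i x_i)
  it <- interval_table(tr, min(bt) / 2)
  lam_oracle <- length(it$x) / sum(it$n * it$x)
  fit <- otudelim:::ml_mixed(it, fix_p1 = 1)
  expect_equal(fit$lambda1, lam_oracle, tolerance = 1e-6)
  expect_equal(fit$loglik,
               sum(log(lam_oracle * it$n) - lam_oracle * it$n * it$x),
               tolerance = 1e-9)

  # constant-rate null (p0 = 0): lambda-hat = (#events) / total waiting time
  nt <- otudelim:::null_intervals(tr)
  lam0_oracle <- length(nt$x) / sum(nt$x)
  fit0 <- otudelim:::ml_null(tr, fix_p0 = 0)
  expect_equal(fit0$lambda0, lam0_oracle, tolerance = 1e-6)

  # ladder tree, p0 = 1: hand-computed optimum
  ladder <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  expect_equal(null_loglik(ladder, 0.4, 1), log(0.96) - 2, tolerance = 1e-9)
  fitl <- otudelim:::ml_null(ladder, fix_p0 = 1)
  expect_equal(fitl$lambda0, 0.4, tolerance = 1e-6)
})

test_that("entities at a threshold: hand case and degenerate limits", {
  tr <- four_tip()
  p <- entities_at_threshold(tr, 1.5)
  expect_true(same_grouping(p, partition(
    c(a = "1", b = "1", c = "2", d = "2"), "truth")))
  expect_equal(n_clusters(entities_at_threshold(tr, 2.5)), 1)
  expect_equal(n_clusters(entities_at_threshold(tr, 0.5)), 4)
})

test_that("entity count is monotone non-increasing in threshold age", {
  tr <- simulate_species_tree(10, seed = 44)
  hs <- sort(candidate_thresholds(tr))
  ks <- vapply(hs, function(h) n_clusters(entities_at_threshold(tr, h)),
               numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("fitting a clean multi-species tree recovers the species boundary", {
  set.seed(55)
  sp <- simulate_species_tree(10, min_divergence_time = 1.5)
  g <- graft_coalescents(sp, 5, 0.01)
  fit <- fit_single_threshold(g$tree)
  expect_equal(fit$n_entities, 10)
  expect_true(same_grouping(fit$entities, g$truth))
  expect_lt(fit$p_value, 0.05)
  expect_lt(fit$threshold_age, min(branching_times(sp)))
  expect_equal(fit$threshold_norm, -fit$threshold_age / fit$t_root)

  # nesting: the mixed ML is never below the null ML
  expect_gte(fit$loglik, fit$null$loglik - 1e-6)
  # confidence set contains the ML count; a wider window never shrinks it
  expect_true(fit$n_entities %in% fit$confidence_counts)
  fit4 <- fit_single_threshold(g$tree, ci_window = 4)
  expect_true(all(fit$confidence_counts %in% fit4$confidence_counts))
})

test_that("nesting holds on assorted small trees", {
  for (s in 1:3) {
    tr <- simulate_coalescent_tree(12, mean_height = 1, seed = 60 + s)
    fit <- fit_single_threshold(tr)
    expect_gte(fit$loglik, fit$null$loglik - 1e-6)
    expect_true(fit$n_entities %in% fit$confidence_counts)
  }
})
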