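# Synthetic barcode datasets with known truth: a Yule species tree, shallow
# within-species coalescents grafted onto its tips, and sequences evolved
# under a two-rate (transition/transversion) substitution model. Every stage
# of the delimitation pipeline can be exercised against the generated truth.
#
# Trees are built in a nested-list form (node = age + children or tip label)
# and converted to ape "phylo" via Newick, which keeps grafting simple.

new_tip <- function(label) list(age = 0, label = label, children = NULL)
new_node <- function(age, children) list(age = age, label = NULL,
                                         children = children)

nested_to_newick <- function(node, parent_age) {
  brlen <- sprintf("%.12g", parent_age - node$age)
  if (is.null(node$children)) return(paste0(node$label, ":", brlen))
  inner <- paste(vapply(node$children, nested_to_newick, character(1),
                        parent_age = node$age), collapse = ",")
  paste0("(", inner, "):", brlen)
}

nested_to_phylo <- function(root) {
  inner <- paste(vapply(root$children, nested_to_newick, character(1),
                        parent_age = root$age), collapse = ",")
  validate_ultrametric(ape::read.tree(text = paste0("(", inner, ");")))
}

phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  ages <- node_ages(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(nd) {
    if (nd <= ntip) return(new_tip(tree$tip.label[nd]))
    new_node(as.numeric(ages[as.character(nd)]),
             lapply(kids[[as.character(nd)]], build))
  }
  build(ntip + 1L)
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Forward simulation: while `j` lineages exist the waiting time to the next
#' split is exponential with rate `yule_rate * j`; the present is the moment
#' the `(k+1)`-th lineage would have appeared, so tips are contemporaneous.
#' For `k = 2` the root age is exponential with rate `2 * yule_rate`.
#' `min_divergence_time` shifts every split into the past by a constant,
#' emulating a clade with no very recent speciation (all species separated by
#' at least that much time); 0 gives the pure Yule process.
#'
#' @param k number of species tips, at least 2.
#' @param yule_rate speciation rate per lineage per unit time.
#' @param seed optional RNG seed for reproducibility.
#' @param min_divergence_time constant added to every node age; default 0.
#' @return an ultrametric `ape::phylo` tree with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(k, yule_rate = 1, seed = NULL,
                                  min_divergence_time = 0) {
  stopifnot(k >= 2, yule_rate > 0, min_divergence_time >= 0)
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rexp(k - 1, rate = yule_rate * (2:k))  # duration with j lineages
  t_root <- sum(w)
  split_ages <- t_root - cumsum(c(0, w[-length(w)]))  # oldest first
  # topology: Yule labelled histories are uniform random joins, so assemble
  # from the present backward, joining a uniform pair at each split age
  labels <- sprintf("sp%02d", seq_len(k))
  active <- lapply(labels, new_tip)
  for (a in sort(split_ages)) {
    pair <- sample.int(length(active), 2)
    joined <- new_node(a + min_divergence_time, active[pair])
    active <- c(active[-pair], list(joined))
  }
  nested_to_phylo(active[[1]])
}

# Kingman coalescent over n labelled samples, scaled so the expected root
# height is target_mean; resampled until the height fits under max_height.
simulate_coalescent <- function(labels, target_mean, max_height,
                                max_tries = 1000) {
  n <- length(labels)
  if (n == 1) return(new_tip(labels))
  theta <- target_mean / (2 * (1 - 1 / n))
  for (try in seq_len(max_tries)) {
    active <- lapply(labels, new_tip)
    t <- 0
    for (j in seq(n, 2)) {
      t <- t + stats::rexp(1, rate = choose(j, 2) / theta)
      pair <- sample.int(length(active), 2)
      joined <- new_node(t, active[pair])
      active <- c(active[-pair], list(joined))
    }
    if (t < max_height) return(active[[1]])
  }
  stop2("coalescent height exceeded the pendant branch in ", max_tries,
        " tries; use a smaller depth_scale")
}

#' Simulate a single-population coalescent tree
#'
#' A standard Kingman coalescent over `n` contemporaneous samples, scaled so
#' the expected root height is `mean_height`. Useful as the null regime for
#' the GMYC test: a tree with no speciation signal.
#'
#' @param n number of samples.
#' @param mean_height expected age of the root.
#' @param seed optional RNG seed.
#' @return an ultrametric `ape::phylo` tree with tips `ind1`, `ind2`, ...
#' @export
simulate_coalescent_tree <- function(n, mean_height = 1, seed = NULL) {
  stopifnot(n >= 2, mean_height > 0)
  if (!is.null(seed)) set.seed(seed)
  nested <- simulate_coalescent(sprintf("ind%d", seq_len(n)), mean_height,
                                Inf)
  nested_to_phylo(nested)
}

#' Graft within-species coalescents onto a species tree
#'
#' Each species tip is replaced by a standard coalescent over its samples,
#' scaled so the expected within-species root height equals
#' `depth_scale * pendant branch length` and rejection-resampled so the
#' realised height never exceeds the pendant branch. Sample ids are
#' `<species>_ind<i>`.
#'
#' @param tree a species tree from [simulate_species_tree()].
#' @param n_per_species samples per species: a single count or a vector, one
#'   per tip (recycled in tip-label order).
#' @param depth_scale ratio of expected within-species height to the pendant
#'   branch; `> 0`, typically well below 1.
#' @param seed optional RNG seed.
#' @return a list with `tree` (the grafted ultrametric `phylo`) and
#'   `truth` (a [partition()] of samples into species, provenance
#'   `"morphology"`).
#' @export
graft_coalescents <- function(tree, n_per_species, depth_scale = 0.01,
                              seed = NULL) {
  stopifnot(depth_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  tips <- sort(tree$tip.label)
  n_per <- stats::setNames(rep_len(n_per_species, length(tips)), tips)
  pendant <- stats::setNames(
    tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2])],
    tree$tip.label)
  nested <- phylo_to_nested(tree)
  truth <- character(0)
  graft <- function(node) {
    if (is.null(node$children)) {
      sp <- node$label
      ids <- sprintf("%s_ind%d", sp, seq_len(n_per[[sp]]))
      truth[ids] <<- sp
      return(simulate_coalescent(ids, depth_scale * pendant[[sp]],
                                 pendant[[sp]]))
    }
    node$children <- lapply(node$children, graft)
    node
  }
  grafted <- graft(nested)
  list(tree = nested_to_phylo(grafted),
       truth = partition(truth, "morphology"))
}

#' Simulate sequence evolution on a tree under a two-rate model
#'
#' Evolves sequences along the tree under a Kimura two-parameter model: the
#' transition rate is `kappa` times the transversion rate, base frequencies
#' are uniform, and branch lengths are measured in time so the expected
#' number of substitutions per site per unit time is `rate`. The root
#' sequence is uniform over bases.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param L sequence length in sites.
#' @param rate substitutions per site per unit time.
#' @param kappa transition/transversion rate ratio (on rates, not counts).
#' @param seed optional RNG seed.
#' @return an [aligned_matrix()] whose rows follow the tree's tip labels.
#' @export
simulate_sequences <- function(tree, L, rate, kappa = 4, seed = NULL) {
  stopifnot(L >= 1, rate >= 0, kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) {
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m <- matrix(rep(root, each = length(tree$tip.label)),
                nrow = length(tree$tip.label),
                dimnames = list(tree$tip.label, NULL))
    return(aligned_matrix(m))
  }
  sim <- phangorn::simSeq(tree, l = L, type = "DNA", bf = rep(0.25, 4),
                          Q = c(1, kappa, 1, 1, kappa, 1), rate = rate)
  m <- toupper(as.character(sim))
  aligned_matrix(m[tree$tip.label, , drop = FALSE])
}

#' Simulation configuration
#'
#' Bundles the generator parameters with their default study conditions: 10
#' species sampled 5 deep, Yule rate 1 with a 1.5-time-unit floor on species
#' divergences (a well-differentiated clade), within-species coalescent
#' heights around 1% of the pendant branch, 533-site sequences at 0.03
#' substitutions/site/unit time with transition bias 4.
#'
#' @param k_species number of species.
#' @param samples_per_species samples per species (scalar or vector).
#' @param yule_rate speciation rate.
#' @param coalescent_depth_scale within-species height as a fraction of the
#'   pendant branch.
#' @param min_divergence_time floor on species divergence times; set to 0 for
#'   a pure Yule tree (overlapping regime).
#' @param seq_length alignment length in sites.
#' @param subst_rate substitutions per site per unit time.
#' @param kappa transition/transversion rate ratio.
#' @param lump_probability probability that a sister-species cherry is lumped
#'   into one morphospecies label, creating morphology-vs-genetics conflicts.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(k_species = 10, samples_per_species = 5,
                       yule_rate = 1, coalescent_depth_scale = 0.01,
                       min_divergence_time = 1.5, seq_length = 533,
                       subst_rate = 0.03, kappa = 4,
                       lump_probability = 0, seed = 1) {
  stopifnot(k_species >= 1, seq_length >= 1, yule_rate > 0, subst_rate >= 0,
            kappa > 0, coalescent_depth_scale > 0,
            lump_probability >= 0, lump_probability <= 1)
  structure(list(k_species = k_species,
                 samples_per_species = samples_per_species,
                 yule_rate = yule_rate,
                 coalescent_depth_scale = coalescent_depth_scale,
                 min_divergence_time = min_divergence_time,
                 seq_length = seq_length, subst_rate = subst_rate,
                 kappa = kappa, lump_probability = lump_probability,
                 seed = seed), class = "sim_config")
}

#' Generate a complete synthetic barcode dataset
#'
#' Composes [simulate_species_tree()], [graft_coalescents()] and
#' [simulate_sequences()] under one seed, and derives a morphology partition
#' from the truth (optionally lumping random sister-species cherries to
#' create conflict scenarios). When `out_dir` is given, writes
#' `alignment.fasta`, `labels.tsv` (morphology), `truth.tsv` (true species)
#' and `tree.nwk` (the grafted tree).
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return a list of class `synthetic_dataset`: `tree` (grafted),
#'   `species_tree`, `truth` and `morphology` [partition()]s, `alignment`
#'   (an [aligned_matrix()] with the morphology labels attached) and `config`.
#' @export
make_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  sp_tree <- simulate_species_tree(cfg$k_species, cfg$yule_rate,
                                   min_divergence_time =
                                     cfg$min_divergence_time)
  g <- graft_coalescents(sp_tree, cfg$samples_per_species,
                         cfg$coalescent_depth_scale)
  aln <- simulate_sequences(g$tree, cfg$seq_length, cfg$subst_rate,
                            cfg$kappa)
  morph <- lump_sisters(sp_tree, g$truth, cfg$lump_probability)
  aln <- aligned_matrix(aln$seq, labels = unclass(morph))
  out <- structure(list(tree = g$tree, species_tree = sp_tree,
                        truth = g$truth, morphology = morph,
                        alignment = aln, config = cfg),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_alignment(aln, file.path(out_dir, "alignment.fasta"))
    write_partition(morph, file.path(out_dir, "labels.tsv"), "morphospecies")
    write_partition(g$truth, file.path(out_dir, "truth.tsv"), "species")
    ape::write.tree(g$tree, file.path(out_dir, "tree.nwk"))
  }
  out
}

# with probability lump_probability, merge each sister-species pair (cherry
# of the species tree) into one morphospecies label
lump_sisters <- function(sp_tree, truth, lump_probability) {
  lab <- unclass(truth)
  if (lump_probability > 0) {
    ntip <- length(sp_tree$tip.label)
    kids <- split(sp_tree$edge[, 2], sp_tree$edge[, 1])
    for (ch in kids) {
      if (length(ch) == 2 && all(ch <= ntip) &&
          stats::runif(1) < lump_probability) {
        pair <- sp_tree$tip.label[ch]
        lab[lab %in% pair] <- paste(sort(pair), collapse = "+")
      }
    }
  }
  partition(lab, "morphology")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d species, %d samples, %d sites (seed %d)\n",
    x$config$k_species, length(x$truth), x$config$seq_length,
    x$config$seed))
  invisible(x)
}
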