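---
title: "Methods: integrative single-locus species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative single-locus species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otudelim)
```

`otudelim` delimits candidate species (operational taxonomic units, OTUs)
from a single mitochondrial barcode locus by combining three independent
lines of evidence — morphospecies assignments, a refined-single-linkage
clustering of genetic distances (the procedure behind barcode index
numbers, BINs), and the single-threshold general mixed Yule-coalescent
(GMYC) model — and labelling every consensus OTU by which methods support
it. This vignette documents the models, the defaults and the reasoning
behind the design choices; the README shows a worked run.

## Alignment quality control

Input is a pre-aligned nucleotide matrix (FASTA) with optional
morphospecies labels (TSV). The QC stage mirrors standard barcode
curation:

* **Length filter.** A record is retained when its count of non-gap,
  non-N residues is *strictly greater* than `min_len` (default 500). The
  strict inequality follows the usual "longer than 500 bp" BIN membership
  wording.
* **Stop-codon screen.** Each ungapped sequence is translated in the three
  forward frames under the vertebrate mitochondrial genetic code (which
  counts AGA and AGG as stops alongside TAA and TAG — using the standard
  code here would miss the most common COI pseudogene signal). A sequence
  passes when at least one frame has no *internal* stop (a stop in the
  final complete codon is terminal and does not count). Barcode amplicons
  are oriented by primer design, so reverse frames are not searched. The
  chosen frame is reported rather than fixed because the reading frame of
  a trimmed alignment is data-dependent.
* **Site classification.** Per column, only unambiguous A/C/G/T calls are
  considered; gaps and IUPAC ambiguity codes are missing data. A column
  with exactly one observed base is conserved, with two or more variable,
  and with none excluded. This is the usual convention for reporting
  "conserved/variable" counts on barcode matrices.
* **Base composition** is pooled over all unambiguous cells rather than
  averaged per sequence: for near-equal-length records the two differ
  negligibly, and pooling is deterministic and ordering-free.

## Kimura 2-parameter distances

For each sequence pair, sites where either member carries a gap or
ambiguity are dropped (*pairwise deletion*, the convention of the BOLD
toolchain; complete deletion would discard most of a ragged matrix). Over
the jointly unambiguous sites, with transition proportion $P$ and
transversion proportion $Q$,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

When an argument of a logarithm is non-positive the pair is *saturated*:
the distance is undefined and the pair is excluded from all summaries
with a warning, rather than clamped — clamping would silently bias
divergence maxima. Distances are proportions internally; percentages
appear only in reports, rounded half-up to one decimal.

The divergence summary compares each morphospecies to its *nearest
neighbour* (the minimum distance from any member to any non-member).
The fraction of morphospecies "more than 2% divergent" uses this
nearest-neighbour distance: it is the conservative comparator standard
in barcoding-gap analyses (a group mean would overstate separation).
A *barcoding gap* is declared only when the global maximum intraspecific
distance is strictly below the global minimum nearest-neighbour distance.

## RESL / BIN clustering

The refined single linkage procedure runs in three steps on the distance
matrix:

1. **Single linkage** at threshold 2.2% (`sl_threshold = 0.022`): an edge
   joins every pair at or below the threshold; clusters are connected
   components.
2. **Markov-clustering refinement** within each multi-member component.
   The similarity graph uses weights $\max(0, 1 - d/0.044)$ — the simplest
   monotone map that reaches zero exactly at the founder threshold — and
   MCL runs with expansion 2 and inflation 2.0 (the canonical MCL default)
   until the flow matrix is idempotent (change below $10^{-8}$, cap 100
   iterations; a non-converged component is kept unrefined with a
   warning). Components can split, never merge.
3. **Founder rule** at 4.4%: any sequence strictly more divergent than
   `founder_threshold` from *every* other sequence becomes its own
   cluster. It runs after refinement so refined singletons can still
   found clusters; the published two-step sketch does not fix the order.

Labels are `BIN_0001`, … in order of first appearance, making the whole
composition deterministic and order-invariant. This is a *local*
implementation: the BIN system proper assigns clusters against a global
registry that is continuously updated, so local cluster counts are
comparable to, but not guaranteed identical with, registry BIN counts.
The MCL edge weighting and stopping rule are not specified in the
published description of RESL; both are exposed as parameters.

## Single-threshold GMYC

The GMYC model assumes an ultrametric tree whose deeper branching events
reflect speciation (Yule process) and whose shallower ones reflect
within-population coalescence, separated by one threshold age $T^\*$.
Every lineage crossing $T^\*$ is an entity. Between consecutive branching
events (interval $i$, waiting time $x_i$), the total event rate is

$$b_i = \lambda_1 n_i^{p_1} + \lambda_2 \sum_j \left[m_{ij}(m_{ij}-1)\right]^{p_2},$$

with $n_i$ the number of diversification lineages (frozen at the number
of crossing lineages once past the threshold) and $m_{ij}$ the lineage
count within entity $j$ (terms with $m_{ij}=1$ contribute zero — enforced
explicitly so that $p_2 = 0$ cannot resurrect them through $0^0$). The
log-likelihood is $\sum_i [\ln b_i - b_i x_i]$ over intervals that
terminate in an observed branching event; the single-rate null uses
$b_i = \lambda_0 n_i^{p_0}$ on the same intervals.

Implementation choices:

* **Candidate thresholds** are midpoints between consecutive distinct
  node ages, plus one candidate older than the root (a single entity)
  and one younger than the youngest node (every tip an entity). The
  youngest candidate makes the null model family a genuine special case
  of the scan, so the likelihood-ratio statistic is never negative.
* **Optimisation.** Rates are maximised on the log scale in
  $(10^{-8}, 10^{6})$, exponents boxed in $[0, 3]$, by Nelder-Mead
  (relative tolerance $10^{-10}$) from multiple starts: closed-form rate
  initialisation at $p = 1$ plus exponent starts at 0.5 and 2. The
  surface is low-dimensional but ridge-prone; parameters that a given
  threshold cannot identify (no coalescent events; constant lineage
  count) are held fixed. One-parameter profiles use golden-section
  search. The closed-form oracles ($\hat\lambda = E/\sum n_i x_i$ for
  pure Yule with $p=1$; $\hat\lambda = E/\sum x_i$ at $p=0$) are matched
  to $10^{-6}$ relative in the tests.
* **Model test.** LR $= 2(\ln L^\* - \ln L_0)$ against $\chi^2_3$
  (threshold, $\lambda_2$, $p_2$ added), the convention of the reference
  single-threshold implementation; `lr_df` is configurable to 2 for
  sensitivity analyses.
* **Confidence set**: entity counts at all thresholds within 2
  log-likelihood units of the maximum (`ci_window`); ties in the scan
  are broken toward the older threshold, i.e. fewer entities.
* **Degenerate waiting times.** Tied node ages (polytomies resolved to
  zero-length branches; identical sequences under UPGMA) are floored at
  $10^{-9} T_{root}$ so all intervals are positive. The threshold age is
  reported both on the tree's timescale and normalised as
  $-T^\*/T_{root}$.

**A caution on distance trees.** When no clock tree is supplied the
pipeline builds a UPGMA tree (average linkage; node age = half the merge
distance; rows pre-sorted lexicographically so hclust's index-order tie
rule becomes a deterministic smallest-id rule). UPGMA trees from finite
alignments place identical haplotypes at age exactly zero; the resulting
pile-up of near-zero coalescent intervals pushes the coalescent rate to
its upper bound and can attract the ML threshold toward the tips,
over-splitting entities. This is a known pathology of single-locus GMYC
on zero-branch trees, not specific to this implementation. On trees with
continuous node ages (simulated clock trees; Bayesian consensus trees)
the behaviour does not arise. Supply a proper time tree whenever one is
available; treat UPGMA-based GMYC entity counts as an upper bound.

## Consensus and agreement patterns

The final partition is the *meet* (common refinement) of the morphology,
BIN and GMYC partitions: two samples share an OTU exactly when every
method places them together. This is the only general rule under which
"distinct by at least one methodology" honours every split. Each OTU is
then flagged with $(M, B, G)$ — whether morphology, BIN or GMYC on its
own delimits exactly that group — and labelled:

| pattern | rule | reading |
|---|---|---|
| A | $M \wedge B \wedge G$ | all methods agree |
| B | $M \wedge \neg(B \wedge G)$ | morphologically distinct, genetically lumped by ≥1 method |
| C | $\neg M \wedge B \wedge G$ | both genetic methods split, morphology lumps |
| D | $\neg M \wedge (B \oplus G)$ | exactly one genetic method splits |
| X | $\neg M \wedge \neg B \wedge \neg G$ | no single method delimits the group |

Pattern D implies morphology does not distinguish the group: if it did,
the OTU would be A or B by the definitions above. The X label arises
only when partitions *cross* (non-nested disagreement); such OTUs are
flagged rather than silently forced into A–D. The pattern-A share is
reported as a percentage rounded half-up to the nearest integer.

## The synthetic-data generator

The generator produces datasets with the statistical structure the
analysis assumes, plus full ground truth:

1. **Species tree**: forward Yule simulation (waiting time at $j$
   lineages $\sim$ Exp($\lambda j$)); the topology is assembled by
   uniform random joins, which is the Yule labelled-history law.
   `min_divergence_time` adds a constant to every node age, emulating a
   clade with no very recent speciation; 0 gives the pure Yule process.
2. **Within-species coalescents**: each tip is replaced by a Kingman
   coalescent over its samples, scaled so the expected root height is
   `coalescent_depth_scale` × the pendant branch, rejection-resampled so
   the realised height fits under the pendant branch.
3. **Sequences**: evolved under a two-rate (transition/transversion)
   model with uniform base frequencies, transition bias `kappa`, branch
   lengths in time × `subst_rate` substitutions/site/time. The two-rate
   model matches the K2P distance the analysis uses; richer models
   (GTR+Γ, rate heterogeneity) are deliberately out of scope.
4. **Morphology**: the true partition, optionally degraded by lumping
   each sister-species cherry with probability `lump_probability`, which
   manufactures pattern-C/D scenarios deterministically per seed.

Defaults define the *clean regime* used throughout the test suite: 10
species, 5 samples each, Yule rate 1 per unit time, divergence floor 1.5
time units, depth scale 0.01, 533 sites (a typical trimmed COI barcode
length), 0.03 substitutions/site/time, kappa 4 (a typical COI transition
bias). Under these conditions expected interspecific K2P distances fall
roughly between 9% and 25% — comfortably above the 4.4% founder
threshold without approaching saturation — while intraspecific distances
stay well below 1%. Sample ids encode the truth (`sp03_ind2`) for
readability; the truth table remains the canonical source.

What passing tests on this generator do **not** show: robustness to
recent speciation (the divergence floor removes it unless set to 0),
introgression or mitochondrial capture, numt contamination, rate
variation across lineages or sites, non-uniform base composition, or
alignment error. Results on real data inherit all of those risks.

## Problem sizes and tolerances in the test suite

Stochastic checks run at fixed seeds with sizes chosen to keep the whole
suite at desk scale: 100 replicates for the GMYC species-count recovery
and type-I calibration (10 species × 5 samples; 20-sample single
population), 100 replicates for clean-regime RESL recovery, 2000
replicates for the two-species Yule split-age moment, 200 for sequence
divergence consistency, and 50 per grid point for the depth-scale
degradation trend. Monte-Carlo assertions use 3-standard-error bands;
deterministic oracles use $10^{-6}$ relative (optimiser vs closed form)
or $10^{-12}$ absolute (hand-evaluated likelihoods and distances).

## Known limitations

* Single-locus evidence only; the consensus treats the two genetic
  methods as independent although they share the COI signal.
* Local BIN clustering cannot reproduce registry-dependent BIN counts.
* GMYC on distance trees over-splits near zero-length branches (above).
* The stop-codon screen is a necessary, not sufficient, numt filter.
* Haplotype collapsing, tree inference, model selection and saturation
  tests (beyond the raw transition/transversion ratio) are out of scope.
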