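---
title: "Methods: tumor-microbiome analysis of colorectal cancer progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-microbiome analysis of colorectal cancer progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crcstage` implements an analysis of in-situ tumor bacterial communities
across colorectal cancer (CRC) progression: benign polyps (BP, the
control group) and tumors graded T1-T4 under TNM staging. The pipeline
starts from a denoised ASV count table — primer handling, denoising and
taxonomic classification are upstream concerns — and covers four layers:

1. **Preprocessing** — taxonomy-based exclusion (Mitochondria,
   Chloroplast, Archaea, Eukaryota), a prevalence filter (detection in at
   least 3 samples, inclusive), rarefaction to an even depth (default
   14,221 reads), relative-abundance conversion, and collapsing to any
   rank from phylum to genus.
2. **Community ecology** — Shannon diversity, Bray-Curtis dissimilarity,
   permutational MANOVA (overall, pairwise, multi-factor), canonical
   analysis of principal coordinates (CAP), average variation degree
   (AVD) as a stability measure, UpSet-style presence-pattern counts,
   specificity-occupancy (SPEC-OCCU) specialist calls, and rank-based
   differential abundance.
3. **Driver-taxon detection** — per-group Spearman co-occurrence
   networks, their common sub-network, a neighbour-shift (NESH-style)
   rewiring score per node, and a betweenness-change criterion; taxa
   with strongly rewired neighbourhoods *and* increased intermediation
   in the case network are flagged as drivers.
4. **Stage diagnosis** — a two-stage random-forest procedure: host-age
   regression on the controls screens age-discriminatory features, which
   are excluded before a multi-class forest screens CRC-stage
   discriminatory features; the final model diagnoses BP and the four
   stages with a 50% vote cutoff, and the report audits accuracy, false
   negatives (cancer diagnosed as control), and age/gender bias.

Because the study's sequencing data are not deposited, a synthetic
cohort generator reproduces the cohort's statistical structure with
known ground truth, enabling parameter-recovery testing.

# Statistical procedures and their numerical choices

## perMANOVA

The dissimilarity matrix is Gower-centred
(`G = -1/2 (I - 11'/n) D^2 (I - 11'/n)`) and partitioned by hat-matrix
projections of the model terms. Terms are tested *marginally*: each
term's sum of squares is the drop from the full projection to the
projection without that term, with a pseudo-F against the full-model
residual. P-values come from freely permuting sample labels,
`p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` (999 permutations by
default); for six or fewer samples an exact mode enumerates all row
permutations. For a single term the partition reduces to the classic
one-factor identity and term plus residual R² sum to one exactly; for
correlated terms, marginal R² need not sum to one (the same semantics as
marginal testing in distance-based redundancy analysis). The test suite
checks the single-term case against an independent implementation based
on the pairwise-distance sums-of-squares identity, and the permutation
p against exhaustive enumeration.

## CAP

Principal coordinates are extracted from the distance matrix (axes with
non-positive eigenvalues dropped and logged), optionally residualized on
a conditioning factor (an ordinary linear regression of the coordinates
on the condition design), and a linear discriminant analysis of the
group factor is fitted on the leading m axes. m maximizes leave-one-out
classification success, with ties resolved toward the smallest m.

## AVD

Within each group every taxon with positive within-group standard
deviation is z-scored; a sample's AVD is the mean absolute z-score over
those taxa, so lower values indicate a more homogeneous (stable)
community. The measure is invariant to per-taxon rescaling, and on
Gaussian data converges to `E|Z| = sqrt(2/pi) ≈ 0.7979`, which the test
suite verifies on a 200 x 10,000 fixture. Groups in which every taxon is
constant return AVD 0 with a `no_variation` flag. Group means are
compared by one-way ANOVA with Tukey HSD compact letters at alpha 0.05
(the letter display is computed by insert-and-absorb over groups ordered
by decreasing mean).

## SPEC-OCCU

Specificity of taxon i in group g is its group-mean relative abundance
normalized by the sum of its group means, so values lie in [0, 1] and
sum to one across groups; occupancy is within-group prevalence. Within
each group the 500 most abundant taxa are scored, and specialists
satisfy specificity >= 0.5 and occupancy >= 0.5. The group-normalized
(IndVal-style) form is used because a raw mean abundance cannot lie on
the [0, 1] axis the specialist rule requires.

## Co-occurrence networks and drivers

Networks are built per group on relative abundances: taxa below 30%
within-group prevalence are dropped, the pair space is restricted to the
200 most abundant retained taxa (standard practice for amplicon
co-occurrence analysis, and what keeps Benjamini-Hochberg correction
over the pair space meaningful), and edges require |Spearman rho| >= 0.6
with BH-adjusted p <= 0.05 (t approximation). Networks are unweighted
beyond the threshold — the threshold already encodes strength — and
betweenness is normalized shortest-path betweenness on each full group
network. The neighbour-shift score of a node with neighbour sets A
(control) and B (case) is

    score = (1 - |A ∩ B| / |A ∪ B|) + |B \ A| / |A ∪ B|,

i.e. Jaccard dissimilarity of the neighbourhood plus the case-gained
fraction: bounded in [0, 2], zero for unchanged or empty neighbourhoods,
and monotone in the number of case-gained neighbours. The scoring
function is deliberately pluggable — any replacement must preserve those
contract properties. A node is a driver when its score reaches the 90th
percentile of common-node scores *and* its betweenness increased from
control to case; community ids from greedy modularity on the case
network are attached for reporting only.

## Two-stage diagnosis model

Forests use 1000 trees, `sqrt(p)` candidate features per split, and
unlimited depth. `sqrt(p)` (the ranger default for both classification
and regression) is used rather than the older `p/3` regression rule
because a large regression mtry makes the strongest of several
correlated informative features available at almost every split, masking
its weaker siblings out of the permutation importance entirely — fatal
for a screen whose purpose is to *enumerate* the informative set.
Importance is permutation importance on out-of-bag samples (the "mean
decrease accuracy" family). For the multi-class stage screen the split
criterion uses inverse-class-frequency class weights: the cohort is
heavily imbalanced (45 controls versus 6 T4 tumors) and unweighted
splitting lets the control class dominate the importance ranking.
Class weights are used instead of case weights deliberately: weighted
bootstrap sampling keeps minority-class samples almost always in-bag, so
they are rarely out-of-bag and permutation importance for features that
mark small classes collapses to zero.

The age screen regresses host age on feature abundances over the BP
*training* controls only, traces cross-validated RMSE over nested
top-feature subsets whose sizes halve (ceiling division) from all
features down to one, repeats the 10-fold cross-validation three times
with fresh fold assignments, and selects the smallest size attaining the
curve minimum. The plain minimum is used rather than a one-standard-error
band: with 32 training controls the fold-level RMSE variance makes the
1-SE band wider than the curve's entire range, collapsing selection to
near-singleton sets. The screen reports out-of-fold Pearson r and R² at
the selected size; no "accuracy" is claimed for the regression.

Diagnosis uses class vote fractions: a class reaching the 0.5 cutoff is
called directly, otherwise the majority class is called with a
low-confidence flag; ties break in the fixed class order T1, T2, T3,
T4, BP. Cohort-wide reports diagnose training samples
from their out-of-bag votes and test samples from ordinary votes, so the
confusion matrix covers the full cohort; a pure test-set report is
always emitted alongside. The rank sweep repeats the whole
screen-fit-diagnose cycle at phylum, class, order, family, genus and ASV
rank and picks the rank maximizing overall accuracy, ties toward the
finer rank. The bias audit compares host age between correct and false
diagnoses (Wilcoxon rank-sum) and gender against correctness (Fisher's
exact test), BH-adjusted across the two tests.

## Published-table arithmetic

`published_confusions()` ships the six per-rank confusion matrices of
the published diagnosis model as data, and
`audit_published_confusions()` recomputes every block's overall accuracy
from its own entries. Five blocks reproduce their printed accuracies
exactly (phylum 62.1%, class 64.2%, order 64.2%, family 66.3%, ASV
87.4%); the genus block's diagonal sums to 60 of 95 (63.2%), which does
not match its printed 70.6%, so that block is flagged inconsistent and
its printed value is never asserted. The ASV block yields 97.8% control
sensitivity, 88.9% T1 accuracy, and zero cancer-as-control false
negatives.

# The synthetic cohort generator

`simulation_config()` defaults encode the emulated study conditions: 95
samples (BP 45, T1 9, T2 13, T3 22, T4 6 — the T2/T3 sizes are inferred
from the published confusion-table row sums rather than stated
directly), host ages uniform on 21-89 years, 70/95 male fraction,
per-sample depths from a truncated normal (mean 81,710, sd 47,466,
floored at twice the rarefaction depth), and 2,000 ASVs before
filtering. Counts are Dirichlet-multinomial draws around a log-normal
baseline (sigma 1.5) whose expected composition is modified by the
planted effects. Phyla are assigned at the class level of a nested
synthetic taxonomy with probabilities making Firmicutes, Bacteroidota
and Proteobacteria carry ~75% of the mass in expectation; 10% of ASVs
lack a genus and 40% a species assignment, exercising the
unassigned-bin path of rank collapsing.

Calibration choices, made once while building the generator:

* **Overdispersion** (Dirichlet concentration, default 1000). Fits of
  Dirichlet-multinomial models to real amplicon data absorb *all*
  biological covariation into the concentration; this generator models
  biological structure (stage effects, age trends, latent co-occurrence
  factors) explicitly, so its residual concentration is set above naive
  whole-data fits. At 1000, abundant taxa (~1% relative abundance) carry
  ~0.3 log-units of residual noise.
* **Planted stage taxa** (15, log2 effect 2.0) sit among abundant taxa;
  half change monotonically across T1-T4 (ramp 0.8-2.0 log2, alternating
  sign — progressive bloom or depletion), half spike at T1, the stage at
  which transiently recruited taxa appear.
* **Planted age taxa** (9, slope 0.03 per year on the natural-log scale)
  sit at moderate abundance (baseline ranks 40-100) with taxon-specific
  slopes (0.85-1.15 x the configured slope, alternating sign). Age
  information in linear log-abundance trends is inherently redundant —
  any strong subset predicts age almost as well as all nine — so the
  minimal-set selection of the age screen typically returns ~8 features
  of which most, but not always >= 7, are planted. This redundancy is a
  property of linear age trends, not of the screen.
* **Planted rewired taxa** (13) occupy top baseline-abundance ranks
  (co-occurrence detection at amplicon depth requires low sampling
  noise) and, in the case group only, share a latent log-normal factor
  with taxon-specific loadings spread over [0.65, 1] x strength (default
  0.8), means corrected to first order. The loading spread reflects
  taxon-specific sensitivity to a shared environmental driver; it also
  avoids the degenerate uniform-loading regime in which the detected
  case subgraph is a complete clique, where every shortest path is a
  direct edge and no node can show the betweenness increase the driver
  criterion requires. The realized factor draw is standardized within
  the case group so the planted correlation structure does not drift
  with the luck of a small-group draw. Driver recovery is exercised on a
  BP = 45 / T1 = 30 two-group cohort: with the study's T1 size of 9, no
  Spearman edge can attain BH-corrected significance over the pair
  space, so no co-occurrence method can recover rewiring at that size.

What the generator does *not* emulate: phylogenetic structure (no tree,
hence no phylogenetic diversity), compositional interactions beyond
closure, batch effects, and read-level error. Passing recovery tests
therefore shows that the estimators detect the modelled effect classes
at study scale — not that they would behave identically on real
sequencing data.

# Problem sizes used by the test suite

Unit tests run on toy fixtures (tens of samples, tens to hundreds of
taxa). The acceptance-level suite uses: 200 zero-effect replicate
cohorts (2 x 10 samples, 60 taxa) for type-I calibration; ten replicate
95-sample default cohorts for age- and stage-screen recovery; ten
BP = 45 / T1 = 30 cohorts for driver recall; five confounded cohorts
(controls aged 21-65, cases 45-89, age slope 0.08) for the
age-deconfounding contrast; and a 200 x 10,000 Gaussian fixture for the
AVD limit. `scripts/acceptance.R` repeats the same computations at
five replicates plus one full rank sweep.

# Known limitations

* Marginal perMANOVA R² values for strongly collinear terms can be
  small even when the joint model explains much variance; interpret the
  age and gender terms jointly with the group term.
* With six samples in the smallest class, stage-screen cross-validation
  folds are reduced below 10 and per-class accuracy for T4 is volatile.
* The driver criterion requires a betweenness increase; a rewired taxon
  whose detected neighbourhood is complete (every association recovered)
  shows no intermediation and is not flagged. This is a property of the
  published criterion, inherited deliberately.
* Rarefaction discards reads and samples below depth; the seed must be
  recorded for exact reproduction (every function that draws random
  numbers takes one).
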