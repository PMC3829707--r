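---
title: "Methods: quantification, cell-cycle detection, modules and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, cell-cycle detection, modules and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ccrnet` implements a complete analysis chain for bacterial cell-cycle
transcriptomics: strand-specific replicate coverage is turned into gene
expression values through consistency filtering; the global expression
distribution is characterized and genes fall into three expression
groups; cell-cycle-regulated (CCR) genes are detected by empirical-Bayes
model selection over enumerated time-course patterns; CCR genes are
organized into signed co-expression modules; and each module's species
conservation profile is scored for phylogenetic signal on a species
tree.  This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was
genuinely open.  Every stage is exercised end to end on the package's
synthetic-data generator, which plants known truth so that recovery can
be measured.

## Coverage quantification

The experimental design is five cell-cycle stages (swarmer through late
predivisional) with three biological replicates each, observed as
per-nucleotide coverage on each strand.  In GC-rich genomes, mapping is
locally unreliable: some windows show large, replicate-inconsistent
coverage excursions that correlate with GC content.  Averaging raw
coverage over a gene therefore biases its expression estimate.

The remedy implemented here works on the coefficient of variation (CV =
standard deviation / mean) of the replicates at each nucleotide:

1. **Split normalization** (`normalize_split()`).  Genes are partitioned
   at a provisional mean depth of 1000x.  Each (time point, replicate)
   sample is rescaled so its summed coverage over each partition's gene
   footprint equals the across-sample mean of those sums; intergenic
   positions follow the bulk scaling.  The handful of extremely
   expressed genes (mostly structural RNAs) hold a large and
   sample-variable share of reads, and normalizing everything by one
   total would propagate their fluctuations into the bulk.
2. **CV tracks** (`compute_cv()`), per time point and strand.  Positions
   where the replicate mean is zero get CV = 0: replicates that
   consistently observe nothing are consistent, so silent regions are
   retained and contribute zero coverage rather than being discarded.
3. **Exact segmentation** (`segment_signal()`).  The CV track is
   segmented into piecewise-constant pieces by dynamic programming that
   is exactly optimal in residual sum of squares for every segment count
   `k`, with `k` selected by BIC, `n*ln(RSS/n) + k*ln(n)`, ties broken
   toward fewer segments.  The segment cost of a time-series signal is
   not a Monge cost (the argmin of the recursion is not monotone — a
   five-point counterexample exists), so no divide-and-conquer shortcut
   is valid and the exact program is quadratic in window length.  The
   track is therefore processed in 2-kb windows with up to
   `max(2, window/250)` segments each; exactness holds per window and
   segment lists are concatenated.  Larger windows are available through
   the `window` argument at quadratic cost.
4. **Filtering and quantification** (`filter_segments()`,
   `quantify_genes()`).  Segments whose mean CV exceeds 1.0 are
   discarded; a gene's expression in a sample is the mean coverage over
   its retained nucleotides on its own strand.  Genes with no retained
   nucleotide fall back to the unfiltered mean and are flagged, and a
   per-gene retained fraction is reported.

Assumptions worth stating: mapping weights are considered already folded
into the coverage values, so the "mean over retained nucleotides" needs
no further weighting; and the CV threshold of 1.0 is a property of the
replicate design (three replicates of a biased window reach CVs well
above 1; well-behaved coverage sits far below it).

## Expression structure

Expression values pooled across samples are heavy-tailed.
`fit_power_law()` fits the continuous maximum-likelihood exponent
`alpha = 1 + n / sum(log(x/xmin))` to the tail, and chooses `xmin` to
minimize the Kolmogorov–Smirnov distance between tail data and fit when
it is not supplied.  The continuous (not discrete) estimator is used
because expression values are averaged coverages, not integers.

`classify_groups()` applies the two conventional cuts: genes whose
maximal per-time-point mean stays below 5x are the low group (candidate
background transcription), genes whose pooled mean exceeds 1000x are the
high group, and the remainder is the bulk.  Per-gene CV is the mean of
the five per-time-point replicate CVs; pooling across time points first
and computing one CV over all 15 samples would conflate cell-cycle
regulation with replicate noise, which is why the per-time-point average
is used (the alternative remains a one-line change).
`smooth_cv_vs_expression()` is a tricube local linear regression (LOESS,
degree 1, default span 0.3) of CV on log expression, evaluable anywhere
by monotone interpolation between fitted points.

## Cell-cycle-regulated gene detection

Patterns over the five ordered time points are formalized as contiguous
equal-mean blockings: one bit per boundary between consecutive stages,
giving `2^4 = 16` blockings (the no-boundary blocking is constant
expression), plus one distinguished `silent` model whose mean is pinned
at the 5th percentile of nonzero gene means — 17 models in all
(`enumerate_models()`).  Up/down direction is read from the fitted block
means afterwards rather than imposed as an order constraint: the
equal-mean grouping is what carries likelihood, and ordering constraints
would alter likelihoods without adding information.

Inference is empirical Bayes with negative-binomial likelihoods
(`estimate_priors()`, `posterior_likelihoods()`):

* For each model, `Q = 100` genes are sampled from the data; each
  sampled gene contributes its per-block means and a dispersion pooled
  over its residuals around those block means.  Pooling matters: a
  per-block moment estimate from three replicates collapses to Poisson
  about half the time, and Poisson-confident priors destroy error
  control.
* A gene's marginal likelihood under a model averages the NB likelihood
  over the model's prior samples.  Each sample's means are first
  rescaled so its expected total matches the gene's observed total (the
  library-scaling step), bounded below by twice the background level so
  the silent model keeps the near-zero regime.  Without rescaling, a
  gene's fit under a model is hostage to whether any sampled gene
  happens to sit at its expression level; `rescale = FALSE` restores the
  raw form.
* Prior samples are then re-weighted by their own genes' posterior
  probability of following the model, for three bootstrap rounds
  (after which the weights are stable).  This step is what
  makes the differential models' priors mean "genes that actually change":
  without it, three quarters of any differential model's prior support
  is flat genes, a flat gene fits the differential priors as well as the
  flat prior, and false discoveries are uncontrolled.
* Model weights are estimated by iterating `weight = mean posterior
  across genes` to an L-infinity tolerance of 1e-6 (at most 100
  iterations), and per-gene posteriors are normalized.  A gene observed
  at zero in every sample is assigned to the silent model directly; its
  likelihood ratios would otherwise reflect only which prior samples
  carry extreme dispersions.

The CCR likelihood of a gene is its summed posterior over the 15
differential models; the default call threshold is 0.5, i.e. a gene is
called when differential regulation is more likely than not.  Following
the study design, inference runs separately on the >1000x genes and the
bulk (`detect_ccr()`), mirroring the split normalization.  Expression
values are rounded to integers for the count likelihood; the split
normalization preserves their scale.

## Co-expression modules

Over the CCR genes, `signed_adjacency()` computes
`a_ij = ((1 + cor_ij)/2)^36`.  The signed map sends anti-correlation to
zero adjacency (anti-phase genes are not "connected"), and the large
soft-threshold power beta = 36 suppresses all but the strongest positive
correlations; it is kept as the default deliberately, with `beta` as an
argument.  `topological_overlap()` folds in shared-neighbor structure,
`detect_modules()` clusters the dissimilarity `1 - TOM` by average
linkage with a static cut at 0.995 of the maximal merge height (chosen
for determinism over the dynamic tree-cut heuristic; a knob, not a
constant of nature), and clusters below 5 genes are pooled as
unassigned.  Before network construction one replicate is dropped from
each of the first three time points — the replicate with the largest
median distance to its two peers (`select_network_samples()`), since the
identity of the removed replicate is otherwise unspecified.

`module_eigenvector()` standardizes each member gene's profile and takes
the first right singular vector as the module eigenvector; variance
explained is the first squared singular value over the total, and gene
contributions are projections onto the eigenvector normalized so the
absolute contributions sum to one (the normalization is this package's
convention; only relative contributions are meaningful).  The
eigenvector sign is oriented so the mean contribution is positive.
`cluster_module_eigenvectors()` collapses eigenvectors to per-time-point
means, correlates and average-links them, and reports a three-group cut,
matching the expectation that cell-cycle modules organize into a few
phase groups.

## Phylogenetic signal of modules

A module's conservation profile sums its member genes' 1/0 conservation
over the species panel (`module_species_profile()`); the profile is the
trait.  Two complementary statistics are computed:

* **Blomberg's K** (`blomberg_k()`): the ratio of observed to
  Brownian-expected variance structure on the tree, exactly the
  closed-form ratio of mean squared errors under the tree's Brownian
  covariance; K = 1 on a star tree by construction, and the permutation
  p-value shuffles tip labels and compares the variance of
  phylogenetically independent contrasts (999 permutations by default).
* **SES-MPD / SES-MNTD** (`ses_mpd_mntd()`): abundance-weighted mean
  pairwise distance and mean nearest-taxon distance over the species
  carrying the module, standardized against a null that shuffles the
  profile values across tips 9,999 times while the tree stays fixed.
  Weighting by conservation counts is the default because the profile is
  counts; presence-only mode is provided.  The weighted MPD uses
  distinct pairs only (self-pairs carry no distance information).

Modules are classified at the conventional threshold of -2 on both
z-scores (`classify_quadrant()`, boundary inclusive): quadrants 2/3 mean
tree-wide clustering (MPD low), quadrant 4 means tip-level clustering
(MNTD low but MPD unremarkable), quadrant 1 means no signal.
Persistence indices are row sums of the conservation matrix
(`persistence_index()`, bands at <50 and >150 of 236 species), orthology
comes from reciprocal best hits at >40% similarity and <20% length
difference (`bbh_orthologs()`), and representative species are drawn one
per clade after cutting a large guide tree at the depth giving the
target clade count (`select_representatives()`).

## The synthetic-data generator

The generator is first-class, tested code; its defaults encode the
emulated study conditions.

* **Design**: 5 time points x 3 replicates; 3,964-gene genome scale with
  stratum fractions 738/3136/90 (low/bulk/high); CCR fraction 1586/3964;
  peak levels power-law with exponent 1.74 (bulk truncated to 5–1000x,
  high above 1000x); planted CCR patterns drawn uniformly from the 15
  differential blockings with per-gene fold changes log-normal around a
  geometric mean of 8.2 (sdlog 0.4).
* **Counts**: gene-level negative binomial with dispersion 0.05 (the
  replicate CV of a well-expressed gene is then √0.05 ≈ 0.22, the
  plateau value), Poisson per nucleotide around the gene-replicate mean.
* **GC inconsistency**: the `affected_fraction` highest-GC windows (10%
  by default) receive, per (window, time point), a spike that inflates
  one randomly chosen replicate by the factor that makes the replicate
  CV exactly `cv_target` (default 1.5), plus a mild log-normal jitter
  (sdlog 0.25) on every replicate.  A mean-one multiplicative noise was
  rejected: it averages out across replicates, whereas the emulated
  phenomenon is a local mapping artifact that biases the window; and
  with three replicates the sample CV of any log-normal calibrated to a
  population CV of 1.5 sits near 0.8, so the planted inconsistency would
  not even register above the CV = 1 filter.  The spike construction
  makes the planted CV hit its nominal value by design.
* **Ambiguous mapping**: duplicate-gene identity pairs share position-wise
  averaged coverage, emulating reads split evenly between identical copies.
* **Conservation**: a constant-rate birth–death species tree conditioned
  on the species count (236 by default).  Gene presence evolves by
  descent with per-branch losses: a loss event on a branch removes the
  gene from the entire subtree.  Losses are branch events, not
  independent per-tip coin flips, because i.i.d. tip losses make the
  profile exchangeable across tips — a profile that by construction can
  carry no phylogenetic signal.  Broadly conserved genes originate at
  the root and are additionally subject to distance-graded ortholog
  detectability, `exp(-d/lambda)` in the patristic distance from the
  focal species (detection of deep orthologs decays with sequence
  divergence); the focal species is the tip with the smallest median
  distance to the rest, since the focal organism of such a study is
  nested among sequenced relatives rather than an orphan lineage.
  Clade-specific genes originate at small clades (2–3 tips, always at
  most 15% of the panel), independently per gene, spread across the tree
  by farthest-point sampling; being young, they are detected wherever
  present.  This plants the two signatures the pipeline is meant to
  distinguish: graded, tree-wide profiles (low MPD) versus scattered
  tip-level clumps (low MNTD, unremarkable MPD).

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: read-level artifacts (the coverage
tracks are taken as already mapped and weighted), operon structure and
correlated neighboring genes, the irreproducibility of true background
transcription (the low stratum here is only Poisson-noisy, so its CV is
not elevated the way real background is), horizontal transfer beyond the
planted clade pattern, and any systematic error shared by all three
replicates, which no replicate-consistency method can detect.

## Numerical choices and degenerate inputs

* Segmentation ties in BIC go to fewer segments; RSS is floored at
  1e-12 inside the log.
* CV at zero-mean positions is 0 by convention (see above).
* NB dispersions are floored at 1e-6 (effectively Poisson) and capped at
  5; prior-sample re-weights are floored at 1/G so no sample becomes
  unreachable.
* Fold changes floor the trough time-point mean at 0.1x so silent
  troughs give finite ratios.
* Zero-variance genes are an error in network construction (they carry
  no correlation information); constant traits make K undefined and are
  flagged rather than guessed.
* All seeded operations restore the caller's RNG state on exit, so
  seeding one stage never silently reseeds the next.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use a 50-kb genome with 60 genes for
coverage-level checks, 2,000 genes for detection recovery (25% planted
CCR at geometric-mean fold 8.2), 350 genes (10 planted modules of 30
plus 50 noise genes) for module recovery, and 236-species trees with
five broad and five clade-specific 10-gene modules for the quadrant
analysis; null calibrations use 499–9,999 randomizations depending on
the statistic.  These sizes were chosen so each check isolates one claim
at the smallest scale where its signal is unambiguous.

## Known limitations

* The static tree cut is simpler and deterministic but weaker than
  dynamic tree cutting on modules of very uneven density; `cut_height`
  is exposed for that reason.
* The empirical-Bayes detector assumes replicates are exchangeable
  within a time point and genes are independent given the model; operon
  co-regulation violates the latter and will locally correlate errors.
* Blomberg's K on count profiles treats the counts as a continuous
  trait; for very small modules the trait is coarse and K is noisy even
  when MPD/MNTD are informative.
* The BBH orthology layer consumes a precomputed similarity hit table;
  it does not run any sequence search.
* Equal-total normalization assumes that summed transcription is
  constant over the cell cycle.  At genome scale the planted patterns
  largely cancel in the totals and the assumption is benign, but on
  very small gene sets (under a hundred genes or so) the totals
  genuinely drift with the cycle, the normalization transfers that
  drift onto flat genes, and the CCR detector overcalls.  The detector
  is calibrated for genome-scale input.
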