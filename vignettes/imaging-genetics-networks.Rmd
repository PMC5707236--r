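---
title: "Genetic risk, functional brain network organization and neuroticism: methods"
author: "neurogenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk, functional brain network organization and neuroticism: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogenet)
```

## The scientific question

Neuroticism — the disposition to respond to experience with negative
emotion — is heritable and a risk marker for internalizing psychopathology.
Two candidate polymorphisms are repeatedly implicated: the serotonin
transporter promoter length polymorphism 5-HTTLPR (short *S* versus long
*L* allele, with the low-expressing *Lg* variant collapsed into *S*), and
the COMT haplotype formed by rs4680 (Val158Met) and rs165599. Rather than
testing genotype against the behavioral trait directly, the endophenotype
approach interposes a neural intermediate: the organization of the
resting-state functional brain network, summarized by graph-theoretic
measures. `neurogenet` implements that analysis chain as a reusable,
fully tested pipeline: genotype processing, ROI time-series cleanup,
weighted network construction, community detection, network measures, and
permutation inference — plus a synthetic-cohort generator so that every
stage can be validated against known ground truth without access to the
original (undeposited) scan data.

## Genotype processing

**Allele frequencies and Hardy-Weinberg equilibrium.** For genotype counts
$(n_{aa}, n_{ab}, n_{bb})$ the first-allele frequency is
$p = (2n_{aa} + n_{ab}) / 2n$. HWE is tested by comparing observed counts
with $(np^2, 2npq, nq^2)$ via a 1-df chi-square without continuity
correction. From the cohort's printed counts this reproduces p = 0.58
(5-HTTLPR), 0.67 (rs4680) and 0.90 (rs165599), and frequencies 0.50 / 0.53
/ 0.69, at two decimals:

```{r hwe}
genotype_report(as_genotype_table(data.frame(
  subject_id = sprintf("s%03d", 1:120),
  httlpr   = rep(c("L/L", "S/L", "S/S"), c(31, 57, 32)),
  rs4680   = c(rep(c("Met/Met", "Val/Met", "Val/Val"), c(34, 57, 28)), NA),
  rs165599 = c(rep(c("A/A", "A/G", "G/G"), c(56, 51, 11)), NA, NA)
)))[, c("marker", "allele_a", "freq_a_report", "hwe_p_report")]
```

**Haplotype phasing.** With two biallelic markers only double
heterozygotes are phase-ambiguous. The package estimates the four
haplotype frequencies by expectation-maximization on the multinomial
likelihood under random mating, initialized at linkage equilibrium (hence
deterministic, no seed). Per-subject posteriors of the compatible
haplotype pairs are proportional to products of haplotype frequencies; a
pair is assigned only when its posterior strictly exceeds 0.80, otherwise
the assignment is missing. A Bayesian phasing program could be substituted
here; at two markers the EM estimator makes identical assignment decisions
under the 0.80 rule, which is why it is the built-in default. On
all-double-heterozygote cohorts the likelihood is symmetric in the two
phase configurations; the estimator deliberately stays at the symmetric
fixed point (both posteriors 0.5, nothing assigned) rather than breaking
the tie arbitrarily.

**Risk groups.** S-carriers (S/S or S/L) versus L-homozygotes; COMT risk =
rs4680 Val/Val and/or rs165599 A/A, COMT non-risk = the complementary
genotype combinations. A missing genotype at a marker that could still
flip the decision yields a missing label; a subject with rs165599 = A/A is
risk regardless of a missing rs4680.

## Time-series cleanup

The pipeline starts from per-subject ROI time series (300 volumes at TR
2 s in the emulated design), taken to be already realigned, normalized and
smoothed upstream. Three cleanup stages follow, in this order:

1. **Nuisance regression**: least-squares residualization of every ROI
   series against an intercept, the six rigid-body motion parameters, the
   global, white-matter and CSF signals, and the backward-difference first
   temporal derivatives of all of these (derivative of the first volume
   defined as 0). Exactly duplicated design columns are dropped; any other
   rank deficiency is an error naming the offending columns. The original
   design regressed per grey-matter voxel before ROI extraction; operating
   per ROI series is equivalent for mean-based ROI signals up to the
   linearity of both operations, and is the only option once voxel data
   are out of scope.
2. **Band-pass filtering** to 0.008–0.08 Hz by FFT masking after linear
   detrend. Because detrending and frequency masking do not commute, the
   in-band image of the trend line is projected out afterwards, making the
   default (hard-mask) operator an exact orthogonal projection — so
   filtering is exactly idempotent, pass-band amplitudes are preserved and
   stop-band content is removed entirely. A cosine roll-off
   (`taper_hz`) is available where a softer transition is preferred. No
   filter family was mandated for this step; an order-free FFT projection
   was chosen because it is exactly reproducible and trivially
   verifiable in the frequency domain.
3. **Scrubbing**: framewise displacement is the sum of absolute backward
   differences of the six motion parameters, rotations converted to arc
   length on a 50 mm sphere. Volumes with FD above the threshold (default
   0.5 mm) are removed together with 1 preceding and 2 following volumes.
   The published procedure's exact FD threshold and augmentation are not
   publicly documented, so both are parameters with these
   literature-standard defaults. A subject is excluded when strictly more
   than one third of volumes are scrubbed. Scrubbed volumes are deleted
   before correlation, not interpolated, and scrubbing is applied after
   filtering (the ordering is configurable by calling the stages
   directly).

## Network construction

Pearson correlations between all ROI pairs over retained volumes;
correlations between ROI centres closer than 20 mm (strict inequality) are
set to zero to suppress shared non-biological signal between adjacent
spheres, as is the diagonal. Constant ROI series yield zero rows with a
warning instead of aborting the subject.

**Proportional thresholding.** At density $\tau$ the
$k = \mathrm{round}(\tau \cdot N(N-1)/2)$ strongest edges are retained
(half-away-from-zero rounding), ranked by signed correlation with
deterministic (row, column) tie-breaking; the weighted graph keeps the
correlation values, the binary graph sets them to 1. The candidate count
$M$ deliberately counts all pairs — distance-zeroed pairs simply hold
value 0 and never win — mirroring the sequencing of zeroing before
thresholding. Negative correlations are never retained at the densities
studied (1–30 %); if positive edges run out, the package keeps all
positive edges and warns rather than admitting negative weights into
measures that assume nonnegativity. The density grid 1–30 % in 1 % steps
produces nested edge sets, which the stack constructor verifies.

## Module decomposition

Modularity is Newman's weighted
$Q = \sum_c (e_{cc} - a_c^2)$. The optimizer is a seeded two-phase Louvain
(local moving with shuffled node order, then aggregation; Q never
decreases by construction), followed by a greedy single-node fine-tuning
pass: every node may move to any other module or a new singleton, the
single best positive-gain move is applied, and the loop stops at a local
optimum — so fine-tuned Q is never below the input Q and termination is
guaranteed by strict increase over a finite move space. The original
study's fine-tuning reference is not publicly specified in detail; this
greedy refinement is a surrogate with the same contract (monotone Q,
deterministic given the input partition).

**Decomposition density.** The study used a single optimal threshold for
module decomposition (1.8 % in the original data); its selection method is
likewise in unavailable supplementary material. The package's default
surrogate scores each candidate density by partition stability: Louvain
under a fixed seed set at each density, stability = mean pairwise NMI
within the density plus mean NMI against adjacent densities; the highest
score wins, ties to the lowest density, and degenerate single-module
densities are excluded. The `strategy` argument accepts a drop-in
replacement. Group decomposition then runs 50 Louvain seeds on the
group-mean graph at the selected density, fine-tunes the best, and that
single partition is reused for every subject's per-module measures —
one module assignment for the whole cohort, as in the original analysis.
On the synthetic cohorts the selected density routinely recovers the
planted six modules exactly.

## Network measures

All measures follow Brain-Connectivity-Toolbox conventions; weighted path
lengths use $1/w$.

- **Global efficiency**: mean inverse shortest-path length over ordered
  pairs; unreachable pairs contribute 0, so disconnected graphs never
  produce infinities.
- **Local efficiency**: binary — global efficiency of each node's
  neighbour subgraph; weighted — the 2010 formulation with shortest paths
  on cube-rooted lengths $(1/w)^{1/3}$ inside the neighbour subgraph and
  terms $(w_{uj} w_{uh})^{1/3} / d_{jh}$, which reduces exactly to the
  binary variant on unit weights. Nodes with fewer than two neighbours
  score 0.
- **Maximized modularity** per subject and density: best of 10 Louvain
  seeds, fine-tuned. (Fine-tuning is applied to the best seed's partition
  rather than all ten — the Q guarantee is identical and the cost is a
  tenth.)
- **Participation coefficient**:
  $P_i = 1 - \sum_m (\kappa_{im}/\kappa_i)^2$ with strength (weighted) or
  degree (binary); isolated nodes score 0. Whole-brain measures plus
  per-module means of local efficiency and participation are emitted per
  density and variant in a long-format table.

## Inference

For each measure the per-density statistic is either the group mean
difference (risk − non-risk) or the difference in OLS slopes of measure on
raw neuroticism score between the groups. The per-density curve is
summarized by its trapezoidal AUC over the density grid — one scalar per
measure independent of any single threshold choice. Significance comes
from label permutation: group labels are shuffled (group sizes preserved),
the AUC recomputed, and
$p = (\#\{|\mathrm{AUC}_{null}| \ge |\mathrm{AUC}_{obs}|\} + 1)/(n_{perm}+1)$
— two-tailed via the absolute value, never exactly zero, exact by
construction under exchangeability. The study value is 5000 permutations;
calibration experiments here use 500 to keep runtimes at desk scale, which
changes only the Monte-Carlo resolution of p, not its validity. No
multiple-testing correction is applied, matching the original analysis;
the inference table reports every test run so the count is visible.

## The synthetic cohort generator

`sim_config()` defaults encode the emulated study conditions: 111
analyzed subjects, 259 ROIs, 300 volumes at TR 2 s, six near-equal
modules, allele frequencies S = 0.50 / Met = 0.53 / A = 0.69, neuroticism
$\mathcal N(135.5, 18.9^2)$ independent of genotype (the cohort showed no
genotype–trait mean association). Time series are drawn from a
block-structured correlation matrix: `within_module_r = 0.5` inside
modules and `between_module_r = 0.1` between them — a contrast strong
enough that community detection recovers the blocks exactly, which is what
a ground-truth validation needs. Two effects are planted *at the
covariance level*, so the whole chain (correlation, thresholding,
decomposition, measures, inference) is exercised end to end rather than
any stage in isolation:

- **Participation effect**: S-carriers have the coupling between the two
  designated modules and the rest reduced by `effect_participation`
  (default 0.05 correlation units), lowering those modules' participation
  coefficients.
- **Slope effect**: COMT-risk subjects have the within-module correlation
  of the two moderated modules reduced by
  `effect_slope`·(neuroticism − mean)/SD (default 0.05 per SD), producing
  a negative neuroticism → local-efficiency slope in the risk group only.

The original report gives only p-values for its network findings, not
effect sizes, so the planted sizes are calibration parameters chosen once:
0.05 gives the permutation test power ≈ 1 at the cohort's group sizes in
the reduced-scale calibration (60 ROIs, 150 volumes), comfortably clearing
the 0.80 design target while remaining small against the 0.4 within/
between contrast. Motion traces (random walk plus occasional spikes),
a shared global signal and motion-coupled nuisance components are added so
cleanup has real work to do; coordinates sit on a six-cluster MNI-like
layout whose jitter guarantees some ROI pairs violate the 20 mm rule.
Gaussian volumes are temporally independent by default (`ar1` adds AR(1)
autocorrelation when wanted); the generator makes no attempt at
hemodynamic realism, scanner drift spectra, or gene-by-environment
structure. Passing tests on these cohorts therefore demonstrates
correctness of the pipeline's computations and calibration of its
inference, not that the original biological findings replicate.

## Numerical choices and degenerate inputs

- Ties: thresholding breaks edge ties lexicographically by (row, column);
  density selection breaks score ties toward the lowest density; Louvain
  move ties resolve to the lowest community index.
- Report rounding is half-away-from-zero at 2 decimals, as in the cohort
  tables; `round_half_up()` is exported.
- Monomorphic markers make the HWE test undefined (error); zero total
  counts are errors; phasing requires at least one subject with both COMT
  markers.
- Covariances that lose positive definiteness after effect injection are
  shrunk toward the identity with a warning.
- All Louvain runs are seeded and the seeds are recorded in the results;
  with a fixed seed every result in the package is bit-reproducible.

## Problem sizes used in the shipped experiments

The package's own validation experiments run at reduced scale, chosen once
as the smallest sizes at which every qualitative property is stable:
metric-oracle checks on 200 random graphs of 5–12 nodes; community
recovery on 6×10-node planted-partition graphs over 10 seeds; null
calibration with 1000 replicates of 111 subjects at 500 permutations;
power over 50 seeded cohorts of 111 subjects × 60 ROIs × 150 volumes; and
the end-to-end run on one cohort of 111 subjects × 120 ROIs × 300 volumes
across the full 1–30 % grid. The generator's defaults remain the full
study geometry (259 ROIs); nothing in the pipeline depends on the reduced
sizes.

## Known limitations

- Image-space preprocessing (realignment, normalization, smoothing,
  eigenvariate extraction for WM/CSF) is out of scope; inputs begin at ROI
  series.
- The optimal-density and fine-tuning procedures are documented surrogates
  for methods whose exact specifications are not public; both are
  pluggable.
- The original cohort's fMRI-dependent p-values cannot be reproduced
  without the undeposited scan data; the synthetic experiments validate
  the machinery, not the biology.
- Only the measures analyzed by the original design are implemented;
  betweenness, clustering, small-world indices and rich-club analyses are
  deliberately absent.
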