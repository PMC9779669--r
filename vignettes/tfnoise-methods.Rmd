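---
title: "Modelling gene expression noise from the TF binding process"
author: "tfnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene expression noise from the TF binding process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfnoise)
```

# Overview

Genetically identical cells in the same environment express the same gene at
different levels.  This package quantifies that cell-to-cell variability
(expression noise), engineers the promoter- and transcription-factor-level
features that predict it, and models mechanistically how the dynamics of TF
binding — independent, cooperative, or competitive — shape it.  It has four
method layers:

1. a **mean-adjusted noise statistic** (polynomial detrending of CV against
   log mean expression),
2. **promoter feature engineering** (motif scanning with mismatches,
   binding-site overlap statistics, positional counts, nucleosome-occupancy
   windows, tAI profiles) and **TF co-expression** classification,
3. a **repeated train/test regression protocol** reporting the fraction of
   variation explained and the predicted R²,
4. a **stochastic two-state (telegraph) simulator** of transcription under
   four TF-binding scenarios, with a greedy sampler of its parameter space.

Synthetic-data generators with known ground truth drive all validation.

# The mean-adjusted noise statistic

For each gene the coefficient of variation CV = sd/mean is computed across
cells (sample sd, n−1 denominator; zero-mean genes are flagged and excluded
from fitting).  Because CV falls systematically with expression level, raw
CV confounds noise with abundance.  We therefore fit least-squares
polynomials of CV on natural-log mean for a range of candidate orders and
define the **mean-adjusted noise** of a gene as the vertical distance of its
CV from the fitted curve.  Being a least-squares residual, the statistic
sums to zero over the fitting set and is empirically uncorrelated with log
mean.

**Order selection.**  Candidate orders (default 1–7) are scored by 10-fold
cross-validated mean squared error.  The default selection applies the
one-standard-error parsimony rule — the smallest order whose CV score is
within one fold-to-fold standard error of the minimum — because the plain
arg-min is known to over-select polynomial order when adjacent orders differ
by less than the CV noise; `selection = "min"` restores the arg-min.  Both
the per-order scores and their standard errors are kept in the returned
`TrendFit` for audit.  A tiny epsilon proportional to the response variance
is added to the comparison threshold so that noiseless (zero-residual)
inputs select the smallest adequate order instead of tie-breaking on
floating-point dust.  A 95% confidence band of the fitted curve is available
through `predictTrend(..., interval = TRUE)`.

The log base is natural; any other base only rescales coefficients.  The fit
is of untransformed CV on log mean; a `logCV` flag fits log(CV) instead for
users who prefer multiplicative residuals.  A distance-to-median style
statistic (`distanceToMedian`, a running median of CV along the
mean-expression order, window 10% of genes) is included for exploration but
is **not** the canonical protein-noise DM, which this package treats as an
externally supplied column.

**Noise bins.**  Genes are stratified into `nBins = 20` bins for low/high
noise contrasts.  Interior edges are equally spaced between the 2.5th and
97.5th percentiles of the noise values; the first and last bins are
open-ended so extreme genes are retained without creating near-empty
interior bins.  The percentile bounds are configurable.

# Synthetic data: what it emulates and what it does not

`simExpressionMatrix` draws negative-binomial counts with gene-specific
dispersion chosen so the true CV of gene *g* equals
*trend*(log μ<sub>g</sub>) + *excess<sub>g</sub>*; for the NB,
CV² = 1/μ + φ, so φ = targetCV² − 1/μ (a target below the Poisson floor is
an invalid specification, and an error).  True means are log-uniform over
`meanRange` (default 5–150 counts, 127 cells — the scale of a small yeast
single-cell experiment).  The default trend is genuinely order 5 by
construction: a smooth decreasing quadratic baseline plus a degree-5
Chebyshev term of amplitude 0.04 CV units, whose best order-4 approximation
error is exactly that amplitude — so order selection on matched data has a
well-defined right answer.  Excess noise defaults to 0 for 80% of genes and
Uniform(0.1, 0.4) for the rest.  The generator does **not** emulate
read-level artefacts (capture efficiency, dropouts, doublets), library-size
variation, or cell-cycle structure; passing tests therefore demonstrate
statistical correctness of the estimators, not robustness to those
artefacts.

`simPromoters` writes i.i.d.-background promoters (default GC 0.38,
budding-yeast-like; no higher-order composition) of length 1010 bp spanning
−1000..+10 around the start codon, with planted motif instances (optionally
mutated and/or reverse-complemented).  Overlapping plants are allowed —
they are what the overlap counters are tested on — and later plants
overwrite earlier ones where they conflict.  Ground truth is returned as a
`GRanges`.  Internal bookkeeping is 0-based half-open on the forward
strand; `toPaperCoord` converts offsets to the biologist convention where
+1 is the first base of ATG and −1 the base before it.

`simFeatureTable` produces standard-normal features (optionally
equicorrelated through a single factor) and the response
y = Xβ + N(0, σ²), with σ derivable from a requested population
R² = var(Xβ)/(var(Xβ)+σ²).  `simCoexpressionPanel` plants regulation
slopes between a gene and its TFs and correlation blocks among TFs.

# Promoter features

**Motif scanning.**  A motif is the explicit set of same-length ACGT
variants expanded from an IUPAC consensus or a weight matrix (every base
whose column weight exceeds a configurable fraction of the column maximum;
the default 0 admits all bases with nonzero weight).  A guard (default 10⁶
variants) turns combinatorial explosions into an informative error.  Every
window whose Hamming distance to any variant is ≤ `maxMismatch` (default 2)
is reported with the minimal distance.  Both strands are scanned — TFs bind
double-stranded DNA — and a palindromic double hit at the same interval is
collapsed to a single "+" record carrying the smaller distance.  Non-ACGT
characters mismatch every base, with a warning.

**Overlap statistics.**  Two sites overlap iff their intervals share at
least 1 bp, strand-agnostic.  Same-TF pairs are counted by default (a flag
excludes them).  Reported: pair count, pairs per site, fraction of sites in
any overlap, mean overlap length, pair counts per positional window (a pair
is attributed to the window containing its overlap midpoint), and — given a
TF role map — the activator/activator, repressor/repressor and mixed pair
fractions.  `overlapDegeneracy` contrasts the mean mismatch load of
overlapping vs non-overlapping sites.

**Positional counts** attribute each site by its start to ten 100-bp
windows upstream of the start codon plus a downstream tail; they always sum
to the number of sites.  **Occupancy windows** average a per-base occupancy
track over twelve promoter windows (100-bp windows from −1000 to −200, then
−200..−150, −150..−100, −100..−50, −50..+10).  "Per occupied site"
averaging is implemented as a configurable threshold: positions with
occupancy above it enter the average; the default 0 takes the plain mean
over covered positions, and uncovered positions are excluded with a
warning.  **tAI** is the geometric mean of codon adaptiveness weights over
the first 5, 10, 15, 20, 25, 30, 40, 50 codons and the full gene; stop
codons are excluded with a warning and prefixes longer than the gene fall
back to the full-gene value, flagged.

# TF co-expression

Pearson correlation with a two-sided test at α = 0.05 classifies a gene's
TFs: significantly positive → activator, negative → repressor, and the OLS
slope of gene on TF is the regulation strength (reported only when
significant).  Raw p-values are used deliberately — the protocol is a
per-gene screen, not a genome-wide discovery — with an optional BH
adjustment flag (off by default).  A TF is (positively) co-expressing when
it has ≥ 3 significantly positively correlated partner TFs.  Expression is
used on the linear scale; a `logScale` flag is provided since the slope
scale is not uniquely determined by the protocol.

# The regression protocol

Features are z-score standardized (constant columns dropped with a
warning); the transform is stored so test splits are scaled with training
statistics.  Per repeat (default 1000): a random 80/20 split; a linear fit
on the training part whose R² is the **fraction of variation explained**;
and the **predicted R²** = 1 − SSE/SST on the held-out part, with SST about
the test-set mean.  This definition is stated prominently because the
squared-correlation alternative differs; predicted R² can be negative.
Reports carry mean ± sd over repeats and are bit-reproducible under a
master seed from which per-repeat seeds are derived.  A random-forest
engine reports the same two statistics for users who want non-linear
trends captured.

**Selection.**  Lasso selection takes the features with nonzero
coefficients at a 10-fold-CV-chosen penalty.  The canonical penalty is the
CV-error minimiser; it reliably retains every true feature but also admits
false positives (an inherent property of the minimising penalty), so the
one-standard-error alternative (`lambdaRule = "1se"`), which is far sparser
and recovers planted orthogonal supports exactly in our tests, is exposed
alongside it.  Ridge selection fits at the CV penalty and applies
approximate t-tests using the ridge fit's effective degrees of freedom —
a pragmatic approximation, flagged as such.  `stepwiseAIC` refines a
candidate set by bidirectional search from the intercept-only model,
processing candidates alphabetically so results are deterministic; on small
candidate sets it matches exhaustive best-subset AIC.  Missing values are
handled complete-case per fitted feature set.  Two screens mirror common
practice: keep features correlated with noise at p < 0.05, or keep features
whose single-feature model explains ≥ 0.05 of the variation or predicts
with R² ≥ 0.05.

# The telegraph simulator

A promoter switches between off and on.  Off durations are
Exp(λ<sub>on</sub>) and on durations Exp(λ<sub>off</sub>), giving a
stationary active fraction λ<sub>on</sub>/(λ<sub>on</sub>+λ<sub>off</sub>)
for a single TF.  The description "intervals between successive events are
exponential with rates λ_on and λ_off" admits two readings; this convention
(rates named for the transition they cause) is the default and a
`swapConvention` flag provides the mirror image.  While the gene is active,
mRNA and protein follow the forward updates

    M[t+dt] = M[t] + (βm − αm·M[t])·dt
    P[t+dt] = P[t] + (βp·M[t] − αp·P[t])·dt

Switching events are realised at their exact exponential times, and the βm
term is weighted by the exact fraction of each dt step spent transcribing —
a hybrid of exact event placement with the printed grid updates that avoids
quantising switch times to the grid.  The grid updates themselves (rather
than an integer-copy-number event algorithm) are the integration engine of
record; the per-cell trajectory API (`simulateStateTrajectory` +
`integrateExpression`) exposes the same semantics piecewise for inspection,
and a pure-R population engine (`engine = "R"`) reproduces the C++ engine
draw for draw as a cross-check.

Scenarios (k TFs): **independent** — each TF has its own telegraph process,
the gene is active when ≥ 1 TF is bound and the rate is the sum over bound
TFs (per-TF multipliers default to 1, so their average transcription rate
equals the single-TF rate); **cooperative** — transcription is all-or-none
(the Hill coefficient is carried but does not alter the all-or-none
behaviour) and occurs only while all k TFs are bound, at the single-TF
rate; **competitive** — one shared site, one telegraph process, and at each
off→on transition one TF is chosen uniformly, transcribing at its
multiplier times βm (defaults 1.3/0.7 for k = 2; for k > 2, evenly spaced
around 1 with configurable spread, all-1 being the "no strength variation"
case).  Concentration conventions keep comparisons controlled: every
scenario uses the single-TF λ<sub>on</sub> (cooperative TFs each match the
single-TF concentration; competitive TFs sum to it), and βp, αm, αp are
shared.

Populations (default 10,000 cells) pool protein values across cells and
across all time points after a burn-in of max(5/αm, 5/αp) time units, which
removes the zero-initial-condition transient; noise is the CV of that pool
and burst frequency the fraction of retained time spent active.  The
default horizon is burn-in + 25 time units and the default step
min(0.05, 0.1/max(α)) — small enough that the always-on steady states are
reproduced to well under 1%.  `proteinCVSE` estimates the Monte-Carlo
standard error of the pooled CV by batching cells.  Cooperative binding
lowers burst frequency (active fraction f^k), hence the mean; `matchMean`
restores a reference mean by monotone bisection on λ<sub>off</sub>,
mirroring the biological argument that cooperative complexes prolong the
on-state.  `compareScenarios` packages the full matched-mean comparison.

Default rates (λ<sub>on</sub> = λ<sub>off</sub> = 1, βm = 100, βp = 50,
αm = 2, αp = 0.1) describe a gene switching on the time scale of mRNA
turnover with a protein lifetime 20× longer — the regime in which promoter
fluctuations propagate visibly to protein noise.  Under them (and across
one-at-a-time rate sweeps in the tests) the scenario ordering is:
independent binding is quieter than a single TF, while competitive and
cooperative binding are noisier at matched means.

# Sampling the parameter space

The sampler explores the six rates toward a target mean protein window
(canonical windows: 1.0–1.1, …, 1.4–1.5 ×10⁶ molecules).  Initialisation
rejection-samples log-uniform vectors within bounds (two decades around the
canonical rates, except αm, αp which are kept within biologically sensible
ranges so burn-in stays bounded) until the 1000-cell mean lies within 5× of
the target window; a closed-form stationary mean pre-screens draws so
simulations are only spent on plausible candidates.  Each iteration
perturbs one parameter multiplicatively by a step factor of 1.1 — a 10%
move, chosen to be comparable to the 10%-wide target windows so that
convergence into a window is geometrically possible; coarser steps
(e.g. a fixed fraction of a multi-decade bound span) can never land inside.
A move that brings the mean closer to the window midpoint is accepted and
the same parameter/direction is kept; a rejected move is reverted with the
direction resampled, and when the rejected mean falls outside
[low/2, 2·high] the parameter is resampled too.  Moves into a bound count
as rejections without simulation.  Chains stop on entering the window or
after 50 iterations; all evaluations within a chain share one RNG stream
(common random numbers), so the greedy descent compares like with like, and
the acceptance invariant — strictly decreasing |mean − midpoint| over
accepted steps — is exact by construction.  Terminal runs are kept only
when the burst frequency lies in (0.2, 0.8): outside it the gene is
effectively always-off or always-on and "noise" is not comparing like
regimes.  The procedure is a greedy hill-climber, not a detailed-balance
MCMC; the field's name for it is kept, with this caveat.

**Scenario comparison.**  `mcmcCompareNoise` (paired mode, the default)
runs one reference chain per replicate and evaluates the other scenarios at
the sampled terminal parameter set — competitive shares the mean by
construction, cooperative is recalibrated via `matchMean` — so each
replicate is a mathematically controlled contrast.  The independent mode
(one chain per scenario) is available, but the between-parameter-set spread
of terminal CVs is orders of magnitude wider than the scenario effect, so
it cannot resolve the ordering at desk-scale replicate counts.  Two test
statistics are reported per contrast: the two-sample Mann–Whitney rank-sum
on the pooled CV distributions, and the within-replicate Wilcoxon
signed-rank, which matches the paired design.  At a few hundred replicates
the medians order correctly and the paired test is decisively significant,
while the unpaired rank-sum needs thousands of usable replicates (the
full-scale protocol) to reach small p-values — with 200 cells per
evaluation its CV estimates also carry sampling noise that dilutes ranks.

# Problem sizes, tolerances and degenerate inputs

Test and acceptance runs use deliberately scaled problem sizes chosen as
the smallest that make each property statistically decisive: 5000 genes ×
127 cells for trend-order recovery; 1000 cells per scenario for noise
orderings (each inequality > 3 Monte-Carlo SEs); 200 replicates × 200
cells for the sampler comparison; 100 random instances for the scanner
oracle; n = 2000, 100 repeats for regression recovery (±0.05 on a planted
0.4).  Degenerate inputs are first-class: single-cell matrices, all-zero
genes, empty site lists, constant features, zero-variance TFs, never- and
always-switching promoters, unreachable calibration targets, and
all-identical noise values each have a defined, tested behaviour (error,
warning, or flagged NA — never silent nonsense).

# Known limitations

The NB count model is a stand-in for real single-cell noise structure, not
a claim about any dataset.  The ridge significance procedure is an
approximation.  The regression "fraction of variation explained" is
training-set R² (consistent with the train/test protocol); a full-data
definition would differ slightly.  The simulator's concentration-to-rate
mapping is qualitative (λ<sub>on</sub> proportional to concentration), and
the sampler's bounds and step size are package defaults where the protocol
leaves them open.  None of the numerical results in this vignette's
qualitative statements are asserted anywhere except where the test suite or
the acceptance script computes them.
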