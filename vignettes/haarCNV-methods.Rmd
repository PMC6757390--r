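---
title: "Methods: wavelet-compressed Forward-Backward Gibbs sampling for CNV segmentation"
author: "haarCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-compressed FBG for CNV segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haarCNV)
```

## The problem and the model

Copy-number variants (CNVs) shift the local mean of a read-depth signal.
haarCNV segments a per-position real-valued track `y[0..T)` — typically the
case-minus-control difference of mapped-read start counts, averaged over
non-overlapping windows of 20 positions — with a hidden Markov model:
`S` latent copy-number states, Gaussian emissions `N(mu_s, sigma2_s)`,
a row-stochastic transition matrix `A` and initial distribution `pi`.
Differencing two tracks from the same multiplexed run cancels shared
additive coverage bias (which would otherwise violate the HMM's
piecewise-constant assumption), and window averaging makes the discrete
low-coverage count noise approximately Gaussian.

Inference is fully Bayesian via Forward–Backward Gibbs sampling (FBG):
each sweep redraws the whole state path from its conditional posterior by a
forward filtering pass and backward sampling, then redraws all parameters
from conjugate posteriors (normal-inverse-gamma per state; Dirichlet rows
for `A` and `pi`).

## Dynamic wavelet compression

Running the forward pass over every position is wasteful on genome-scale
data. haarCNV instead presents the data to the sampler as *blocks*: the
segments of the Haar wavelet regression of `y` at the universal threshold

    lambda_u = sqrt(2 ln T) * sigma,

where `sigma^2` is, at each sweep, the **smallest** sampled emission
variance. Coefficients of pure Gaussian noise fall below `lambda_u` with
high probability, so blocks delimit exactly the mean shifts that are
resolvable above the current noise level; as the sampler's noise estimate
tightens, the compression refines ("zooming in" on candidate regions).
Within a block of `n` positions assigned to state `s`, the emission term is
computed exactly from the block's sufficient statistics `(n, sum, sumsq)`
and the `n - 1` self-transitions contribute `A[s,s]^(n-1)`. At
`lambda = 0` every block is a singleton and the forward variables equal the
textbook per-position recursion exactly (this is tested).

Blocks are regenerated each sweep from two static structures built once:

* **Breakpoint weights.** `b[t]` is the largest `|<psi_{j,k}, y>|` over all
  Haar wavelets with any of their three discontinuities at `t`; the
  regression at threshold `lambda` has a discontinuity before `t` iff
  `b[t] >= lambda`. The weights are computed in place and in linear time by
  the *maxlet transform* (a lifting-scheme Haar transform storing `|d_{j,k}|`
  at each wavelet's central discontinuity, with `Inf` for wavelets whose
  support crosses the end of the data) followed by the *Haar boundary
  transform* (a top-down pass taking the maxima over the edge-discontinuity
  wavelets, which sit at offsets `t ± 2^(l-1)`). The printed lifting
  recursion elsewhere shows a sum for the detail step; the difference
  `(c_{j-1,2k} - c_{j-1,2k+1})/sqrt(2^j)` is what equals the inner product,
  and the brute-force oracle test enforces that choice. `b[0] = Inf`
  (there is always a boundary before the first position); boundary
  comparisons use `>=`, which matters only on a measure-zero set for
  continuous weights.

* **Breakpoint array.** Jump pointers `p[t]` spanning maximal *stretches*
  in which every weight is strictly below `b[t]`, built in one pass with a
  deque of pending indices and capped at `m = 65536` (so jumps fit 2-byte
  integers without losing compressivity, only maximality). Threshold queries
  follow pointers, skipping whole stretches; for randomly ordered weights a
  block of `N` positions is crossed in expected `O(log N)` jumps. The deque
  holds the running right-to-left maxima, so its expected size at any cursor
  is at most the harmonic number `H_T ≈ ln T`; the expectation is largest at
  the end of the pass, and the constructor reports both the final and the
  maximum queue length (the maximum of the *realized* length over a pass
  fluctuates above `H_T`, which is why the test measures the end-of-pass
  length).

* **Integral array.** Per-position cumulative sufficient statistics,
  organised in cells of `c = 65536` positions with sums running high-to-low
  inside each cell, plus a zero sentinel at `T`. A block query adds the
  entry at `s` and the interior cell-start entries and subtracts the entry
  at `e` unless `e` is a cell start: `O(1 + (e-s)/c)` time, and every number
  touched has within-cell magnitude, so cancellation error does not grow
  with genome position. Accumulation is in double precision; the cell
  scheme is kept regardless because it bounds error growth (verified
  against long-double summation at `10^7` positions to relative error
  `< 1e-8`).

The earlier *wavelet tree* block generator is retained only as a reference
(`waveletTreeBlocks()`): its subtree-maximum pruning emits boundaries at
internal node centres even when their own coefficients are below threshold,
so it is *subcompressive*; the property suite checks that the breakpoint
array's boundaries are always a subset of the tree's.

## Compressed marginal records

Posterior summaries need per-position state-visit counts across sweeps.
These are kept as a queue of segments, each with a signed-integer count
encoding: a negative entry stores a count for the current state and
advances the state by one; a positive entry jumps the state label (runs of
zero-count states collapse to one number); a literal `0` marks segment
starts in the flattened queue. Indices must be strictly increasing and
strictly above the current state, so the encoding is canonical, and a
segment holds at most `2S + 1` entries for `S` states. Folding in one
sampled path is a single merge-walk that splits segments where run
boundaries fall inside them, so the final partition refines every recorded
sweep's block partition. (The published worked example of this encoding is
internally inconsistent by one state — its printed count vector puts the
final counts one state above what its printed state list implies; haarCNV
follows the printed encoding and state list, under which the example
decodes to states 0,1,3,4,5,6,9.)

States are *not* relabelled across sweeps: the data-anchored prior means
(below) keep states attached to distinct signal levels, and calling
operates on marginal counts, so label switching is not corrected — the
standard behaviour for this pipeline.

## Priors, initialization and numerics

"Automatic" priors are a deterministic heuristic, `autoHyperparams()`:
prior means at `S` evenly spaced quantiles of the data between the 0.5th
and 99.5th percentiles (the median for `S = 1`); `nu = 1`, `alpha = 1`;
`beta` equal to a robust noise-variance estimate
`(median |diff(y)| / (sqrt(2) * 0.6745))^2` (successive differences of a
piecewise-constant signal are pure noise almost everywhere). With
`alpha = 1` the inverse-gamma prior has no finite mean, so `beta` is
matched to the noise *scale* (prior mode `beta/2`) rather than to a prior
expectation; this keeps the prior heavy-tailed while anchored to the data's
noise level. Dirichlet concentrations are all 1. A constant signal falls
back to a variance floor of `1e-8`.

The first sweep needs a threshold before any variance has been sampled; it
is bootstrapped from the same MAD estimate. The initial model is
deterministic: means at the prior means, variances at the MAD estimate,
uniform transition rows and initial distribution. The forward pass rescales
per block after subtracting the per-block maximum log emission, and aborts
with a diagnostic if a row still underflows. A single seeded R generator
drives all draws in a fixed documented order (path, then per-state
variance/mean pairs, then transition rows, then the initial distribution),
so runs are bit-reproducible from the seed.

Defaults mirror the intended genome-scale operating point: 8 states,
200 recorded sweeps after 1800 burn-in, window 20, `c = m = 65536`,
calling threshold `|state mean| >= 1` (the smallest single-copy dosage
shift in a differential coverage signal at these units). Burn-in marginals
are discarded unless `recordBurnIn = TRUE`.

## Segment calling

`callSegments()` takes each marginal segment's modal state (ties to the
lower label), merges adjacent segments with equal modal state (posterior
fraction combined as the length-weighted mean), and flags a call when the
modal state's posterior-mean emission mean — averaged over recorded sweeps
— has absolute value at least `minAbsMean` (default 1). BED output rescales
window coordinates to bases by the window width.

## What the simulators emulate — and what they do not

`genPiecewise()` draws uniform segment boundaries, segment means from a
fixed level set and i.i.d. Gaussian noise: exactly the model the sampler
assumes. `genDifferentialCoverage()` is one step closer to real data: two
Poisson count tracks at ~4x coverage (a typical low-coverage WGS design)
sharing a smooth additive sinusoidal bias, with the case track's rate
scaled by copy number; the difference cancels the bias exactly in the
rates, and 20-position averaging brings the noise near Gaussian. Neither
simulator models GC-dependent (multiplicative) bias, mappability, read-level
artefacts or real genome coordinates, so passing tests demonstrate
correctness of the inference machinery under the stated noise model, not
robustness to every real-data pathology.

The recovery checks run at deliberately moderate sizes chosen for a laptop
R session: transform oracles at `T <= 257`, dense-FBG equivalence at
`T <= 64`, deque statistics at `T = 10^4` over 200 permutations, integral
array honesty at `T = 10^7`, and parameter recovery at `T = 2 * 10^4` with
200 recorded sweeps after 300 burn-in (the shorter burn-in suffices at this
scale because quantile-anchored priors start the chain near the posterior
mode). The recovery criterion uses the binary per-position F-measure — CNV
(true |segment mean| >= 1) versus called (modal state's posterior-mean
|mu| >= 1) — matching the calling rule.

## Known limitations

* One chromosome at a time; the CLI simply loops over chromosomes.
* The number of states is fixed (no Dirichlet-process prior on `S`);
  unused states simply keep their priors.
* Univariate emissions only.
* The wavelet-tree path is a reference implementation, not optimized.
* Label switching is possible in principle if two states' posteriors
  overlap heavily; with data-anchored prior means and marginal-count
  calling this has no practical effect on calls, but per-state traces
  should be read with that caveat.

## A worked example

```{r example, eval = FALSE}
sim <- genPiecewise(2000, 5, c(-2, 0, 2), 0.3, seed = 11)
fit <- runFBG(sim$signal, nStates = 3, iterations = 100, burnIn = 100,
              seed = 5)
fit
callSegments(fit)
```
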