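---
title: "Methods: Jensen-Shannon connectivity distance for functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Jensen-Shannon connectivity distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectodist)
```

## The model

`connectodist` measures how far a task condition moves a cohort of
functional connectomes (FCs) away from a resting-state baseline, edge by
edge. For each region pair $(i, j)$ the across-subject vectors of Pearson
correlation values in the two cohorts are discretized into probability
distributions $P$ and $Q$ over uniform bins, and compared with the
Jensen-Shannon divergence

$$\mathrm{JSD}(P \,\|\, Q) = \tfrac12 D_{KL}(P \,\|\, M) +
  \tfrac12 D_{KL}(Q \,\|\, M), \qquad M = \tfrac12 (P + Q),$$

where $D_{KL}(P\|Q) = \sum_i P(i) \log_2 P(i)/Q(i)$. With base-2
logarithms $0 \le \mathrm{JSD} \le 1$, with 0 iff $P = Q$ and 1 exactly at
disjoint support, and $\sqrt{\mathrm{JSD}}$ is a true distance metric
(symmetric, identity of indiscernibles, triangle inequality). The package
verifies all three properties against brute-force evaluation in its test
suite.

Two comparison modes exist:

* **Unpaired** (different subjects in the two cohorts): each edge's values
  are binned on $[-1, 1]$ with width 0.2 (10 bins).
* **Paired** (repeated measurements on the same subjects): the element-wise
  task$-$rest differences are binned on $[-2, 2]$ with width 0.1 (40 bins)
  and compared against a point-mass null $Q$ with probability 1 at the bin
  containing 0 — the expectation of no change between repeated
  measurements.

Downstream, the per-task JS maps are thresholded at the 95th percentile of
the pooled upper-triangular values across tasks; an edge survives iff its
value is *strictly* greater than the cutoff. For an eight-network partition
(seven cortical systems plus subcortex), centralized processing
$\mathrm{CP}_k$ is the fraction of within-network-$k$ edges surviving and
distributed processing $\mathrm{DP}_{kl}$ the fraction of surviving
$k$–$l$ edges. Both are stored as fractions and rendered as percentages.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| unpaired binning | $[-1,1]$, width 0.2 | Pearson range, 10 bins |
| paired binning | $[-2,2]$, width 0.1 | difference range, 40 bins |
| threshold percentile | 95 | pooled across tasks, strict survival |
| rest bandpass | 0.001–0.08 Hz | first-order Butterworth, zero phase |
| task bandpass | 0.001–0.25 Hz | more liberal band for task runs |
| null realizations | 100 | surrogate / permutation repetitions |
| SC/SI bins | 5 intervals of 20% | percentile bins on positive edges |

The sampling interval of the time series is always a required input; the
package never assumes a repetition time.

## Numerical choices

* **Bin-edge convention.** Bins are half-open $[lo, hi)$ with the final bin
  closed, so both range endpoints are representable. Bin breaks are
  constructed on a rounded decimal grid so that a value lying exactly on a
  decimal edge (e.g. a paired difference of exactly 0.1) is assigned to the
  bin on its right, consistently with the convention. Values within
  floating-point noise of an edge follow the represented doubles; with
  continuous data the choice is measure-zero.
* **Zero-mass bins.** $0 \cdot \log 0 = 0$; the mixture $M$ is positive
  wherever $P$ or $Q$ is, so the divergence is always finite.
* **Percentile definition.** Linear interpolation on the sorted pooled
  values (`stats::quantile` type 7). Strict survival makes the all-ties
  case well defined (nothing survives). Percentiles 0 and 100 are allowed
  and behave as limits: everything strictly above the minimum, respectively
  nothing.
* **Zero-phase filtering.** The first-order Butterworth bandpass is applied
  forward and reverse. Each pass starts from the steady state for a
  constant input at the boundary sample, which suppresses the startup
  transient; a constant (DC) series maps to exactly zero.
* **Degenerate inputs.** Zero-variance regions, constant series, empty
  cohorts, mismatched region orderings and out-of-range values raise typed
  errors naming the offender; networks with fewer than two regions yield
  `NA` CP with a warning; disconnected structural graphs yield `NA` search
  information with a warning.

## Search information

For the structural side, search information $\mathrm{SI}(i \to j)$ is the
number of bits a random walker needs to follow the shortest path from $i$
to $j$: minus $\log_2$ of the product over consecutive path steps
$(u \to v)$ of $w_{uv} / s_u$, with $s_u$ the weighted strength of $u$.
Defaults, both configurable and both documented as genuinely open choices:
shortest paths are computed on edge lengths $1/w$ (`"minusLog"` transform
available), and the walker has no memory of the incoming step (the
memory-aware variant subtracts the incoming edge's weight from the strength
at intermediate nodes). The group-level SI map is symmetrized as the mean
of the two directions before percentile binning. The implementation is
checked exhaustively against a path-enumeration oracle on all connected
weighted graphs with up to six nodes.

## Null models

The AAFT surrogate scheme (rank-remap to a Gaussian realization,
independent phase randomization per region, rank-remap of the original
amplitudes onto the result) preserves each series' amplitude distribution
exactly and its power spectrum approximately, while destroying
inter-regional correlation — the quantity under test. Surrogate JS maps are
compared against the original data's pooled cutoff by default
(re-thresholding per realization is available by flag). The label
permutation test reassigns whole FC matrices to the two groups, preserving
each matrix's correlation structure.

A structural property of the count statistic is worth stating plainly:
because the cutoff is the 95th percentile of the observed maps themselves,
the observed suprathreshold count is ~5% of edges *by construction*. The
nulls therefore separate only when the threshold is driven by genuinely
distant edges — when a nontrivial fraction of edges (more than 5%) carries
real signal, as in task-versus-rest contrasts — and not when only a handful
of edges shift. The package's validation fixtures for the null models plant
graded shifts on 7% of edges for exactly this reason; sparse-effect
fixtures are used where the question is edge recovery, not count
calibration.

## The synthetic-data generator

`generate_cohorts()` draws each subject's region $\times$ T series from a
zero-mean multivariate normal whose target correlation matrix is
block-structured over the partition (defaults: within-network $r = 0.2$,
between-network $r = 0.05$, T $= 1200$ frames at 0.72 s — the length of a
typical resting-state run). Planted edges shift the task target by
`delta_r`. Every subject receives an independent random deflection of the
target (sd 0.05 by default), emulating the stable individual differences of
real cohorts; without it, long runs collapse each edge's across-subject
distribution into a single bin and the JS noise floor degenerates to zero.
In paired mode the deflection is shared between a subject's rest and task
draws, so it cancels in the paired differences. Planted targets are
repaired to the nearest valid correlation matrix by eigenvalue clipping
(floor $10^{-8}$) and renormalization. `generate_sc()` produces a coupled
synthetic structural matrix on the log10-like $[0, 5]$ scale with higher
within-network weights, and can map planted `|delta_r|` onto a weight range
so that structural weight covaries with the planted functional shifts — the
construction used to validate the structure–function contrast (centralized
processing rising across structural-weight bins while distributed
processing stays at the noise floor).

What the generator does *not* emulate: hemodynamics, autocorrelated BOLD
noise, motion, physiological artifacts, or spatially realistic parcel
geometry. Passing tests demonstrate the statistical machinery is correct
and well calibrated under the stated model, not that any neuroscientific
conclusion transfers to real data.

## A note on the paired variant

The paired distance compares the difference distribution against a point
mass at the zero bin $[0, 0.1)$. Since symmetric sampling noise places
roughly half of the differences below zero — outside that bin — the paired
map has a substantial noise floor on unchanged edges even at long T
(empirically $\approx 0.57$ under the generator's defaults). What the
pairing buys is *invariance to subject-level heterogeneity*: the shared
deflection cancels exactly in the differences, so the paired map does not
change as subject effects grow, whereas the unpaired map's noise level
does. Genuinely shifted edges still stand far above the paired floor. The
test suite asserts exactly these properties.

## Problem sizes used in validation

The acceptance-level checks run at 100 regions with 20–50 subjects per
cohort and 100–1200 frames, 100 surrogate realizations and 50–100
permutations, 10 replicates for recovery experiments; divergence oracles
use 1,000 random pairs/triples, and the search-information oracle
enumerates all paths on graphs of up to six nodes. These sizes give stable
statistics for every property tested while keeping a full validation run in
a few minutes on one CPU.

## Known limitations

* The JS distance is a group-level (cohort) measure; it does not produce
  per-subject distance maps.
* With 50-subject cohorts and 10 bins, the divergence estimate between
  identical generating distributions is positive (histogram sampling
  noise); the thresholding step is rank-based and unaffected, but raw JS
  values should not be read as bias-corrected divergence estimates.
* The surrogate and permutation nulls calibrate the *count* of
  suprathreshold edges, not per-edge significance.
* The paired null bin is asymmetric around zero by construction (it is the
  bin containing 0 under the half-open convention); alternatives such as a
  zero-centred bin would change the noise floor but not the ordering of
  edges.
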