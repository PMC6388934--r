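---
title: "Methods: estimating lineage variability maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating lineage variability maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagemap)
```

This vignette documents the statistical model behind `lineagemap`, the
assumptions it rests on, the numerical choices made where the design was
genuinely open, and what the simulation-based tests do and do not
establish about real data.

## Data model and assumptions

The unit of observation is a *pedigree*: a complete binary tree of depth
`G` rooted at a founder cell, with one scalar trait per cell. Replicate
pedigrees are assumed independent and identically distributed — all
founders drawn from one population under one condition. Positions are
labeled by binary paths (`1`, `10`, `11`, `100`, ...), ordered
generation-major and numerically within a generation; this fixed ordering
is the contract for every matrix in the package. Missing cells (death or
tracking loss) are treated as missing completely at random over the
complete layout; the package does not model death-dependent missingness,
and incomplete topologies are represented as missingness, not as distinct
tree shapes.

The central assumption is that the tree is *unordered*: the labels of two
sisters are arbitrary. Consequently every quantity estimated must be
invariant under swapping daughter subtrees at any internal node. That is a
statement about identifiability, not biology — asymmetric divisions are
detectable, but only through the extra variance they inject into
particular subtree levels, never through which daughter carries it.

Invariance forces the mean to be constant within generations (the `q_g` of
`pool_mean()`) and the covariance to be constant on 3-index orbits
`(g, g′, a)`: generation of the earlier cell, of the later cell, and of
their most recent common ancestor (`orbit_index()`). Pooling entries over
orbits (`pool_covariance()`) equals the group average over all allowed
permutations; the package tests this against the brute-force group
enumeration (`tree_permutations()`, feasible only to `G = 4` since the
group has order `2^(2^(G-1)-1)`).

## Spectral decomposition

`spectral_basis(G)` constructs the orthonormal basis of *natural
variables*: for a source at subtree level `ℓ ≥ 1` and transverse index
`τ`, the column for observation generation `g` carries `+1/√(2^(g−ℓ))` on
the generation-`g` descendants of the subtree root's daughter ending in 0,
the negative of that on the other daughter's descendants, and 0 elsewhere;
the `ℓ = 0` columns are uniform generation averages, carrying variation
*between* pedigrees. Conjugating any orbit-structured covariance by this
basis yields an exactly block-diagonal spectral covariance, one block
`ξ⁽ℓ⁾` of dimension `G − ℓ` per level, with the `d_ℓ = 2^(ℓ−1)` transverse
copies identical; `as_spectral()` verifies both facts numerically
(relative tolerance `1e-8`, configurable) and pools the copies.

Two conventions are free and fixed here once: the sign convention (`+` on
the daughter ending in 0 — any choice yields the same pooled blocks, which
are invariant under column negation) and the column order (lexicographic
in `(ℓ, τ, g)`). The classical 4-variable Fourier and Haar decompositions
are included (`circulant_spectrum()`, `nested_pair_spectrum()`) purely as
references that pin the construction to known closed forms.

## Estimation

With complete data the fit is one pass: biased (`1/n`) sample moments;
generation pooling of the mean; orbit pooling of the covariance; spectral
transform; within each block, a Markov fit of order `M` (each variable
regressed on its `min(M, j−1)` predecessors, innovation variance = Schur
complement, block reassembled from the modified Cholesky factors
`L Φ Lᵀ`); inverse transform. The fitted block precision is banded with
bandwidth `M`, the block diagonal is preserved exactly (so the variance
components equal what a single-generation nested ANOVA would give), and
with `M ≥ G − ℓ − 1` the block fit is saturated.

One deliberate refinement: the covariance is pooled about the *structured*
mean — `P(S + rrᵀ)` with `r = ȳ − μ̂_G` — rather than about the raw sample
mean. The two differ by an `O(1/n)` term, but only the former is the exact
Gaussian MLE under the symmetry constraint, and exactness of the M-step is
what guarantees the EM loop below never decreases the observed-data
log-likelihood. The package treats the MLE form as definitive.

The key sample-size result is that `n ≥ M + 2` replicates give a positive
definite estimate regardless of `G`: the binding constraint is the `ℓ = 0`
block, whose sample version has rank `n − 1`, so Markov-1 innovations are
strictly positive exactly when `n − 1 ≥ 2`. The tests exercise both sides
of this bound (all fits PD at `n = 3` over hundreds of repetitions up to
`G = 8`; degenerate fits at `n = 2`). Rank-deficient predictor blocks —
legitimate in degenerate data, e.g. no within-pedigree variation — are
fitted with the minimum-norm least-squares solution, which is exact for
positive semidefinite input; genuinely inconsistent normal equations
remain an error naming the offending block.

### Missing data

`fit_lineage()` switches to EM when any cell is missing (every position
must be observed in at least one pedigree). The E-step imputes each
pedigree's missing coordinates by Gaussian conditioning and accumulates
the conditional-covariance correction to the second moments; the M-step is
the complete-data machinery on the expected moments. Initialization is
deterministic: generation means of the observed entries, pooled covariance
of mean-imputed data plus a `1e-6 × mean-variance` ridge (scale-aware and
inside the feasible set). Convergence is declared at a relative
log-likelihood change below `em_tol = 1e-8`, capped at
`em_max_iter = 500` (values not prescribed by the underlying theory;
chosen as conventional defaults, with a warning flag on non-convergence).
A `1e-8 · trace` ridge guards singular observed-block solves, logged when
used.

## Maps and fate profiles

Correlation and partial-correlation maps are direct transforms of `Σ̂` and
`K = Σ̂⁻¹`. Dynamic maps re-express each spectral block as a structural
equation model via the modified Cholesky decomposition: transmission
coefficients `β` (never clipped — `|β| > 1` is reported as amplification)
and innovation variances `Φ`. Edge pruning in `export_graph()` is a
display option only and never feeds back into computation.

Fate is defined operationally as the trait at the deepest fitted
generation `G`, avoiding any clustering or thresholding of phenotypes.
Fate restriction `η²(ℓ|G)` normalizes the components `ξ_GG(ℓ) d_ℓ`; the
total satisfies the reconstruction identity
`σ_GG = Σ_ℓ ξ_GG(ℓ) d_ℓ / N_src` with `N_src = Σ_ℓ d_ℓ = 2^(G−1)`, which
`variance_components()` verifies on every call (this count of sources is
also what makes the identity hold — the oracle tests pin it). Negative
estimated components, possible under sampling noise in saturated fits, are
floored at zero with a warning before normalizing. Fate expression
`R²(g|G)` uses the orbit entry between a generation-`G` cell and its
direct ancestor, `(g, G, g)`; the cumulative version regresses on the
whole ancestor chain using pooled orbit entries (the only well-defined
choice after symmetrization). For a covariance whose ancestor chain is
Markov — such as the analytic branching model — `R²_cml = R²` exactly. For
a Markov-1 *fit* of noisy data the identity is only approximate: the band
constrains the spectral blocks, and marginalizing to the ancestor chain
does not preserve Markovness. Deviations are small (order `1e-3` in the
benchmark simulations) but the package does not pretend they are zero.

## The simulator: what it emulates, and what it does not

`simulate_branching()` implements the benchmark used throughout the tests:
a stationary process with founder `~ N(0,1)` and each daughter
`h·mother + √(1−h²)·noise`, so any two positions correlate as `h^D` with
`D` the lineage distance. Defaults follow the benchmark design: `h = 0.8`,
and the standard stress configuration is 20 pedigrees with a 20% missing
fraction. Missingness is MCAR; each pedigree consumes its own seeded
substream so enlarging `n` never reshuffles earlier pedigrees.
`simulate_lineage()` generalizes to any orbit-structured positive-definite
covariance for parameter-recovery experiments, and `scramble_ordering()`
applies random daughter swaps — orbit-pooled estimates are exactly
invariant to it, which the tests check.

What passing these tests shows: the estimator recovers a known
tree-Gaussian at the stated sample sizes, the sparsity bound is tight, the
spectral algebra is exact, and the partial-correlation map recovers the
conditional-independence structure of a true branching process. What they
do not show: behavior under non-Gaussian traits, informative (death-
dependent) missingness, non-stationary true dynamics, or model
misspecification in real lineages — real T-cell and worm pedigrees are
precisely the cases where sister correlations depart from the branching
`h²` pattern.

Problem sizes in the test suite (depths 2–8, 20–200 repetitions,
`n = 2000` for the high-precision recovery runs) were chosen so the whole
suite documents each claim at Monte-Carlo tolerances calibrated from
100-replicate studies; tolerances are three standard deviations of the
relevant estimator and are frozen in the tests.

## Ingesting published data

`ingest_lineage_xlsx()` reads the supplementary workbook of the published
T-cell (n = 19, lifetime-averaged cell area, analyzed at `G = 5`), worm
(n = 10, lifetime-averaged PHA-4 reporter intensity) and branching
(n = 20) datasets. The workbook's internal layout is not standardized, so
the ingester auto-detects, per sheet, either a long layout (columns for
pedigree id, binary position label, trait value) or a wide layout
(position labels as column headers), reports what it detected, and
validates the replicate count against the published sizes. A sheet that
matches neither layout is an explicit, descriptive error. The workbook is
not redistributable with the package; the real-data acceptance check runs
only when it is supplied at `inst/extdata/S1_Data.xlsx`.

## Known limitations

Single scalar trait; complete binary topologies only (multifurcation
unsupported; unequal depths only via missingness); Gaussian likelihood is
invoked solely for EM and log-likelihood reporting — with complete data
the estimator is moment-based and distribution-free; no shrinkage
alternatives to the Markov band; the `ℓ = 0` level confounds founder
heterogeneity with any pedigree-level batch effects, which replicate
design must address upstream.
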