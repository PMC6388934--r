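# lineagemap

Statistical lineage maps for variable, unordered cell pedigrees.

Time-lapse tracking and barcoding experiments produce *pedigrees*: binary
family trees of cells, each descending from a single founder, with a
phenotype measured at every cell. In organisms with an invariant lineage
(the *C. elegans* embryo) a single pedigree is a lineage map. In most other
systems — T lymphocytes, stem cells, vertebrate embryos — pedigrees are
highly variable and the labels distinguishing two sister cells are
arbitrary, so simply averaging pedigrees washes out exactly the bifurcation
patterns one is looking for. `lineagemap` builds **lineage variability
maps**: estimates of the full pattern of second-order variation (the
variance of, and covariance between, every lineal position), from which it
derives correlation graphs, directed per-subtree dynamics, and fate
profiles.

## The model

Positions of a complete `G`-generation tree are labeled by binary paths
from the founder `1` (daughters `10`, `11`, granddaughters `100` … `111`,
`p = 2^G − 1` positions). For an unordered tree, swapping the two daughter
subtrees below any internal node changes nothing, so the `p × p` covariance
`Σ` must be invariant under that permutation group: entries are constant on
*3-index orbits* `(g, g′, a)` — the generations of the two cells and of
their most recent common ancestor. Two constraints make estimation possible
from a handful of pedigrees:

* **Symmetry.** Pooling every sample-covariance entry over its orbit (the
  Reynolds group average, computed in `O(p²)`) gives a structured estimate
  with `G(G+1)(G+2)/6` free parameters instead of `p(p+1)/2`.
* **Sparsity.** An orthonormal change of basis `T` — the generalization of
  the Haar wavelet transform to all nodes of a tree, whose columns are unit
  *bifurcated-subtree* indicators labeled `(ℓ, τ, g)` — block-diagonalizes
  any orbit-structured `Σ`: `Σ_Ω = TᵀΣT` is a direct sum of one
  `(G − ℓ) × (G − ℓ)` block per subtree level `ℓ`, repeated `d_ℓ` times
  over `τ`. Within each block the natural variables form a time series over
  generations; bounding its Markov order at `M` (banded precision, fitted
  by sequential regressions / modified Cholesky) reduces the number of
  pedigrees needed for a positive-definite estimate to `n ≥ M + 2`,
  independent of depth. With `M = 1`, three pedigrees suffice for any `G`.

Missing cells (death, tracking loss) are handled by an EM loop: Gaussian
conditional imputation in the E-step, the pooled + banded fit as the exact
constrained MLE in the M-step.

From the fitted `Σ̂` and its spectral blocks `ξ̂⁽ℓ⁾` the package computes:

* **Lineage correlation maps** — undirected graphs of Pearson correlations
  `ρ_jj′ = σ_jj′/√(σ_jj σ_j′j′)` or partial correlations
  `ϱ_jj′ = −κ_jj′/√(κ_jj κ_j′j′)` (with `K = Σ̂⁻¹`) between all positions.
* **Dynamic lineage maps** — directed graphs per subtree level: regression
  (transmission) weights `β` and innovation variances `Φ` from the modified
  Cholesky factors of each block; `|β| > 1` flags amplification.
* **Fate profiles** — fate restriction
  `η²(ℓ|G) = ξ_GG(ℓ) d_ℓ / Σ_ℓ′ ξ_GG(ℓ′) d_ℓ′` (share of last-generation
  variance attributable to each subtree level, `ℓ = 0` being variation
  between pedigrees) and fate expression `R²(g|G) = ρ²_gG` (squared
  correlation of a last-generation cell with its direct ancestor at
  generation `g`), with cumulative versions of both.

## Worked example

Simulate the benchmark stationary branching process (mother–daughter
correlation `h = 0.8`, correlation `h^D` at lineage distance `D`), with the
realistic nuisance of 20% missing cells, and fit the model:

```r
library(lineagemap)

tbl <- simulate_branching(n = 20, G = 5, h = 0.8,
                          missing_fraction = 0.2, seed = 1)
fit <- fit_lineage(tbl, M = 1)
fit
#> <lineage_fit> G = 5 (p = 31), n = 20 pedigrees, Markov order M = 1
#>   per-generation means: 0.0656, 0.12, 0.134, 0.0827, 0.00469
#>   iterations: 51; log-likelihood: -462.9731; converged: TRUE
```

Twenty pedigrees determine all 31 variances and 465 covariances because the
constrained model has only 25 free covariance parameters (`glance(fit)`),
and the estimate is positive definite (`min_eigenvalue` 0.03 > 0). The fate
profile then reads off where the variance of the generation-5 phenotype
("cell fate") originates:

```r
fate_profile(fit)
#> <fate_profile> G = 5
#>   fate restriction eta^2(ell | G): 0.307 0.080 0.171 0.245 0.197
#>   fate expression  R^2(g | G):   0.157 0.262 0.389 0.636
```

For this featureless stationary process every subtree level contributes
comparably (the analytic profile is 0.303, 0.135, 0.176, 0.205, 0.180) and
predictability decays smoothly toward the closest ancestor
(`R²(4|5) = 0.636 ≈ h² = 0.64`). A founder-restricted lineage would instead
concentrate `η²` at `ℓ = 0`; an invariant lineage would put it at `ℓ ≥ 1`
with `η²(0) ≈ 0`. `correlation_map(fit)`, `partial_correlation_map(fit)`
and `dynamic_map(fit)` return the graph representations (tibbles with
`autoplot()` methods, exportable to GraphML/DOT/CSV via `export_graph()`).

A command-line interface wraps the same functions:

```sh
exec/lineagemap simulate --h 0.8 --G 6 --n 20 --missing 0.2 --seed 1 --out ped.csv
exec/lineagemap fit --input ped.csv --M 1 --out fit/
exec/lineagemap fate --input ped.csv --out fate/
exec/lineagemap complexity --G 4
```

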