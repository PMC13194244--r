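---
title: "Haar-like wavelets on phylogenies: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haar-like wavelets on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treehaar)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and what the synthetic calibration does and does not establish.

## Planted trees and the ultrametric covariance

All computation hangs on a *planted* binary tree: a rooted binary tree
whose root `∘` has a single child, reached through the planted edge. The
covariance between two leaves is the total edge length from their least
common ancestor up to `∘`, planted edge included. This is the Brownian
model of neutral trait evolution: shared path length to the root is shared
evolutionary history, so the matrix is ultrametric and positive
semidefinite by construction.

Two depth conventions coexist and differ by exactly one per leaf. The
*planted* convention (count the planted edge) is the one under which the
sparsification bound `1 − ξ ≤ 2(EPL + 1)/n² − 3/n` holds — on the
balanced four-leaf toy tree the planted bound is 0.875 against a
structural nonzero fraction of 10/12, whereas the unplanted bound (0.375)
would be violated. The *unplanted* convention (`L₁ = 0`) is the natural
base case for the moment recursions. Package default: unplanted for
depths and moments; the bound and the covariance use the planted edge
internally, so no user-visible switch exists to get it wrong.

Multifurcations are resolved into a left-to-right cascade of zero-length
edges. Zero-length edges contribute nothing to any covariance entry, so
the resolved tree has bit-identical covariance; the wavelets, however,
are those of the *resolved* binary tree, which is a genuine (documented)
choice rather than an approximation of a polytomy wavelet theory.

## The Haar-like basis and the sparse transform

One wavelet per interior node: the constant `1/√n` at `∘`, and for every
split `v` a vector positive on the left block and negative on the right,
with coefficients chosen so the vector is zero-sum and unit-norm. Because
leaves are numbered left to right, every support is a contiguous
leaf-rank interval, and the basis is stored as intervals plus two
coefficients per node — `O(n)` memory, never a dense matrix.

The transform `ΦᵀCΦ` is computed from a single postorder pass over the
subtree second moments `S(w) = Σ ℓ(e)|L(e)|²` (edges in the subtree of
`w`, including `w`'s parent edge):

* `λ_v = c₋² S(v₋) + c₊² S(v₊)`, and `λ_∘ = S(top)/n` over all edges;
* for an ancestor wavelet `u`, the entry is `φ_u`'s constant value on the
  block containing `L(v)` times `c₋ S(v₋) − c₊ S(v₊)`;
* every other pair has disjoint supports and is structurally zero.

This closed form is *not* re-derived symbolically in the package; it is
validated against the dense oracle `ΦᵀCΦ` (materialized basis times
materialized covariance) on hundreds of seeded random trees from both
ensembles with unit and exponential edge lengths, to `1e-10` absolute
agreement, plus exact trace conservation. Changing only the planted-edge
length moves only `λ_∘` (by `ℓ₀ n`), since all other wavelets are
orthogonal to constants.

Sparsity is reported two ways, because "vanishing" is ambiguous on
balanced trees: *structural* counts support-disjoint pairs only, which is
edge-length-independent; *numerical* additionally counts stored entries
below a tolerance (default `1e-12`), which on symmetric trees catches the
balanced cancellations (the toy tree's ten structural pairs all cancel).
Both are exposed; the guaranteed bound speaks about the structural count.

## Random tree ensembles

The critical beta-splitting law `q(n, i) = n/(2 h_{n−1} i(n−i))` is
sampled exactly through the mixture identity
`n/(i(n−i)) = 1/i + 1/(n−i)`: draw `J` with probability proportional to
`1/j` by inverse CDF on the cumulative harmonic numbers, then return `J`
or `n − J` on a fair coin — `O(log n)` per split and no approximate
continuous inversion. The "uniform" ensemble is uniform over *ordered*
binary shapes (Catalan split law), evaluated in log-space to avoid
overflow; the leaf-labelled uniform model is out of scope. Default edge
lengths are 1 — structural sparsity patterns are length-independent — and
the default planted length is 0.

The exhaustive small-`n` oracle enumerates all `Cat(n−1)` ordered shapes
with exact rational probabilities and per-shape `Σ depth` and
`Σ depth²`, from which all first and second moments of the external path
length follow by exchangeability. It refuses `n > 10`.

## Moment recursions and asymptotics

`E(L_n)` obeys the classical recursion
`E(L_n) = 1 + (1/h_{n−1}) Σ E(L_i)/(n−i)`. The matching second-moment
recursion `E(L_n²) = 1 + (1/h_{n−1}) Σ (2E(L_i) + E(L_i²))/(n−i)` is
derived from the same conditional split argument; since it is a derived
rather than quoted formula, the test suite gates it on exact rational
equality with the exhaustive oracle for every `n ≤ 8` before anything
else relies on it. The pair-product moment `E(Z_n)` uses the recursion
with ancestor weights `(i−1)/(n−i)` and the convolution
`Σ E(L_i)E(L_{n−i})`; `E(EPL²) = n E(L_n²) + n(n−1) E(Z_n)`.

**Arithmetic choice.** The recursions run in double precision (they are
sums of positive terms and numerically benign); an exact rational mirror
of the same recursions exists for the oracle comparisons. The rational
helper stores integer-valued doubles with gcd reduction and refuses past
`2^53` — harmonic-number denominators grow roughly like `e^n`, which
bounds exact work to small `n` by design; that is exactly the regime the
exhaustive oracle covers, so nothing is lost. The default table size used
in the package's own validation work is `n ≤ 2^13 = 8192`, where the
`O(N²)` recursions take about two seconds.

The asymptotic expansions for `E(EPL)`, `E(EPL²)` and `Var(EPL)` are
polynomials in `log n` with coefficients built from `ζ₂, ζ₃, ζ₄, γ` (the
package hard-codes 20-digit values; `b₀ ≈ 0.78234`). The expansion terms
are exposed coefficient-by-coefficient so the key structural fact — the
squared mean cancels the `n² log⁴ n` and `n² log³ n` terms of the second
moment, leaving the `n² log² n` variance — is checked numerically on the
stored coefficients rather than asserted. The relative error of the mean
expansion decreases monotonically over `n = 2⁶..2¹³` (about `1.3e-5` at
the top end), and `E(EPL)/n² → 0` along the same grid, which is the
hypothesis driving asymptotic sparsification.

## The distance and its permutation test

`d_h` uses only the diagonal `λ_v`, by definition — even on trees whose
transform has nonzero off-diagonals. This is definitional, not an
approximation toggle: on trees with an exactly diagonal transform,
`d_h² = fᵀCf` for `f = a/|a| − b/|b|`, which the tests verify. Haar
coordinates are computed by one cumulative-sum pass (`O(n)` total),
component ranking breaks ties by postorder node id, and OTUs absent from
the tree are rejected unless `drop_unknown = TRUE` asks for
drop-and-renormalize (logged via a message).

The null hypothesis is compositional identity of the two environments,
under which all pooled reads are exchangeable; resampled pairs draw `|a|`
reads without replacement from the pooled counts — a multivariate
hypergeometric draw, implemented as sequential conditional univariate
draws through `stats::rhyper`, vectorized across resamples. The contract
is distributional, verified by goodness of fit, not by algorithm
identity. One pooled draw services every component, so testing all splits
costs the same stream of resamples as testing one, and resampling is
streamed in batches so memory never scales with `N`.

Two p-value conventions: the default `add_one`, `(1 + #{≥})/(N + 1)`,
can never report zero and is immune to the all-tied degenerate case
(pooled mass on one leaf makes every resample statistic zero; a strict
`>` comparison would then report `p = 0` for a zero observation). The
`strict` mode, `#{>}/N` floored at `1/N` with a flag, reproduces the
"discovery probability" reporting convention for components the
resampler never reaches: with a Bonferroni factor `m` the reported bound
is `m/N` — at the DKW-sized `N(ε = 10⁻⁴, δ = 0.01) = 264,915,869` and
`m = 12` that floor is `4.53e-8`. Corrections: Bonferroni `min(1, mp)`
with explicit `m` (so `m = 1` is the identity), and Benjamini–Hochberg
via `stats::p.adjust`. Neither correction is privileged; screening many
components suits BH, reporting a fixed short list suits Bonferroni.

## The synthetic generator, calibration, and what they show

The generator models each environment as a multinomial draw from a leaf
composition — reads as i.i.d. draws from a layer distribution. The
pooled-hypergeometric draw is the *test's* resampling device, not the
data model, so calibration is a genuine end-to-end check rather than a
tautology. Defaults were chosen once as realistic study conditions: a
50-leaf critical beta-splitting reference tree, symmetric Dirichlet(1)
composition, sample depths `|a| = |b| = 10⁴`, `N = 2000` resamples, 500
null replicates. The alternative shifts mass `ε` from the right to the
left block of one split, renormalized, so exactly that coordinate (and
its ancestors' coordinates, partially) moves in expectation while splits
disjoint from it stay centred — which the tests verify directly on the
coordinate means.

Under the null the add-one p-value at level `α = 0.05` rejects with
probability `⌈α(N+1)⌉/(N+1) ≈ 0.04998` (discreteness, no ties). The
calibration check asserts every per-component rejection rate inside the
exact binomial band with *simultaneous* 99% coverage across the 49
components (per-component level `1 − 0.01/49`): with 49 marginal 99%
bands asserted jointly, a perfectly calibrated test would fail the
assertion about 39% of the time, so the simultaneous band is the sound
construction, fixed before any simulation was run. An aggregate check
(mean rate within 0.03 of nominal) and super-uniformity
(`P(p ≤ u) ≤ u + 3 se` at `u = 0.01, 0.05, 0.1`) run on the same
simulation. The power study uses 200 replicates per effect size over
`ε ∈ {0, 0.05, 0.1, 0.2}` with `N = 500` resamples — a screening depth
chosen once for the power grid, where p-value resolution below `1/500`
is irrelevant; the null calibration keeps `N = 2000`.

What passing these checks shows: the resampling null, the streaming
statistics and the p-value conventions are correct under multinomial
sampling from a fixed composition on a balanced reference tree. What it
does not show: robustness to overdispersed counts, read-depth artifacts,
compositional zeros structured by taxonomy, or misspecified reference
trees — real data have all of these, and the test's validity there rests
on exchangeability of pooled reads, not on the generator.

## Numerical and design notes

* Newick I/O rides on `ape`; single-leaf trees (`"A:1;"`) are parsed
  directly because `ape` cannot represent them; the writer emits 10
  significant digits and always writes the planted edge as the root
  branch length, making write→read a true round trip.
* Structural off-diagonal pairs are enumerated by ancestor walks
  (`O(depth)` per node) with preallocated buffers; entries are sorted by
  `(u, v)` for deterministic files. Matrix Market output stores the upper
  triangle of the symmetric matrix in wavelet order (root first, then
  interior nodes by postorder rank).
* No balanced-cancellation detection exists beyond the numerical
  tolerance; `tol` applies to stored entries only.
* All `λ_v ≥ 0` always (the covariance is PSD); a negative value would
  indicate a defect, and the tests assert nonnegativity on random trees.
* The dense covariance materializer refuses beyond 2048 leaves by
  default and points to the sparse path.
* Degenerate inputs: zero-total samples are errors for distances and
  tests; trees with one leaf have an empty split table, a single constant
  wavelet and zero external path length; `ε` shifts beyond the target
  block's mass are errors rather than clamped.

## Known limitations

* Exact rational work is bounded by the `2^53` overflow guard; beyond the
  oracle regime everything is double precision.
* The uniform ensemble's split-law sampling is `O(m)` per clade (pmf
  materialization), fine for the sizes used here but slower than the
  critical sampler's `O(log n)`.
* Polytomy resolution preserves covariance but not any polytomy-native
  wavelet construction; trees dominated by huge polytomies will show
  cascade artefacts in per-split interpretations.
* The permutation test assesses one component's significance; it does not
  compare significance *between* components — ranking remains by
  magnitude.
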