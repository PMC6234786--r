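---
title: "drydiv: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{drydiv: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside `drydiv`: the models each stage
assumes, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, the numerical choices, and the
package's own resolutions of points the underlying methods leave open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Data model

All stages operate on *chronograms*: rooted, binary, ultrametric trees
with branch lengths in Myr. Ages run backward from the present (tips at
0, root at the crown age). Ultrametricity is enforced within a relative
tolerance of `1e-6` (configurable) because text round-trips of dated
trees lose digits; the offending tip is named against the *median*
root-to-tip depth, so the minority tip is reported rather than whichever
tip happens to be deepest. Polytomies are rejected by default, because
both the DIVA recursion and the birth–death likelihood assume binary
speciation; an optional seeded random resolution inserts zero-length
branches, which the likelihood treats as simultaneous branching.

Geographic ranges are non-empty subsets of a configurable area alphabet,
default `A–D` for the four continental dryland regions (Africa, Asia,
Australia, New World). Multi-area ("widespread") tips are legitimate
observations for range reconstruction but are excluded from the regional
divergence statistics (Section 5), mirroring the exclusion rule used in
regional diversification summaries.

## 2. DIVA / S-DIVA

### Model

Dispersal–vicariance parsimony scores a joint assignment of ranges to all
internal nodes by event costs: vicariance (a widespread range splitting
into two non-empty, disjoint, covering subsets) and within-single-area
duplication are free; each area gained along a branch costs
`dispersal = 1`, each lost costs `extinction = 1` (both configurable).
`diva_reconstruct()` minimizes total cost exactly with a Sankoff-style
two-pass dynamic program over the `2^A − 1` range states (optionally
capped at `max_areas`), and — via exact counting in both passes — returns
for every node the *proportion of most-parsimonious reconstructions*
(MPRs) assigning each range. The test suite proves the DP against a
brute-force enumeration over all assignments on hundreds of small random
trees.

`sdiva()` averages per-node MPR proportions over a tree sample: each
internal node of the representative tree is identified by its tip set;
every sampled tree containing that clade contributes its MPR proportions;
contributions are averaged over contributing trees, and the fraction of
trees containing the clade is reported as coverage. A clade absent from
every sampled tree is reported unresolved rather than silently dropped.

### Open points and how this package resolves them

* **Vicariance variant.** Wrapped DIVA implementations differ on whether
  a bipartition may split a widespread range into two multi-area sides.
  Default: any non-empty bipartition is allowed;
  `strict_vicariance = TRUE` restricts one side to a single area.
* **`max_areas`.** Default: uncapped (all areas). RASP-style analyses
  often cap at 2; the cap is a first-class parameter.
* **Ties.** Modal-range ties are broken lexicographically by range label
  and flagged, so pipelines are deterministic and the flag is auditable.
* **Dispersal timing.** A dispersal detected on an edge is reported with
  both the stem (parent) and crown (child) age of that edge; published
  summaries often print a single age without stating the convention, so
  both are given and the choice left to the reader.
* **`all_mpr` extraction.** Beyond modal ranges, `extract_dispersals()`
  can count, exactly, the fraction of MPRs in which a given area is
  gained on a given edge, using the same DP tables. This is the
  recommended rule when reconstructions are ambiguous.

## 3. Piecewise birth–death shift detection

### Likelihood

Branching times `x1 > x2 > …` (the internal-node ages) are sufficient
statistics. With piecewise-constant speciation λ and extinction μ
(epochs youngest-first, boundaries at the shift times) and uniform
sampling fraction ρ, the building blocks are `p0(t)` (no sampled
descendant from a lineage at age `t`) and its density companion `p1(t)`.
Within an epoch both have closed forms (the classical sampled
birth–death expressions); across epoch boundaries they are propagated
backward in time by continuity, ρ entering only at the present. The
log-likelihood, conditioned on the crown age and on both crown lineages
surviving to be sampled, is

    logL = Σ_{i≥2} [ln λ(x_i) + ln p1(x_i)] + 2 ln p1(x1) − 2 ln(1 − p0(x1)).

Two independent code paths — the constant-rate closed form and the
piecewise recursion — are required by the tests to agree to `1e-9`, and
`p0` (constant and two-epoch) is validated against 10^5 forward
simulations from the package's own simulator.

### Numerical choices

* Rates are optimized per epoch in the (net rate `r = λ − μ`, turnover
  `ε = μ/λ`) parameterization with box constraints
  (`r ∈ [1e-4, 5]`, `ε ∈ [0, 0.999]`), which avoids the λ–μ ridge.
* The `λ → μ` limit is evaluated by a series guard when
  `|λ − μ|·t < 1e-8`; the Riccati solution is written with decaying
  exponentials only, so large `r·t` cannot overflow.
* Shift times live on a regular grid (default 0.1 Ma). For one shift the
  grid is scanned exhaustively; each grid point is optimized from a warm
  start (the neighbouring point's optimum) plus the no-shift fit, and
  the winning placement is re-polished from five seeded starts. For two
  or more shifts the search is greedy (add one shift on the full grid,
  then refine each shift coordinate-wise over the grid) — exhaustive
  enumeration of shift pairs at 0.1 Ma is quadratic in the grid and out
  of desk-scale budget; the greedy refinement is documented behaviour,
  not an approximation that is silently hidden.
* A likelihood that underflows to `−∞` during optimization is clamped to
  a large penalty; non-convergent fits are flagged in the comparison
  table rather than silently used.

### Model selection

Nested models are compared sequentially by `2ΔlogL` against a χ²
reference, stopping at the first non-significant step (`alpha = 0.05`).
The degrees of freedom per shift are genuinely ambiguous in practice:
counting two rates plus the shift time gives 3, while the convention in
several published shift analyses is consistent with 2. Default
`df_per_shift = 3` (the conservative choice); every comparison row also
reports the p-value under df = 2, so either convention can be read off
directly.

The `start` argument restricts candidate shift times to ages older than
a missing-taxa cutoff (Section 4), mirroring the practice of not
searching for shifts inside the poorly sampled recent past; passing
`start = grid_step` disables the restriction.

## 4. Missing-taxa diagnostic

`missing_fraction_profile()` is an explicitly *heuristic* surrogate: the
observed lineage count `L(t)` is compared with a crown-conditioned
constant-rate expectation `E(t) = N_total e^{−r̂ t}`,
`r̂ = ln(N_total/2)/x1`, where `N_total` comes from a clade-richness
table (clades not listed are assumed fully sampled). The missing
fraction is `m(t) = max(0, 1 − L(t)/E(t))` and the reported cutoff is
the youngest grid age where `m` rises by more than `jump_threshold`
(default 0.05) toward the present between adjacent grid points. The
source analyses cite an approach for locating such a cutoff without
printing formulas; this profile is our operationalization and is labelled
as such in the output — it anchors the `start` of the shift search and
nothing else.

## 5. Regional divergence statistics

* **Assignment.** Internal nodes take the single region of their modal
  DIVA range when that range has size one and is untied; widespread or
  tied nodes are *excluded* but still counted, so per-tree totals are
  conserved (regions + excluded = n − 1, a tested invariant). How
  published regional summaries collapsed widespread ancestral ranges is
  unstated; the alternative `method = "tip_descendant"` (majority region
  of descendant tips) ships for sensitivity analysis.
* **Binning.** Age bins are half-open `[0, w), [w, 2w), …`, anchored at
  the present, default width 5 Myr. Across the tree sample each cell is
  summarized by the median, type-7 interpolated 25–75% quantiles, and
  the min–max span — all bit-reproducible.
* **Representative tree.** The representative contributes to the sample
  as one additional member (a 101-tree sample for 100 posterior draws),
  and the cumulative curves, exponential fits and lineage densities are
  computed on it.
* **Exponential fits** are log-linear least squares of
  `ln N = ln a + b·τ` (τ = time since the crown age) on the cumulative
  step function at its own node times: deterministic and closed-form,
  adequate for a descriptive accumulation summary; `b` is per Myr.
  Regions with fewer than three distinct divergence times are refused
  (flagged), not extrapolated.
* **Lineage density** of a node assigned region R at age `t` counts the
  branches alive at `t` (parent strictly older, child not older) whose
  child node is assigned R; the root, having no subtending branch,
  counts itself. The cited "lineage density" notion is not specified in
  the source analyses; this definition — a per-region
  lineages-through-time evaluated at the region's own divergence times —
  is our documented operationalization, verified against a brute-force
  recount in the tests.
* **Synchrony table**: pure interval arithmetic of clade age intervals
  against a query window (default 15–10 Ma, the mid-late Miocene onset
  window), with the overlapping fraction as the summary. No statistical
  test of synchrony is attempted.

## 6. The synthetic world

The generator's defaults state one concrete world, used by the fixture,
the tests and the acceptance experiment:

* **Tree process**: crown age 59.89 Ma; pure birth (μ = 0) with net rate
  0.053 species/Myr shifting to 0.142 at 10.4 Ma; uniform sampling
  ρ = 0.55. These are the fitted values reported for the motivating
  dryland clade, used here as ground truth for parameter-recovery
  testing.
* **Conditioning**: `simulate_bd_tree()`'s default is plain crown
  survival (each crown subtree retains at least one sampled tip); under
  it the pure-birth expectation `E[N] = 2 e^{λT}` holds exactly and is
  tested. Analysis-grade draws use the generator's stricter resimulation
  rule — at least four sampled tips per crown subtree in the recovery
  experiment, two in the fixture — because rate estimation on
  near-degenerate trees is meaningless. The recovered pre-shift rate
  still carries the well-known small-sample downward bias of
  survival-conditioned birth–death MLEs (~10–15% at the ~50-tip median
  size of this world), which is inside the experiment's stated ±20%
  tolerance and is reported, not corrected.
* **Ranges**: gain rate `d = 0.002` per absent area per lineage-Myr, loss
  rate `e = 0.001` per occupied area (loss forbidden at range size one),
  root in region A. On a ~120-lineage, 60-Myr tree this yields on the
  order of eight dispersal events — the scale of the handful of
  intercontinental dispersals reported for such clades. At speciation a
  widespread range splits by a uniformly random bipartition, consistent
  with the free vicariance event DIVA scores.
* **Pseudo-posterior**: node ages multiplied by independent mean-one
  lognormal noise (default CV 0.1, roughly half the relative HPD width
  typical of deep-node dating), then repaired top-down so parents stay
  older than children; branch lengths are recomputed from ages, so trees
  remain ultrametric and topology is untouched.

What the generator does *not* emulate: topology uncertainty in the
posterior (only ages move, so clade coverage in S-DIVA is always 1),
clade-biased sampling (an option exists but is not the default world),
range-dependent speciation or extinction, and any form of rate variation
among contemporaneous lineages. A green test therefore establishes
correctness of the estimators *under their own model*, not robustness to
these violations.

## 7. Known limitations

* DIVA cost enumeration is exponential in the number of areas; the
  bitmask DP is comfortable to ~8 areas, far beyond the 4 used here, but
  not meant for fine-grained area schemes.
* The LRT for a grid-searched shift time is only approximately χ².
  Measured on a 100-replicate pure-birth null (the acceptance type-I
  experiment), df = 3 with the matched fixed-turnover fitter selects the
  no-shift model 97% of the time at α = 0.05; with turnover additionally
  free the rejection rate rises to ~14% (two extra parameters, a
  boundary at ε = 0, and the grid search together make χ²₃ slightly
  anti-conservative). For shift scans against a pure-birth null, fix the
  turnover; in general read the p-values as calibrated heuristics, not
  exact tail probabilities.
* The missing-fraction profile inherits every weakness of its
  constant-rate expectation; it is a cutoff-finding device, not an
  estimate of true sampling through time.
* Reversible-jump Bayesian shift mosaics (per-branch rate maps) are out
  of scope by design; the piecewise ML analysis is this package's
  shift-detection instrument.
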