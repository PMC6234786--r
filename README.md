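# drydiv

Biogeography and diversification-shift analysis on dated phylogenies.

`drydiv` implements the analysis chain used to ask *when and where a clade
diversified*: given an ultrametric, dated phylogeny (a chronogram, branch
lengths in Myr) of an arid-adapted plant family spread over four
continental dryland regions, plus a posterior sample of such trees, it

1. reconstructs **ancestral geographic ranges** by dispersal–vicariance
   parsimony (DIVA), averaged over the tree sample onto a representative
   tree (**S-DIVA**), and extracts timed dispersal events between regions;
2. detects **temporal shifts in diversification rate** with a
   piecewise-constant birth–death likelihood on the branching times,
   incomplete uniform taxon sampling, an exhaustive grid search over shift
   times, and sequential likelihood-ratio model selection, plus a
   missing-taxa time-cutoff diagnostic;
3. summarizes **region-specific divergence accumulation**: binned
   divergence series (median / IQR / span over the tree sample),
   cumulative accumulation curves with exponential fits, nodal lineage
   density, and a cross-clade synchrony table.

A fully seeded synthetic-data generator produces chronograms,
biogeographic histories and pseudo-posterior samples with known truth, so
every stage is testable against simulation.

## The models in brief

**DIVA.** Ranges are non-empty subsets of an area alphabet (default
`{A, B, C, D}` = Africa, Asia, Australia, New World). Speciation in a
single-area ancestor duplicates the range; a widespread ancestor splits by
vicariance into two non-empty disjoint subsets, at no cost. Each area
gained along a branch costs 1 (dispersal), each area lost costs 1
(extinction/extirpation). `diva_reconstruct()` minimizes total cost
exactly by a two-pass dynamic program over the (capped) 2^A − 1 range
states and counts all most-parsimonious reconstructions (MPRs), so
per-node range probabilities are exact MPR proportions. `sdiva()` averages
these over a posterior sample, per clade, onto the representative tree.

**Birth–death shifts.** With speciation λ(t), extinction μ(t) piecewise
constant in time and uniform sampling fraction ρ, the probability p0(t)
that a lineage at age t leaves no sampled descendant satisfies, within an
epoch,

    p0(t) = 1 − ρ(λ−μ) / (ρλ + (λ(1−ρ) − μ) e^{−(λ−μ)t}),

propagated across epochs by continuity; with its density companion p1(t),
the log-likelihood of branching times x1 > x2 > … conditioned on the crown
age and survival of both crown lineages is

    logL = Σ_{i≥2} [ln λ(x_i) + ln p1(x_i)] + 2 ln p1(x1) − 2 ln(1 − p0(x1)).

`fit_shifts()` profiles per-epoch (net rate r = λ−μ, turnover ε = μ/λ)
over a 0.1-Ma grid of shift times and selects the number of shifts by
sequential LRT (default df = 3 per shift; p-values under df = 2 are
reported alongside).

## Worked example

```r
library(drydiv)

# a ~60-Myr, 4-region radiation with a known rate shift, 55% sampling
fx <- dryland_fixture(seed = 1, n_posterior = 100)
tr <- attr(fx$trees, "representative")

# 1. ancestral ranges over the 101-tree sample
nrf <- sdiva(fx$trees, fx$regions)
nrf
#> S-DIVA node-range frequencies: 45 internal nodes over 100 trees (mean coverage 1.00)
extract_dispersals(nrf, rule = "modal", regions = fx$regions)[, 3:6]
#>   area  stem_age    crown_age support
#> 1    B 15.283704 1.170481e+01       1
#> 2    C  6.913148 7.105427e-15       1
#> 3    D  5.645249 1.421085e-14       1

# 2. shift detection on the representative tree
fit <- fit_shifts(tr, kmax = 1, grid_step = 0.1, start = 8.7, rho = 0.55,
                  turnover = "fixed", seed = 1)
fit
#> Birth-death shift-model comparison (rho = 0.55, alpha = 0.05, df/shift = 3)
#>  k shift_times    loglik     lrt df            p        p_df2 converged selected
#>  0             -158.8808      NA NA           NA           NA      TRUE    FALSE
#>  1        16.4 -150.5032 16.7553  3 0.0007935385 0.0002299495      TRUE     TRUE
#> selected: 1 shift(s) at 16.4 Ma; net rates (young -> old): 0.14 | 0.02986
```

Read: three dispersals out of the ancestral region (into Asia at a
15.3–11.7 Ma branch, and into Australia and the New World along terminal
branches), and a one-shift diversification model (LRT = 16.8,
p ≈ 8e-4 under df = 3) with net rate rising from 0.030 to 0.140
species/Myr.  This single 46-tip draw was simulated with a true shift at
10.4 Ma from 0.053 to 0.142 species/Myr; the rate recovery is close, the
shift time noisy — the acceptance experiment shows the *median* over 50
replicates lands on the truth.

The whole chain, with TSV/JSON outputs and a checksummed manifest:

```r
d <- tempfile(); dryland_fixture(seed = 1, dir = d)
run_pipeline(list(tree = file.path(d, "mcc.nwk"),
                  trees = file.path(d, "posterior.nwk"),
                  regions = file.path(d, "regions.tsv"),
                  richness = file.path(d, "richness.tsv"),
                  rho = 0.55, out_dir = "out"))
```

or from the shell: `Rscript inst/cli/drydiv.R pipeline --tree ... --regions ...`.

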