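# combsim

Simulation and phylogenetic analysis of repeated bacterial symbiont
replacement.

## The problem

Vertically transmitted insect endosymbionts usually co-speciate with their
hosts, leaving congruent, well-resolved phylogenies. Some host groups break
the pattern: their symbionts form a *comb-like* clade — long terminal
branches separated by internodes so short that bootstrap support collapses —
suggesting that resident symbionts are repeatedly *replaced* by fresh
domestications of a slowly evolving, free-living progenitor bacterium. Each
new symbiont starts as a near-copy of the contemporary progenitor and then
evolves fast, so descendants share almost no derived characters.

`combsim` is for researchers who want to test that hypothesis
quantitatively. It provides:

* **A forward simulator** (`run_simulation`): a progenitor sequence evolves
  for `n_cycles` discrete cycles at rate *r_p* (expected substitutions per
  sequence per cycle) and spawns descendants at birth cycles
  `round(n_cycles * Beta(α, β))` that thereafter evolve independently at
  *r_d*; optionally one descendant splits mid-run into `cospec1`/`cospec2`
  (a co-speciation event). Pure point substitutions: a Poisson(*r·Δt*)
  number of events, uniform sites, uniform alternative bases, no indels.
* **Calibration** (`calibrate_params`): stochastic hill-climbing with
  common random numbers that tunes the rates so that the simulated mean and
  variance of progenitor-descendant Jukes–Cantor distances match observed
  values (descendant/progenitor ratio fixed, default 8, for
  identifiability).
* **Tree analytics** (`jc_distance`, `nj_tree`, `bootstrap_tree`,
  `mean_bootstrap_value`, `tree_shape_metrics`, `bipartition_support`):
  JC distances with explicit saturation handling, neighbor joining,
  column-resampling bootstrap with per-bipartition support, the mean
  bootstrap value (MBV) over all internal edges, and terminal/internal
  branch-length comb metrics.
* **rRNA structural divergence** (`call_substitutions`,
  `classify_substitutions`, `score_variability`, `fisher_exact_2x2`):
  substitutions mapped onto a dot-bracket secondary structure and classed
  conservative (pairing preserved, G·U counted canonical, compensatory
  changes honored) versus disruptive (stem–loop transitions), scored against
  a positional variability map, with exact Fisher tests.
* **Rates and dating** (`tajima_rrt`, `lineage_rates`, `ng86_ds`,
  `tsd_extrapolate`): Tajima's relative-rate test
  (χ² = (m₁−m₂)²/(m₁+m₂), df 1), three-point K1/K2 decomposition,
  Nei–Gojobori dS/dN, and the linear synonymous clock
  TSD = dS / dS_cal × T_cal through the progenitor–SOPE anchor
  (0.046 ↔ 28,000 years).
* **Synthetic data** (`make_progenitor`, `make_structure_fixture`,
  `make_codon_pair`, `make_replacement_dataset`) and a **pipeline runner**
  (`run_pipeline`, plus a thin CLI at `inst/cli/combsim.R`).

## Worked example

The co-speciation experiment: baseline replacement regime (rates
0.002/0.016 per sequence per cycle, 12 descendants, 5000 cycles) with the
earliest-born descendant splitting at cycle 2500.

```r
library(combsim)

sim <- run_simulation(replacement_preset("cospeciation", seed = 42))
sim
#> Replacement simulation: 14 lineages, 1460 nt, 5000 cycles (seed 42)
#>   labels: prog cospec1 cospec2 d1597 d1601 d1974 d2360 d2494 d2519 ...
summary(sim)
#> Progenitor-descendant JC divergence: mean 0.0290, variance 0.000184 (13 pairs)

tr <- bootstrap_tree(sim$sequences, n_reps = 100, seed = 42)
mean_bootstrap_value(tr)
#> [1] 33.81818
bipartition_support(tr, c("cospec1", "cospec2"))
#> [1] 100
tree_shape_metrics(tr)
#> Tree shape metrics
#>   terminal branches: n = 14, mean length 0.02212
#>   internal branches: n = 11, mean length 0.00186
#>   terminal/internal ratio: 11.9
#>   mean internal support: 33.8%
```

The numbers tell the whole story: descendant divergence sits near 3%
(mean 0.029) as calibrated; the tree is a comb (terminal branches ~12×
longer than internodes) with poor overall resolution (MBV ≈ 34%); yet the
one genuine shared-history split — cospec1|cospec2 — is recovered with 100%
bootstrap support. Replacement erases deep structure; co-speciation leaves a
signal.

Dating an acquisition from its synonymous divergence:

```r
tsd_extrapolate(c(0.428, 0.341, 0.089))
#> [1] 260522 207565  54174
```

i.e. symbionts at fusA dS 0.428, 0.341 and 0.089 from the progenitor
diverged roughly 261, 208 and 54 thousand years ago — recent against host
radiations measured in tens of millions of years.

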