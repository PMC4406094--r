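# dmland

Can limited dispersal *alone* — no geographic barriers, no spatially varying
selection — make reproductively isolated genotypes cluster in space and
persist? `dmland` is an individual-based, spatially explicit
landscape-genetics simulation built to answer that question for a
continuously distributed population carrying a classical two-locus
Dobzhansky–Muller incompatibility (DMI). It is aimed at population
geneticists and landscape ecologists studying isolation by distance (IBD),
incipient speciation and spatial genetic structure.

## The model in brief

5000 individuals occupy fixed home-range sites placed uniformly on a
rectangle of area 7237.60 units² whose diagonal — the maximum possible
distance — is 123.2 units (density 0.691 individuals/unit²). Each generation
(non-overlapping, dioecious, constant capacity):

1. every female draws one mate among males within the movement limit
   `d_max`, with probability ∝ 1/max(d, d_floor)² (truncated inverse-square
   kernel);
2. each pair produces a Poisson(λ = 4) brood under Mendelian inheritance
   with free recombination and per-allele mutation (μ = 0.0005);
3. all adults die;
4. offspring disperse, in random order, to vacant sites within `d_max` of
   their natal site (same kernel) and survive with probability equal to
   their genotype's viability.

The genome has 22 diallelic loci. Locus 1 (A/a) and locus 2 (b/B) carry the
incompatibility: genotypes with ≥1 copy of a **and** ≥1 copy of B (AaBB,
AaBb, aaBB, aaBb) are inviable; AABB, AABb, AAbb, Aabb and aabb are fully
viable. Founders are monomorphic AAbb; a arises by forward mutation, B by
backward mutation, so the two isolated pure classes AABB and aabb must both
*evolve*. The 20 neutral loci track spatial structure through Wright's
inbreeding coefficient pooled over all individuals,

&nbsp;&nbsp;&nbsp;&nbsp;*F* = 1 − *H*<sub>o</sub>/*H*<sub>e</sub>,

a Wahlund-style heterozygote deficit when mating is distance-limited.
Per generation, DBSCAN (MinPts = 4, ε = 2 units) is run separately on the
AABB and aabb carriers; a *reproductive-isolation (RI) event* is flagged
when both classes form at least one spatial cluster simultaneously, and
persistence is the run length of consecutive flagged generations.

The experimental variable is the movement limit, from 2.5% to 100% of the
123.2-unit maximum — i.e. from ~21 potential mates to the whole population.

## Worked example

A small landscape (150 sites, area 400, diagonal 30) for ten generations:

```r
library(dmland)
cfg <- scenario_config(movement_fraction = 0.3, n_sites = 150,
                       generations = 10, area = 400, max_distance = 30,
                       eps = 1.5, seed = 15)
run <- run_replicate(cfg)
tail(run$stats[, c("generation", "n_alive", "Ho", "He", "F", "ri_flag")], 3)
#>    generation n_alive        Ho        He          F ri_flag
#> 9           8     150 0.4660000 0.4860778 0.04130569       0
#> 10          9     150 0.4666667 0.4866311 0.04102583       0
#> 11         10     150 0.4696667 0.4843544 0.03032444       0
```

150 individuals survive every cycle (λ = 4 saturates the sites), F stays
near 0 — ten generations of moderate movement produce no measurable
substructure, and no RI event is flagged. At study scale the gradient is
what matters: `run_sweep()` shows F at generation 1000 falling from ≈0.30
(2.5% movement) to ≈0.02 (100%), and RI-flagged generations falling from
hundreds out of 1000 to zero as movement increases —

```r
sw <- run_sweep(fractions = c(0.025, 1.00), replicates = 3, base_seed = 1,
                generations = 1000)
sw$summary[, c("movement_fraction", "mean_ri_events", "mean_duration",
               "F_final_mean")]
#>   movement_fraction mean_ri_events mean_duration F_final_mean
#> 1             0.025            635      9.430693   0.29619531
#> 2             1.000              0            NA   0.01536128
```

The analytic mating-neighborhood table is `neighborhood_table()`: expected
neighbors 21 / 82 / 185 / 329 / 741 / 1317 / 2058 / 5000 at movement radii
of 2.5–100% of the maximum distance.

## Repository layout

* `R/`, `src/` — the package: landscape substrate, genome and DMI fitness,
  the generation engine (plain-R reference semantics plus a compiled
  production engine with its own seeded RNG), pooled F statistics, DBSCAN +
  k-dist heuristic + RI-event statistics, and the sweep runner.
* `analysis/01_landscape_geometry.R` … `03_ri_events.R` — numbered drivers
  that reproduce the study tables on desk scale and write CSVs (and a
  trajectory figure) under `results/`.
* `vignettes/limited-dispersal-ri.Rmd` — the model, its assumptions,
  parameter choices and known limitations.

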