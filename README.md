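# schoolfeed

Individual-based simulation of feeding competition and growth in a
school of farmed rainbow trout, for screening feed-distribution
strategies *in silico*.

## The problem

Feed is the dominant cost of an aquaculture operation, and how it is
*distributed in space* shapes the stock in a way that mean growth does
not reveal: when a fixed daily ration is broadcast over a narrow patch,
the fish that arrive first — and that swim faster as they grow —
monopolize intake.  Ninety days later the stock has the same mean body
mass but a far wider, right-skewed mass distribution, which destabilizes
grading and sale.  Rearing trials that compare feeding methods take
months; `schoolfeed` reproduces the process in minutes.

## The model

Two coupled layers, iterated daily for 90 days:

**Feeding bout** (1000 s at Δt = 0.025 s).  Each fish follows a
boid-style schooling model: Newtonian motion `m a = F` with
`F = Σ F_k` over six fixed-magnitude steering rules — separation (w₁ =
0.6), cohesion (w₂ = 0.4), alignment (w₃ = 0.4), boundary avoidance
(w₄ = 1.0), feed attraction (w₅ = 3.0 while hungry, else 0) and random
movement (w₆ = 0.2).  Perception is a sphere of radius 2 TL minus a 30°
rear dead cone; speed is capped at `Cv · TL` (Cv = 1.5 s⁻¹ cruising,
7.0 s⁻¹ feeding).  Pellets (5 mm spheres at water density, 0.065 g)
are scattered uniformly over a square of side 1.5 / 1.0 / 0.5 m
(Feeding A / B / C), sink at 0.025 m/s, and are ingested on contact by
fish whose intake is below the satiation cap `Smax = 0.04 W`.

**Growth update.**  `W ← W + FCE · S` with FCE = 1, then
`TL = (W/a)^{1/b}` with a = 0.0209, b = 2.843 (g, cm).  The daily
ration is 1.86 % of school biomass.

The package provides the full experiment pipeline (seeded, replicable,
per-fish per-day ledger), the final-day statistics (mean, sample SD,
adjusted Fisher–Pearson skewness, Kruskal–Wallis location test,
Bartlett variance test), a pure-R reference kernel that serves as the
oracle for the vectorized C++ engine, and a small CLI
(`inst/cli/schoolfeed.R`: `run`, `compare`, `summarize`).

## Worked example

```r
library(schoolfeed)

cfg_A <- experiment_config(method = feeding_method("A"), rng_seed = 1L)
cfg_C <- experiment_config(method = feeding_method("C"), rng_seed = 1L)
run_A <- run_experiment(cfg_A)   # ~1.5 min each
run_C <- run_experiment(cfg_C)

compare_methods(list(A = run_A, C = run_C))
```

```
<method_comparison>
 method   n mean_g  sd_g skewness degenerate
      A 100  202.3 22.34   0.1501      FALSE
      C 100  202.3 63.09   1.3278      FALSE
  Kruskal-Wallis (location): p = 0.009395 (significant at 0.05)
  Bartlett (variance): p = 1.256e-21 (significant at 0.05)
```

Both methods deliver the same mean growth (202.3 g from 38.53 g — the
analytic ceiling for a 1.86 % ration of current biomass at FCE = 1 is
38.53 · 1.0186⁹⁰ = 202.4 g), but the narrow square (C) produces a
three-fold larger standard deviation and a strongly right-skewed
distribution: a handful of dominant fish and a long tail of
under-performers.  Because the ration is a hard budget, the competition
is zero-sum: C's winners depress its *median*, which is why the rank
test flags location here even though the means are identical (see the
methods vignette).  Per-individual histories are available via
`extract_individual_history(run_C$ledger, "max")` (or `"min"`), and
`write_ledger()` exports the full per-day per-fish ledger as CSV.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities
from scratch against the installed package — the pellet-mass closed
form; median day-1 feeding-completion times for Feeding A and C over
ten seeded bouts; and mean, SD, skewness and Bartlett p-value of the
day-90 mass distributions from full 90-day runs of Feeding A, B and
C — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the run takes a few minutes on
one CPU.
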