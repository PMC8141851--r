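# colonymh

Metaheuristics run as synthetic gene circuits inside a simulated growing
bacterial colony — and their classical bit-string counterparts, side by
side.

`colonymh` is for researchers in synthetic biology and bio-inspired
computing who want a desk-scale testbed for the idea that a cell colony can
*execute* a metaheuristic: every bacterium carries one candidate solution
as its set of conjugative plasmids, and the algorithm's operators are
native cell processes.

| algorithm element | colony mechanism |
|---|---|
| candidate solution | plasmid-presence bit string of one cell |
| fitness function | `{1,0,x}` pattern compiled to a repressor cascade ending in GFP |
| crossover (SGA) | bacterial conjugation: copy one plasmid to a touching neighbor |
| mutation (SGA) | promoter mutation at division: per-plasmid bit flip |
| temperature (SA) | a diffusing, degrading aTc field; cooling factor α maps to degradation λ = −ln(α)/T_div |
| solution pool | the growing colony itself (200 → 10,000 cells) |

The benchmark is an adapted SAT instance: one clause per plasmid, so a
pattern like `1100` means "plasmids 1 and 2 required, 3 and 4 forbidden".
Fitness evaluation is a three-tier transcriptional circuit — forbidden
inputs activate `araC` (OR gate), required inputs cooperatively repress
`trpR` (AND gate), then `trpR ⊣ lacI ⊣ cI ⊣ GFP` with `araC → cI` — and the
package proves the compiled circuit equivalent to direct pattern evaluation
by exhaustive enumeration. Both implementations report the **generation of
the first optimal solution**; the colony's growing pool makes it reach
optima in fewer generations than the fixed classical pool, which is the
headline comparison.

The package also includes a quorum-sensing Game of Life: a static cell
lattice where live cells emit AHL and a band-detector rule (live iff the
local concentration sits between two calibrated thresholds) plays the
role of the crowding rules, bootstrapped by an aTc start switch, compared
against an exact grid implementation.

## Worked example

```r
library(colonymh)

# classical fixed-pool SGA at the baseline configuration
sga_run("1100", P = 200, c = 0.01, m = 0.01, seed = 42)
#> <mh_run> sga_classic on pattern 1100
#>   first optimum at generation 2

# the same search as a growing colony
cfg <- mh_config("SGA", "1100", N0 = 200, Nf = 10000, m = 0.01, c = 0.01)
res <- run_colony(cfg, seed = 42)
res
#> <colony_run> SGA on pattern 1100
#>   first optimum at generation 1.5 (stopped at generation 1.5, 595 cells)

tidy(res)    # per-minute trajectory: n_cells, n_optimal, n_gfp, ...
autoplot(res)
```

The colony found its first optimum at generation 1.5: a cell assembled the
required plasmid pair around generation 0.9 and its GFP reporter matured
12 minutes (0.6 generations) later. Averaged over seeds, the colony mean
at this baseline (1.43 generations over 30 seeds, counting censored runs
at their stop generation) sits below the classical mean (2.16 over 100
seeds), because the solution pool doubles every 20 simulated minutes
while the classical pool stays at 200.

The interpreter turns a flat parameter file into both a runnable config
and a gro-style skeleton specification:

```r
cfg <- parse_mh_config("
  algorithm: SA
  pattern: '1100'
  N0: 200
  Nf: 10000
  alpha: 0.25
")
cat(emit_skeleton(cfg))
#> skeleton colonymh/1
#> algorithm SA
#> ...
#> signal atc D=12 lambda=0.0693147180559945 alpha=0.25 amount=100
#> ...
```

A thin CLI wraps the same functions (`inst/exec/mh`): `mh run`,
`mh sweep`, `mh emit`, `mh ca`, `mh fixture`.

Parameter sweeps over the published grids (fitness pattern, mutation rate,
conjugation rate, population size, cooling factor) run with
`run_sweep("T3", replicates = 30, seed0 = 1)`, which returns per-run rows
and a summary with found-only and stop-censored means.

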