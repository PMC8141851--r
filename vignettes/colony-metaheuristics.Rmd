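---
title: "Metaheuristics in growing bacterial colonies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaheuristics in growing bacterial colonies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonymh)
```

## The problem

Metaheuristics such as the Simple Genetic Algorithm (SGA) and Simulated
Annealing (SA) explore large solution spaces with stochastic operators —
crossover, mutation, a cooling temperature. `colonymh` runs these searches
in two forms side by side:

* **classical**: bit strings in a fixed-size pool (SGA) or a single bit
  string (SA), the reference implementations;
* **colony**: an agent-based 2D simulation of a growing bacterial colony in
  which every cell is one candidate solution, and the evolutionary
  operators are native cell processes — conjugation for crossover, promoter
  mutation at division for mutation, and a diffusing, degrading
  environmental signal (aTc) for the annealing temperature.

The benchmark problem is an adapted Boolean satisfiability (SAT) instance:
each disjunctive clause of a propositional formula is carried as a single
protein on its own conjugative plasmid, so a candidate solution is the
plasmid-presence bit string of a cell, and the fitness function is a
pattern over `{1, 0, x}` — plasmid required, forbidden, or irrelevant. A
cell is *optimal* when every constrained position is satisfied. Performance
is compared in **generations to the first optimal solution**, the one
quantity shared by both implementations (wall-clock time is not
comparable). Fractional generations are meaningful in the colony:
`gen(t) = t / T_div` with a 20-minute division time.

## The fitness circuit

The pattern is not evaluated symbolically in the colony narrative; it
compiles to a three-tier repressor cascade:

1. input plasmids expressing proteins `p1..pL` (don't-care positions are
   omitted);
2. a transduction tier: every *forbidden* protein activates `araC` (an OR
   gate), while the *required* proteins jointly repress `trpR` (a
   cooperative AND gate — trpR stays on while any required protein is
   missing);
3. an evaluation tier: `trpR ⊣ lacI`, with `cI` driven either by araC or by
   a constitutive promoter repressed by lacI, and `cI ⊣ GFP`.

GFP is therefore on exactly when no forbidden plasmid is present and all
required plasmids are. `eval_circuit()` computes the Boolean steady state
of this wiring by a topological pass over promoters; it never reads the
pattern directly, which makes the exhaustive equivalence test against the
definitional `is_optimal()` (all genotypes, patterns up to length 8) a
genuine two-route check. The compiler uses Boolean steady-state semantics
with no kinetics; the only temporal element of reporting is the maturation
delay below.

```{r circuit}
compile_pattern("1100")
```

## The colony engine

Cells are circles of radius 1 µm (not the rod-shaped cells of full
colony simulators; only radial colony expansion matters for the mechanisms
modelled here). The engine steps in 1-minute ticks:

* **Division.** Clocks are drawn from Normal(20, 2) minutes truncated at 5;
  founders start at a uniformly random phase of their cycle so generations
  desynchronize immediately (a `init_phase = "full"` switch restores
  deterministic doubling for growth-law tests). A divider splits into two
  daughters ±1 µm along a random direction; each daughter's genotype is
  mutated independently, each bit flipping with probability `m` (the
  "resample" reading — set the bit to a uniform random state, half the
  effective rate — is a config switch).
* **Shoving.** Overlaps are resolved by iterative pairwise half-overlap
  displacement (over-relaxed by a factor 1.4) on a spatial hash grid.
  Convergence is judged on the *post-sweep residual* overlap (< 0.05 r): a
  criterion based on the overlaps seen during a sweep systematically
  leaves states just above tolerance, because Gauss–Seidel displacements
  create fresh contacts after they are measured. Sweeps are capped at 100
  per step; the cap never binds for colonies up to a few thousand cells,
  while in larger colonies residual center overlap persists as internal
  pressure (full relaxation there is a global problem needing thousands
  of sweeps and buys nothing for the mechanisms modelled).
* **Conjugation.** Each cell attempts transfer with probability
  `c·dt/T_div`; a donor with at least one plasmid picks a uniform neighbor
  within 2.2 r and copies one uniformly chosen present plasmid into it.
  Duplicates are no-ops; there is **no plasmid loss** anywhere in the
  model, so bits are only removed by mutation.
* **Reporting.** A cell whose circuit is satisfied starts a maturation
  timer; GFP turns on after `tau_gfp = 12` minutes (0.6 generations).
  Daughters inherit the timer (the fluorophore is partitioned at
  division); a cell that stops being optimal goes dark and resets. The
  12-minute default makes optimal founders first report at 0.6
  generations, consistent with sub-generation first-appearance values for
  the least constrained pattern; detection can be switched to raw genotype
  level (`detection = "genotype"`).

Runs stop at the first detection or when the colony reaches `Nf` cells
(10,000 at baseline, about six generations from 200 founders).

## Classical baselines

The classical SGA keeps a fixed pool of `P` bit strings, initialized — like
the colony founders — as 50% empty solutions and 50% single-plasmid
solutions assigned round-robin. Each generation: a crossover pass in index
order (each individual receives, with probability `c`, one uniformly
chosen present plasmid from a uniformly chosen other individual), a
mutation pass (each bit flips with probability `m`), then evaluation.
Evaluation after the update pass means an optimal founder is reported at
generation 1, never 0. Selection is random; there is no elitism, matching
the conjugation-styled crossover rather than a textbook recombination.

Classical SA holds one bit string, proposes single-bit flips, scores
energy as the number of violated constrained positions, and accepts by the
Metropolis rule. Cooling is **geometric**, `T ← alpha·T` per iteration:
although the cooling is sometimes described as linear, a decrease *rate*
`alpha` strictly inside (0, 1) forces the multiplicative reading, and that
is also what the colony mapping uses. Defaults `T0 = 1`, `T_min = 1e-3`;
the initial state is a uniform random genotype (a config choice — the
reference description is silent).

## Temperature as an aTc field

The annealing colony deposits a single central aTc bolus (Gaussian with
width equal to the initial colony radius, total mass 100 a.u.) on a
reaction–diffusion grid (spacing 2 µm, no-flux boundaries, forward
differences under the stability bound `D·dt/dx² ≤ 1/4`). The cooling factor
maps to first-order degradation as `lambda = -log(alpha)/T_div`, so the
field decays by exactly `alpha` per generation; cells additionally
experience cooler values as shoving pushes them outward, and diffusion
(default `D = 12` µm²/min, on by default, a declared choice where no value
is stated) flattens the center. Conjugation is gated by a Hill response
`H(aTc) = aTc²/(K² + aTc²)` with `K` at 10% of the initial central
amplitude — `H(0) = 0`, saturating at 1; no kinetic constants are given in
the source material, so both are exposed in the config. The SA colony
mutates at rate 0 by default: solution perturbation is conjugation alone.

## The quorum-sensing cellular automaton

The Game-of-Life demonstration replaces growth with a static lattice of
cells at pitch 2 r (a disordered disc layout is available; the lattice
makes calibration and rasterized comparison well defined). Live cells emit
AHL; every `update_every = 20` minutes each cell samples its local
concentration and applies a band rule — live iff the concentration lies in
`[c_low, c_high]` — so under- and over-crowding both kill, the
band-detector version of B3/S23. Because the environment starts with no
AHL, bootstrap seed cells (GFP-marked) are clamped live and emitting while
a decaying aTc level stays above threshold; the override lapses on its
own.

Calibration is computed, not guessed: the steady field of one emitting
cell (an exact sparse linear solve of the discrete balance) gives the mean
per-neighbor contribution at the 8 Moore positions, and the band edges are
the sensed concentrations for 2 and 4 emitting neighbors. The default
kernel (`D = 16` µm²/min, `lambda = 0.08`/min) is the most spatially
peaked one for which an isolated live cell's own steady field still falls
below `c_low` — i.e. single cells are not self-sufficient and die. This is
a real trade-off: sharper kernels localize the neighborhood but make
single cells immortal; flatter kernels couple each cell to the whole
colony and reduce the dynamics to near-global oscillations. A continuous
field cannot reproduce the exact 8-neighbor count rule, so the colony
automaton is compared to the grid reference qualitatively (Jaccard index
of rasterized live sets), never asserted equivalent.

## Synthetic data and what the tests show

All inputs are generated in code. `init_population()` realizes the
published initialization; `make_fixture()` draws random patterns uniformly
over `{1, 0, x}` and builds a one-literal-per-clause formula with an
explicit truth assignment realizing each clause value (the assignment is
explicit precisely because the source material leaves it open). The
generator emulates the *study conditions* — pool sizes, rates, stop
criteria — not real biology: digital protein states, no plasmid loss, no
nutrient limitation, no death, circular cells. Passing tests therefore
show that the mapping between the classical and colony operators behaves
as designed under those idealizations, not that a wet-lab colony would
reproduce the numbers.

Replicate counts are fixed in advance: 30 seeded runs where a mean is
pinned exactly, 100 for stochastic classical means, 60 matched seeds for
colony trend sweeps (30 for the slowest grid points), chosen for
statistical power against trend gaps of a few tenths of a generation.
Trend checks for pattern restrictiveness compare the published pairings
(most- vs least-constrained, and each middle pattern against the
endpoints) because the middle pair differs by fractions of a generation —
noise-level even in the published colony figures. The colony crossover
trend is likewise tested as a full-span decrease plus a negative fitted
slope: with the baseline mutation rate active, conjugation contributes
only a few hundredths of a generation between adjacent rate points
(measured against a per-run sd of ~0.5), so adjacent-pair ordering is not
statistically meaningful there. Colony means are stop-censored: a run
that reaches the final cell count without an optimum counts at its stop
generation, a conservative lower bound.

## Numerical choices

* Explicit diffusion with flux-form no-flux boundaries conserves mass
  exactly (to 1e-9 over 1000 steps in tests); degradation is applied as an
  exact exponential factor.
* Steady states for calibration use a sparse direct solve; the iterative
  path (available for cross-checking) carries an O(dt) deposit artifact at
  the source node and is compared away from it.
* Engine ticks are 1 minute; signal fields substep automatically to the
  stability bound.
* Division at coincident centers (a degenerate relaxation case) falls back
  to a deterministic push along x.
* Conjugation neighbor queries and shoving run in C++ on a uniform hash
  grid; both consume R's RNG stream, so whole runs are reproducible from a
  single seed.

## Known limitations

* The classical SGA reproduces the published near-forced rows and all
  qualitative trends, but not every printed mean: the published baselines
  for the same nominal configuration disagree with each other across
  tables, so absolute agreement beyond the robust rows is not attainable
  from the stated description.
* Annealing with the baseline cooling factor 0.25 freezes conjugation
  within about two generations; fully-constrained patterns are usually
  censored at the stop size, which the analysis treats explicitly.
* The colony automaton reproduces the specified edge behavior (bootstrap,
  extinction, band deaths) but its spatial patterns only loosely track
  grid Life, for the neighborhood reasons above.
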