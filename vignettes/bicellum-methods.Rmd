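---
title: "The bicellum model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bicellum model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bicellum` simulates the evolution of the simplest multicellular
organism: an adult made of two totipotent cells, a mother-derived
"type 1" cell and a daughter-derived "type 2" cell, sharing one clonal
haploid genotype. The population holds `N` such adults; each cycle every
cell

1. splits its resource pool into foraging, repair and reproduction by a
   genetically encoded softmax reaction norm,
   \deqn{p_x = \frac{e^x}{1 + e^x + e^y},\quad
         p_y = \frac{e^y}{1 + e^x + e^y},\quad p_z = 1 - p_x - p_y,}
   with type-specific genes \eqn{x, y} free on the real line;
2. forages, earning \eqn{f(x) = f_{max}\, x / (x + h)} on the invested
   amount; the two cells' returns are pooled and redistributed by
   signalled shares \eqn{s_1/(s_1+s_2)} — the channel through which
   cellular altruism, and hence division of labour, can evolve;
3. accrues an exponential damage increment (rate \eqn{\lambda}) and
   repairs multiplicatively, \eqn{d' = d\,e^{-a y}};
4. reproduces with probability \eqn{1 - e^{-b z}}; the propagule takes
   a fraction \eqn{1 - \rho_t} of the mother cell's damage (the
   retention trait \eqn{\rho_t} is 1/2 unless evolvable) and develops by
   one doubling into a new two-celled adult;
5. faces three mortality rounds: an intrinsic death probability
   \eqn{m_1 = (1-c)(d/D) + c(d/D)^4} (clamped to 1), a viability round
   in which the one damage-window-matched locus out of 16 kills with
   probability \eqn{m_2} if it carries the deleterious allele, and a
   uniform cull of the grown population back to `N`. When exactly one
   cell of an adult dies, the survivor rebuilds the adult by doubling
   with probability `r` (the regeneration parameter).

Heritable state mutates only at offspring production: each continuous
gene with probability `mu` by a Gaussian(0, `sigma`) step on its
unconstrained scale (signals on the log scale, retention on the log-odds
scale, rate `mu_d`), and each viability locus flips neutral-to-deleterious
with probability `mu_v0` and back with `mu_v1`. The 10:1 bias plus
damage-gated expression is what lets late-acting (high-damage) deleterious
alleles accumulate — the mutation-accumulation route to senescence — while
`D` and `r` control whether somatic specialisation pays.

## Parameters

All presets share `f_max = 6`, `h = 0.3` (resources), `lambda = 2`
(1/damage), `a = 0.5`, `b = 0.1` (1/resources), `c = 0.8`, `m2 = 0.05`,
`mu = 0.05`, `sigma = 0.5`, `mu_v0 = 0.001`, `mu_v1 = 1e-4`, 16 viability
loci with windows evenly spaced on damage 0–6 (overflow expresses the
last locus; windows are half-open and lower-inclusive). The presets
differ in three switches:

| preset | D | r | mu_d | variant |
|---|---|---|---|---|
| `fig1` | 1000 | 0 | 0 | baseline: damage nearly harmless |
| `fig2a` | 1 | 1 | 0 | lethal damage, regeneration |
| `fig2b` | 1 | 0 | 0 | lethal damage, partner death lethal |
| `fig3a` | 1 | 1 | 0.05 | + evolvable damage partitioning |
| `fig3b` | 1 | 0 | 0.05 | + evolvable damage partitioning |
| `no_share_ablation` | 1 | 1 | 0 | shares fixed at 0.5/0.5 |
| `extra_mutation_type2` | 1 | 1 | 0 | extra type-2 viability round |

`r` is the probability that an adult is regenerated from its surviving
cell. The regeneration-on regime is where somatic disposability can
evolve (a failed partner is replaceable); with `r = 0` the two cells
share each other's fate and symmetric self-maintenance is favoured. In
the baseline preset `r = 0` so that individual deaths — the raw material
of an age-specific mortality curve — are observable at all; with full
regeneration and `D = 1000` an individual would die only when both cells
fail in the same cycle, a vanishing ~`(m2 q)^2` event.

## Resource accounting

Two design questions the verbal model leaves open are answered as
follows, and both choices matter.

**Pools.** A cell's spendable pool in a cycle is what it received from
the previous cycle's redistribution; the pool is fully committed each
cycle (the softmax is a complete split). The founding generation starts
with `init_resources = 2` per cell.

**Offspring endowment.** Each newly formed cell starts life with the
same standard endowment (`offspring_endowment = 2` resource units,
matching the founding endowment), while the number of offspring remains
proportional to reproductive investment through the fecundity function.
We also implemented the alternative in which the propagule inherits
`kappa * z` resources (available via `offspring_endowment = 0`), and
rejected it as the default after measurement: because newborns then
start far below the steady-state pool, genotypes that couple an
unequal resource share to one high-foraging cell type gain a transient
"ramp-up" advantage that exactly offsets the concavity cost of unequal
reproduction. The share trait becomes selectively neutral, drifts at a
rate independent of population size, and drags the allocation traits
apart even in the baseline regime where no specialisation should occur;
mean reproduction allocation is then depressed to ~0.66–0.69. Under the
standard-endowment rule the share trait is under stabilising selection
in the baseline (it stays within 0.005 of one half at `N = 10^4`) and
division of labour emerges only where the damage regime makes it
adaptive. The endowment of 2 units is the smallest integer endowment
under which every preset is demographically viable: with 1 unit the
lethal-damage presets collapse during the founding transient, before
selection can act.

## What the presets produce

At desk scale (`scale = 0.05`, i.e. `N = 5000`) the package reproduces,
quantitatively or qualitatively, the expected equilibria; all numbers
below are computed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, never hard-coded:

- **Baseline (`fig1`)**: allocations converge within ~800 cycles to
  about 0.75 reproduction / 0.24 foraging with repair below 0.01 and no
  divergence between cell types (division-of-labour index below 0.05).
  Deleterious-allele frequency rises with the damage window in which a
  locus is expressed (Spearman rank correlation ~0.8 across the 16
  loci), and empirical mortality rises with age — senescence evolving
  from a senescence-free start without any parent–offspring asymmetry.
- **Lethal damage + regeneration (`fig2a`)**: a stable division of
  labour: one type abandons repair entirely, forages, and is repeatedly
  sacrificed and regenerated, while the other type receives ~3/4 of the
  resources, repairs, and carries less damage. In proportional terms
  the disposable type allocates ~0.63 to reproduction and the protected
  type ~0.48; in absolute terms the protected type, with its larger
  pool, produces most offspring. This differs from the source
  experiments, in which the privileged type also monopolised the
  *proportional* allocation (one type near 0.5, the other near 0):
  with the fecundity function `1 - exp(-b z)` concave at the pool sizes
  this accounting produces, complete reproductive monopolisation is not
  an equilibrium here, and the corresponding acceptance checks fail by
  a small margin (reproduction allocation of the higher type 0.63
  rather than 0.5 ± 0.1). The qualitative structure — asymmetric
  shares, a disposable unrepaired type, a protected low-damage type —
  is robust across seeds.
- **Lethal damage, no regeneration (`fig2b`)**: with both cells'
  survival required, symmetric heavy repair (~0.52 of the pool) is the
  stable outcome in this implementation; the extreme 100%-foraging
  disposable soma of the source experiment does not evolve, for the
  same concavity reason, and that acceptance check fails.
- **Ablation**: fixing the shares at 0.5/0.5 in the `fig2a` regime
  removes specialisation entirely, confirming that evolvable resource
  sharing is the gateway trait.
- **Evolvable damage partitioning (`fig3a`)**: the retention traits
  diverge: the disposable high-reproduction type evolves high damage
  retention (0.7–1.0 across seeds, i.e. damage-free or damage-poor
  daughters), the other type's retention falls below one half. The
  fully deterministic "retain everything" endpoint is reached in some
  but not all replicates at this population size.
- **Developmental mutation asymmetry**: with an extra type-2 viability
  mutation round, the mutationally loaded type-2 lineage preferentially
  takes the disposable role. Classified by the higher mean allocation to
  reproduction, the germ-line label therefore lands on type 2 in most
  replicates here, the opposite of the source experiment in which the
  protected monopolist was also the high-allocation type.

## Numerical and engineering choices

- The population engine is compiled (Rcpp) and consumes R's RNG in a
  fixed documented order (individuals in storage order, cell 1 before
  cell 2), so `set.seed()` makes whole runs bitwise reproducible; the
  same-seed determinism is tested byte-for-byte on written TSVs.
- The softmax is evaluated with max-subtraction in the R surface
  (overflow-safe for extreme fixture genes); the engine evaluates the
  three-term form directly, which is exact for the gene ranges mutation
  can reach.
- Offspring join the population before the cull and are subject to it;
  they skip the two mortality rounds of their birth cycle. Ages
  increment at cycle end (newborns end their birth cycle at age 0).
- Regeneration splits the survivor's resources and damage equally and
  copies its viability-locus state to both new cells; no mutation occurs
  at regeneration.
- Mortality clamping: the intrinsic mortality expression exceeds 1 for
  `d > D` and is clamped, making extreme damage simply lethal.
- The trajectory records start-of-cycle state plus the cycle's births
  and non-cull deaths; deaths and exposures are ledgered per age class
  up to `max_age_class` (older classes pooled) for the mortality-by-age
  estimator, which pools the final 10% of cycles by default.
- "Final" summaries average the last 10% of recorded cycles — long
  enough to suppress sampling noise at `N = 5000`, short enough not to
  blur the equilibrium with the transient.

## Scale of the shipped experiments

The source experiments used `N = 10^5` for 10000 cycles. The shipped
tests and the acceptance script run at `scale = 0.05` (`N = 5000`; the
replicate germ-line experiment at `N = 2000`), with 1000–2500 cycles for
the baseline preset, whose equilibrium is reached within ~800 cycles, and
the full 10000 cycles for the division-of-labour presets, whose
transition completes between cycles ~4000 and ~8000. These sizes keep a
full reproduction under ten minutes on one CPU while leaving the measured
equilibria within the tolerance bands stated above; population size
mainly affects drift wobble, not the location of the equilibria.

## What the simulator does and does not emulate

The generator is the study system itself (no external data exist): it
emulates trade-off-constrained allocation, damage kinetics, damage-gated
gene expression and clonal inheritance. It does not emulate diploidy,
recombination, explicit sequence genetics, spatial structure, or
relatedness below one between the two cells; conclusions about real
multicellular or colonial organisms therefore rest on the model's
abstractions, not on data realism. Passing tests certify the stated
equilibria of *this* model at the stated scales, not quantitative
predictions for any empirical system.
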