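---
title: "A stochastic lattice chemistry for protocell emergence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic lattice chemistry for protocell emergence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protocellsim)
set.seed(1)
```

## Overview

`protocellsim` simulates an artificial chemistry on a two-dimensional
hexagonal lattice in which bounded, self-maintaining, replicating
structures — protocells — emerge from a homogeneous molecular soup. The
model couples three ingredients:

1. **Reaction–diffusion patterning.** Two morphogen pairs (a short-range
   activator lineage, molecules 2/4, and a long-range inhibitor lineage,
   molecules 3/5) realize a discrete, stochastic activator–inhibitor system.
   Their competition is resolved per cell by a threshold comparison
   controlled by a shape parameter `w`.
2. **Proto-genetic information.** Polymer 1 ("informant") is a 100-mer of
   molecules 6 and 7 whose molecule-6 fraction *is* `w`. Cells read `w` from
   the informants they contain; informants replicate by copying the template
   ratio from local monomer pools, so the parameter is heritable.
3. **A membrane.** Polymer 2 is a 100-mer of molecule 12, synthesized where
   the patterning subsystem signals membrane activity (molecule 13) and
   degraded elsewhere. Its spatial accumulation defines the cell-like
   region.

All state is integer molecule counts; every reaction is a multiset rewriting
rule that conserves the total monomer inventory exactly. The package also
contains a deterministic cellular-automaton reference model implementing the
same threshold comparison directly, used to cross-validate the chemistry,
plus entropy accounting and pattern metrics.

## The lattice

`lattice_config(width, height)` builds a periodic hexagonal grid in
odd-row-offset coordinates. Each cell has exactly six neighbors
(E, W, NE, NW, SE, SW) and the neighbor relation is symmetric across the
wrap. Because the half-cell row offset alternates with row parity, the row
count must be even — an odd height would break neighbor symmetry across the
vertical boundary, so the constructor rejects it. Widths of at least 3 and
even heights of at least 4 are accepted.

```{r}
cfg <- lattice_config(6, 6)
neighbors(cfg, 1, 1)
```

## Diffusion

Free species move by a *residual rate* `r`: of `b` molecules in a cell,
`round(b * r)` stay, and the movers split evenly over the six neighbors
(`floor(moved / 6)` each); the indivisible remainder (`moved mod 6`
molecules) goes one-by-one to distinct neighbors chosen uniformly at random.
Large `r` means slow spreading. The default residual table makes the
activator lineage slow (`r = 0.75` for molecules 2/4) and the inhibitor
lineage fast (`r = 0.05` for molecules 3/5) — the classic Turing condition —
while signal carriers (8–11, 13–15) move freely (`r` near 0 or 1 as
appropriate) and the raw material (molecule 1) mixes completely (`r = 0`).
Polymer boxes diffuse per box: each box independently stays with probability
`r` (informants `r = 0.1`, membrane boxes `r = 0.75`), the movers choosing a
direction uniformly.

Rounding uses round-half-up throughout (`floor(x + 0.5)`), not R's
banker's rounding: the rule must be deterministic and monotone in `b` so
that the residual fraction is exact for the tabulated rates.

## Reactions

Each step applies, in every cell, a fixed stage order (see
`?network_definition` for the full rule list):

* **A** maturation: 2 → 4 at 5 %, 3 → 5 at 2 % per step. Fractional
  expectations are realized as `floor(count * p)` plus a Bernoulli unit with
  probability equal to the fractional part, so the expected conversion is
  exactly `count * p` with the smallest possible variance.
* **B** amplification: molecules 4 and 5 catalytically convert the
  molecule-1 pool into signal carriers 8, 11 and 9, one unit per catalyst
  unit, drawing the pool down in listed order.
* **C** threshold comparison: the pooled 8 + 9 count converts to molecule 10
  at ratio `w` (round-half-up), the remainder resets to molecule 1. Pooling
  before rounding matters: it makes the subsequent survival condition for
  molecule 11 exactly `n11 > round((n8 + n9) * w)`, the same comparison the
  reference automaton applies (`N1 > N2 * w`).
* **D** pair annihilation 10 + 11 → 1 + 1: the more abundant side survives.
* **E** the window subsystem (below).
* **F** morphogen regeneration: molecules 11, 13 and 14 convert molecule 1
  back into fresh 2 and 3.
* **G** removals: 4, 5 at 5 %, 8, 9 at 100 %, 10, 11 at 5 %, 13 at 75 %.

### The persistence window

Stage E is a single pass of three 100 % rules in listed order:
14 + 11 → 14 + 1, 15 + 11 → 15 + 13, 13 + 11 → 11 + 11. Molecules 14 and 15
act purely catalytically. The net effect is that molecule 13 — the membrane
trigger — survives the pass only when the incoming molecule-11 count lies in
one finite contiguous window: with `c14` and `c15` counts of molecules 14
and 15 the window is exactly `{c14 + 1, …, c14 + 2 * c15 − 1}`, i.e. 4–20
for the standard counts (3, 9). The lower edge is anchored by the
molecule-14 destruction step; the upper edge arises because surplus
molecule 11 converts the freshly made 13 back via the third rule. The test
suite verifies contiguity and the edge formulas by brute-force enumeration.

### Stage-F gating: a design choice

With stage F applied unconditionally, molecule 14 (present in every cell)
acts as a ubiquitous morphogen source: informant-free cells then accumulate
molecule 11 without bound, the activator pool runs away, and the shape
parameter loses its effect — every `w` produces the same transient bloom and
collapse. The package therefore gates stage F on the presence of
molecule 13 by default (`network_definition(regen_gate = "mol13")`):
membrane-active cells are the morphogen sources, which ties the source
strength to the persistence window and keeps the pattern amplitude
self-limited. This restores the expected phenomenology (mesh at low `w`,
intermittent replication at the standard `w`, extinction at high `w`).
`regen_gate = "none"` recovers the ungated variant for comparison.

### Cells without informants

Where a cell contains no informant, `w` is undefined. The package skips the
stage-C ratio conversion there (no molecule 10 is produced) rather than
substituting an arbitrary default: informants cover only a small fraction of
the lattice, and treating their absence as `w = 1` (full inhibition)
extinguishes all dynamics, while `w = 0` would make patterning global and
information-independent.

## Polymers

Informant synthesis happens in cells holding at least one template, at least
one unit of molecule 11, and sufficient free monomers: one new 100-box is
filled per cell per step, its composition `round(w_local * 100)` molecule-6
units (round-half-up) and the rest molecule 7, debited from the local pools.
Compositions are stored in a registry (`p1_comps`) with per-cell box counts
(`p1_counts`), so a lattice of thousands of cells tracks arbitrarily many
composition lineages cheaply. Informants never decompose.

Membrane synthesis fills one 100-box of molecule 12 per step in cells with
molecule 13 present and at least 100 free monomers. Degradation empties each
box with probability 0.05 per step — but only in cells lacking molecule 13,
so active cells maintain their membrane against decay.

## A step, and what is conserved

`step_grid()` applies: diffusion of everything → stages A–F (reading
`w_local` from the informants after diffusion) → informant synthesis →
membrane synthesis → stage G → membrane degradation. The grand total

```
sum(species) + 100 * (#polymer-1 boxes) + 100 * (#polymer-2 boxes)
```

is invariant under every stage, exactly, at every step; the test suite
asserts bit-exact equality along full runs.

## Entropy accounting

* **Morphological entropy** of an occupancy vector is
  `max_config_entropy − config_entropy`, with the configuration entropy the
  Stirling form `X ln X − Σ m_i ln m_i` (natural log). Uniform placement
  gives 0; full clustering of `X` units gives `X ln(number of cells)`. It is
  recorded for the membrane-box arrangement and grows as domains form.
* **Diffusion entropy production** is the discrete gradient functional
  `Σ (Δn)² / mean(n)` over unordered adjacent cell pairs (each lattice edge
  counted once).
* **Reaction entropy production** tallies `+1` for each molecule converted
  away from molecule 1 and `−1` for each returned, accumulated over the run
  (`S_R_cum` in the ledger). In a healthy run it increases monotonically —
  the chemistry keeps dissipating — while the morphological entropy stays
  positive after domain formation: sustained order paid for by sustained
  dissipation.

## Initial condition and seed geometries

The standard initial state is uniform: 10⁶ of molecule 1, 5 × 10⁴ each of
monomers 6 and 7, 10⁵ of monomer 12, and window controls (3, 9) per cell; a
central radius-2 hex disk (19 cells) is seeded with 100 each of molecules 2
and 3; ten founder informants encoding `w = 0.650` (composition 65:35) are
scattered over a central radius-3 disk. `seed_geometry()` offers three
central seed arrangements (one radius-2 disk, one radius-1 disk, two
radius-1 disks) to check that results do not depend on the exact seed shape.

## Pattern metrics and classification

The membrane region is the set of cells holding at least one polymer-2 box;
`count_domains()` labels its connected components under hexagonal
6-adjacency with periodic wrap. `classify_pattern()` reduces a recorded
domain time series to four qualitative classes: **mesh** (final coverage
above 0.25 of the lattice), **extinct** (coverage returns to zero after
having been positive), **replicating** (domain count exceeded 1 while
coverage stayed moderate), **stationary** (otherwise). The classifier
requires at least 500 recorded steps so transients are not classified.

## The cellular-automaton reference

`run_ca()` implements the threshold comparison directly as a two-state
automaton: a cell activates when its active count `N1` within hex radius
`s = 2` (19 cells) exceeds `w` times the active count `N2` within radius
`t = 4` (61 cells). A banded variant deactivates cells again above a second
threshold `w2`, splitting compact domains into spots. The automaton shares
the chemistry's neighborhood geometry and is used in the test suite as an
independent oracle for the stage-C/D survival condition.

## Worked example

A reduced-scale run (the defaults are a 100 × 100 lattice for 2 000 steps;
60 × 60 for 1 500 steps reproduces the qualitative regimes in a few minutes
and is what the test suite uses):

```{r, eval = FALSE}
run <- run_protocell(run_config(width = 60, height = 60, steps = 1500,
                                seed = 2, w = 0.650, record_every = 25))
summary(run)
plot(run)
```

Sweeping the shape parameter across the three regimes:

```{r, eval = FALSE}
runs <- sweep_protocell(run_config(width = 60, height = 60, steps = 1500,
                                   record_every = 25),
                        axis = "w", values = c(0.575, 0.650, 0.725))
sapply(runs, function(r) classify_pattern(r$ledger))
#>       0.575       0.65       0.725
#>      "mesh" "replicating"  "extinct"
```

At the standard `w = 0.650` the outcome is *intermittent*: domains form,
split, and sometimes the whole population dies out; across seeds both
`"replicating"` and `"extinct"` occur. This is a property of the regime, not
a numerical artifact.

## What these experiments do and do not show

The simulations demonstrate that heritable information (the informant
ratio), metabolism (the dissipative reaction cycle) and compartmentalization
(the membrane region) can arise and couple in a closed, conservative toy
chemistry, and that a single inherited parameter selects qualitatively
different fates. They do not model real prebiotic chemistry: species are
abstract tokens, rate constants are per-step probabilities chosen for
pattern formation rather than fitted to kinetics, and the 100-mer polymer
sizes are bookkeeping conventions. Conclusions should be read at the level
of mechanism classes, not molecules.

## Limitations

* Dynamics at the regime boundaries are stochastic; single runs near
  `w = 0.650` can die out. Ensemble statements require multiple seeds.
* The lattice is synchronous; all cells update from the pre-step state.
  Asynchronous update schemes may shift regime boundaries.
* Informant compositions replicate exactly (ratio copying with round-half-up)
  — there is no mutation operator, so evolutionary dynamics beyond
  persistence of the founder ratio are out of scope.
* Performance is adequate for lattices up to a few hundred cells per side
  (a 60 × 60 × 1 500-step run takes on the order of a minute); the
  implementation is vectorized base R, not compiled code.
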