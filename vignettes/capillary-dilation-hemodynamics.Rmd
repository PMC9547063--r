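---
title: "Modelling focal capillary dilation in cortical microvascular networks"
author: "capflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling focal capillary dilation in cortical microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Brain capillaries are covered by pericytes, contractile mural cells that
set capillary tone.  When a few contiguous pericytes die, the capillaries
they covered dilate focally.  Because a capillary bed is a tightly coupled
resistor network, a purely local dilation redistributes flow globally:
dilated segments draw extra flow, sister branches at divergent
bifurcations are "stolen" from, and the heterogeneity of capillary flow
rises.  `capflow` provides an in silico version of this experiment: it
builds synthetic cortical microvascular networks, simulates blood flow
with discrete red-blood-cell (RBC) tracking, applies focal dilations of
+0.6, +1.1 and +1.6 µm to a set of 13–15 capillaries (the average adult,
average aged, and extreme aged responses to ablation of three pericytes),
and quantifies the resulting flow redistribution.

## Flow model

Reynolds numbers in the microvasculature are below one, so each vessel is
a Poiseuille resistor.  For vessel $ij$ with diameter $D_{ij}$ and length
$L_{ij}$,

$$ q_{ij} \;=\; \frac{p_i - p_j}{R^e_{ij}}
   \;=\; \frac{\pi D_{ij}^4}{128\, L_{ij}\, \mu\, \mu^e_{rel}}\,(p_i-p_j), $$

with plasma viscosity $\mu$ (default $1.2\times10^{-3}$ Pa s, a
conventional plasma value — a package default, not a measured quantity)
and the relative effective viscosity $\mu^e_{rel}(D, H_d)$ taken from the
standard empirical in vitro law (recorded as `law_version =
"pries_invitro"`).  Units are µm, mmHg, µm³/ms throughout; the conversion
constant is centralised in the package.

Mass balance at every interior bifurcation yields a sparse symmetric
positive-definite system on the node pressures.  `solvePressures()` uses
a sparse Cholesky factorisation (`Matrix`); inside the RBC loop the C++
core re-solves with an IC(0)-preconditioned conjugate gradient, warm
started from the previous pressure field, converged until the *true*
residual (recomputed, not the recursive CG residual) falls below
$10^{-12}$ of the mean absolute flow.  Pressures are solved relative to
the mean boundary pressure, which preserves precision in the pressure
differences that determine the flows.  Interior-node imbalance is
asserted after every solve; the worst case across a run is reported in
the simulation diagnostics.

## Blood rheology

Three empirical laws couple the RBCs to the flow field:

* **Effective viscosity** $\mu_{rel}(D, H_d)$: equals 1 at zero
  hematocrit, increases with hematocrit, and as a function of diameter
  passes through the Fåhræus–Lindqvist minimum near 7–10 µm.
* **Fåhræus effect**: RBCs travel faster than bulk blood, so the tube
  hematocrit $H_t$ is below the discharge hematocrit $H_d$.  The forward
  relation $H_t/H_d = H_d + (1-H_d)X(D)$ is inverted in closed form
  (quadratic); at very small diameters the fitted $X(D)$ slightly exceeds
  one, so the inverse is clamped to keep $H_d \ge H_t$.
* **Phase separation (Zweifach–Fung)**: at a divergent bifurcation the
  daughter with the larger flow receives a disproportionately large RBC
  fraction; below a flow-fraction cutoff $X_0$ a daughter receives no
  RBCs at all, which is what allows flow steal to fully de-perfuse a
  branch.  The logit-linear law with the diameter-asymmetry term is used
  for parents wider than the single-file threshold (10 µm).

The C++ implementations of these laws are the single source of truth;
the exported R functions (`relativeViscosity()`, `dischargeHematocrit()`,
`phaseSeparation()`) are thin wrappers over them, and the test suite
checks them against values computed with an independent implementation.

## Discrete RBC tracking

RBCs are tracked individually.  Each cell advects along its vessel at
$v_{rbc} = u \cdot H_d/H_t$, the bulk velocity times the Fåhræus ratio.
A cell reaching a bifurcation within a step stops at the node and is
routed at the start of the next step:

* boundary node → the cell leaves the domain (boundary nodes are
  pressure reservoirs);
* one outflow → the cell follows it;
* divergent, parent wider than 10 µm → the empirical phase-separation
  law is sampled;
* divergent, single-file parent → the cell follows the path of the
  largest pressure force.  We evaluate that force as the viscous drag of
  the branch stream on the cell sitting at the junction mouth, which is
  proportional to the branch bulk flow, so the cell enters the currently
  strongest stream.  This choice matters: a *static* force measure (the
  pressure gradient, with or without a lumen-area factor) is not
  self-limiting — the favored branch collects every cell, clogs, and can
  end up carrying *less* flow than its sister while still attracting all
  cells, which inverts the Zweifach–Fung partitioning.  The drag-based
  rule is self-limiting (a loading branch slows down and stops
  collecting) and reproduces the expected partitioning; with exactly
  symmetric daughters the tie is broken at random and the hematocrit
  feedback produces alternation and a 50/50 time-averaged split.

A vessel already at the hematocrit cap accepts no further cells (they
wait at the node until the next re-solve); likewise injection skips a
full entry vessel.  Tube hematocrit is cell count × cell volume / vessel
volume, capped at 0.9 for the viscosity law (persistent excess is counted
as jamming in the diagnostics); the mouse RBC volume default is 55 µm³.
New cells enter at every inflow boundary vessel as Poisson arrivals with
rate $|q| H_{in} / V_{rbc}$ at the fixed inflow (discharge) hematocrit of
0.3, and the initial state seeds every vessel at the tube-hematocrit
equivalent of 0.3.

Hematocrit, viscosity and pressures are re-coupled every
`couplingInterval` steps; between re-solves the flow field is frozen.
The default time step is 0.1 ms (cells move well under one vessel length
per step; an over-coarse step is rejected with a suggested bound).  The
time-averaged flow field — the unit of comparison between scenarios — is
accumulated over a 15.4 s window after a warm-up of one full window, so
averaging starts from a developed RBC distribution.  The per-vessel RBC
flux is counted from cells leaving each vessel during the window; the
mean discharge hematocrit is stored so the product
$\bar q \cdot \bar H_d / V_{rbc}$ can be compared against the counted
flux (they agree within a few percent on loop toys).

Randomness uses per-entity counter-based streams derived from the
simulation seed: every boundary vessel owns its injection stream and
every node its routing stream.  Runs are bit-for-bit reproducible for a
given seed, and paired scenario comparisons (baseline vs dilated under
the same seed) share injection times and routing draws — common random
numbers — which removes part of the Monte-Carlo noise from their
differences.  The remaining scenario-comparison noise is physical: RBC
routing is chaotic, and trajectories decorrelate within seconds of
simulated time.

## The synthetic network generator

Real vectorised cortical networks are not generally available, so the
generator emulates their summary statistics:

* a connected 3-D capillary mesh: a jittered cubic lattice whose random
  connected edge subset has mean bifurcation degree ≈ 3, with tortuous
  segment lengths (mean ≈ 60 µm, configurable — a free parameter chosen
  as a plausible cortical segment length);
* capillary-zone diameters from a truncated normal, 3.04 ± 0.59 µm on
  [2.17, 4.81] µm, matching in vivo capillary measurements;
* ≥ 94 % of vessels are capillaries;
* penetrating arterioles (trunk 15 µm, tapering with depth) descending
  from the pial surface, coupling to the mesh at every trunk level
  through short transition offshoots; ascending venules (trunk 20 µm,
  twice as numerous) draining it; pial vessels connect trunks to
  boundary nodes at the surface;
* first-order transition vessels — arteriole-capillary transition zone
  and postcapillary venules — are drawn wider (~5 ± 0.5 µm on [4, 6]):
  these are ensheathing-pericyte territory in vivo and are not part of
  the capillary-zone diameter statistics.  Without this, the transition
  segments dissipate most of the arteriovenous pressure difference once
  loaded with RBCs and capillary perfusion falls an order of magnitude
  below in vivo flux;
* all lattice nodes on the domain faces are flagged as boundary nodes
  (cut capillaries), as in an acquired tissue block.

Default boundary conditions put 60 mmHg on arterial-side boundary nodes,
10 mmHg on venous-side ones, and interpolate capillary cuts between the
two levels by relative hop distance to the nearest arterial and venous
boundary nodes.  These are package conventions (config-exposed), chosen
to give arteriole → capillary → venule flow for the overwhelming majority
of transition vessels; all downstream analyses are relative (baseline vs
dilated), so the absolute pressure level matters little.

What the generator does *not* emulate: real angio-architecture (vessel
curvature, depth-dependent densities, pial collateral networks, true
branch-length distributions), oxygen transport, vessel compliance, or
pulsatility.  Passing tests on synthetic networks therefore demonstrate
the *mechanisms* (steal, heterogeneity increase, stall redistribution),
not quantitative agreement with any particular animal's microvasculature.
Capillary flows in the synthetic mesh are a few µm³/ms — lower than
typical awake-mouse fluxes, largely because every capillary-zone segment
draws from the narrow in vivo diameter distribution — so relative-change
analyses carry more Monte-Carlo noise than they would on a real acquired
network, which is why scenario comparisons are paired and case data are
pooled.

## The in silico ablation protocol

A **base capillary** must satisfy all of: capillary type; cortical depth
20–120 µm (midpoint z); more than 4 branch orders from the 0th-order
descending-arteriole main branch; more than 1 branch from the ascending
venule main branch; at least 2 branches from the simulation-domain
boundary; and x-y distance to the network centre below 0.9 × the mean
vessel distance.  The **affected set** grows from the base capillary's
upstream bifurcation (higher-pressure endpoint at baseline; near-zero
flow ties break toward the lower-arteriole-order endpoint): adjacent
capillaries (generation 1), then their neighbors, until ≥ 6 cells are
added; the same expansion then starts at the downstream node until the
set holds ≥ 13 capillaries.  Vessels that are 0th-order mains, less than
two branches from a descending-arteriole main, or less than two branches
from the boundary are never added.  Within a generation, vessels join in
ascending id order, and the final generation is truncated so the set
never exceeds 15 — both deterministic tie-breaks the rule itself leaves
open.  Dilation then adds exactly +0.6, +1.1 or +1.6 µm to every affected
diameter and re-runs the simulation under the same seed.

## Analysis conventions

* Relative flow changes are computed on *magnitudes* of the
  time-averaged flow, so a direction reversal registers as a large
  change.  Changes whose absolute difference is below 0.1 µm³/ms are set
  to zero, and only relative changes above 10 % count as increases or
  decreases.
* Neighbor classes are mutually exclusive with precedence dilated >
  gen1 > gen2 (adjacency = sharing a node; gen1/gen2 restricted to
  capillaries).
* The distance-to-centre profile measures each vessel's midpoint against
  the mean coordinate of the dilated capillaries' bifurcations, binned
  (default 50 µm), increases and decreases separated, medians and
  quartiles per bin.
* The baseline heterogeneity reference is the median SD of baseline flow
  over many affected-style sets built around qualifying base capillaries
  (sampled when more qualify than requested); the 0.50 and 0.75
  quantiles are kept alongside.
* The stall threshold is the 5th percentile (linear interpolation
  between order statistics, the default quantile rule) of baseline flow
  magnitudes among vessels with midpoint depth ≤ 200 µm.
* Multi-case summaries pool the per-vessel records of all cases.

## Problem sizes and numerical settings used by the tests

The shipped acceptance checks run two generated networks of ≈ 3,000
vessels (seeds 1 and 2) with two base capillaries each — four cases, 14
simulations of 15.4 s warm-up + 15.4 s averaging at dt = 0.1 ms with a
10 ms coupling interval at this scale (1 ms on toys).  These sizes were
chosen so a full experiment runs in minutes on a single CPU while leaving
dozens of qualifying base capillaries per network; the generator reaches
larger networks by configuration.

## Known limitations

* The in vitro viscosity law ignores the endothelial surface layer; no
  in vivo variant is provided.
* No oxygen transport, no vessel compliance, no pulsatility, no blood
  cell adhesion or leukocytes.
* Single-file routing is a one-cell-per-event rule; cell–cell
  interactions inside a vessel are summarised by the hematocrit-dependent
  viscosity only, so per-cell plugging effects in the narrowest vessels
  are underrepresented.  On an *isolated* capillary-scale Y-bifurcation
  this lets the starved sister branch fall to plasma viscosity and gain
  bulk flow even as it loses its RBC supply; in a full network, where
  sister branches stay hematocrit-fed through their other connections,
  bulk-flow steal appears alongside RBC-flux steal.  The package's toy
  steal demonstrations therefore use a transition-scale bifurcation in
  the empirical partitioning regime.
* Boundary pressures for capillary cuts are a documented convention, not
  fitted to data; only relative comparisons should be interpreted.
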