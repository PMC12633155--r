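---
title: "Methods: the fibrogrid reaction–diffusion model of fibrotic signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fibrogrid reaction–diffusion model of fibrotic signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fibrogrid` couples two classic modeling idioms: a logic-based
normalized-activity ODE network (the style long used for fibroblast and
cardiomyocyte signaling models, where each species is an activity in
[0, 1] rather than a copy number) inside every cell, and a discrete
reaction–diffusion layer between cells. This vignette is the package's own
account of the model, its parameters, the numerical scheme, and the
design decisions taken where more than one defensible choice existed.

## The per-cell network

Every species obeys

$$\frac{dX_i}{dt} = \sum_j k_j \prod_{a \in A_j} X_a
  \;-\; \sum_l k_l \, X_i \prod_{m \in M_l} X_m \;-\; k_{deg} X_i,$$

production edges minus inhibition edges minus first-order decay.
Multiplicative combination is used everywhere: an edge with several
activators is an AND gate, and inhibitors multiply onto the target's own
activity. This is the single combination rule of the model; there is no
saturating Hill layer. The consequences matter for interpretation:
activities superpose linearly at junctions where several edges converge
(until the [0, 1] clamp engages), and a chain of unit-rate production
edges transmits its upstream activity with gain one.

Three species classes are structurally special but mathematically the
same form:

* **Inputs** integrate the external stimulus and the local feedback field:
  $dX/dt = k_{input} I_{ext} + k_{feedback} C_{fb} - k_{deg} X$. Their
  fixed point, $\min(1, (k_{input} I + k_{feedback} C)/k_{deg})$, is the
  closed form the test suite checks the integrator against.
* **Receptors** carry a ligand production edge at $k_{receptor}$ and
  competitive inhibition edges at $k_{inhibition}$ (BAMBI on the TGF-β
  receptor, Smad7 via receptor degradation, ER-β on AT1R, PKA-mediated
  β-AR desensitization). The receptor pool is normalized to 1 — receptor
  synthesis and trafficking are not modeled, so $R_{total}$ never appears
  as a dynamic quantity.
* **Kinase/phosphatase cycles** use a production edge from the upstream
  kinase (optionally ANDed with a substrate species) and inhibition edges
  from phosphatases.

Per-edge rates default by class — $k_{receptor}$ for ligand→receptor
edges, $k_{inhibition}$ for every inhibition, $k_{activation}$ for all
other production — because the model deliberately exposes only eight
global constants; an edge may override its rate where the topology needs
a weight (see below).

## The reference network

The packaged network (`build_reference_network()`, also shipped as
`inst/extdata/reference_network.yaml` with a one-line literature
rationale per edge) encodes the canonical cardiac-fibrosis pathway map:
TGF-β/Smad3 collagen induction with Smad7/BAMBI negative feedback; AngII
through Gq/PLC/Ca/PKC and NADPH-oxidase ROS; IL6/JAK/STAT; IL1 and TNF-α
through TAK1/IKK/NF-κB; norepinephrine through cAMP/PKA/CREB; PDGF
through Ras/ERK and PI3K/Akt/mTOR; ET1 through Gq; natriuretic peptides
and estrogen as the anti-fibrotic arm (cGMP/PKG inhibition of Ca, RhoA
and Smad3; ER-β antagonism of AT1R); and integrin/FAK/Rho/ROCK
mechanotransduction converging on MRTF/SRF and YAP. The census is 132
species — 10 inputs, 10 receptors, 8 second messengers, 15
kinases/phosphatases, 12 MAPK components, 8 transcription-factor
families, 18 mechanotransduction components, 20 ECM outputs, 4 secreted
feedback precursors and 27 further intermediates — wired by 212 edges.

Two sets of explicit edge weights are the only departures from the
class-default rates, and both are structural requirements of a
normalized-gain network rather than tuning:

* **Mechanosensing attenuation.** The loop tension → integrin → FAK →
  RhoA → ROCK → MLC → tension would have loop gain ≥ 1 with unit rates,
  making the resting cell self-sustaining: any initial noise would latch
  the whole mechanotransduction and PI3K axis at full activation. The two
  loop-closing edges (tension and matrix-tension feedback onto integrin)
  carry rate 0.4, putting the resting loop gain at 0.8 so quiescent
  tissue relaxes to the zero fixed point while stimulated tissue still
  engages the loop.
* **Collagen output weights.** Procollagen I and III sum five production
  edges (Smad3; the cooperative Smad3·AP-1 AND gate; CTGF; EGR1; CREB).
  With unit rates, Smad3 alone saturates the precursor, leaving no
  dynamic range for combinatorial stimulation. The weights (0.5, 1.0,
  0.3, 0.2, 0.2) let a single pathway reach roughly half-maximal
  synthesis and multi-pathway stimulation approach saturation, which is
  what makes the multi-cytokine scenario visibly exceed TGF-β alone.

Phosphatases (PP1, PP2A) have no production edges: they act only as
constitutive brakes and stay at zero in a fully quiescent cell. This is a
known simplification of the normalized-activity formalism — at the zero
state every pure-degradation species has derivative exactly zero, a
property the test suite asserts.

## Spatial coupling

Four diffusible feedback molecules (TGF-βfb, AngIIfb, IL6fb, ET1fb) are
secreted from intracellular precursors at $k_{production}$, diffuse over
the 8-connected neighborhood with periodic boundaries,

$$\frac{dC^{(k)}_{ij}}{dt} = D_k \sum_{(m,n) \in N_{ij}} (C^{(k)}_{mn} -
  C^{(k)}_{ij}) + P^{(k)}_{ij} - \lambda_k C^{(k)}_{ij},$$

and feed back onto their cognate input species. Mechanical tension is
the fifth feedback mechanism of the biology, but it propagates through
cell–matrix contacts rather than by diffusion, so it is modeled as an
intracellular species (tensionfb) inside the 132, not as a spatial
field — which is also what makes the variable accounting exact:
$132 \cdot N^2$ intracellular plus $4 \cdot N^2$ field variables, i.e.
1.36 million coupled ODEs at $N = 100$.

The Laplacian sums raw neighbor differences over all 8 neighbors with no
distance weighting of the diagonals and no $1/|N|$ normalization; it is
antisymmetric in cell pairs, so it conserves the grid total exactly (the
conservation tests run it for 100 steps and on random fields). ECM fields
obey the same equation with the diffusion coefficient hard-wired to
$0.2 \, k_{diffusion}$ — the 20% factor is part of the model, not a
tunable — reflecting the limited mobility of large matrix proteins.
Production $P$ is $k_{production}$ times the designated intracellular
precursor, and clearance $\lambda$ defaults to $k_{degradation}$; both
reuse declared constants so the eight-constant interface stays complete.

## Numerical scheme

* **Integrator**: forward Euler,
  $X(t+\Delta t) = X(t) + \Delta t \, dX/dt$, with every concentration
  clamped to [0, 1] once per completed update. Derivatives are always
  evaluated on the current (pre-clamp) state; the clamp is part of the
  update, not of the right-hand side.
* **Adaptive step**: $\Delta t = \min(dt_{max}, \theta / \max|dX/dt|)$
  with $dt_{max} = 0.1$ and safety factor $\theta = 0.1$, taking the
  maximum over all intracellular and field derivatives. When nothing
  changes, the step caps at $dt_{max}$. The preset scenarios instead use
  a fixed $\Delta t = 0.1$ so that iteration counts map one-to-one onto
  simulation time (500 iterations = 50 time units), which keeps snapshot
  indices meaningful across runs.
* **Stability**: the explicit 8-neighbor scheme requires
  $8 D \Delta t < 1$; the defaults give $8 \cdot 0.25 \cdot 0.1 = 0.2$,
  comfortably inside the stable region, and the clamp bounds any
  remaining excursion.
* **Grid**: coordinates are 0-based with modulo-$N$ wrap-around;
  $N \ge 3$ is enforced so the 8-neighborhood never aliases onto the
  center cell. Degenerate inputs (empty brush mask, zero-state grids,
  non-finite derivatives) either yield well-defined results (an empty
  mask reports an `NA` inside-mean rather than erroring) or fail fast
  with the offending cell and species named.

## Initial conditions and what the scenarios emulate

Runs start from uniform random noise: every intracellular species and
every ECM plane draws from $U[0, a]$ with amplitude $a = 0.1$ by default,
seeded and therefore exactly reproducible; secreted feedback fields start
at zero. The uniform distribution is a modeling choice — the biology
motivates "small random initial activity", not a specific law — and the
amplitude is configurable. The three preset scenarios emulate the
canonical spatial experiments: unstimulated relaxation (case 1),
localized TGF-β = 1 in an X-shaped brush mask (case 2, the X taken as
both full diagonals at width 1), and six-cytokine combinatorial
stimulation in the same mask (case 3). Assigned inputs are held constant
for the whole run.

These synthetic conditions capture paracrine spread, gradient formation
and combinatorial synergy, but deliberately not several features of real
scar tissue: there is no fibroblast heterogeneity (every cell runs
identical parameters), no cell migration or proliferation, no explicit
mechanics (tension is a signaling species, not a force balance), no
stochasticity beyond the initial condition, and normalized units
throughout (no physical concentrations, diffusivities or seconds).
Passing the packaged tests therefore demonstrates correctness of the
stated model on these conditions — not quantitative fidelity to tissue
data.

## Problem sizes and verification strategy

The test suite and the acceptance script run the full 500-iteration case
scenarios at $N = 30$ (900 cells, ~122k coupled ODEs) and verify the
engine at $N = 100$ only through the variable census; the spatial
orderings being checked (inside > ring > far outside; case 3 ≥ case 2 ≥
case 1 in grid-mean procollagen I) are scale-robust, and per-cell values
of any particular published frame are figure-only data that no
reimplementation can match cell-by-cell. Correctness of the vectorized
engine rests on dual-route checks: derivative evaluation against a naive
term-by-term summation over the raw edge list, full grid steps against a
per-cell, per-neighbor loop, single-cell trajectories against an
independent ODE solver (deSolve), reachability against igraph, and
closed-form fixed points of the input and receptor equations.

## Known limitations

Single integrator (no Runge–Kutta or implicit option), 2-D grids only,
periodic boundaries only, homogeneous cell population, and a curated —
not inferred — topology: the reference network is one defensible
synthesis of the pathway literature, shipped as an editable YAML file
precisely so users can disagree edge by edge and substitute their own
network without touching the engine.
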