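# fibrogrid

Spatially resolved simulation of cardiac fibroblast signaling and
extracellular-matrix (ECM) remodeling.

Cardiac fibrosis — the excessive deposition of collagen and other matrix
proteins by fibroblasts — is a central process in heart failure. Whether a
patch of scar tissue grows or resolves is decided by an intracellular
signaling network (growth factors, cytokines and mechanical tension acting
through receptors, second messengers, kinase cascades and transcription
factors onto collagens, matrix metalloproteinases and their inhibitors),
coupled *between* cells by secreted paracrine molecules that diffuse
through the tissue. `fibrogrid` simulates exactly this: a tissue of
N × N fibroblasts, each running the same ordinary-differential-equation
model of the fibroblast signaling network, coupled by diffusing feedback
molecules and slowly diffusing ECM fields, with brush-mask stimulation of
arbitrary cell subsets.

The package is aimed at systems-biology researchers who want a scriptable,
reproducible engine for spatial what-if experiments on fibrotic signaling
— localized cytokine application, combinatorial stimulation, rate-constant
perturbations — without a GUI in the loop.

## The model

Every molecular species is a normalized activity `X ∈ [0, 1]`. Inside each
cell, species follow mass-action kinetics with multiplicative regulation:

```
dX_i/dt =  Σ_j k_j  Π_{a ∈ activators_j} X_a        (production edges)
         − Σ_l k_l  X_i  Π_{m ∈ inhibitors_l} X_m   (inhibition edges)
         − k_degradation X_i
```

A production edge with several activators is an AND gate (the activators
multiply). Input species (TGF-β, AngII, IL6, IL1, TNF-α, NE, PDGF, ET1,
natriuretic peptides, estrogen) instead integrate external stimulus and
paracrine feedback, `dX/dt = k_input·I_ext + k_feedback·C_fb − k_deg·X`;
receptor activation with competitive endogenous inhibition (BAMBI on the
TGF-β receptor, ER-β on the AT1 receptor, ...) and kinase/phosphatase
cycles are the same form with class-specific rate constants.

Cells sit on a periodic N × N lattice. Four secreted feedback molecules
(TGF-βfb, AngIIfb, IL6fb, ET1fb) diffuse over the 8-connected
neighborhood,

```
dC_ij/dt = D Σ_{(m,n) ∈ N_ij} (C_mn − C_ij) + k_production·X_precursor − λ C_ij ,
```

and re-enter neighboring cells through the `k_feedback` term, closing the
autocrine/paracrine loop. ECM fields (procollagen I/III, proMMPs, TIMPs,
periostin, fibronectin, ...) obey the same equation but diffuse at 20% of
the feedback rate, reflecting their bulkier biophysics. Integration is
clamped forward Euler with an adaptive step, `dt = min(dt_max,
θ / max|dX/dt|)`; every concentration is clipped to [0, 1] after each
update. The packaged reference network has 132 species and 212 edges per
cell; at the default 100 × 100 grid that is 1,320,000 intracellular plus
40,000 field variables — 1.36 million coupled ODEs.

Eight global rate constants (`k_input`, `k_feedback`, `k_degradation`,
`k_receptor`, `k_inhibition`, `k_activation`, `k_production`,
`k_diffusion`) are user-tunable, defaulting to
(1, 0.5, 1, 2, 0.5, 1, 0.01, 0.25).

## Worked example

Localized TGF-β stimulation of an X-shaped cell population (preset
case 2) on a 30 × 30 grid:

```r
library(fibrogrid)
net <- build_reference_network()
summary(net)
#> <ecm_network> 132 species, 212 edges, 10 inputs
#>   feedback fields: TGFBfb, AngIIfb, IL6fb, ET1fb
#>   ECM fields: 20
#> Species by module:
#>                input             receptor     second_messenger
#>                   10                   10                    8
#>   kinase_phosphatase                 mapk transcription_factor
#>                   15                   12                    8
#>  mechanotransduction        ecm_precursor   feedback_precursor
#>                   18                   20                    4
#>                other
#>                   27

sim <- run_simulation(scenario_case(2, 30), net,
                      simulation_config(grid_size = 30, seed = 1))
summary(sim, field = "proCI")
#> <ecm_simulation> [case02_tgfb_x] 500 iterations (t = 50), 4 snapshots, 30 x 30 grid
#> Region summary of proCI at each snapshot:
#>   iter    0: inside 0.04835, ring 0.04818, far 0.05158, range [1.503e-05, 0.09993]
#>   iter  100: inside 0.007346, ring 0.002267, far 0.001888, range [0.001504, 0.007946]
#>   iter  300: inside 0.00679, ring 0.001727, far 0.001309, range [0.00102, 0.007341]
#>   iter  500: inside 0.006283, ring 0.001196, far 0.0007361, range [0.0006161, 0.006789]
```

At iteration 0 the three regions are indistinguishable (random initial
noise). As the run progresses, procollagen I accumulates in the stimulated
X (inside ≈ 0.0063 at iteration 500, in normalized concentration units),
a diffusion-fed gradient forms in the adjacent ring (≈ 0.0012), and the
far field relaxes toward its unstimulated baseline (≈ 0.0007) — stimulated
cells synthesize collagen, and paracrine feedback plus ECM diffusion carry
the response a few cell diameters beyond the stimulus.
`plot(sim, "proCI")` renders the final frame with the fixed black-to-yellow
scale used by all heatmap output.

The same run from the shell, with snapshots, heatmap PNGs, probe time
series and a reproducibility manifest written to `out/`:

```sh
Rscript inst/cli/fibrogrid run --reference --case 2 --grid 30 --seed 1 --out out
Rscript inst/cli/fibrogrid census --reference --grid 100
Rscript inst/cli/fibrogrid validate --network inst/extdata/reference_network.yaml
```

(after installation the script is at `system.file("cli", "fibrogrid",
package = "fibrogrid")`). Rate constants can be overridden per run with,
e.g., `--set k_diffusion=0.5`.

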