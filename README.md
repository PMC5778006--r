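# cbfsim

Coupled blood-flow and oxygen-transport modelling for cortical microvascular
networks.

`cbfsim` simulates steady-state haemodynamics and oxygenation in segmented
cortical vascular networks — the kind of node/segment graphs produced by
two-photon imaging and skeletonisation — and runs in-silico neurovascular
experiments on them: single-cell and whole-vessel vasoconstrictions,
constriction cascades along penetrating arterioles, global arteriolar
dilation, and erythrocyte-deformation viscosity changes. Because imaged
networks are rarely shareable, the package ships a seeded generator of
cortical-like synthetic networks (pial vessels, descending penetrating
arterioles, precapillary side branches, a jittered capillary mesh, ascending
venular trees) so every stage of the pipeline is reproducible from a seed.

## The models

**Blood flow.** Each segment is a cylindrical Poiseuille resistor. With
nodal pressures `p_k` and boundary fluxes `Q_0i`, conservation at junctions
reads `Σ_k K_ik p_k = −Q_0i`, where the conductance of segment *j* is
`π d_j⁴ / (128 μ_j l_j)`. The effective viscosity `μ_j(d, H_D)` follows the
empirical in-vivo (endothelial-surface-layer corrected) blood viscosity law,
and discharge haematocrit `H_D` is distributed through the network by the
empirical phase-separation law at diverging bifurcations, iterated with the
flow solution to a joint tolerance of 10⁻³.

**Unknown boundary conditions.** Cortical blocks expose hundreds of cut
vessels with unmeasured boundary values. Unknown boundaries are estimated by
minimising

    ½ k_p Σ_k w_k (p_k − p_0k)² + ½ k_τ Σ_j l_j (τ_j − τ_0j)²

subject to mass conservation and to the known boundary values (a sparse KKT
system in pressures and Lagrange multipliers), with target pressure
`p_0 = 31 mmHg`, target wall shear stress starting at `5 dyn/cm²` with
random signs, and `k_τ` doubled from 10⁻⁴ until two consecutive iterations
give the same flow directions in every segment.

**Oxygen.** Intravascular O₂ is carried as
`f = Q [H_D C₀ S(P_b) + α_eff P_b]` with Hill saturation
`S(P) = Pⁿ/(Pⁿ + P₅₀ⁿ)`; tissue consumption is Michaelis–Menten
`M(P) = M₀ P/(P₀ + P)`. Vessels act as distributions of oxygen sources along
their axes; the tissue PO₂ field is the Green's-function superposition
`P(x) = Σ G(x; x′) q(x′)` with the free-space kernel `G = 1/(4π D α r)`, a
diameter-dependent intravascular resistance `P_v = P_b − K q_v` at the wall,
and a zero-net-monopole closure that enforces global O₂ conservation.

## Worked example

```r
library(cbfsim)

spec <- synthetic_network_spec(seed = 7)
net  <- generate_cortical_network(spec)
net
#> <vasc_network> 569 segments, 366 nodes (16 boundary)
#>   classes: arteriole=64, capillary=489, venule=16

bl <- baseline_solution(net, oxygen = TRUE,
                        config = flow_config(seed = 11))
perfusion(net, bl$state, prod(spec$domain_um))
#> [1] 97.45204    # ml/min/100 g
glance(bl$oxygen)$mean_tissue_po2_mmHg
#> [1] 49.84784    # mmHg
rbc_balance(net, bl$state, bl$bcs)$outflow_mean_hd
#> [1] 0.44977     # inlet haematocrit 0.45 recovered at the outflows

# single-cell (10 µm) constriction of a penetrating arteriole by −19.41%
pen <- subset(net$segments, subtype == "penetrating")$segment_id
res <- run_constriction_experiment(bl, perturbation_spec(
  "constriction", target_segments = pen[3],
  diameter_change = -0.1941, extent = "single_cell_10um"), oxygen = FALSE)
res$throat$velocity_pct
#> [1] 52.89041    # velocity rises at the throat, like constricting a hose

summarize_changes(res, group = "class", metric = "velocity_pct")
autoplot(res)    # box plots with the extreme-outlier rule
```

The numbers above were produced by the code shown (they vary with the
generator seed). A velocity *increase* at the constriction together with a
velocity *decrease* downstream of a propagated (unidirectional) cascade is
the qualitative signature the perturbation experiments probe; flow and
velocity changes are always reported separately, because they can move in
opposite directions.

## Package layout

| file | contents |
|---|---|
| `R/network.R`, `R/io.R`, `R/classify.R` | network data model, CSV/JSON/Amira-SpatialGraph I/O, vessel classification |
| `R/rheology.R` | in-vivo/in-vitro viscosity laws, phase separation |
| `R/flow.R`, `R/haematocrit.R`, `R/converge.R` | Poiseuille solver, boundary-condition estimation, haematocrit propagation, coupled loop |
| `R/oxygen.R` | Green's-function oxygen transport |
| `R/perturb.R`, `R/summaries.R` | constriction / dilation / deformation experiments, box statistics |
| `R/synthetic.R`, `R/fixtures.R` | synthetic cortical generator, canonical fixtures |
| `inst/extdata/*.yaml` | rheology, oxygen and boundary-curve parameter files |
| `vignettes/methods.Rmd` | the methods vignette: models, assumptions, numerical choices, limitations |
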