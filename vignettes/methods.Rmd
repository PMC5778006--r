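---
title: "Models and numerical methods in cbfsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in cbfsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbfsim)
```

`cbfsim` couples three model layers on a segmented vascular graph: Poiseuille
network flow with empirical blood rheology, constrained estimation of unknown
boundary conditions, and Green's-function oxygen transport. This vignette
describes each layer the way we actually compute it — the assumptions, the
tunable parameters with their units and defaults, the numerical choices that
the equations alone do not determine, and what the synthetic-network test bed
does and does not establish about real cortical data.

## The vascular graph

A network is two tibbles: nodes (`node_id`, position in µm, boundary flag)
and segments (`segment_id`, endpoints, diameter and length in µm, an SMA
flag). Segments are cylinders; boundary nodes have graph degree 1 and sit on
the faces of the tissue block. The SMA (α-smooth-muscle-actin) flag is taken
as given — deciding whether mCherry signal lies within 1.5 vessel radii over
90% of a vessel's length is image processing that belongs upstream of this
package.

Classification is a total function of the flags and geometry: SMA segments
are arterioles; non-SMA segments wider than 8 µm whose connected component
touches a boundary node are venules; everything else is capillary. Arterioles
at or above 10 µm are penetrating (the tie at exactly 10 µm goes to the
larger class, because the printed definitions use strict inequalities and a
deterministic rule is needed); those whose both endpoints lie within one mean
segment length of the cortical surface plane are pial. SMA arterioles below
10 µm are precapillary. Capillary branching order is the breadth-first
distance, in segments, from the nearest precapillary/capillary interface.

## Blood flow

Poiseuille flow with conservation at junctions gives the nodal system
$\sum_k K_{ik} p_k = -Q_{0i}$, where $K = L\,M$ is assembled from the signed
segment conductances $\pm \pi d_j^4 / (128 \mu_j l_j)$. The user-facing unit
system is µm, mmHg, nl/min, mm/s, cP and dyn/cm²; the conversion constant
that makes a conductance in nl/min per mmHg is derived exactly from SI
(1 mmHg = 133.322387415 Pa) and is verified in the test-suite against hand
unit conversion.

**Rheology.** The effective viscosity is the empirical in-vivo apparent
viscosity law (plasma viscosity 1 cP by default), which includes the
endothelial surface layer through an effective lumen narrowing
$(d/(d-1.1\,\mu m))^2$; note that this narrowing persists at zero
haematocrit, so the in-vivo law does not reduce to plasma viscosity in the
cell-free limit, and it is monotone increasing as the diameter falls below
about 10 µm. The classical Fåhræus–Lindqvist minimum near 7 µm is a property
of the in-vitro (glass-tube) law, which is also shipped and can be selected
in `inst/extdata/rheology_params.yaml`. Red-cell partition at diverging
bifurcations uses the empirical phase-separation law (coefficients
−13.29 / 6.98 / 0.964 on the $(1-H_D)/d_F$ scale); junctions of degree
greater than three are split sequentially, largest-flow daughter first, and
a daughter clamped at the physical ceiling hands its excess red-cell flux to
its sibling so that the flux balance is exact.

**Boundary-condition estimation.** When boundary values are unknown the
solver minimises
$\tfrac12 k_p \sum_k w_k (p_k - p_{0k})^2 +
 \tfrac12 k_\tau \sum_j l_j (\tau_j - \tau_{0j})^2$
subject to conservation and to the known boundary values, with
$w_k$ half the summed length of the segments adjoining node $k$ and
$\tau_j = 4\mu_j Q_j/(\pi r_j^3)$. The defaults are $k_p = 0.1$,
$p_0 = 31$ mmHg at every node, $k_\tau$ starting at $10^{-4}$ and doubling,
and a target shear of 5 dyn/cm² whose per-segment signs start random (from
the seed in `flow_config()`) and are replaced by the current flow signs; the
magnitude is updated to the length-weighted mean |shear| of the previous
iterate. The loop stops when two consecutive iterates agree in every
direction. Segments whose flow magnitude is below the stagnation floor
(10⁻⁶ nl/min absolutely, or 10⁻⁴ of the network mean |flow| relatively)
carry no meaningful direction and keep their previous sign.

The KKT saddle system is solved by sparse QR (residual checked against
10⁻¹⁰ of the right-hand side); on networks of up to a few dozen nodes the
test-suite compares it against an independently assembled dense solve at
10⁻¹⁰ relative.

**Numerical safeguards in the coupled loop.** Alternating the estimation,
the viscosity law and haematocrit propagation is not a contraction on a
capillary mesh: haematocrit–viscosity feedback produces genuine period-2
limit cycles, and micro-flow segments flip direction indefinitely. Three
safeguards make the loop robust without changing its fixed points:
(i) the estimation is *continued* across outer iterations (signs, shear
weight and target magnitude are warm-started) instead of restarted, and the
shear weight is capped at $k_{\tau,\max} = 10^4$ for conditioning;
(ii) once the relative L2 flow change falls below 1% the flow-direction
pattern, the stagnant set and the estimation objective are frozen, making
the remaining map smooth; and (iii) each segment's haematocrit update is
under-relaxed adaptively (halved whenever the update oscillates in sign,
floor 0.02, recovering to 0.5). Convergence requires the maximum absolute
haematocrit change and the floored maximum relative flow change to fall
below 10⁻³, with an L2 escape (10⁻⁴ of the network flow norm) for the case
where a single near-stagnant segment dithers at the numerical floor.

## Oxygen transport

Tissue PO₂ obeys $D\alpha \nabla^2 P = M(P)$ with Michaelis–Menten
consumption $M(P) = M_0 P/(P_0+P)$; convective transport along a vessel is
$f(P_b) = Q\,[H_D C_0 S(P_b) + \alpha_{\rm eff} P_b]$ with Hill saturation;
conservation gives $df/ds = -q_v$, and the wall jump condition is
$P_v = P_b - K q_v$ with a diameter-indexed intravascular resistance. The
tissue field is the superposition of vessel sources and tissue sinks through
the free-space kernel $G = 1/(4\pi D\alpha r)$.

Parameter defaults live in `inst/extdata/oxygen_params.yaml`:
$D = 2.41\times10^{-5}$ cm²/s and $\alpha = 1.736\times10^{-3}$
µmol cm⁻³ mmHg⁻¹ from the Green's-function oxygen-transport literature;
$C_0 = 22.3$ µmol per cm³ of red cells; $n = 3$, $P_{50} = 38$ mmHg,
$P_0 = 1$ mmHg; $M_0 = 1.71$ µmol cm⁻³ min⁻¹ scaled by 0.825, the midpoint
of the 80–85% operating range of oxygen consumption, giving an exerted
demand of 1.41 µmol cm⁻³ min⁻¹ (both numbers are kept in the file). The
effective blood solubility is approximated by a constant, as the plasma and
red-cell solubilities are close. The intravascular resistance table is a
set of representative magnitudes chosen to give intravascular drops of a
few mmHg at physiological efflux rates; it is deliberately isolated in the
parameter file because no printed values were available to us.

**Discretisation.** Each segment is divided into axial elements no longer
than `max_source_spacing` (each element is one source). Element kernels are
closed-form uniform finite-line-source integrals — with point sources the
wall self-coefficient error is first-order in the element length and the
solution converges unacceptably slowly in the element size; with line
kernels the field at fixed probes changes by less than 1% under twofold
source or grid refinement on the single-vessel fixture, which is the
resolution-independence property the test-suite asserts. Tissue consumption
is represented by point sinks at the cells of a rectangular sampling grid
(equivalent-sphere mean self-potential on the diagonal).

**Conservation closure.** In a strictly free-space formulation the net
monopole of sources plus sinks leaks oxygen to infinity; on a desk-scale
block this leak is not negligible, and it also destabilises the source
solve. We therefore add one scalar unknown — a far-field offset
$P_\infty$ — and one constraint, $\sum q + \sum s = 0$, to the wall-matching
system. Global O₂ balance (inflow − outflow = integrated consumption) then
holds by construction at every iterate, and the test-suite verifies it to
2% end-to-end. The offset plays the role of the homogeneous solution that a
sealed tissue block admits.

**Fixed-point iteration and its safeguards.** Each iteration sweeps the
convective flux along every flow path (junction mixing happens at a common
equilibrium PO₂, because haemoglobin-bound oxygen travels with the red
cells — mixing at a common bulk concentration is wrong and produces
unbounded dissolved PO₂ when blood passes from high- to low-haematocrit
segments), inverts $f \mapsto P_b$ by damped Newton, solves the linear
system for the source strengths, and updates the Michaelis–Menten sinks by
Picard iteration. Blood PO₂ is capped at 1.3× the largest inflow value and
each element's strength is bounded by 25× its per-length share of the total
demand; both caps are inactive at the fixed point and only prevent early
iterates from entering runaway regimes. All updates are under-relaxed
(initially 0.5), and the relaxation shrinks automatically whenever the
residual fails to decrease — this quenches the limit cycles that otherwise
appear around the depletion clamps ($f \ge 0$, $P \ge 0$; clamp events are
counted and reported). Negative tissue PO₂ is clamped to zero.

The Krogh cylinder is the analytic oracle: a single axial vessel with
zero-order consumption (the Michaelis constant set to 0.01 mmHg) inside a
coaxial tissue cylinder of radius 40 µm. The computed mid-height radial
profile is compared with the closed form
$P(r) = P_w + \frac{M}{4D\alpha}(r^2-r_v^2) -
 \frac{M R^2}{2D\alpha}\ln(r/r_v)$, anchored at the innermost sampled ring
because the wall jump is a separately parameterised mechanism; agreement is
within 5% (in practice well under 1%).

## Perturbation experiments

A `perturbation_spec()` names a kind (constriction, dilation, viscosity
scaling), targets, a diameter change, and a spatial extent. A single-cell
constriction splits the target into three colinear pieces and rescales the
central 10 µm (placed at the segment midpoint — the placement is not
specified anywhere, and the midpoint avoids node effects). Whole-vessel
extents rescale the maximal unbranched path of the same class and subtype
through degree-2 nodes. Cascades additionally trace the baseline flow
upstream (largest inflow at each junction) to the adjoining penetrating
arteriole and rescale it — entirely for the bidirectional cascade, only the
surface-ward part for the unidirectional one; pial vessels are not part of
the cascade.

**Boundary policy for re-solves.** Following the constriction protocol,
capillary boundaries are pinned at their baseline pressures (pressure
assumed maintained by adjoining tissue), arteriolar and venular boundaries
at their baseline flows, and the boundary feeding the local penetrating
arteriole — found by tracing the baseline flow upstream to a boundary
node — is set unknown and re-estimated. Two choices make this re-estimation
well behaved. First, the estimation state (signs, weights) is continued from
the baseline. Second, and more importantly, the re-estimation is *anchored
to the baseline*: the target pressures are the baseline nodal pressures and
the target shears the baseline signed shear stresses, so a null perturbation
(0% diameter change) is an exact fixed point of the whole pipeline, and a
real perturbation yields the minimal deviation from the baseline state that
the new geometry and constraints admit. With generic targets instead, the
free boundary lets the optimiser drift away from baseline even with no
perturbation at all, which would contaminate every percentage change.

Percentage changes are $100\,(x' - x)/|x|$ per segment; segments stagnant at
baseline (below the stagnation floor) are excluded from flow, velocity,
haematocrit and PO₂ changes and counted, because a relative change of
numerical noise is meaningless. Flow changes and velocity changes are
computed and reported independently — they are different physical readouts
and routinely disagree in sign at and around constrictions. Box summaries
use type-7 quartiles and the extreme-outlier fences
$q_3 + 3(q_3-q_1)/2$ and $q_1 - 3(q_3-q_1)/2$.

The erythrocyte-deformation experiment selects capillaries whose baseline
segment PO₂ is below 25 mmHg, multiplies their law viscosity by 0.8 (held
fixed through the re-solve), optionally combines this with a +4.5% dilation
of all non-pial SMA vessels, and re-solves flow and oxygen under the
baseline boundary set and baseline-anchored targets.

## The synthetic generator

`generate_cortical_network()` emulates a segmented cortical block in a
420 × 420 × 400 µm³ domain: a jittered cubic capillary lattice (pitch 62 µm,
diameters from a truncated normal with mean 5.5 and sd 1.2 µm inside the
3–9 µm pericyte range, pruned to a mean degree of about 3 but kept connected
through a random spanning tree), two descending penetrating arterioles
(taper 18 → 11 µm, 50 µm steps) each fed by a pial arteriole (20–26 µm)
ending at a domain face, SMA precapillary side branches (5–9 µm) into the
lattice, two ascending venular trunks (13 → 9 µm) with non-SMA capillary
drains and pial venules (12–16 µm), and a dozen capillary stubs cut at the
faces. Everything is drawn from one seeded generator, so the network is a
pure function of its spec.

Baseline boundary conditions mirror the study design: pial arteriolar and
venular boundaries get diameter-dependent pressures from logistic curves
that rise towards 75 mmHg on the arteriolar side and fall towards 15 mmHg
on the venular side around a 31 mmHg capillary pivot, and every other
(capillary) boundary is estimated. Capillary inflow PO₂ follows a declared
exponential depth curve, 60 mmHg at the surface decaying towards 38 mmHg
(its analytic mean is stored with the curve and checked by quadrature);
arteriolar and venular inflows get 90 and 40 mmHg. The curve shapes are
explicit parametrisations committed to
`inst/extdata/boundary_curves.yaml` — the fitted functions they stand in
for were not available to us, so they are declared, not inferred.

**What the generator does and does not establish.** The generator
reproduces the *structural grammar* of a cortical block — classes, diameter
ranges, connectivity, boundary structure — at roughly 500–600 segments, some
fifty times smaller than an imaged network, with two arteriolar and two
venular trees instead of many. Passing tests on it demonstrates that the
solvers conserve mass and oxygen, honour the empirical laws, and reproduce
the qualitative haemodynamic signatures (throat velocity increase under
local constriction, downstream velocity decrease under cascades,
deformation-driven capillary hyperaemia). It does not reproduce the printed
magnitudes of the imaged network: with the same demand parameter and
perfusion in the physiological range, the synthetic block is over-supplied
(oxygen extraction fraction of order 0.1 rather than ~0.5, capillary PO₂
and pressures running high), because short synthetic paths connect
well-oxygenated arterioles to most of the capillary mesh. Those magnitudes
depend on the specific imaged architecture and are out of scope here.

## Problem sizes and tolerances used by the tests

The suite runs entirely on generated objects: cortical networks of ~570
segments (several seeds), a 63-segment binary tree with a single inflow, a
12-segment hand-traceable cascade toy, single-vessel and Y fixtures, and a
Krogh cylinder with a 10 µm grid. Oxygen solves in tests use 35–40 µm grids
and 40 µm source elements; the acceptance script uses the same sizes. The
flow–haematocrit tolerance is 10⁻³ (as in the coupled model definition),
oxygen fixed points iterate to 0.02–0.05 mmHg, O₂ balance closes to 2%, the
Krogh comparison to 5%, and linear-algebra oracles to 10⁻¹⁰.

## Known limitations

* Steady state only: no pulsatility, compliance, or time-dependent solute
  transport.
* The stagnation floor (10⁻⁴ of mean |flow|) declares micro-flow segments
  direction-less; their haematocrit is inherited, not transported.
* The haematocrit fixed point is not unique on meshes with loops; the
  direction-freezing strategy selects the branch continuously connected to
  the uniform-haematocrit start, and a different shear-sign seed can select
  a different micro-state on loop-rich networks (the suite checks
  seed-robustness on tree topologies, where the optimum is unique).
* The far-field-offset closure seals the tissue block; exchange with
  neighbouring blocks (vascular steal) is out of scope.
* Intravascular resistance values are representative, not fitted.
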