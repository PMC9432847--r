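---
title: "A hybrid model of retinal hemodynamics, oxygen transport, and metabolic signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid model of retinal hemodynamics, oxygen transport, and metabolic signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retmicro)
```

# The model

`retmicro` predicts blood flow, oxygenation, and conducted metabolic wall
signals in the retinal microcirculation using a *hybrid* representation: the
arterioles — the vessels that actively regulate flow — are a fully
heterogeneous directed tree, while the capillaries and venules downstream of
each terminal arteriole are lumped into compartments of identical parallel
segments. This keeps the spatial heterogeneity where it matters for
regulation while remaining computationally light downstream.

## Hemodynamics

Each segment carries Poiseuille flow, with conservation of mass at every
junction. Two empirical laws close the system:

* the **in-vivo apparent viscosity law**, a function of diameter and
  discharge hematocrit capturing the Fåhræus–Lindqvist effect. At the 6 µm
  capillary diameter it yields 9.05 cP for hematocrit 0.40 and 1 cP plasma —
  the inlet hematocrit/plasma pair is chosen precisely because it reproduces
  the control-state viscosities at all three control diameters (6, 29.5,
  137.3 µm), which is also how the test suite pins the law down;
* the **phase-separation law** at bifurcations, a logit-linear partition of
  red-cell flux in fractional blood flow with a plasma-skimming threshold.
  Daughter hematocrits are recovered from exact red-cell flux conservation
  and clamped to `[0, 1]` with flux re-balance. At junctions with more than
  two daughters (the inlet fan-out into the four main branches) the daughters
  inherit the parent hematocrit, which conserves flux and avoids applying a
  two-branch law outside its domain.

The solver alternates a sparse linear pressure solve, a single downstream
hematocrit pass (the network is a tree, so one topological sweep is exact),
and an under-relaxed viscosity update (factor 0.5) until the maximum relative
flow change is below 1e-6 (at most 100 iterations). Boundary conditions are
Dirichlet: 40 mmHg at the inlet and 24 mmHg at *every* terminal node — the
fixed 16 mmHg arteriolar drop. Holding each terminal at the same pressure is
the simplest reading of a globally prescribed drop; it makes terminal flows
purely resistance-weighted.

## Arteriolar oxygen transport (Green's function method)

Steady tissue oxygen transport obeys `D·α ∇²P = M(P)` with Michaelis–Menten
consumption (`P₀ = 10` mmHg, demand `M₀` in cm³O₂/100 cm³/min). Vessels are
subdivided into finite source elements; tissue sample points act as sinks.
The PO₂ field is a superposition of free-space kernels
`G = 1/(4π D α |x−x′|)` plus an unknown far-field constant, with an optional
single mirror image across each face of the tissue slab approximating no-flux
boundaries. The linear system enforces (i) the blood PO₂ at every element
surface and (ii) global balance — total vessel efflux equals total tissue
consumption — which closes the free-space formulation. Blood PO₂ is marched
along the flow direction by `df/ds = −q` with the oxygen content inverted
through the Hill curve at each step; at junctions blood PO₂ is continuous and
each daughter rebuilds its content from its own hematocrit, so oxygen flux is
conserved exactly.

Numerical choices that matter:

* **Element self- and near-coupling.** Within a segment, element–element
  coupling uses the exact uniform-line-source coefficient averaged along the
  target element at the vessel-wall radius (the same expression at distance
  zero is the self term). A bare point kernel here makes the first-kind
  system oscillatory at practical element sizes.
* **Cell-averaged sink kernel.** Each tissue point represents a finite cell;
  inside the cell's equivalent-sphere radius the kernel follows the smooth
  uniform-sphere profile instead of the `1/r` singularity. Without this, the
  granularity of the tissue grid imprints on the vessel wall condition.
* **Semi-implicit Michaelis–Menten.** The tissue update solves
  `(I + G_tt D) P = P_∞ + G_tv q` with the sink linearized at the previous
  iterate (`D = M₀ V/(P₀+P_prev)`), damped with factor 0.5 and accelerated by
  Aitken extrapolation of the dominant slow mode; tissue PO₂ is clamped at
  zero. Convergence is declared when the largest PO₂ change is below
  1e-3 mmHg (at most 200 iterations).
* **Tissue sampling.** A regular grid over a thin slab (default 40 µm
  spacing, 200 µm thickness, two z-layers). Points closer to a vessel axis
  than half the grid spacing are excluded — the grid cannot resolve the
  near-wall boundary layer, and such points read spuriously high. For
  network-scale runs the grid is restricted to a perivascular sleeve
  (`tissue_max_dist_cm`), representing the superficial tissue layer the
  arterioles actually serve; the deeper tissue is supplied by the capillary
  compartments of the model's second stage. The slab thickness and boundary
  treatment are configuration choices, not measured quantities, and the
  free-space-plus-images kernel is an implementability compromise: its error
  is quantified against an independent axisymmetric finite-difference solver
  in the test suite (agreement within 5% on a single-vessel instance).

## Compartment construction and the control state

The control state represents a healthy retina: inflow pressure 40 mmHg,
intraocular pressure 15 mmHg (the effective outflow pressure), capillary
diameter 6 µm, capillary wall shear stress 15 dyn/cm², capillary density
50,000/cm², arteriolar network volume 0.0025 cm³. Terminal arterioles are
"small arterioles" (SA); everything upstream is the "large arteriole" (LA)
classification, with the LA diameter taken from the most-upstream vessel of
each pathway. Symmetry assumptions mirror arterioles onto venules:
`n_SV = n_SA = 1`, `n_LV = n_LA = Q_SA/Q_LA`, equal lengths, and venular
diameters from the cube-root wall-shear-rate relation. Wall shear rates are
interpolated from a diameter table; above the tabulated range the maximum
tabulated value is used (measured shear rates are nearly flat at large
diameters).

The published shear-rate-versus-diameter source table is not reproduced here;
the package ships a clearly-synthetic default anchored at the control-state
ratios `τ/μ` (6 µm: 15/9.05 cP ≈ 166 s⁻¹; 69 µm: 15.6/2.28 cP ≈ 684 s⁻¹;
140 µm: 14.7/2.39 cP ≈ 615 s⁻¹) with a 2200 s⁻¹ knot at 20 µm representing
the arteriolar shear-rate peak typical of microvascular design curves. Users
with access to measured values should override `shear_rate_table`.

Venular pressure drops are computed first (Poiseuille), then the capillary
drop is the residual of `P_a − IOP`; a negative residual is reported as an
infeasible control state rather than clamped. Fractional segment counts are
allowed — compartments are continuum descriptions, not integer vessel
counts. The hematocrit used for capillary and venular viscosities defaults
to 0.40 (`hd_capillary = NULL` switches to each pathway's terminal
hematocrit).

The Krogh tissue width `d` solves the capillary-density balance — total
capillary length over total tissue volume (arteriolar volume + capillary
cylinders + venular volumes) equals the prescribed density — by bracketed
root-finding on `[0, 1]` cm; the right-hand side is strictly decreasing in
`d`, so the root is unique. On the default synthetic network the solution is
22.1 µm.

## Capillary oxygen extraction and the zero-clamp

Along each capillary, the bound-oxygen flux `Q H_D C₀ S(P_b)` (plus the
dissolved term `α_b P_b` by default — the compartment flux law omits it in
some formulations, so `include_dissolved` exposes the choice) decreases by
the Krogh-cylinder consumption per length at the local blood PO₂. The radial
problem `D·α (1/r)(r P′)′ = M(P)` with a wall Dirichlet condition and zero
flux at the tissue radius is solved by second-order finite differences on 50
radial nodes with semi-implicit Michaelis–Menten linearization, which
preserves positivity and handles the anoxic limit smoothly. The axial march
is classical fourth-order Runge–Kutta on at least 100 samples; the
consumption-versus-PO₂ curve is precomputed once per demand level on a knot
grid and interpolated by a monotone spline, which removes the per-step
boundary-value solves without measurable loss (the spline is checked against
direct solves in the tests). If blood PO₂ reaches zero, all downstream values
are set to zero and the clamp position recorded. Venules exchange no oxygen
(tissue width zero): their PO₂ equals the capillary outflow value.

The capillary inflow PO₂ of each chain is recovered by inverting the
flow-weighted oxygen content of the terminal arterioles feeding it; with one
terminal arteriole per chain this reduces to that arteriole's outflow PO₂,
but the weighted form is kept for generality.

## Conducted metabolic signal

Each vessel point generates `S_loc = P₀/(P₀+PO₂)`; the conducted signal
satisfies `dS/dx = S_loc − S/L₀` with `x` measured upstream from the outflow
node and `L₀ = 1` cm. The integrator is exact for piecewise-linear `S_loc`
(exponential integrator per interval), and the vessel average follows
analytically as `S_meta = (L₀/L)(∫S_loc dx − S_up + S_out)`, so the
quadrature error is set by profile sampling alone (checked to 1e-6 against
dense brute force). Propagation starts from zero signal at the downstream end
of every large venule, passes LV → SV → C, hands the capillary upstream value
to the terminal arteriole, and walks the tree in reverse-topological order.

At converging junctions the combination rule is genuinely open: the default
adds the daughters' upstream signals (additive conduction, consistent with
superposition in conducted-response models); a flow-weighted mean is
available via `junction_rule = "flow_weighted"`. Both are implemented
precisely because the choice is unsettled; results in this package's
summaries use the additive default.

## The synthetic network

The confocal-image-derived mouse and human networks behind the original
retinal work are unpublished, so `generate_synthetic_tree()` emulates their
stated gross structure: four main branches repositioned to the
superior/inferior temporal/nasal quadrants, heterogeneous tree topology,
uniform terminal-arteriole diameters, and mouse→human scaling hooks
(`scale_network()` with diameter factor 3.6 and length factor 5.9). Daughter
diameters satisfy the Murray relation exactly, with the bifurcation split
fraction drawn uniformly in `0.5 ± jitter/2` and log-normal length jitter;
`jitter = 0` gives a symmetric deterministic tree. Defaults — 140 µm main
branches, 6 bifurcation levels (128 terminals), 20 µm terminals,
length-to-diameter ratio 15, jitter 0.2 — were chosen to land the network on
the observable scales: total inflow ~0.9 × 10⁻³ cm³/s (tens of µL/min, the
measured retinal range), a solved Krogh width of ~22 µm, and mean small-venule
diameters near 29.5 µm. The branch angles of the human retina are not
tabulated anywhere accessible, so they are exposed as parameters rather than
guessed beyond the default quadrant positions.

What the generator does **not** emulate: the tortuosity, space-filling
coverage, and side-branching of real retinal arterioles (segments are
straight chords; the tree is strictly bifurcating), the multilayer capillary
plexus, and venular heterogeneity. Passing tests on this network therefore
demonstrate correct model mechanics and qualitative demand responses, not
quantitative agreement with any individual retina.

## Problem sizes and tolerances

The package defaults (25 µm vessel elements, 40 µm tissue spacing) suit
single-vessel and few-vessel instances, where they are verified against the
finite-difference oracle. Network-scale analyses in the documentation and
test suite use 200 µm elements and a 500 µm perivascular grid on the
128-terminal network — about 900 source elements and 500–1100 tissue points —
which keeps a three-demand sweep to roughly a minute while preserving every
qualitative pattern (monotone PO₂ decline, rising and spreading signal, ~1%
oxygen balance closure). Guards (`max_vessel_elements`,
`max_tissue_points`) fail loudly rather than silently degrade when a
configuration would produce an intractable discretization.

## Degenerate inputs and tie-breaks

Zero demand reproduces the no-sink limit exactly (tissue PO₂ equals the
equilibrated inflow value). Zero-flow daughters at a bifurcation receive zero
hematocrit with all red cells in the flowing branch. A single-segment network
is its own degenerate pathway (its LA and SA diameters coincide). Negative
solved flows flip segment orientation once after the flow solve; with
tree-topology Dirichlet conditions this does not occur in practice.

## Known limitations

* Venules are fixed downstream resistances; variation of PO₂ and signal
  *within* a venular compartment is not represented (venular heterogeneity
  exists only across pathways).
* One retinal layer: the intermediate and deep capillary plexuses are not
  spatially resolved; their oxygen role is lumped into the Krogh
  compartments.
* No flow regulation: the conducted signal is computed but not fed back into
  vessel wall mechanics; diameters are fixed inputs.
* The free-space Green's kernel with slab images is approximate near domain
  edges; the 5% oracle agreement quantifies the effect at single-vessel
  scale.
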