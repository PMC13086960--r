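---
title: "Modeling surfactant-assisted uptake through epicuticular wax nanopores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling surfactant-assisted uptake through epicuticular wax nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waxpore)
```

## The scientific problem

Less than a tenth of the active ingredients (AIs) sprayed onto crop leaves
is typically absorbed. The first barrier an AI meets is the epicuticular
wax, a crystalline hydrocarbon film a few hundred nanometers thick whose
surface exposes terminal CH3 groups. Hydrophilic AIs such as
3-O-methyl-glucose (MG) cannot dissolve in this wax; their uptake appears
to depend on accelerator surfactants — alcohol ethoxylates such as C12E6 —
that penetrate nanometer-scale hydrophobic voids in the wax, dragging
water and AI molecules along as discrete water nanoclusters. Hard water
(Ca²⁺) antagonizes this route by binding to deprotonated carboxylate
groups on the wax surface, displacing the surfactant film.

`waxpore` implements the model-building and analysis machinery needed to
study this mechanism quantitatively at desk scale:

1. **wax builder** — orthorhombic crystalline alkane slabs with a
   cylindrical nanopore and optional COO⁻/COOH surface functionalization;
2. **solution composer** — surfactant monolayers at a target surface
   excess Γ, AI at fixed molar ratio, salts, water, and neutralizing
   counterions, with exact formal-charge bookkeeping;
3. **synthetic trajectory generator** — labeled trajectories with known
   penetration kinetics and water-cluster structure, standing in for a
   molecular-dynamics engine so that every analysis stage has a ground
   truth;
4. **trajectory metrics** — deepest-water penetration depth, per-species
   pore occupancy, density scans, in-pore net charge, discrete
   water-cluster detection;
5. **uptake kinetics** — the foliar-uptake statistic
   $R(t) = -\ln(1 - M_t/M_0)$ and the exponential-saturation depth fit;
6. **free-energy post-processing** — anchored ΔG extraction, penetration
   barriers, the ideal two-surfactant reference surface, and convergence
   RMSDs for adaptive-bias free-energy profiles.

## The wax model

The slab is built from all-trans united-atom alkane chains on the
orthorhombic crystalline n-alkane lattice: subcell constants
$a = 0.742$ nm, $b = 0.496$ nm, two chains per subcell in a herringbone
setting (±45°), chains perpendicular to the (001) surface. With the
default C–C bond of 0.154 nm and a 114° valence angle, the axial rise is
$0.154\sin(57^\circ) = 0.129$ nm per carbon, so a 30-carbon chain spans
$29 \times 0.129 = 3.75$ nm. One **layer** is defined as that backbone
extent plus a 0.40 nm CH3–CH3 interlayer gap (two methyl van der Waals
radii), i.e. 4.15 nm — the package's realization of a wax layer of
"about 4 nm per 30 carbons". The CH3 surface defines $z = 0$; wax
occupies $z < 0$, so penetration depths are negative.

```{r geometry}
lat <- lattice_spec()
axial_rise(lat)
layer_thickness(lat)
slab <- build_crystal_slab(c(6, 6))
slab
```

A 6 nm × 6 nm lateral target rounds to 8 × 12 subcells (192 chains,
realized box 5.936 nm × 5.952 nm). Rounding everywhere is
half-away-from-zero.

### The nanopore

Two carving conventions exist and cannot be satisfied simultaneously on
this lattice: an accessible radius of 0.75–0.8 nm and a removal count of
about fourteen chains. The package treats **by-count carving (14 chains
per layer)** as authoritative and provides by-radius carving with the
convention *accessible radius = chain-axis cut radius − methyl radius
(0.20 nm)* for sensitivity work. The default pore depth of 15 nm spans
the four stacked layers of the pore slab
($\lceil 15 / 4.15 \rceil = 4$). Ties in the nearest-chain ordering are
broken by distance and then ascending chain id, making carving
deterministic.

```{r pore}
pore_slab <- build_crystal_slab(c(6, 6), lattice_spec(layer_count = 4))
carved <- carve_pore(pore_slab, pore_spec())
carved$removed
```

### Surface functionalization

Carboxylate coverage is specified as a fraction of **all** CH3/CH2 carbon
groups in the slab (the working values are 0.5% and 1.5%), realized at
uniformly sampled terminal CH3 sites of the chosen face. On the flat
192-chain C30 slab (5760 carbons), 1.5% gives 86 COO⁻ groups and a wax
charge of −86; 0.5% gives 29. COOH replacement is charge-neutral. A
4-layer slab has more carbons than top-face terminal sites at 1.5%, so
such requests error out rather than silently saturating — the
functionalized reference systems use the flat slab. For
`face = "pore_wall"` the eligible sites are terminal CH3 carbons of
chains within a 0.5 nm shell of the pore cut radius, in every layer the
pore spans; pore-wall carbons count toward the fraction base.

## The solution phase

The composer converts the surface excess into an integer count,
$n = \operatorname{round}(\Gamma A N_A)$ — 76 molecules for
$\Gamma = 3.5\times10^{-6}$ mol/m² on 36 nm² — and reports the *realized*
Γ from that count, which can differ from the request by at most
$1/(A N_A)$. AI counts follow the molar ratio against the total
surfactant count over both interfaces (8:3 for C12E6); the water count
follows from the target AI concentration interpreted as **moles per
liter of water** ($n_w = \operatorname{round}(n_{AI} \cdot 55.5 /
c_{AI})$, default $c_{AI} = 2.2$). Salt molalities use the same
water-based convention. Counterions (Ca²⁺ in hard-water systems, Na⁺
otherwise) make the total formal charge exactly zero; an odd COO⁻ count
facing a divalent counterion re-protonates one site to COOH with a
warning.

Surfactants are coarse bead chains (12 tail beads + head beads) — enough
for counting, density, and charge analyses; force-field topologies are
out of scope. Insertions use a jittered grid (0.31 nm spacing, ±0.015 nm
per axis), which guarantees the 0.25 nm minimum heavy-atom separation by
construction and keeps composition $O(n)$. A consequence is that the
realized water *density* sits slightly below bulk; concentrations are
defined by mole ratios, not by realized volume, so the reported
$c_{AI}$ is unaffected.

```{r compose}
fx <- functionalize_surface(slab, functionalization_spec(fraction = 0.015))
out <- compose_solution(fx, solution_spec(
  salts = data.frame(species = "CaCl2", conc = 1.1), seed = 1))
out$report
ionic_strength("CaCl2", 1.1)
```

## What the synthetic generator emulates — and what it does not

The generator produces depth kinetics directly from the saturation law
$z(t) = -(M_0/B)(1 - e^{-At})$ plus i.i.d. Gaussian noise on the depth,
and pore systems with prescribed water-cluster and ion layouts (cluster
members on a compact 0.28 nm grid, below the 0.35 nm contact cutoff;
bulk-connected clusters get a vertical water bridge crossing $z = 0$).
It validates the *analysis machinery*, not the physics: there are no
forces, no thermal motion, no correlated noise, and cluster shapes are
idealized. Passing tests therefore demonstrate that the estimators
recover known ground truth under the stated noise model — they do not
validate force fields or sampling. Layouts that would merge clusters (or
thread a bulk bridge through another cluster) are rejected as
incompatible rather than silently producing a different ground truth.

Default study conditions for the kinetics recovery study are
$A = 0.02$ ns⁻¹, prefactor 3 nm, $\sigma = 0.05$ nm, 2000 samples over
200 ns — a trace saturating within the typical 200 ns observation window
at sub-nanometer noise.

## Trajectory observables

All metrics operate on molecule centers of mass (mass-weighted; for the
geometry-only 3-site water this is near the oxygen) and honor periodic
boundaries laterally but not along $z$, which the wax slab breaks:

* **deepest-water depth** — per frame, the minimum water COM $z$ among
  waters laterally inside the pore cylinder; averaged over frames. The
  lateral gate (COM within the pore radius) is the package's choice; a
  `discard` fraction (default 0) allows dropping pre-equilibration
  frames.
* **penetration trace** — the same per-frame minimum for a chosen
  species, anchored at its $t = 0$ value.
* **occupancy / net charge** — molecules (or summed molecule charges)
  whose COM lies inside the cylinder at a stated time, default the final
  frame.
* **density scans** — 2-D COM histograms (top or side view) accumulated
  over frames, one grid per species.
* **water clusters** — connected components of the O–O contact graph at
  a 0.35 nm cutoff (first hydration-shell distance; no cutoff is
  standard, this is the package's choice). A cluster is bulk-connected
  if any member sits above $z = 0$; otherwise it is a discrete cluster
  of the kind that stabilizes hydrophilic AIs inside hydrophobic pores.

Every metric is tested against an exhaustive per-molecule oracle on
randomized instances (up to 500 molecules, 100 seeds in the acceptance
suite).

## Kinetics fitting

`fit_penetration_rate()` fits $|z_0 - z(t)|$ to
$\text{prefactor}\,(1 - e^{-At})$ by Levenberg–Marquardt least squares
(no weighting), with starting values prefactor = maximum excursion and
$A = 1/t_{1/2}$. Because $M_0/B$ is a constant lump, only the combined
prefactor is reported — never $B$ or $M_0$ separately. Rates are in
ns⁻¹, with a helper conversion to h⁻¹ for comparison with uptake assays
that run over tens of hours. Noise-free traces recover $A$ to better
than $10^{-6}$ relative; under the default noise conditions the rate is
recovered within 5% in at least 95 of 100 seeded replicates. Flat traces
are rejected as degenerate instead of returning a spurious fit.

## Free-energy post-processing

Profiles live on a reaction coordinate ξ (COM height, nm) in kT units.
The operations follow three fixed conventions:

* the PMF minimum is shifted to 0 kT before every RMSD comparison;
* anchored values interpolate linearly between grid points;
* $N$ in the RMSD definitions is the number of grid points summed over.

With the standard anchors (surface ξ = 3.0 nm against bulk ξ = 0.25 nm;
entrance minima at ξ = 0.7/0.4 nm against the deep-pore ξ = −3.0 nm) the
operations reproduce the definitional adsorption free energies
(−14/−21 kT for C12E6/C12G1) and penetration barriers (16/20 kT) when
given profiles carrying those anchor values. Because the published
anchor/sign conventions are internally inconsistent (a surface anchor at
ξ = 3.0 nm alongside ξ = 0 "at the surface"; a barrier formula whose
literal sign would be negative for an uphill process), anchors are fully
caller-specified and the barrier is reported as a magnitude. The ideal
two-surfactant reference surface is the outer sum of the min-shifted 1-D
profile — exactly symmetric, so its symmetry RMSD is identically zero.
Converged adaptive-bias profiles carry an uncertainty of roughly
±1.5 kT; reports propagate no smaller implied precision.

```{r pmf}
xi <- seq(0, 4, by = 0.01)
prof <- pmf_profile(xi, pmin(0, pmax(-14, -14 * (xi - 0.25) / 1.75)))
free_energy_difference(prof, 3.0, 0.25)
```

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; `run_pipeline()`
derives per-stage seeds from one global seed, so (config, seed)
determines every numeric output, and the same configuration run twice
yields identical results. The test and acceptance workloads use
desk-scale sizes chosen to exercise every code path with exhaustive
oracles: slabs of 48–768 chains, composed systems up to ~40,000 sites,
100-seed recovery studies at 2000 samples per trace, and randomized
metric instances of 30–120 molecules (the oracles are $O(n^2)$, which is
exact and fast at these sizes).

## Known limitations

* The wax model is a pure-alkane crystal: mixed real waxes (esters,
  fatty alcohols), the (100)/(010) surfaces, micrometer roughness, and
  dewaxing dynamics are out of scope.
* The composer builds geometry and bookkeeping, not force-field
  topologies; droplet shape and evaporation are not modeled.
* The synthetic generator cannot stand in for molecular dynamics where
  the physics itself is the question (free-energy surfaces, ion-specific
  solvation); the package post-processes such results, it does not
  produce them.
* Headline simulation observables — adsorption free energies, water
  penetration depths of −0.42/−0.55/−0.66 nm (C12E6) and
  −0.24/−0.27/−0.31 nm (C12G1), uptake counts at 200 ns — require
  hundreds of nanoseconds of force-field MD and are covered here by
  definitional and procedural checks, not by re-simulation.
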