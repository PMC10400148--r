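---
title: "A voxel reaction-diffusion model of C4 photosynthesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A voxel reaction-diffusion model of C4 photosynthesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kranzsim simulates C4 (maize-type, NADP-ME) leaf photosynthesis on a 3D
voxel grid. A run chains four models: a procedural Kranz-anatomy generator,
Monte Carlo photon transport, an electron-transport/ATP-production model,
and a finite-volume reaction-diffusion solver for CO2, HCO3-, and O2. This
vignette describes each model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic tissue does and does not capture.

## The synthetic Kranz anatomy

`generate_kranz_geometry()` builds one concentric Kranz unit: a vascular
cylinder along the leaf's long axis, wrapped in a bundle-sheath annulus
whose outer layer is a centrifugal chloroplast sheet, surrounded by
spherical mesophyll cells packed between two epidermis slabs, with the
remaining interior as intercellular airspace (IAS) and cylindrical stomatal
pores piercing both epidermes (stomatal ratio 1.0). The default desk-scale
grid is 64 x 32 x 84 voxels at 2 um pitch (one air layer above and below
165 um of tissue): the tissue is statistically homogeneous along the vein
axis, so a half-length vein segment carries the same anatomy statistics at
half the computational cost; the full-scale 0.67 um resolution of real
segmented tissue is supported by the same code but is not the default.

Mesophyll cells carry a central vacuole (60% of cell volume), parietal
chloroplast patches, and peripheral cytosol. Bundle-sheath cells are
chloroplast-rich: the measured maize anatomy implies about 54% chloroplast
by volume in the sheath, which is incompatible with a 60% vacuole, so the
sheath vacuole defaults to 20% (both fractions are per-cell-type
parameters). Interveinal mesophyll cells - those whose centroid lies more
than one cell diameter beyond the sheath surface - are slightly smaller and
chloroplast-enriched (36% vs 19% plastid volume): the reported facts that
interveinal cells hold 25% of the mesophyll volume while their chloroplasts
are 18% of all chloroplast volume (with mesophyll:sheath chloroplast near
13:15 um3 per um2 leaf) jointly imply roughly 1.9-fold plastid enrichment
in those cells, and the generator reproduces that covariance.

The generator's composition and packing defaults were calibrated once so
that the reference tissue reproduces measured maize statistics: IAS near
22% of tissue volume, exposed mesophyll surface S_M near 12 m2 m-2,
bundle-sheath surface near 1.9 m2 m-2, and chloroplast volumes near 13
(mesophyll) and 15 (sheath) um3 um-2. Perivein cells are pressed into the
sheath surface (`ring_penetration_factor`) so that the plasmodesmatal
contact area reaches about 1.9 m2 per m2 of leaf, matching the essentially
complete mesophyll wrap of the real sheath; only a thin polar sliver is
left uncovered.

Surface areas are estimated by normal-weighted face counting: raw face
counting overestimates smooth surfaces (3/2 for spheres, 4/pi for
axis-aligned cylinders); weighting each exposed face by the local surface
normal - estimated from the gradient of a box-smoothed indicator - removes
the bias for both phantoms to within about 1% at radius 10 voxels (a fixed
2/3 correction is available for comparison but is biased for cylinders).

What the synthetic tissue does not capture: real cell shapes are lobed and
irregular, real airspace is more tortuous, and the real arrangement of
chloroplasts relative to the incident light is irregular rather than
procedurally parietal. Tests passing on this geometry therefore demonstrate
correct model mechanics and realistic aggregate anatomy, not fidelity to
any particular micrograph.

## Chloroplast movement scenarios

`apply_aggregative_movement()` relocates each mesophyll cell's chloroplast
voxels into the shell of the cell nearest the mesophyll-sheath contact
surface (the plasmodesmatal zones), ranking voxels by breadth-first
distance to the contact faces: this is the voxel equivalent of dilating the
sheath domain, intersecting it with each cell, and filling to the cell's
chloroplast quota. Relocation conserves every label class count exactly per
cell (the displaced vacuole/cytosol voxels swap places with the freed
chloroplast voxels). `apply_avoidance_movement()` applies the same
construction to interveinal cells only. The per-cell conservation tolerance
is configurable (default 10%), although the rank-based construction
conserves counts exactly.

A known limitation, documented deliberately: in a single concentric unit
with per-cell conservation, aggregation leaves the chlorophyll content of
the vertical columns over the sheath nearly unchanged (each cell's cap
lands below the same cell), so the absolute light absorption of the
bundle-sheath chloroplasts under vertical illumination barely increases,
unlike in the real, irregular tissue where the reported increase is large.
Many alternative constructions were evaluated (polar contact gaps with
lifted cells, relocation seeded on the contact surface, per-arrangement
LET fractions, per-arrangement capacity partitions); none produces the
aggregative bundle-sheath gain without breaking the measured anatomy or
the bundle-sheath CO2. The simulator therefore reproduces the directional
responses that do not depend on that gain - transmittance rising strongly
under both movements, mesophyll absorbance dropping, avoidance lowering
assimilation, leakiness rising under both movements - but aggregative
assimilation and ATP decline rather than rise at high light.

## Light propagation

`run_photon_transport()` is a voxel-grid Monte Carlo: photon packets launch
uniformly over the adaxial face at normal incidence, free paths are sampled
from the local extinction coefficient, absorption is deposited by the
albedo-weight method, scattering is Henyey-Greenstein, refractive-index
steps (gas 1.0 / tissue 1.36) apply Fresnel reflection or refraction at
voxel faces, lateral boundaries are periodic (the domain is a symmetric
repeating unit, so the lateral loss is zero by construction), and packets
below weight 1e-4 undergo Russian roulette. The spectral basis is two
wavelengths, 470 and 665 nm, combined 10%/90%.

Chloroplast absorption comes from leaf chlorophyll (539 umol m-2, split
50/50 between mesophyll and sheath) divided by each class's chloroplast
volume per leaf area, times an in-vivo specific absorption coefficient
(defaults 0.00466 m2 umol-1 at 665 nm, 0.00653 at 470 nm). Epidermis,
vacuole, and cytosol absorb weakly (100 m-1). Cell walls are not explicit;
their scattering is lumped into the chloroplast scattering coefficient,
which is a calibration knob: the default 2e5 m-1 with anisotropy 0.90 gives
a transport mean free path well below the leaf thickness, and reproduces a
total absorbance near 0.85, transmittance near 0.06, and a
bundle-sheath:mesophyll chloroplast absorbance ratio near 0.55 on the
reference tissue, close to the published leaf-level optics. Weaker
scattering (2e4 m-1, g 0.95) leaves the tissue nearly ballistic and is
noticeably less realistic.

## Electron transport and ATP production

Per cell class i (mesophyll M, bundle sheath BS), a fraction u_i of
absorbed light drives linear electron transport (LET), the rest cyclic
(CET). The CET fraction follows from the limiting-light rates of the two
photosystems (phi1 = 0.94, phi2 = 0.83) and is scale-free in the absorbed
irradiance; the limiting-light LET efficiency alpha2 and the ATP yield per
LET electron, (2 + fQ - fCET) / (h (1 - fCET)) with fQ = 1 and h = 4,
follow. The LET rate itself is the smaller root of the non-rectangular
hyperbola with convexity theta = 0.97, evaluated voxel by voxel against the
volumetric capacity jmax_i/(d f_i) - so brightly lit chloroplast voxels
saturate locally while dim ones run on the linear limb, exactly as a
spatially resolved light field demands. NADPH production is half the LET
electron flux.

u_M = 0.89 and u_BS = 0.28 and the capacities jmax_M = 138.43 and
jmax_BS = 64.01 umol m-2 s-1 are inputs held fixed across movement
scenarios: they describe thylakoid composition, which chloroplast position
does not change on the movement timescale. A demand-balancing alternative -
choosing u so the produced ATP:NADPH ratio matches a stated demand
(`balance_let_fraction()`), or re-partitioning the capacities between the
classes in proportion to alpha2 x absorbed irradiance per class - is
provided for exploration but off by default; enabling capacity
re-partition is the only setting under which the aggregative arrangement
raises whole-leaf ATP at high light in this geometry.

Whole-leaf ATP splits 40% to the C4 cycle (PEP regeneration, spread
uniformly over mesophyll cytosol) and 60% to the C3 cycle (spread uniformly
over bundle-sheath chloroplasts), at all irradiances; the fluorescence
calibration jATP = s' I (dF/Fm') / (1 - x) with s' = 0.325 supports fitting
jmax from chlorophyll-fluorescence records, with the bundle-sheath capacity
tied to the mesophyll one through the alpha2-weighted absorbed-irradiance
ratio to avoid overfitting.

## Biochemistry

Rubisco carboxylation in sheath chloroplasts is the minimum of the
enzyme-limited rate (Vcmax 78.5 umol m-2 s-1, Km 485 ubar CO2 / 146 mbar
O2, specificity 2862) and the C3-ATP-limited rate; PEP carboxylation in
mesophyll cytosol is the minimum of the bicarbonate-saturated PEPC rate
(Vpmax 183, Kh 0.02 mol m-3) and half the C4-cycle ATP supply.
Decarboxylation releases CO2 uniformly over sheath chloroplasts at the
whole-leaf PEP carboxylation rate. Photorespiration releases 0.5 CO2 per
oxygenation in the sheath cytosol and consumes 1.5 O2 per oxygenation in
the sheath chloroplasts. Day respiration (1.70 umol m-2 s-1) is released at
a single volumetric rate over all respiring tissue (epidermis, both
cytosols, vasculature) chosen so the volume integral equals the leaf value
exactly; the per-class formulation printed with an extra volume-fraction
factor does not integrate to the leaf value, and the conserving reading is
used.

Two parameter reconstructions deserve emphasis. First, several constants
are stored with explicit exponents that published tables truncate:
k1 = 3.9e-2 s-1 (spontaneous hydration; together with k2 = 23 s-1 and the
H2CO3 acid constant 0.2 mol l-1 this reproduces the true H2CO3 pKa near
3.5), Henry's O2 coefficient 3.2e-2, PEPC's Kh = 2e-2 mol m-3, and the CA
equilibrium constant 5.6e-4 mol m-3 with protons expressed in mol m-3.
Second, the carbonic anhydrase capacity must be on the mol scale:
2.1e5 *mol* m-3 s-1. On the umol scale the maximum hydration flux at
physiological CO2 (Vmax C / K_CO2 with K_CO2 = 2.8 mol m-3) would be about
0.16 umol m-2 s-1 of leaf - three hundredfold below the steady PEP
carboxylation it must feed, since in a C4 leaf every fixed carbon passes
through bicarbonate. The mol-scale value keeps mesophyll cytosol within a
fraction of a percent of CA equilibrium, which matches the observable
behaviour of C4 leaves and of the published model.

## Transport and the coupled solve

The state variable is the liquid-equivalent concentration psi: dissolved
concentration in liquid voxels and H x gas concentration in gas voxels
(Henry coefficients 0.83 for CO2, 0.032 for O2), which makes psi continuous
across gas-liquid faces and turns the partition jump into an effective gas
diffusivity D_gas/H. Face conductances are serial resistances: two
half-voxels plus wall (thickness/porosity), membrane (permeability), or
plasmodesmata terms by label pair. The sheath is insulated against the
airspace (suberin); mesophyll and sheath exchange only through
plasmodesmata (porosity 0.03 over 0.354 um of cytosol); the cuticle is
impermeable, so gas enters through the stomatal pores, whose effective
diffusivity is calibrated by secant iteration until the source-free leaf
conductance matches the stomatal target (default 0.2 mol m-2 s-1) within
1%; bicarbonate is confined to the liquid phase with zero membrane
permeability. Ambient air above and below the leaf is a Dirichlet boundary;
lateral domain faces are no-flux.

Because CA exchanges CO2 and HCO3- orders of magnitude faster than
diffusion moves either, the two species are not solved independently in the
cytosol: bicarbonate there is slaved to CO2 (B = rho C, rho = K_eq/[H+] at
pH 7.5, about 17.7), the mesophyll-cytosol carbon unknown diffuses through
both channels (effective diffusivity D_CO2 + rho D_HCO3 - the classic
facilitated-diffusion limit, justified because the CA equilibration
length, sqrt(D/k_CA) ~ 35 nm, is far below the voxel size), and PEPC
enters the carbon equation directly. Outside the cytosol bicarbonate is
kinetically inert (k1 = 0.039 s-1) and is solved as a passive scalar;
bicarbonate exchanged between that passive system and the slaved pool
(through plasmodesmata) is booked back into the carbon equation with its
own-species slope implicit, so total carbon is conserved exactly (a dark
leaf returns A_n = -R_d to five decimal places). The charged bicarbonate
ion is confined to the cytosol: the tonoplast excludes it from the acidic
vacuole (with the printed constants an open tonoplast would set up a
perpetual cytosol-to-vacuole bicarbonate loop), and membranes block it
elsewhere; isolated pools (stroma, vacuole, vasculature) equilibrate to
the spontaneous-hydration equilibrium and carry no net flux. Attempts to
solve the pair with the exchange term split between two scalar solves
stall (each solve only relaxes onto the equilibrium manifold), and a fully
coupled block-Krylov solve works but is several-fold slower; the slaved
formulation is both the fastest and the closest to the physics.

The plasmodesmatal channel uses the pure-water diffusivity rather than the
crowding-corrected cytosol value: the sleeve is an open aqueous channel,
and the published bundle-sheath CO2 back-computes to a mesophyll-sheath
conductance consistent only with the faster reading.

The outer loop is Picard iteration with under-relaxation 0.5 (raised
adaptively once the contraction is smooth): all nonlinear rates are
evaluated at the current fields with the negative part of each rate's
own-species slope folded into the diagonal, the linear systems are solved
by conjugate gradients preconditioned with symmetric Gauss-Seidel (the
strong gas/liquid/membrane conductance contrasts defeat Jacobi scaling),
and iteration stops when the relative change of A_n falls below the outer
tolerance on two consecutive sweeps, followed by one undamped pass so that
the reported fields solve the final linearized systems exactly - this is
what brings the species mass-balance residuals (boundary flux against the
volume-integrated source of the last solve) below 1e-6. The default outer
tolerance is 3e-5 on A_n (floor 1 umol m-2 s-1): the iteration reaches
that level within ~15-20 sweeps, while driving the last decade to 1e-6
costs an order of magnitude more work and changes A_n by ~0.001
umol m-2 s-1 and the bundle-sheath CO2 by ~20 umol/mol - far below every
quantity of interest; the strict value remains available through the `tol`
argument. Negative concentrations are clipped only inside rate
evaluations, never in the solution. Net photosynthesis is the signed
inward CO2 flux across the ambient boundary per leaf area (a dark leaf
yields -R_d); the printed formulation with an absolute value would hide
respiration's sign. Leakiness is L = Vp - A_n - R_M and Phi = L/Vp.

## Orchestration, slices, and the 0-D oracle

`run_aci_curve()` and `run_light_curve()` sweep ambient CO2 and irradiance,
re-using one Monte Carlo light solution per geometry (absorbed fractions
scale linearly with incident flux) and one stomatal calibration.
`run_2d_slice_mode()` extracts anatomical cross-sections (x-z planes at
chosen positions along the vein axis - the only orientation in which a 2D
gas model has an adaxial-abaxial direction), holds the airspace at the 3D
run's mean intercellular concentrations (a 2D slice cannot resolve the
airspace network), restricts the 3D light solution to the slice, and solves
in-plane; the pure-water (eta 1) and viscous (eta 2) variants are both
supported. `well_mixed_oracle()` is an independent algebraic two-compartment
model (mesophyll cytosol with hydration and PEPC; sheath with
decarboxylation, Rubisco, and photorespiration; one plasmodesmatal and one
stomatal conductance) used to cross-check the 3D solver: scaling all
diffusivities and permeabilities by 1e4 drives every compartment uniform
and the two must then agree on A_n to within 2%.

## Problem sizes and defaults used by the shipped checks

The package's own test suite runs the full pipeline on the reference
desk-scale grid (64 x 32 x 84 at 2 um, 1e5 photon packets per wavelength)
for the headline checks and on a coarse 32 x 16 x 44 grid at 4 um for
property tests; the acceptance script uses 1e6 packets per wavelength. At
these sizes a full coupled solve converges in ~18-20 Picard iterations.
On this geometry the converged default state at 1500 umol m-2 s-1 and
380/210 ambient gives A_n ~ 36 umol m-2 s-1, intercellular CO2 ~ 180
umol/mol, leakiness ~ 0.16, and mean bundle-sheath-chloroplast CO2 ~ 2100
umol/mol - about one third above the published full-resolution value,
a gap dominated by the coarse-grid interface legs (three times the
published grid's) and the sphere-packed contact geometry. The
full-resolution regime (0.67 um, ~1e7 voxels) is supported by the same
code paths but takes HPC-scale resources and is out of scope for the
shipped checks.
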