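---
title: "Models and numerical choices in hydrosite"
author: "hydrosite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in hydrosite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hydrosite implements, at desk scale, the computational chain used to
analyse G-protein-coupled-receptor binding sites in terms of probe
interaction fields, explicit water networks and toy-model binding free
energies.  This vignette is the package's own account of the models it
uses, the parameters that matter, and the places where a design decision
had to be made.  Everything quantitative that the vignette mentions is
computed by the test suite or by `scripts/acceptance.R`; nothing here is
an independent empirical claim.

## 1. The probe energy model

Commercial field engines evaluate the interaction of a chemical probe
group (a water, a methyl, an aromatic CH) on a lattice around a protein,
but their parameter tables are proprietary.  hydrosite uses a
transparent surrogate with the same qualitative behaviour:

* **Lennard-Jones**: `E_LJ = eps_ij [(rmin_ij/r)^12 - 2 (rmin_ij/r)^6]`
  with Lorentz-Berthelot combination against a six-class van der Waals
  table (`carbon_sp3`, `carbon_sp2_aromatic`, `polar_N`, `polar_O`,
  `sulfur`, `hydrogen`).
* **Electrostatics**: `E_elec = 332.06 q_p q_a / (4 r^2)` kcal/mol, a
  distance-dependent dielectric (`eps_r = 4r`) as is conventional for
  implicit-solvent grid work.
* **Hydrogen bonds**: a 10-12 radial term with well depth -4.0 kcal/mol
  at r0 = 2.9 Angstrom, multiplied by `cos^2(theta)` against the donor or
  acceptor's ideal direction and cut off 120 degrees from ideal.  Ideal
  directions come from geometry: water oxygens use their two O-H vectors
  plus the anti-bisector, other polar atoms point away from their bonded
  heavy neighbours, and atoms with no neighbours are isotropic.

Probe epsilons are **group-level** (the whole methyl or water, not one
atom), which is why they are an order of magnitude above per-atom
force-field values: OH2 (0.60, 3.20 A), C1= (1.00, 3.70 A), C3 (1.00,
3.90 A).  They were fixed once so that the canonical binding-site motifs
land in the conventional contour ranges: a doubly hydrogen-bonded
hydration site evaluates near -8 kcal/mol with the water probe, and a
snug aromatic subpocket reaches below the -2.7 kcal/mol lipophilic
contour.  Lattice values are clamped at +100 kcal/mol so atom centres
stay finite.

The **DRY** hydrophobic probe is the C3 Lennard-Jones term plus an
entropy reward of -0.85 kcal/mol where a lattice point is buried (at
least half of its 26 half-Angstrom neighbours are inaccessible at the
+1 kcal/mol methyl level), plus a penalty equal to the local water
hydrogen-bond magnitude - the hydrophobic probe is kept out of polar
regions.  **CRY** is the pointwise minimum of C1= and DRY and is the
field used for lipophilic hotspot surveys and water scoring.

Default lattice spacing is 0.5 A.  Hotspots are 26-neighbourhood local
minima at or below a threshold, with greedy suppression keeping the
deepest minimum within 1.5 A.  The standard contour levels are -2.7
kcal/mol for C1=/CRY (with -2.5 also in common use and available as an
argument), -6.0 for OH2, and +1 for the C3 pocket surface.

## 2. Water networks

Placement follows the iterative hotspot-filling protocol: water-probe
hotspots are recomputed with all previously placed waters in the
environment, and accepted - deepest first, skipping anything within the
2.4 A clash distance - while the cutoff is raised from -8 to
-1 kcal/mol in 1 kcal/mol steps (the step size is a package choice; the
endpoints are the protocol's).  Placement is confined to 10 A around
the ligand centroid, or around the pocket centre for apo input.  Each
accepted water's hydrogens are oriented by a 60-orientation trial sweep
plus Nelder-Mead refinement of its explicit interaction energy.
Placement is fully deterministic.

Relaxation replaces the original protocol's short restrained molecular
dynamics with rigid-body Metropolis Monte Carlo (translations up to
0.2 A, rotations up to 15 degrees; optionally ligand moves of 0.1 A /
5 degrees) under the explicit pairwise model.  This serves the same
purpose - annealing the hydrogen-bond network, and letting a mobile
ligand respond to it - while staying deterministic per seed.  For
speed, each move is scored against an environment subpack within about
11 A, refreshed every five sweeps; movers drift at most 0.2 A per
sweep, so the 2.5 A margin keeps the cached neighbourhood valid, and
clash tests are always exact.

Scoring is relative to bulk: the bulk reference is the mean in-context
water-probe energy over the interior waters of a jittered-lattice box at
0.0334 molecules/A^3 (about 1 g/cm^3).  Waters within 8 A of the ligand
(or pocket centre) get

```
dG_est = (E_OH2,context - E_bulk) + lambda_lip * max(0, -E_CRY)
```

with `lambda_lip = 0.5`.  The protocol states that the water and CRY
probes are both used for scoring but not how they combine; this additive
form is the package's choice, picked because it reproduces the
qualitative behaviour the method is known for - waters sitting in strong
lipophilic hotspots score unhappy even when acceptably hydrogen bonded.
Classification bands are the canonical ones: red above 3.5 kcal/mol,
yellow (2.0, 3.5], grey [-1.0, 2.0], blue below -1.0.

## 3. The synthetic world

Every stage is exercised on generated fixtures with known ground truth:

* **Toy cavities** are spherical shells of apolar pseudo-atoms (sparse,
  3 A spacing, so open wall stretches never drop below the -1 kcal/mol
  placement cutoff) enclosing a solvent cavity.  Polar hydration sites
  are pairs of serine-like hydroxyls aimed at the planted position from
  2.9 A; lipophilic sites are cups of aromatic carbons all at the C1=
  Lennard-Jones optimum from the planted position.  An optional
  *adjacent pair* plants a polar site and a cup close together.  Two
  calibrations of that pair are used: 4.0 A separation with a 2.6 A cup
  opening realises the methyl/des-methyl scenario (the cup holds either
  the ligand methyl or, once the methyl is gone, a water), while 3.6 A
  with a 3.1 A opening brings the lipophilic hotspot inside the 4 A
  polar-hotspot adjacency that defines a druggable subpocket.  In the
  4.0 A variant the anchor hydroxyls are biased away from the cup, so a
  des-methyl ligand whose terminal carbon is pulled deeper into the
  half-empty cup stretches its anchor hydrogen bonds - the toy analogue
  of the ligand repositioning that accompanies removal of a buried
  methyl.
* **Toy ligands** are rigid: a polar nitrogen anchored on a hydration
  site, aliphatic linkers, and optionally a terminal methyl seated on
  the lipophilic site; the methyl and des-methyl forms differ by exactly
  one heavy atom.
* **Bulk boxes** put waters on a jittered cubic lattice at bulk density
  with random orientations; the jitter is capped so no O-O pair can fall
  below 2.4 A.
* **Toy landscapes** are one-dimensional: a flat unbound region at
  progress coordinate 0, a Gaussian bound well of stated depth at 1, a
  Gaussian barrier between, soft harmonic walls outside [-0.25, 1.25],
  and an optional Gaussian perturbation on the bound well standing in
  for a binding-site mutation.  One progress unit corresponds to 10 A of
  physical path, which is what makes the conventional adiabatic-bias
  parameters (10 A initial target, 1 kJ/nm^2 spring) meaningful.  The
  ground-truth free-energy difference is the Boltzmann quadrature over
  the state windows [-0.25, 0.25] and [0.75, 1.25].

What a green test does *not* establish: the fixtures reproduce the
energetic motifs the methods consume - hotspots, hydration sites,
enclosure, displacement - not protein structure.  There are no backbone
topologies, no conformational flexibility beyond rigid-body moves, no
long-range electrostatics of a charged binding site, and the bulk box
has no cutoff corrections.  Agreement on fixtures validates the
machinery, not predictions for any real receptor.

## 4. Binding free energies on toy landscapes

Stage 1 runs six consecutive overdamped Langevin segments under the
ratchet bias `E = kappa/2 (rho - rho*)^2` (active only above the
best-yet marker `rho*`, floored at the segment target).  After each
segment the target is divided by 100 and the spring constant multiplied
by 100, starting from 10 A and 1 kJ/nm^2 (2.39e-3 kcal/mol/A^2).  The
concatenated trajectory is resampled uniformly in step index to exactly
102 snapshots.  Because the literal final target (10/100^5 A) is far
below thermal jitter, "binding reached" is checked at 1.0 A, roughly
three per-step thermal displacements.

Stage 2 seeds one walker per snapshot.  Walkers run sequentially under
the landscape plus the shared accumulated bias on a path collective
variable, depositing Gaussians (width 0.1, initial height 3 kcal/mol,
bias factor 50 at 300 K) into a single shared ledger; each deposit's
height is the well-tempered law evaluated against the bias already
present.  The free-energy profile is `F(s) = -(gamma/(gamma-1)) V(s)`,
re-zeroed.

Three numerical choices matter here and were each forced by a failure
mode observable on the toys:

* **Path variable construction.**  A two-frame path variable over a
  10 A one-dimensional path with lambda = 0.6 /A^2 degenerates into a
  near-step function and cannot transmit bias forces, so the variable is
  built from 19 frames laid equally along the binding path and extended
  4 A past both states.  Without the guard frames the variable
  saturates exactly where the bound well sits, walkers deposit
  unopposed, and the end region accumulates runaway bias.  Walkers are
  reflected at the landscape's own domain boundaries, which lie well
  inside the guard range.
* **State windows.**  The bound/unbound windows are the landscape's
  state windows mapped through the path variable, and state free
  energies are Boltzmann integrals of `exp(-F(s)/kT)` over them.  With
  this choice the variable's Jacobian cancels exactly and the estimate
  is directly comparable to the quadrature ground truth; fixed windows
  on [0, 1] with min/mean estimators are not (and fail the symmetric-
  landscape check), though they remain available as overrides.
* **Read-out.**  One hundred and two sequential short walkers with a
  bias factor of 50 anneal their deposition history only
  logarithmically, which leaves a residual imbalance of a few kcal/mol
  in the raw hill sum.  After deposition ends, the bias is therefore
  frozen and 24 walkers sample the biased surface in equilibrium; the
  histogram estimate `F(s) = -kT log rho(s) - V(s)` cancels the residual.
  The ledger and the pure well-tempered reconstruction are kept intact
  and tested separately.

Dynamics use the conventional 0.002 time step with a mobility of 40
A^2 mol/kcal per unit time; per-step displacements are capped at 0.5 A
so the very stiff late-stage ratchet springs stay stable under the
explicit Euler-Maruyama update.  The walker budget (20,000 biased steps
each, deposit stride 50, 16,000-step read-out) was calibrated once
against the convergence property - recovery of the quadrature
free-energy difference within 1 kcal/mol as a five-seed mean, and zero
within 0.5 kcal/mol on a symmetric landscape - and then frozen.

Variant comparison reuses the same reference binding path for every
perturbation, mirroring the protocol's treatment of binding-site
mutants, and reports the free-energy shift against the unperturbed
reference together with a per-seed sign tally.

## 5. Druggability

A subpocket is a lipophilic (CRY) hotspot at or below the lipophilic
threshold.  It is called druggable when a water-probe hotspot lies
within the adjacency radius (4 A - the protocol shows adjacency
visually, never numerically, so the radius is a package choice) *and* at
least one red/yellow water sits within the same radius: the signature of
a pocket where a ligand gains binding energy by displacing frustrated
water.  The report is a per-subpocket table plus free-text flags, not a
scalar score; no scalar druggability index is defined anywhere in the
protocol, and the package does not invent one.

## 6. Known limitations

* The pairwise energy model is a surrogate; absolute probe energies are
  only meaningful relative to its own bulk calibration.
* Monte-Carlo relaxation explores a neighbourhood of the placement
  solution; it will not find rearrangements requiring concerted moves.
* The free-energy machinery is validated on one-dimensional landscapes;
  nothing in the package claims transferability of the toy calibration
  to all-atom systems.
* Water entropy is represented only implicitly (the DRY reward and the
  bulk reference); there is no inhomogeneous-solvation-theory analysis.
* Protonation states and tautomers are whatever the typing table says;
  there is no optimisation of either.
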