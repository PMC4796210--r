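# hydrosite

Energetic analysis of protein binding sites at desk scale, for
computational chemists and structural bioinformaticians working on
pocket druggability and water-aware ligand design (the GPCR setting is
the motivating case, but nothing in the code is receptor-specific).

The package implements four connected pieces of machinery:

1. **Probe interaction fields.** A chemical probe group — water (OH2),
   aromatic carbon (C1=), methyl (C3), hydrophobic (DRY) — is evaluated
   on a lattice around the structure with
   `E = E_LJ + E_elec + E_hb`, where `E_LJ` is a 12-6 Lennard-Jones
   term with Lorentz–Berthelot combination,
   `E_elec = 332.06 q_p q_a / (4 r^2)` (distance-dependent dielectric),
   and `E_hb` is a directional 10-12 hydrogen-bond term with a
   −4.0 kcal/mol well at 2.9 Å scaled by `cos²θ` against the partner's
   ideal geometry. The composite **CRY** probe is the pointwise minimum
   of C1= and DRY and maps lipophilic/hydrophobic hotspots; the C3
   field at +1 kcal/mol defines the pocket surface.

2. **Explicit water networks.** Waters are placed iteratively from OH2
   hotspots (field recomputed after every round, cutoff raised from −8
   to −1 kcal/mol, placement within 10 Å of the ligand), relaxed by
   rigid-body Metropolis Monte Carlo, rescored in context within 8 Å
   (`ΔG = (E_OH2,context − E_bulk) + λ·max(0, −E_CRY)` against a
   calibrated bulk-water box) and classified into the canonical bands:
   red above 3.5 kcal/mol, yellow (2.0, 3.5], grey [−1.0, 2.0], blue
   below −1.0 — "unhappy" red/yellow waters are the ones a good ligand
   displaces.

3. **Druggability.** A subpocket is a CRY hotspot at the −2.7 kcal/mol
   contour; it is druggable when an OH2 hotspot (−6.0 kcal/mol) and at
   least one unhappy water sit within the 4 Å adjacency radius.

4. **Toy-landscape binding free energies.** On one-dimensional analytic
   binding landscapes, an adiabatic-bias ratchet
   (`E = κ/2 (ρ − ρ*)²` active only beyond the best-yet marker ρ*, six
   segments, target ÷100 and κ ×100 per segment) generates a 102-snapshot
   binding path; each snapshot seeds a well-tempered metadynamics walker
   (300 K, bias factor γ = 50, initial hill height 3 kcal/mol, σ = 0.1)
   writing to one shared hill ledger over a path collective variable
   `s = Σᵢ tᵢ e^(−λDᵢ) / Σᵢ e^(−λDᵢ)`; the profile is
   `F(s) = −(γ/(γ−1)) V(s)` and `ΔG_bind = F(bound) − F(unbound)`.
   Every generator ships with quadrature ground truth, so recovery is
   testable.

Everything runs on synthetic fixtures — toy cavity receptors with
planted polar and lipophilic sites, rigid toy ligands, bulk boxes,
double-well landscapes — generated in code with known ground truth. Real
PDB files are read and written too, but nothing requires one.

## Worked example

A compact toy cavity with a hydration site 3.6 Å from an aromatic
subpocket — the druggable-pocket motif:

```r
library(hydrosite)

fx <- make_toy_cavity(2, 1, seed = 5, shell_radius = 10, site_radius = 6.5,
                      adjacent_pair = TRUE, pair_separation = 3.6,
                      cup_clearance = 3.1)
cry <- compute_probe_field(fx$complex, "CRY", grid_around(fx$center, 9))
find_hotspots(cry, -2.7)
#>    x   y    z energy
#> 1 -2 1.5 -6.0  -4.27
#> 2 -3 3.0 -4.5  -3.19

net  <- place_waters_iterative(fx$complex, center = fx$center)
bulk <- calibrate_bulk_reference(make_bulk_box(18, 1))   # -15.17 kcal/mol
net  <- classify_waters(rescore_waters(fx$complex, net, bulk))
net
#> WaterNetwork: 95 waters, 94 scored (classes: blue:49 grey:13 red:24 yellow:8)

assess_druggability(fx$complex, net)
#> DruggabilityReport:
#>  - 1 druggable of 2 lipophilic subpockets
#>  - hotspots span 2.3 Angstrom
#>  pocket volume 1407 A^3
#>   hotspot_energy nearest_polar_hotspot_distance unhappy_water_count druggable
#> 1      -4.273627                       3.937004                   1      TRUE
#> 2      -3.187214                       1.870829                   0     FALSE
```

The two CRY hotspots are the planted subpocket; the deeper one has a
water hotspot 3.9 Å away and one unhappy (red/yellow) water inside the
adjacency radius, so it is flagged druggable — a ligand placing a
lipophilic group there gains the displacement free energy of that
water.

Binding free energy on the default double-well landscape (bound well
−5 kcal/mol, 3 kcal/mol barrier; the quadrature ground truth for the
state difference is −4.06 kcal/mol):

```r
land <- make_binding_landscape(depth_bound = -5, barrier = 3)
path <- run_binding_path(land, seed = 1)     # 102 snapshots, ratchet ABMD
res  <- run_metascore(land, path$snapshots, seed = 42)
res
#> MetaScoreResult: dG_bind = -4.22 kcal/mol (bound 1.95, unbound 6.17; 40800 hills)
```

## Acceptance script

`scripts/acceptance.R` re-runs the protocol-level quantities from
scratch on the installed package — it generates the default landscape,
runs the adiabatic-bias binding-path stage and counts the snapshots it
emits, then runs the shared-hills well-tempered metadynamics stage and
reads the height of the first Gaussian deposited at zero accumulated
bias — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
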