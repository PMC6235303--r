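# crowdsolv

Solvation analysis of nucleic acids in crowded solvents, from classical MD
trajectories.

When a small co-solute ("crowder", e.g. ethylene glycol) is added to a
DNA–water–salt system, it competes with water for the DNA surface: it
displaces first-shell waters, rewires the hydrogen-bond network, slows water
exchange, and shifts the ion atmosphere and the per-water solvation
thermodynamics. `crowdsolv` is an R toolkit for quantifying all of these
effects from trajectory frames, aimed at molecular-simulation practitioners
who want the full solvation battery — structure, kinetics, thermodynamics —
behind one consistent data model, with every estimator validated against
synthetic systems whose statistics are known in closed form.

## What it computes

* **Pair-correlation functions** g(r) = ρ(r)/ρ°, normalized by the bulk
  density of the same system (ρ° = molecules / mean box volume), with
  first-peak/first-minimum detection and trapezoid coordination numbers
  CN = ∫₀^rm ρ°·4πr²·g(r) dr.
* **Hydrogen bonds** by the geometric criterion d(D···A) ≤ 3.5 Å and
  ∠D–H–A ≥ 135° (inclusive), classified WW / WE / EW / EE / SW / SE / SS with
  whole-system and local (≤ 7 Å from the solute surface) normalization, and
  per-pair maximum continuous lifetimes.
* **Solvation shells and kinetics**: molecule-level shell membership
  (any probe atom within 3.5 Å of any solute atom), waters replaced per
  crowder (N⁰_w − N_w)/N_c, minor-groove water-spine counts, residence
  times / MRT from occupancy series, and Einstein diffusion coefficients
  D = slope(MSD)/6.
* **Voxel solvation thermodynamics** (GIST-style): per-voxel water density
  g(r_k) = N_k/(ρ°·V_k·N_f), solute–water and half-assigned water–water
  energies (Coulomb 332.0636·qᵢqⱼ/r + 12-6 LJ, Lorentz–Berthelot),
  first-order translational entropy
  TΔS = −k_B·T·Σ_k (N_k/N_f)·ln g_k / N̄, region summaries per water, the
  assembly ΔG = ΔE_sw + ΔE_ww − TΔS_trans, OpenDX density export, and the
  end-state binding free energy per crowder from externally supplied
  solvation terms.
* **Ion distributions in curvilinear-helicoidal coordinates** (D, R, A)
  around the duplex axis: molarity maps (1660.539 Å³·M per molecule), 2D
  marginals, and minor/major-groove occupancy (minor: A ∈ [33°, 147°],
  R ≤ 10.25 Å, D ∈ [2, 22]).
* **DNA structure**: quaternion-superposition RMSD/RMSF, axis end-to-end
  distance and bending angle, Hassan–Calladine-style groove widths
  (cross-strand P–P minus 5.8 Å), essential-dynamics PCA, and eigenvector
  similarity indices γ (subspace overlap) and ζ (eigenvalue-weighted,
  interchange-sensitive).
* **Synthetic trajectory generators** — uniform (ideal-gas) boxes, radial
  density profiles, two-state Markov shell occupancy with analytic mean
  residence time dt/(1 − p_stay), ideal double-helix and exact
  hydrogen-bond fixtures, Brownian walkers, rigid three-site waters — so
  every estimator is testable without reference MD data.

Input formats: PDB topologies (species classes assigned per residue name
from a YAML config, with per-atom charges and LJ parameters), multi-model
PDB or extended-XYZ trajectory frames with orthorhombic boxes.

## Worked example

A solute site at the centre of a 20 Å box, surrounded by solvent with a
first shell at 2.8 Å over an excluded core and unit background:

```r
library(crowdsolv)

b <- box(20, 20, 20); ctr <- c(10, 10, 10)
solv <- generate_radial_profile_box(
  function(r) 4 * exp(-(r - 2.8)^2 / (2 * 0.35^2)) + ifelse(r < 2.4, 0, 1),
  n = 270, b = b, n_frames = 800, reference = ctr, seed = 1)

a <- solv$topology$atoms
top <- make_topology(name = c("P", a$name), resname = c("REF", a$resname),
                     resid = c(1L, a$resid + 1L),
                     species = c("SOLUTE", a$species),
                     element = c("P", a$element))
coords <- array(0, c(271, 3, n_frames(solv)))
coords[1, , ] <- ctr; coords[-1, , ] <- solv$coords
traj <- trajectory(top, coords, b)

g  <- compute_pcf(traj, ref_sel = 1, target_sel = 2:271,
                  bin_width = 0.1, r_max = 8)
ex <- find_first_extrema(g)
cn <- coordination_number(g, ex$r_min)
cat(sprintf("first peak at %.2f A (g = %.2f), first minimum at %.2f A, CN = %.2f\n",
            ex$r_peak, ex$g_peak, ex$r_min, cn))
```

```
first peak at 2.85 A (g = 4.69), first minimum at 4.25 A, CN = 20.09
```

The detected peak sits within one bin of the constructed shell position
(2.8 Å), and the coordination number is the integral of the shell plus
background up to the first minimum at the system's own bulk density
(0.0338 molecules/Å³ here, close to neat water).

Residence kinetics against an analytic ground truth, and the free-energy
and replacement arithmetic used for the region thermodynamics:

```r
occ <- generate_markov_occupancy(p_stay = 0.9, p_enter = 0.1,
                                 n_molecules = 500, n_frames = 3000,
                                 dt = 0.1, seed = 1)
residence_times(occ$series, occ$dt)
#> residence: 74945 stays, MRT = 1.004 ps        (analytic: 1.0 ps)

gist_free_energy(de_sw = -4.0760, de_ww = 2.5469, tds_trans = -0.2313)
#> [1] -1.2978                                   (kcal/mol per water)

replacement_ratio(743.09, 470.32, 134.44)
#> [1] 2.028935                                  (waters per crowder)
```

A config-driven batch mode (`run_pipeline()` /
`inst/scripts/crowdsolv.R run --config config.yaml`) executes the enabled
stages in dependency order and writes per-stage TSV/OpenDX outputs plus a
JSON summary; re-running an identical config reproduces the summary
bit-identically.

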