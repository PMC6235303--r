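---
title: "Methods: solvation analysis of a nucleic acid in a crowded solvent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solvation analysis of a nucleic acid in a crowded solvent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdsolv)
```

# The problem

A duplex DNA in water with salt and a small neutral crowder (ethylene glycol
is the motivating case) is a five-component system in which the crowder
competes with water for the solute surface. The analyses in this package
quantify that competition from classical MD trajectory frames along three
axes: *structure* (pair correlations, shells, grooves, ion distributions),
*kinetics* (residence times, hydrogen-bond lifetimes, diffusion), and
*localized thermodynamics* (voxel-based inhomogeneous solvation theory).
The package assumes orthorhombic periodic boxes, a species class
(`SOLUTE, WATER, CROWDER, CATION, ANION`) assigned to every molecule by
residue name, and frames stored at a fixed interval `dt`.

# Data model and geometry

All distance-based stages use the minimum-image convention in an
orthorhombic box; triclinic cells are rejected at the reader level rather
than silently mishandled. Atom and frame indices are 1-based throughout,
the natural R convention (file formats that are 1-based anyway are
unaffected). Hydrogen–heavy bonding, needed for donor assignment, is taken
from the topology when supplied and otherwise inferred by an intra-residue
distance criterion (< 1.2 Å), which is robust for standard geometries and
fails loudly (a hydrogen without a heavy partner simply never donates).

# Pair correlations and coordination numbers

`compute_pcf()` histograms minimum-image reference–target distances with a
uniform bin width (default 0.1 Å, the resolution at which hydration-shell
features are conventionally resolved) and normalizes each shell by
`rho_bulk * V_shell`. Two decisions matter:

* **Normalization is system-specific.** `rho_bulk` is the target species'
  molecule count divided by the *mean box volume of the same trajectory*.
  In crowded systems the bulk density of each species changes with
  composition, and normalizing by anything else silently distorts
  cross-concentration comparisons. An override argument exists for
  fixtures with a known analytic density.
* **Self and intramolecular pairs are excluded.** Solvent-structure g(r)
  is a between-molecule quantity; counting an atom against its own
  molecule produces spurious short-range peaks.

`find_first_extrema()` scans a centered moving average (default window
5 bins; the smoothing used for extremum detection is not standardized in
the literature, so the window is exposed) for the first local maximum with
smoothed g > 1, then the first local minimum after it; ties break toward
smaller r so plateaus resolve deterministically. If g never turns back up,
the last bin is returned with a warning rather than an error, since a
monotone tail is a legitimate (if unconverged) outcome.

`coordination_number()` integrates `rho0 * 4 pi r^2 g(r)` by the trapezoid
rule on the bin centers, augmented with the exact endpoints r = 0 (where
the integrand vanishes identically) and r = r_m (g interpolated linearly).
Without the endpoint terms a 0.1 Å grid loses several percent of the
integral; with them the quadrature error for smooth profiles is far below
the 1% documented accuracy, and halving the bin width moves smooth-profile
CNs by < 0.5%.

# Hydrogen bonds

The detector is purely geometric: donor–acceptor distance ≤ 3.5 Å and
D–H–A angle (at the hydrogen) ≥ 135°. Both cutoffs are *inclusive* — the
criterion is stated as a cutoff, and boundary geometries are accepted — and
the comparisons carry a 1e-9 numeric guard so exactly-on-the-boundary
fixtures are classified deterministically. A donor with two hydrogens may
bond two different acceptors simultaneously, but one (donor, acceptor)
pair counts once per frame even if both hydrogens qualify; without this
rule lifetime runs would double-count. Class labels follow donor→acceptor
direction (WE = water donates to crowder, EW the reverse); solute classes
(SW, SE, SS) are direction-agnostic. The "local" region contains a bond if
*either* endpoint (donor heavy or acceptor) is within 7 Å of any solute
atom — the endpoint rule is a documented choice; a bond-midpoint rule
would differ only for bonds straddling the boundary. Normalizers count
molecules with any atom in the region, matching the molecule-level shell
convention. Lifetimes are maximal runs of consecutive frames with strict
continuity (one broken frame ends a run); no intermittent/autocorrelation
kinetics are attempted because presence/absence per stored snapshot is the
quantity of interest.

# Shells, residence times, diffusion

Shell membership is molecule-level: a solvent molecule belongs to the
first solvation shell if any of its probe atoms is within the cutoff
(default 3.5 Å) of *any* solute atom, hydrogens included. The default
probe is the water oxygen (the conventional water position proxy) and
every atom for crowders and ions, so an ethylene glycol counted by one
hydroxyl is in the shell — whole molecules occupy the shell, not atoms.
The waters-replaced-per-crowder statistic is the difference formula
`(N_w(0%) - N_w(c)) / N_c(c)` on mean shell counts. Averaging
per-trajectory ratios instead gives values differing in the second decimal;
the difference formula is implemented because it is the stated definition
and is exactly reproducible from reported mean counts.

Residence analysis converts per-molecule occupancy series into stay
records by run-length encoding. Stays touching either end of the series
are *censored*; they are included in the MRT by default (dropping them
biases the estimate low, since long stays are the most likely to be cut),
and a flag allows the exclusive convention. An all-absent series signals
an undefined MRT (`NA` with a warning) instead of fabricating a zero.

`msd_diffusion()` computes MSD over lag times in a user window with
non-overlapping time origins by default (overlapping origins are offered
but correlate successive displacements), fits a line, and reports
D = slope/6. Coordinates must be unwrapped; the generators produce
unwrapped walks. The fit's R² is checked (default threshold 0.99) so
ballistic or caged motion is flagged rather than silently converted into a
diffusion coefficient.

# Voxel thermodynamics

The voxel grid (default 0.5 Å spacing, the conventional resolution for
hydration maps) accumulates, per frame, each water whose **oxygen** lies in
a voxel: a visit count, the water's full interaction energy with the
restrained solute, and **half** of its interaction with every other water.
The half-assignment makes voxel and region sums additive — summing E_ww
over all voxels recovers the total water–water energy exactly, which is
locked by a double-loop conservation test at 1e-8 kcal/mol. When a region
sum is referenced per water against the neat-water value `Eww0` (the *full*
mean interaction energy per water), the half convention is undone by the
factor 2 in `gist_region_summary()`. Because the reference convention of
other implementations may differ by this bookkeeping, the convention here
is documented and oracle-tested rather than assumed interchangeable.

Energies use Coulomb 332.0636 kcal·Å/(mol·e²) and 12-6 Lennard-Jones with
Lorentz–Berthelot combination, full minimum-image sums by default (the
intended systems are small; a cutoff flag exists). The solute must be
identical across frames to 1e-6 Å — voxel maps around a moving solute are
meaningless — and only SOLUTE and WATER species may be present;
`strip_species()` removes crowders and ions first, so the crowders enter
only through the volume they exclude in the configurations.

The entropy term is the first-order translational expression
`TdS = -kB T sum_k (N_k/N_f) ln g_k / N_mean`; orientational entropy is
deliberately not implemented (its quaternion-neighbor estimator converges
far too slowly for trajectories of this scale to be trustworthy), and the
free-energy assembly `dG = dE_sw + dE_ww - TdS_trans` therefore excludes
it. For an ideal gas every term vanishes in the sampling limit; for any
strictly structured density the entropy term is negative by Jensen's
inequality — both are property-tested.

# Helicoidal ion coordinates

The duplex axis is a least-squares straight line through the per-level
C1'–C1' midpoints (strand II is taken antiparallel: residue j pairs level
n+1−j). A straight axis is an approximation adequate for a short,
nearly straight duplex and exact for the synthetic fixtures; externally
computed curved axes can be supplied per frame and are validated for
orthonormality. D is the continuous level coordinate from projection onto
the (piecewise) axis, R the perpendicular distance, and A the azimuth from
the level's long-axis reference about the tangent by the right-hand rule.
The reference direction is C1'(strand II) → C1'(strand I), orthogonalized
against the tangent and oriented so that the minor groove of an ideal
B-form fixture falls at A = 90°, inside the conventional minor-groove
window [33°, 147°]; the window values fix only the groove *width*, so the
zero direction is anchored constructively by the fixture and locked by a
test. Histogram bins are 1/6 level in D, 0.5 Å in R, 5° in A; bin volumes
use the curvilinear metric `dD·rise × R·dA × dR` at the bin-center radius,
and molarity is `counts / (n_frames · V_bin) × 1660.539`. Marginal maps
divide summed counts by summed volumes, so every marginal conserves the
total visitation count.

# DNA structural metrics

Superposition uses the quaternion (Horn) method — exact, reflection-free —
verified against both a Kabsch-SVD oracle and a numerical optimizer.
RMSF superposes all frames onto their mean structure (two-pass) and
averages per-atom fluctuations per residue, mass-unweighted. The bending
angle is midpoint-hinged: straight axes are fitted to each half of the
level midpoints and the angle between their directions subtracted from
180° (180° = straight); the end-to-end distance spans the first and last
points of the global straight fit. Groove widths follow the
cross-strand P–P construction: for each interior level, the minor (major)
raw width is the minimum P–P distance to partner-strand levels offset in
the 5' (3') backbone direction (default offsets 0…6 and −6…0, exposed in
the interface), minus 5.8 Å for the two phosphate van der Waals radii.
Terminal pairs are excluded; physically clashed fixtures return negative
widths with a warning rather than clamping.

Essential-dynamics PCA eigendecomposes the 3N×3N covariance of the fitted
ensemble (default selection: solute heavy atoms); eigenvalue order is
descending, rank deficiency truncates with a warning, and the eigenvalue
sum equals the total positional variance to 1e-8. The similarity indices
compare two sets of n = 10 leading eigenvectors: γ is the subspace overlap
(mean squared inner product, the squared RMSIP), 1 for identical
subspaces, 0 for orthogonal ones, invariant under within-set permutation;
ζ weights diagonal overlaps by eigenvalue importance,
`sum_i w_i (a_i·b_i)² / sum_i w_i` with `w_i = sqrt(λ^A_i λ^B_i)`, so it is
1 only for identical sets in identical order and drops when eigenvectors
interchange. These closed forms are this package's choices; they satisfy
the defining properties of the index pair (range, permutation behavior,
interchange sensitivity) and are locked by constructive tests.

# What the synthetic generators do and do not emulate

The generators supply *statistical* ground truth, not physics. Frames are
i.i.d. in space (uniform or radial-profile placements), Markovian in shell
occupancy, or Brownian in displacement; the helix is rigid and ideal; the
hydrogen-bond fixture is a single exact geometry. This is precisely what
the estimators consume — densities, run lengths, displacement variances,
rigid geometry — so a passing suite certifies the *estimators*, not any
force field: real trajectories add correlated dynamics, finite-size and
cutoff artifacts, and conformational flexibility that no synthetic test
here represents. Structural tests use single-site waters; energetic tests
use rigid three-site waters (0.9572 Å, 104.52°) because water–water
energies need charge geometry. Radial profiles are realized by rejection
sampling (simple and exact for bounded profiles; an unbounded profile is
an error) rather than inverse-CDF.

# Numerical choices and degenerate inputs

* Boundary comparisons (hydrogen-bond cutoffs) carry a 1e-9 guard;
  extremum ties break toward smaller r.
* The pipeline validates its whole config before running and reports every
  offending field at once; a failing stage aborts its dependents only.
* Degenerate inputs fail loudly: empty selections, all-absent occupancy,
  fewer than 4 helix levels, zero-length reference vectors, `r_max`
  beyond half the box, moving solutes in voxel accumulation.
* Problem sizes in the test suite were chosen so the full suite runs in
  about a minute on one CPU while keeping Monte-Carlo assertions several
  standard errors away from their tolerances: 1e5-sample statistics for
  the ideal-gas g(r), voxel entropy, groove-window occupancy and
  Kolmogorov–Smirnov checks; ≥ 1e5 stays for the residence-time recovery;
  exact brute-force equalities on systems of a few hundred atoms.

# Known limitations

* Orthorhombic boxes only; no triclinic support.
* No orientational entropy; the voxel free energy is the translational
  assembly only, and its water–water reference convention, while
  self-consistent and conservation-tested, may differ from other codes by
  an additive bookkeeping constant.
* The straight-fit axis is not a curvilinear helical axis; strongly bent
  duplexes need externally supplied axes.
* No base-pair-step helical parameters, no binary trajectory formats, no
  intermittent hydrogen-bond kinetics, and the integral-equation solvation
  terms consumed by `binding_free_energy()` must be computed externally.
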