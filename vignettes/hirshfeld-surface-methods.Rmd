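---
title: "Hirshfeld surfaces and model interaction energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hirshfeld surfaces and model interaction energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how `hirshfeldr` computes what it computes: the
models, the tunable parameters and their defaults, the numerical choices,
what the synthetic fixtures do and do not emulate, and the known
limitations.  It is the place to look before trusting a number.

# The stockholder partition

For a molecule $M$ in a crystal, the stockholder weight is

$$w_M(\mathbf r) = \frac{\sum_{a \in M} \rho_a(|\mathbf r - \mathbf R_a|)}
                        {\sum_{a \in \text{crystal}} \rho_a(|\mathbf r - \mathbf R_a|)},$$

where $\rho_a$ is a spherically averaged, neutral, ground-state atomic
electron density and the denominator runs over every symmetry and lattice
image whose density reaches $\mathbf r$.  By construction
$0 \le w \le 1$ and $\sum_M w_M = 1$ everywhere (the package tests this
partition of unity to $10^{-9}$ at 1000 random points per fixture).  The
$w = 0.5$ isosurface is the Hirshfeld surface (HS).

Two practical consequences deserve emphasis:

* **Junction gaps.** $w_M > 0.5$ requires a strict majority.  Along
  edges where three or more molecules meet, no molecule reaches 0.5, so
  the HSs of all molecules do not quite fill the cell.  With the shipped
  atomic densities the gap is a few percent of the cell volume (about
  6.6% for the urea fixture).  The gap region is exactly the
  low-density interstitial space: adding the 0.002 a.u. procrystal void
  volume to the HS volumes recovers the urea cell volume to 0.4%.  In
  *sparse* model crystals this bookkeeping breaks down — the HS extends
  into regions whose density is below the void isovalue, so HS and void
  volumes overlap and their sum exceeds the cell.  The tiling identity is
  therefore a well-packed-crystal property, not a universal one.
* **Density floor.** Where the procrystal density falls below
  $10^{-15}$ e/bohr³ (deep voids of very sparse models) the weight is
  returned as 0 with a warning rather than as 0/0.

# Atomic densities

The default $\rho_a$ are radial tabulations generated by the package's
own `atomic_scf()`: a spherically averaged, spin-unrestricted
Hartree–Fock atom with fractional per-$m$ occupations (each $m$ component
of an open subshell carries $n_{nl}/(2l+1)$ electrons of its spin, which
keeps the density exactly spherical), solved in a large even-tempered
Gaussian basis with the package's integral engine.  Energies reproduce
the HF limit to microhartrees for closed-shell atoms (H $-0.500000$,
He $-2.861678$ vs $-2.861680$); open-shell atoms sit above their
(non-spherical) ground-term references by the expected spherical-averaging
penalty, which is immaterial for density work.  The hydrogen density
matches the exact $e^{-2r}/\pi$ to ~$5\times10^{-4}$ relative out to
6 bohr.  Tabulations are shipped as plain-text 200-point log grids
(`inst/extdata/atomic-densities/`, format documented in
`write_density_grid()`), resampled internally to a finer uniform-log grid
for fast linear interpolation; all 36 elements H–Kr integrate to $Z$
within $10^{-3}$ electrons.

An analytic fallback/reference source is also built in: single-zeta
Slater-type-orbital shell densities (Clementi–Raimondi best single-zeta
exponents for H–Ar, Slater's-rules exponents for K–Kr), exact sums of
exponential terms that integrate to $Z$ by construction
(`atomic_density(..., source = "sto")`).  Single-zeta valence tails are
systematically too compact — switching urea from STO to the HF grids
moves the O⋯H+H⋯O contact share from 32.3% to 36.8% — which is why the
HF tabulations are the default.  Users can substitute their own
tabulations per element with `read_density_grid()`; the provenance of the
active table is reported by `atomic_density_provenance()`.

Neutral atoms are used even for ionic species; charged-species densities
are out of scope and results for salts should be interpreted accordingly.

Per-element cutoff radii (where $\rho_a < 10^{-10}$ e/bohr³, ~7–25 bohr)
bound all neighbor gathering; the truncation error is orders of magnitude
below mesh resolution.

# Isosurface extraction

Scalar fields are sampled on axis-aligned Cartesian grids and contoured
by **marching tetrahedra**: each grid cube is split into six tetrahedra
sharing the body diagonal, a translation-invariant decomposition whose
shared faces split along matching diagonals, so meshes are watertight
with no ambiguous configurations.  Vertices are linearly interpolated
along crossing edges, then refined by bisection against the exact field
to $|f - f_\text{iso}| < 10^{-4}$ (times the isovalue scale), because
$d_\text{norm}$ and fingerprints are sensitive to vertex placement.
Winding is outward (positive enclosed volume).

Resolution presets: low 0.8 Å, medium 0.5 Å, high 0.2 Å grid spacing;
high is the default for quantitative work and all headline numbers.
These values are this package's declaration of the conventional
"surface resolution" knob.  Hirshfeld grids pad the molecule bounding box
by 2.5 Å (auto-expanded once if the surface touches the boundary).
Sphere benchmarks: area and volume within 2% of analytic at 0.2 Å, with
errors decreasing monotonically under grid refinement.

Void surfaces contour the procrystal density (default 0.002 a.u.) over a
region of unit cells; points outside the region count as high density so
the mesh closes at the region boundary, and volumes are reported per unit
cell.  Thin void sheets narrower than the grid spacing are partially
missed: on urea the 0.2 Å mesh volume is ~10% below a fine voxel count,
whereas on an open structure with fat voids the two agree to 0.01%.
Use a finer spacing when thin channels matter.

# Surface properties

* `d_i`/`d_e`: exact nearest-atom distances (brute-force scan, C++) to
  the molecule's own atoms and to the environment cluster; the cluster
  radius grows automatically until every `d_e` is well inside it.
* `d_norm`: the vdW-normalized sum using Bondi radii with the 1.09 Å
  hydrogen variant (`vdw_radius()`), shipped as a swappable table since
  the choice visibly shifts $d_\text{norm}$ maps.
* Fragment patches: connected same-label regions where the label is the
  neighbor molecule owning the nearest external atom; patch areas always
  sum to the total area.
* Curvature: principal curvatures from a quadric fit over the 2-ring
  vertex neighborhood in the tangent frame (3-ring fallback for
  degenerate rings).  Convention: outward normals, convex positive, so
  spheres have shape index $+1$; shape index
  $S = (2/\pi)\arctan((\kappa_1+\kappa_2)/(\kappa_1-\kappa_2))$ with
  $S = \pm 1$ at umbilics, curvedness
  $C = (2/\pi)\ln\sqrt{(\kappa_1^2+\kappa_2^2)/2}$.  The original
  program's exact normalization is not published; these forms are this
  package's declared choice, validated on spheres and saddles.

# Fingerprints

The fingerprint is the area-weighted histogram of $(d_i, d_e)$, default
range 0.4–2.6 Å with 0.01 Å bins (an expanded 0.4–3.0 Å mode is a flag
away); out-of-range area is accumulated separately and warned about.
Contact percentages are computed from exact vertex areas, never from bin
counts, so element-pair percentages sum to 100 to $10^{-6}$ regardless of
binning.  Decomposition on meshes coarser than the high preset warns.
For a crystal of identical molecules related by translation the
fingerprint is diagonal-symmetric up to binning error and the junction
regions (where a third molecule competes, $d_e$ slightly exceeds the
swapped $d_i$); the tests verify the asymmetry shrinks with bin size.

Plot exports (PNG raster, SVG/EPS vector rectangles) are hand-emitted and
byte-deterministic; the color ramp is fixed (log-like blue→green→red
against a constant reference) so plots of different structures are
comparable, and masked (greyed) bins render the non-matching remainder.

# Wavefunctions and the integral engine

Monomer wavefunctions enter only through Molden files ([Atoms] in Å or
bohr, [GTO] with s/p/d and sp shells, [MO]; [5D] spherical-d honored;
f shells and ECPs are rejected).  The package never computes molecular
wavefunctions; their provenance (e.g. matching the B3LYP/6-31G(d,p)
calibration level) is the user's responsibility and only warned about.
Every contracted function is renormalized to unit self-overlap on load,
absorbing writer-dependent normalization conventions; the invariant
$\mathrm{Tr}(PS) = N$ is tested to $10^{-6}$.

All integrals (overlap, kinetic, nuclear attraction at arbitrary centers,
electron repulsion) come from a built-in McMurchie–Davidson engine over
Cartesian Gaussians (C++), validated against textbook H₂/STO-3G matrix
elements, numerical quadrature, and point-charge closed forms.  ESP
fields are analytic density-contracted attraction integrals; electric
fields use central differences of the ESP (step $10^{-3}$ bohr).

# The energy model

Raw terms, all in kJ/mol (1 hartree = 2625.499639 kJ/mol):

* $E_\text{ele}$: nuclear–nuclear + nuclear–electron + electron–electron
  Coulomb between unperturbed monomer densities.
* $E_\text{pol} = -\tfrac12\sum_A \alpha_A |F_B(A)|^2 + (A\leftrightarrow B)$
  over isotropic free-atom polarizabilities (shipped table, swappable);
  fields from the partner wavefunction, or from user-supplied point
  charges as an explicitly approximate fallback.
* $E_\text{dis}$: Grimme D2 with the published $C_6$/$R_0$ parameters and
  damping steepness $d = 20$; the global scaling is deliberately *not*
  applied — the model's own $k_\text{dis}$ plays that role.
* $E_\text{rep}$: first-order Heitler–London energy of the
  antisymmetrized product of the frozen closed-shell monomer determinants
  minus the monomer energies and $E_\text{ele}$ — the operational form of
  the Su & Li / Hayes–Stone exchange + repulsion sum.  Tested against an
  independent Löwdin-orthogonalized dense-matrix assembly to $10^{-8}$
  relative and for exponential decay.

The scale factors (CE-HF for HF/3-21G monomers: 1.019/0.651/0.901/0.811;
CE-B3LYP for B3LYP/6-31G(d,p): 1.057/0.740/0.871/0.618) live in one
versioned constants block (`energy_model()`); raw terms are always
reported alongside the scaled total.

Neighbor enumeration uses crystallographic symmetry: neighbors within a
closest-contact radius (default 3.8 Å) are grouped into classes by an
exact test — a space-group operation mapping the unordered pair onto the
unordered pair, so inverse pairs merge — and each class is computed once,
with the seed wavefunction mapped onto the neighbor by rotating
basis-function coefficients (s/p/Cartesian-d blocks; improper operations
included).  Lattice energies are
$\tfrac12\sum \text{multiplicity} \times E_\text{tot}$ with a radial
convergence trace; the default table radius for lattice sums is 15–25 Å
by plain radial convergence (no Ewald/Wolf acceleration, so charged or
strongly dipolar lattices converge slowly and should be treated with
care).

Energy frameworks place a node at every whole molecule of a supercell and
an edge where the selected *scaled* component (the sidecar records this
choice) exceeds a cutoff (default 5 kJ/mol); edges copy their class row
from the table, never recompute.  Export is a colored PLY of 16-gon
cylinders (radius ∝ |E|, capped at half the shortest edge; electrostatic
red, dispersion green, total blue/gold for binding/non-binding) plus a
JSON sidecar that round-trips the graph.

# Crystal handling

CIF reading covers the core tags: cell, symmetry as explicit
`_symmetry_equiv_pos_as_xyz`/`_space_group_symop_operation_xyz` operator
lists or a Hermann–Mauguin symbol resolved through a small internal table
of common groups, and the atom-site loop.  Disorder keeps the
highest-occupancy component per disorder group and drops sub-0.5
occupancy sites with a warning.  Fractional coordinates are wrapped to
[0, 1); all module boundaries speak Cartesian Å.

Bonds: Cordero-style covalent radii + 0.4 Å tolerance.  Molecules are
completed across symmetry images and lattice translations by breadth-first
growth; a base atom reachable under two different lattice shifts means a
periodic (polymeric) network, which is rejected, as is growth past a
configurable atom limit.  Symmetry-equivalent molecules are identified as
one species by an element-count + distance-multiset fingerprint.

X–H bond lengths are optionally normalized to neutron-derived values
(C–H 1.083, N–H 1.009, O–H 0.983, B–H 1.180 Å) via
`normalize_h_positions()`; bridging hydrogens are left alone with a
warning.  Formal charges for molecular ions are never inferred from a
CIF; they are explicit user input to the polarization fallback.

Deterministic ordering is enforced everywhere (neighbor lists sorted by
centroid distance then lattice key; patch tables by area), so outputs are
byte-reproducible.

# Fixtures: what they emulate

* `cubic_atom` — one atom in a P1 cube: trivial symmetry, void baseline.
* `diatomic` — an N₂-like molecule split across a cell boundary in a
  well-packed P1 cell: periodic molecule completion and the reference
  surface for the shared-isovalue check.
* `hbond_dimer_crystal` — two HF molecules with a 1.6 Å F–H⋯F contact:
  hydrogen-bond contact analysis without symmetry.
* `urea_like` — the urea structure (published tetragonal cell,
  neutron-quality coordinates embedded as an offline stand-in): the
  realistic multi-molecule test bed; reproduces urea's textbook
  H-bonding (each O accepts 2 × 2.00 Å + 2 × 2.06 Å).
* `acetic_like` — an idealized acetic-acid monomer placed in the
  published space-group setting; labelled synthetic, used for
  structural (Z = 4, one species) tests only.
* `molden_h2` — H₂/STO-3G with the analytic minimal-basis MO
  coefficient $1/\sqrt{2(1+S_{12})}$.

These fixtures exercise every code path but are small and high-symmetry:
passing tests demonstrate correctness of the algorithms, not the
robustness of CIF parsing against the full wildness of deposited files
(esoteric dialects, heavy disorder, polymeric frameworks are rejected
rather than handled).

# Problem sizes and runtime choices

Quantitative surfaces use the 0.2 Å preset (~10⁴–10⁵ grid points, ~10⁴
vertices; seconds per molecule).  Test-suite meshes use the medium preset
where only bookkeeping is under test.  Energy tests use H₂ toys (2–4
basis functions) where the quartic-scaling plain integral loops are
instantaneous; the engine is adequate up to mid-sized monomers
(~100 basis functions) but makes no claim to production-DFT speed.
Atomic SCF tabulation (the one-off generation of the shipped density
grids) takes seconds for s/p elements and about a minute per 3d element.

# Known limitations

* The urea "two fragment patches" statement from the original program's
  worked example is not reproduced as a global count: with the full
  O⋯H+H⋯O element filter the highlighted area decomposes into one
  acceptor cap plus three donor regions (four connected regions; six
  neighbor molecules are involved, matching urea's H-bond topology).
  The count of two corresponds to a partial fingerprint selection in a
  particular view, which is inherently interactive and not a
  well-defined batch quantity.
* Four-term energies require externally computed monomer wavefunctions;
  no quantum-chemistry back end is bundled and the package never runs
  molecular SCF.
* Neutral-atom promolecules; no relativistic or charged-species
  densities; elements H–Kr.
* No adaptive grids, mesh decimation, or interactive rendering; no Ewald
  summation for lattice energies; f-function and ECP wavefunctions are
  rejected.
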