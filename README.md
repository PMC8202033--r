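# hirshfeldr

Hirshfeld surface analysis and model intermolecular interaction energies
for molecular crystals, in R.

Molecular crystals are held together by intermolecular interactions, and
understanding a crystal structure largely means understanding which
contacts its molecules make and how strongly they bind.  `hirshfeldr`
implements the two standard quantitative tools for that question:

1. **Hirshfeld surfaces and fingerprint plots.**  The stockholder weight
   of a molecule in its crystal is

   $$w(\mathbf{r}) = \frac{\rho_\text{promolecule}(\mathbf{r})}
                           {\rho_\text{procrystal}(\mathbf{r})},$$

   the ratio of the molecule's superposed spherical-atom density to that
   of the whole crystal.  The $w = 0.5$ isosurface — the Hirshfeld
   surface (HS) — partitions the crystal into non-overlapping molecular
   regions.  Decorating it with the contact distances $d_i$ and $d_e$
   (nearest atom inside/outside), the vdW-normalized
   $d_\text{norm} = (d_i - r^\text{vdw}_I)/r^\text{vdw}_I +
   (d_e - r^\text{vdw}_E)/r^\text{vdw}_E$, curvature measures, fragment
   patches, or wavefunction-derived properties (electron density,
   electrostatic potential, orbital and deformation densities) summarizes
   a molecule's entire packing environment; the area-weighted 2D
   histogram of $(d_i, d_e)$ is the *fingerprint plot*, decomposable by
   element-pair contacts.

2. **Scaled four-term pair interaction energies.**  For a pair of
   molecules with frozen monomer wavefunctions (read from Molden files),

   $$E_\text{tot} = k_\text{ele} E_\text{ele} + k_\text{pol} E_\text{pol}
     + k_\text{dis} E_\text{dis} + k_\text{rep} E_\text{rep},$$

   with the classical Coulomb energy between unperturbed monomer charge
   distributions, a polarization term from isotropic atomic
   polarizabilities in the partner's electric field, Grimme's D2
   dispersion, and the Hayes–Stone/Su–Li exchange-repulsion; the
   $k$ factors are the published CE-HF and CE-B3LYP calibrations.
   Symmetry-unique neighbor pairs are detected from the crystal's space
   group, summed into lattice-energy estimates, and rendered as *energy
   frameworks* (cylinder graphs with radius ∝ |E|).

Everything — CIF parsing, symmetry expansion, molecule completion,
spherical atomic densities, marching-tetrahedra isosurfaces, Gaussian
integrals for the quantum terms — is self-contained; the only external
inputs are a CIF file and, for quantum properties and energies, monomer
Molden files.

The package is aimed at crystallographers and computational chemists who
want scriptable, reproducible Hirshfeld-surface and interaction-energy
analyses (batch processing, custom statistics over surfaces, method
development) rather than an interactive viewer.

## Worked example

A urea crystal (bundled offline stand-in with published cell and
neutron-quality coordinates) analysed end to end:

```r
library(hirshfeldr)

cr <- read_cif(make_fixture("urea_like"))
cr
#> crystal 'urea_like': 5 asymmetric-unit atom(s), 8 symop(s)
#> unit cell  a=5.5780 b=5.5780 c=4.6860 A  alpha=90.000 beta=90.000 gamma=90.000 deg  V=145.801 A^3

mols <- complete_molecules(cr)
mols[[1]]
#> molecule: CH4N2O (8 atoms, 7 bonds)

mesh <- hirshfeld_surface_properties(cr, mols[[1]], resolution = "high")
mesh
#> trimesh: 10044 vertices, 20084 faces, area 89.103 A^2, volume 67.818 A^3
#>   channels: field, w, d_i, d_e, d_norm

contact_percentages(mesh)
#>   inside outside   percent
#> 2      H       H 42.417499
#> 4      H       O 36.845414
#> 3      H       N 11.612344
#> 1      C       H  9.124743

dec <- decompose_fingerprint(mesh, inside = "O", outside = "H",
                             include_reciprocal = TRUE)
round(dec$percent, 1)
#> [1] 36.8

tab <- interaction_energy_table(cr, mols[[1]], radius = 4.2, terms = "dis")
tab[, c("class", "symop", "R", "n_class", "E_tot")]
#>   class         symop        R n_class      E_tot
#> 1     1   y-1, -x, -z 4.452762       4 -7.7786994
#> 2     2     x, y, z-1 4.686000       2 -6.3646344
#> 3     3 y-1, -x, -z+1 4.734902       4 -6.0792896
#> 4     4     x-1, y, z 5.578000       4 -1.4615788
#> 5     5   x-1, y-1, z 7.888483       2 -0.3194847
```

The surface encloses 67.8 ų of the 145.8 ų cell (two molecules per
cell, the remainder being interstitial space and small 0.002 a.u. void
pockets).  Hydrogen-bonding O⋯H/H⋯O contacts cover 36.8% of the surface
area.  The dispersion-only energy table lists the five symmetry-unique
neighbor classes within a 4.2 Å contact radius, with the operator
relating the pair, the centroid distance `R` and the class multiplicity;
`E_tot` here is the scaled dispersion term only (full four-term energies
need a monomer wavefunction, `wfn = read_molden(...)`).

A batch command-line interface wraps the same functions:

```sh
inst/cli/hirshfeldr fingerprint --cif urea.cif --inside O --outside H --reciprocal --out results/
```

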