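Package: hirshfeldr
Title: Hirshfeld Surface Analysis and Model Interaction Energies for
    Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads crystal structures from CIF files, expands
    crystallographic symmetry and perceives whole molecules, and partitions
    crystal space with the stockholder (Hirshfeld) weight function built from
    spherical atomic electron densities.  Extracts triangulated Hirshfeld,
    promolecule-density and crystal-void isosurfaces, decorates them with
    contact-distance (d_i, d_e, d_norm), fragment-patch and curvature
    (shape index, curvedness) properties, and summarizes intermolecular
    contacts as area-weighted two-dimensional fingerprint plots with
    element-pair decomposition.  Consumes monomer wavefunctions from Molden
    files through a built-in Gaussian-integral engine to map electron
    density, electrostatic potential, orbital and deformation densities onto
    surfaces, and computes scaled four-term pairwise intermolecular
    interaction energies (electrostatic, polarization, Grimme D2 dispersion,
    exchange-repulsion) for symmetry-unique molecular pairs, with energy
    frameworks and lattice-energy estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
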