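test_that("unit cell round-trips fractional and Cartesian coordinates", {
  cell <- unit_cell(5.2, 6.3, 7.1, 83, 95, 102)
  expect_gt(cell$volume, 0)
  set.seed(7)
  f <- matrix(runif(30), ncol = 3)
  expect_lt(max(abs(cart_to_frac(cell, frac_to_cart(cell, f)) - f)), 1e-10)
})

test_that("symmetry operators parse, format and compose", {
  op <- parse_symop("-x+1/2, y+1/2, z+1/2")
  expect_equal(op$rot, diag(c(-1, 1, 1)))
  expect_equal(op$trans, c(0.5, 0.5, 0.5))
  expect_equal(symop_to_string(op), "-x+1/2, y+1/2, z+1/2")
  ## composition: inversion o inversion = identity
  inv <- parse_symop("-x,-y,-z")
  id <- compose_symops(inv, inv)
  expect_equal(id$rot, diag(3))
  expect_equal(id$trans, c(0, 0, 0))
})

test_that("urea-like operator set is a closed group of order 8", {
  cr <- fixture_crystal("urea_like")
  expect_length(cr$symops, 8)
  expect_true(check_symop_closure(cr$symops))
  ## brute-force closure double-check on all 64 compositions
  keys <- vapply(cr$symops, hirshfeldr:::symop_key, character(1))
  for (a in cr$symops) for (b in cr$symops) {
    expect_true(hirshfeldr:::symop_key(compose_symops(a, b)) %in% keys)
  }
})

test_that("minimal P1 CIF parses and inversion doubles a general position", {
  cr <- fixture_crystal("cubic_atom")
  expect_length(cr$symops, 1)
  expect_equal(nrow(cr$asym), 1)
  expect_equal(expand_unit_cell(cr)$element, "Ne")
  ## general-position atom under P-1
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(6, 6, 6), lapply(c("x,y,z", "-x,-y,-z"), parse_symop),
            data.frame(element = "C", label = "C1", fx = 0.21, fy = 0.33, fz = 0.05),
            tmp)
  expect_equal(nrow(expand_unit_cell(read_cif(tmp))), 2)
})

test_that("read_cif reports missing tags and unsupported elements", {
  tmp <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_a 4"), tmp)
  expect_error(read_cif(tmp), "_cell_length_b")
  writeLines(c("data_x",
               "_cell_length_a 4", "_cell_length_b 4", "_cell_length_c 4",
               "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
               "loop_", "_symmetry_equiv_pos_as_xyz", "  'x,y,z'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "  U1 U 0 0 0"), tmp)
  expect_error(read_cif(tmp), "unsupported element")
})

test_that("space-group symbols resolve through the internal table", {
  tmp <- tempfile(fileext = ".cif")
  writeLines(c("data_x",
               "_cell_length_a 5", "_cell_length_b 6", "_cell_length_c 7",
               "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
               "_symmetry_space_group_name_H-M 'P 21/c'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "  C1 C 0.1 0.2 0.3"), tmp)
  cr <- read_cif(tmp)
  expect_length(cr$symops, 4)
  expect_true(check_symop_closure(cr$symops))
})

test_that("bond perception follows covalent radii plus tolerance", {
  ## two C atoms at standard bond length -> 1 bond; far apart -> none
  expect_equal(nrow(perceive_bonds(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))), 1)
  expect_equal(nrow(perceive_bonds(c("C", "C"), rbind(c(0, 0, 0), c(4, 0, 0)))), 0)
  ## water: O-H 0.96 A twice, H..H 1.51 A not bonded (hand check: O-H cut
  ## 0.66+0.31+0.4 = 1.37; H-H cut 0.31+0.31+0.4 = 1.02)
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.32, 0.905, 0))
  b <- perceive_bonds(c("O", "H", "H"), xyz)
  expect_equal(nrow(b), 2)
  expect_setequal(paste(b[, 1], b[, 2]), c("1 2", "1 3"))
})

test_that("molecules are completed across periodic boundaries", {
  cr <- fixture_crystal("diatomic")
  mols <- complete_molecules(cr)
  expect_length(mols, 1)
  expect_length(mols[[1]]$element, 2)
  expect_equal(as.numeric(stats::dist(mols[[1]]$xyz)), 1.1, tolerance = 1e-8)
  ## generator traces every atom to the asymmetric unit
  expect_true(all(mols[[1]]$generator$asym_idx %in% seq_len(nrow(cr$asym))))
})

test_that("urea-like cell completes to two 8-atom molecules of one species", {
  mols <- complete_molecules(fixture_crystal("urea_like"))
  expect_length(mols, 2)
  expect_equal(vapply(mols, function(m) length(m$element), 0L), c(8L, 8L))
  expect_equal(unique(vapply(mols, `[[`, 0L, "species")), 1L)
  ## stoichiometry: CO(NH2)2
  expect_equal(sort(table(mols[[1]]$element)),
               sort(table(c("C", "O", "N", "N", "H", "H", "H", "H"))))
})

test_that("acetic-like Z=4 cell gives four molecules, one species", {
  mols <- complete_molecules(fixture_crystal("acetic_like"))
  expect_length(mols, 4)
  expect_equal(unique(vapply(mols, function(m) length(m$element), 0L)), 8L)
  expect_equal(unique(vapply(mols, `[[`, 0L, "species")), 1L)
})

test_that("cluster radius search matches a brute-force supercell scan", {
  cr <- fixture_crystal("urea_like")
  seed <- complete_molecules(cr)[[1]]
  radius <- 3.5
  cl <- cluster_within_radius(cr, seed, radius)
  ## brute force: all molecules in a 5x5x5 supercell of images
  base <- complete_molecules(cr)
  hits <- 0
  for (t1 in -2:2) for (t2 in -2:2) for (t3 in -2:2) for (b in seq_along(base)) {
    cand <- hirshfeldr:::translate_molecule(base[[b]], cr$cell, c(t1, t2, t3))
    if (hirshfeldr:::same_molecule(cand, seed)) next
    if (hirshfeldr:::min_intermolecular_distance(seed$xyz, cand$xyz) <= radius) {
      hits <- hits + 1
    }
  }
  expect_equal(length(cl), hits)
  ## deterministic order: centroid distances non-decreasing
  cd <- vapply(cl, function(m) sqrt(sum((m$centroid - seed$centroid)^2)), 0)
  expect_true(all(diff(cd) > -1e-9))
})

test_that("tiny radius yields no neighbors", {
  cr <- fixture_crystal("urea_like")
  seed <- complete_molecules(cr)[[1]]
  expect_length(cluster_within_radius(cr, seed, 0.5), 0)
})

test_that("a very large radius on a P1 cell finds all 26 first-shell images", {
  cr <- fixture_crystal("cubic_atom")
  seed <- complete_molecules(cr)[[1]]
  cl <- cluster_within_radius(cr, seed, 4 * sqrt(3) + 0.01)
  expect_equal(length(cl), 26)
})

test_that("slabs replicate the unit cell exactly", {
  cr <- fixture_crystal("urea_like")
  ua <- expand_unit_cell(cr)
  s1 <- generate_slab(cr, c(1, 1, 1))
  expect_equal(nrow(s1), nrow(ua))
  s331 <- generate_slab(cr, c(3, 3, 1))
  expect_equal(nrow(s331), 9 * nrow(ua))
  ## 2x2x2 positions match brute-force lattice enumeration
  s222 <- generate_slab(cr, c(2, 2, 2))
  brute <- do.call(rbind, lapply(0:7, function(k) {
    t <- c(k %% 2, (k %/% 2) %% 2, k %/% 4)
    frac_to_cart(cr$cell, sweep(as.matrix(ua[, c("fx", "fy", "fz")]), 2, t, `+`))
  }))
  got <- as.matrix(s222[, c("x", "y", "z")])
  ord1 <- do.call(order, as.data.frame(round(got, 6)))
  ord2 <- do.call(order, as.data.frame(round(brute, 6)))
  expect_lt(max(abs(got[ord1, ] - brute[ord2, ])), 1e-8)
})

test_that("H normalization rescales X-H bonds and preserves heavy geometry", {
  ## C-H at 0.93 A -> 1.083 A along the same direction
  m <- hirshfeldr:::new_molecule(c("C", "H"), rbind(c(0, 0, 0), c(0.93, 0, 0)),
                                 c("C1", "H1"), NULL)
  m2 <- normalize_h_positions(m)
  expect_equal(as.numeric(m2$xyz[2, ]), c(1.083, 0, 0), tolerance = 1e-10)
  ## no hydrogens -> identity
  m3 <- hirshfeldr:::new_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                                  c("C1", "O1"), NULL)
  expect_equal(normalize_h_positions(m3)$xyz, m3$xyz)
  ## urea molecule: all heavy-atom pairwise distances preserved
  mol <- complete_molecules(fixture_crystal("urea_like"))[[1]]
  mol2 <- normalize_h_positions(mol)
  heavy <- mol$element != "H"
  expect_equal(as.matrix(stats::dist(mol2$xyz[heavy, ])),
               as.matrix(stats::dist(mol$xyz[heavy, ])), tolerance = 1e-10)
  ## N-H bonds now at the standard length
  hb <- mol2$bonds[apply(mol2$bonds, 1, function(b) any(mol2$element[b] == "H")), ]
  lens <- apply(hb, 1, function(b) sqrt(sum((mol2$xyz[b[1], ] - mol2$xyz[b[2], ])^2)))
  expect_true(all(abs(lens - 1.009) < 1e-8))
})

test_that("symmetry-unique pair classes partition the neighbor list", {
  cr <- fixture_crystal("urea_like")
  seed <- complete_molecules(cr)[[1]]
  up <- unique_molecule_pairs(cr, seed, 3.8)
  members <- attr(up, "members")
  expect_equal(sum(up$n_class), length(members))
  expect_equal(as.integer(table(members)), up$n_class)
  ## every class reports a parseable mapping operator
  expect_false(any(up$symop == "unresolved"))
  for (s in up$symop) expect_s3_class(parse_symop(s), "symop")
})

test_that("pair classes agree with a brute-force RMSD-matching oracle", {
  cr <- fixture_crystal("urea_like")
  seed <- complete_molecules(cr)[[1]]
  up <- unique_molecule_pairs(cr, seed, 3.8)
  nbrs <- cluster_within_radius(cr, seed, 3.8)
  members <- attr(up, "members")
  ## oracle: pair fingerprints via sorted element-labelled cross distances
  fp <- vapply(nbrs, function(m) {
    d <- c(outer(seq_along(seed$element), seq_along(m$element),
                 Vectorize(function(i, j) sqrt(sum((seed$xyz[i, ] - m$xyz[j, ])^2)))))
    lab <- c(outer(seed$element, m$element,
                   function(a, b) paste(pmin(a, b), pmax(a, b))))
    paste(sort(paste(lab, round(d, 3))), collapse = "|")
  }, character(1))
  ## same class => same fingerprint
  for (k in unique(members)) {
    expect_length(unique(fp[members == k]), 1)
  }
  ## different classes => different fingerprints
  expect_equal(length(unique(fp)), nrow(up))
})

test_that("pair classes are invariant to the choice of seed image", {
  cr <- fixture_crystal("urea_like")
  seed <- complete_molecules(cr)[[1]]
  seed2 <- hirshfeldr:::translate_molecule(seed, cr$cell, c(1, 0, 1))
  up1 <- unique_molecule_pairs(cr, seed, 3.8)
  up2 <- unique_molecule_pairs(cr, seed2, 3.8)
  expect_equal(nrow(up1), nrow(up2))
  expect_equal(sort(up1$n_class), sort(up2$n_class))
  expect_equal(sort(round(up1$R, 6)), sort(round(up2$R, 6)))
})

test_that("polymeric networks are rejected", {
  ## chain of C atoms along a short axis: every image bonds to the next
  tmp <- tempfile(fileext = ".cif")
  write_cif(unit_cell(1.5, 8, 8), list(parse_symop("x,y,z")),
            data.frame(element = "C", label = "C1", fx = 0, fy = 0, fz = 0), tmp)
  expect_error(complete_molecules(read_cif(tmp)), "polymeric|periodic")
})

test_that("XYZ export writes valid blocks", {
  mol <- complete_molecules(fixture_crystal("urea_like"))[[1]]
  tmp <- tempfile(fileext = ".xyz")
  write_xyz(mol, path = tmp, comment = "urea molecule")
  lines <- readLines(tmp)
  expect_equal(as.integer(lines[1]), 8)
  expect_length(lines, 10)
})
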